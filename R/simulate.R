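#' Configuration for the synthetic feature-table generator
#'
#' Describes a multi-group untargeted LC-MS study: a medium blank (`LB`),
#' pooled-QC injections (`QC`), and bacterial culture groups, with a fixed
#' number of replicates per group. Intensities are log10-normal
#' (multiplicative noise); the dispersion defaults are free parameters of the
#' generator, chosen to look like a well-behaved LC-MS batch.
#'
#' @param n_features_per_mode Number of features to simulate.
#' @param groups Group labels; must include `"LB"` and `"QC"`.
#' @param n_reps_per_group Replicates per group (default 6).
#' @param baseline_log_mean Mean of per-feature baseline log10 intensity.
#' @param baseline_log_sd SD of per-feature baseline log10 intensity
#'   (between-feature spread).
#' @param rep_noise_sd Within-group replicate SD on the log10 scale.
#' @param qc_noise_sd Technical SD of pooled-QC injections, log10 scale.
#' @param missing_rate Fraction of entries made absent, uniformly at random
#'   (must be `< 1`).
#' @param seed Integer seed; identical seed and config give identical output.
#' @return A `sim_feature_config` list.
#' @export
sim_feature_config <- function(n_features_per_mode = 200,
                               groups = c("LB", "QC", "B108", "B253", "B263",
                                          "B313", "B424", "B505", "B585"),
                               n_reps_per_group = 6,
                               baseline_log_mean = 5,
                               baseline_log_sd = 0.5,
                               rep_noise_sd = 0.08,
                               qc_noise_sd = 0.02,
                               missing_rate = 0.02,
                               seed = 1) {
  if (n_reps_per_group < 2) stop("n_reps_per_group must be >= 2")
  if (!(missing_rate >= 0 && missing_rate < 1))
    stop("missing_rate must be in [0, 1)")
  if (!all(c("LB", "QC") %in% groups))
    stop("groups must include 'LB' and 'QC'")
  if (anyDuplicated(groups)) stop("duplicate group labels")
  stopifnot(n_features_per_mode >= 1, baseline_log_sd >= 0,
            rep_noise_sd >= 0, qc_noise_sd >= 0)
  structure(list(n_features_per_mode = as.integer(n_features_per_mode),
                 groups = groups,
                 n_reps_per_group = as.integer(n_reps_per_group),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 rep_noise_sd = rep_noise_sd,
                 qc_noise_sd = qc_noise_sd,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_feature_config")
}

#' A planted differential feature (ground truth for the screen)
#'
#' @param feature_index 1-based index of the feature to plant.
#' @param target_strains Strain labels whose mean is raised relative to LB.
#' @param fc_vs_lb True fold change of target strains versus the LB blank
#'   (>= 1).
#' @param fc_vs_b313 True fold change of target strains versus the
#'   non-protective control strain B313 (>= 1).
#' @param compound_cas Optional CAS string of the compound the feature stands
#'   for (used when testing annotation downstream).
#' @return A `planted_candidate` list.
#' @export
planted_candidate <- function(feature_index, target_strains,
                              fc_vs_lb, fc_vs_b313, compound_cas = "") {
  if (length(target_strains) == 0L) stop("target_strains must be nonempty")
  if (!is.finite(fc_vs_lb) || fc_vs_lb <= 0 ||
      !is.finite(fc_vs_b313) || fc_vs_b313 <= 0)
    stop("fold changes must be finite and positive")
  structure(list(feature_index = as.integer(feature_index),
                 target_strains = target_strains,
                 fc_vs_lb = fc_vs_lb, fc_vs_b313 = fc_vs_b313,
                 compound_cas = compound_cas),
            class = "planted_candidate")
}

#' Simulate a multi-group LC-MS feature table with planted candidates
#'
#' Background features share a common log10-normal baseline across all
#' biological groups. Each planted candidate raises the group mean of its
#' target strains by `fc_vs_lb` relative to LB, and sets the B313 mean so
#' that the target-strain/B313 ratio equals `fc_vs_b313`. QC injections are
#' the grand mean of the non-QC samples of each feature, perturbed by
#' `qc_noise_sd` on the log10 scale. Entries are made absent uniformly at
#' rate `missing_rate`, except QC entries of planted features (so planted
#' features always survive QC filtering on presence grounds alone).
#'
#' @param config A [sim_feature_config()].
#' @param planted List of [planted_candidate()] objects (possibly empty).
#' @param ion_mode `"positive"` or `"negative"`.
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (data.frame: `feature_id`, `feature_index`, `strain`, `fc_vs_lb`,
#'   `fc_vs_b313`, `cas`, one row per planted feature-strain pair).
#' @export
simulate_feature_table <- function(config, planted = list(),
                                   ion_mode = c("positive", "negative")) {
  stopifnot(inherits(config, "sim_feature_config"))
  ion_mode <- match.arg(ion_mode)
  p <- config$n_features_per_mode
  strains <- setdiff(config$groups, c("LB", "QC"))
  for (pc in planted) {
    if (!inherits(pc, "planted_candidate"))
      stop("planted must be a list of planted_candidate objects")
    if (pc$feature_index < 1L || pc$feature_index > p)
      stop("planted feature_index ", pc$feature_index,
           " out of range 1..", p)
    unknown <- setdiff(pc$target_strains, strains)
    if (length(unknown))
      stop("unknown group label(s) in target_strains: ",
           paste(unknown, collapse = ", "))
  }
  idx <- vapply(planted, `[[`, integer(1), "feature_index")
  if (anyDuplicated(idx)) stop("planted feature_index values must be unique")

  set.seed(config$seed)
  # feature m/z and RT; redraw on feature_id collision so ids stay unique
  mz <- stats::runif(p, 80, 600)
  rt <- stats::runif(p, 30, 900)
  ids <- make_feature_id(mz, rt)
  while (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    mz[dup] <- stats::runif(length(dup), 80, 600)
    rt[dup] <- stats::runif(length(dup), 30, 900)
    ids <- make_feature_id(mz, rt)
  }
  features <- data.frame(feature_id = ids, mz = mz, rt_seconds = rt,
                         ion_mode = ion_mode, stringsAsFactors = FALSE)

  bio_groups <- setdiff(config$groups, "QC")
  n_rep <- config$n_reps_per_group
  samples <- data.frame(
    sample_id = paste0(rep(config$groups, each = n_rep), "_",
                       rep(seq_len(n_rep), length(config$groups))),
    group = rep(config$groups, each = n_rep),
    replicate = rep(seq_len(n_rep), length(config$groups)),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  # per-feature, per-group log10 means
  mu <- matrix(baseline, nrow = p, ncol = length(bio_groups),
               dimnames = list(ids, bio_groups))
  for (pc in planted) {
    i <- pc$feature_index
    mu[i, pc$target_strains] <- baseline[i] + log10(pc$fc_vs_lb)
    if ("B313" %in% bio_groups)  # fc_vs_b313 is moot without the control
      mu[i, "B313"] <- baseline[i] + log10(pc$fc_vs_lb) -
        log10(pc$fc_vs_b313)
  }

  x <- matrix(NA_real_, p, nrow(samples),
              dimnames = list(ids, samples$sample_id))
  bio_cols <- which(samples$group != "QC")
  for (j in bio_cols) {
    g <- samples$group[j]
    x[, j] <- 10^(mu[, g] + stats::rnorm(p, 0, config$rep_noise_sd))
  }
  qc_cols <- which(samples$group == "QC")
  grand <- rowMeans(x[, bio_cols, drop = FALSE])
  for (j in qc_cols) {
    x[, j] <- grand * 10^stats::rnorm(p, 0, config$qc_noise_sd)
  }

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(x)) < config$missing_rate,
                   nrow = p)
    if (length(idx)) drop[idx, qc_cols] <- FALSE
    x[drop] <- NA_real_
  }

  truth <- do.call(rbind, lapply(planted, function(pc) {
    data.frame(feature_id = ids[pc$feature_index],
               feature_index = pc$feature_index,
               strain = pc$target_strains,
               fc_vs_lb = pc$fc_vs_lb, fc_vs_b313 = pc$fc_vs_b313,
               cas = pc$compound_cas, stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(feature_id = character(), feature_index = integer(),
                        strain = character(), fc_vs_lb = numeric(),
                        fc_vs_b313 = numeric(), cas = character())
  list(table = feature_table(features, samples, x), truth = truth)
}

#' Simulate pooled-larvae extract quantification data
#'
#' Runs the in-situ concentration model in reverse: a true body-surface
#' concentration (mg/liter in the larval water film of `water_mass_mg` mg)
#' implies a per-larva metabolite mass, and pooling `n_larvae` larvae into
#' `extract_volume` liters of wash water implies an extract concentration.
#' Replicates get multiplicative log-normal noise with coefficient of
#' variation `cv` (mean-one, so `cv = 0` is exactly deterministic).
#'
#' @param true_conc data.frame with columns `metabolite`, `axenic`,
#'   `nonaxenic` (true body-surface concentrations, mg/liter).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_reps Replicates per group (default 5; each replicate is one pool
#'   of `n_larvae` larvae).
#' @param seed Integer seed.
#' @param n_larvae Larvae per pooled replicate (default 20).
#' @param extract_volume Wash volume in liters (default 0.0015).
#' @param water_mass_mg Body-surface water film per larva, mg (default 0.0920).
#' @return data.frame: `metabolite`, `group`, `replicate`,
#'   `extract_conc_mg_per_l`, `n_larvae`, `extract_volume`.
#' @export
simulate_quant_dataset <- function(true_conc, cv = 0.1, n_reps = 5, seed = 1,
                                   n_larvae = 20, extract_volume = 0.0015,
                                   water_mass_mg = 0.0920) {
  stopifnot(is.data.frame(true_conc),
            all(c("metabolite", "axenic", "nonaxenic") %in% names(true_conc)))
  if (any(true_conc$axenic < 0) || any(true_conc$nonaxenic < 0))
    stop("concentrations must be >= 0")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(as.integer(seed))
  groups <- c("axenic", "nonaxenic")
  out <- expand.grid(metabolite = true_conc$metabolite, group = groups,
                     replicate = seq_len(n_reps), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$metabolite, out$group, out$replicate), ]
  rownames(out) <- NULL
  surf <- ifelse(out$group == "axenic",
                 true_conc$axenic[match(out$metabolite, true_conc$metabolite)],
                 true_conc$nonaxenic[match(out$metabolite, true_conc$metabolite)])
  per_larva <- surf * water_mass_mg * 1e-6          # mg per larva
  extract <- per_larva * n_larvae / extract_volume  # mg/liter in the wash
  if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    noise <- stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    extract <- extract * noise
  }
  out$extract_conc_mg_per_l <- extract
  out$n_larvae <- n_larvae
  out$extract_volume <- extract_volume
  out
}

#' Simulate a dose-response bioassay
#'
#' Germination assays draw binomial germinated counts out of `n_conidia`
#' conidia with success probability `control_rate * effect_model(dose)`;
#' growth assays draw normal colony diameters whose net growth (diameter
#' minus the agar plug) is scaled by `effect_model(dose)`. `effect_model`
#' must map dose 0 to 1 (no effect in the control).
#'
#' @param dose_multipliers Dose levels as multiples of the in-situ recipe
#'   (0 = control must be present for relative rates downstream).
#' @param effect_model Function dose -> response fraction; monotone
#'   non-increasing in practice, with `effect_model(0) == 1`.
#' @param n_reps Replicates per dose (default 6).
#' @param seed Integer seed.
#' @param assay `"germination"` or `"growth"`.
#' @param n_conidia Conidia counted per germination replicate (default 200).
#' @param control_rate Control germination fraction (default 0.9).
#' @param control_diameter Control colony diameter, mm (default 43).
#' @param plug_diameter Agar plug diameter, mm (default 3).
#' @param diameter_sd Replicate SD of diameters, mm (default 0.5).
#' @return data.frame: `assay`, `dose_multiplier`, `replicate`, `value`
#'   (germinated fraction, or colony diameter in mm), plus `plug_diameter`
#'   for growth assays.
#' @export
simulate_bioassay <- function(dose_multipliers, effect_model, n_reps = 6,
                              seed = 1, assay = c("germination", "growth"),
                              n_conidia = 200, control_rate = 0.9,
                              control_diameter = 43, plug_diameter = 3,
                              diameter_sd = 0.5) {
  assay <- match.arg(assay)
  if (any(dose_multipliers < 0)) stop("dose multipliers must be >= 0")
  eff <- vapply(dose_multipliers, effect_model, numeric(1))
  if (abs(effect_model(0) - 1) > 1e-12)
    stop("effect_model(0) must equal 1 (control unaffected)")
  if (assay == "germination" && any(eff < 0 | eff > 1))
    stop("effect_model must return values in [0, 1] for germination assays")
  set.seed(as.integer(seed))
  out <- expand.grid(dose_multiplier = dose_multipliers,
                     replicate = seq_len(n_reps),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$dose_multiplier, out$replicate), ]
  rownames(out) <- NULL
  eff_row <- eff[match(out$dose_multiplier, dose_multipliers)]
  if (assay == "germination") {
    prob <- pmin(1, pmax(0, control_rate * eff_row))
    out$value <- stats::rbinom(nrow(out), n_conidia, prob) / n_conidia
  } else {
    net <- (control_diameter - plug_diameter) * eff_row
    out$value <- pmax(plug_diameter,
                      plug_diameter + net +
                        stats::rnorm(nrow(out), 0, diameter_sd))
    out$plug_diameter <- plug_diameter
  }
  cbind(assay = assay, out, stringsAsFactors = FALSE)
}

#' Simulate interval-censored survival data
#'
#' Event times are exponential with the given per-day hazard, discretized
#' upward to the observation grid (survival checked every
#' `obs_interval_days`); subjects alive at the horizon are censored there.
#'
#' @param group_hazards Named numeric vector: per-day hazard per group
#'   (0 means no deaths).
#' @param n_per_group Subjects per group (default 45).
#' @param horizon_days Last observation day (default 20).
#' @param obs_interval_days Observation interval in days (default 2).
#' @param seed Integer seed.
#' @return data.frame: `subject_id`, `group`, `time_days`, `event`
#'   (1 = death, 0 = censored).
#' @export
simulate_survival <- function(group_hazards, n_per_group = 45,
                              horizon_days = 20, obs_interval_days = 2,
                              seed = 1) {
  if (is.null(names(group_hazards)) || any(names(group_hazards) == ""))
    stop("group_hazards must be a named vector")
  if (any(group_hazards < 0)) stop("hazards must be >= 0")
  if (horizon_days <= 0) stop("horizon_days must be positive")
  stopifnot(obs_interval_days > 0, n_per_group >= 1)
  set.seed(as.integer(seed))
  recs <- lapply(names(group_hazards), function(g) {
    h <- group_hazards[[g]]
    t_true <- if (h == 0) rep(Inf, n_per_group) else
      stats::rexp(n_per_group, rate = h)
    t_obs <- ceiling(t_true / obs_interval_days) * obs_interval_days
    event <- as.integer(t_obs <= horizon_days)
    t_obs[event == 0L] <- horizon_days
    data.frame(subject_id = paste0(g, "_", seq_len(n_per_group)),
               group = g, time_days = t_obs, event = event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
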