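# End-to-end driver: simulate -> QC -> screen -> annotate -> quantify ->
# cocktail -> bioassay -> survival, writing every intermediate table and a
# machine-readable manifest.

#' Read the published body-surface concentration means
#'
#' The packaged table transcribes the per-metabolite mean in-situ
#' concentrations (mg/liter) for axenic and nonaxenic larvae, with a
#' detection flag (thymine was detected on neither group).
#'
#' @param path Path to the delimited table; defaults to the packaged copy.
#' @return data.frame: `metabolite`, `group`, `mean_conc_mg_per_l`,
#'   `detected`.
#' @export
read_surface_concentrations <- function(path = system.file(
  "extdata", "surface_concentrations.tsv", package = "symbioscreen")) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "group", "mean_conc_mg_per_l",
                  "detected") %in% names(out)))
  out$detected <- as.logical(out$detected)
  out
}

conc_long_to_wide <- function(conc) {
  mets <- unique(conc$metabolite)
  data.frame(
    metabolite = mets,
    axenic = conc$mean_conc_mg_per_l[match(
      paste(mets, "axenic"), paste(conc$metabolite, conc$group))],
    nonaxenic = conc$mean_conc_mg_per_l[match(
      paste(mets, "nonaxenic"), paste(conc$metabolite, conc$group))],
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects the knobs of every stage of the all-synthetic demonstration
#' pipeline. Defaults mirror the study design: six replicates per
#' metabolomics group, fold-change thresholds 2 (vs LB) and 10 (vs B313),
#' VIP cutoff 2, 10 ppm annotation tolerance, 0.0920 mg body-surface water
#' film, 0.1 mg/liter cocktail inclusion threshold, a 2^1..2^-6 dose
#' series, and 45 larvae per survival group observed every 2 days.
#'
#' @param out_dir Directory for stage outputs.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param sim A [sim_feature_config()] (its seed is overridden from `seed`).
#' @param screen A [screen_config()].
#' @param qc A [qc_filter_config()].
#' @param tol_ppm Annotation tolerance, ppm.
#' @param water_mass_mg Body-surface water film per larva, mg.
#' @param inclusion_threshold Cocktail inclusion threshold, mg/liter.
#' @param quant_cv Coefficient of variation of the simulated quantification.
#' @param norm_method Sample normalization method (default `"median"`,
#'   which is robust to a handful of high-abundance differential features
#'   at the modest feature counts the demonstration simulates).
#' @param library_path Compound library path.
#' @param conc_path Surface-concentration table path.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("symbioscreen_run_"),
                            seed = 1,
                            sim = sim_feature_config(n_features_per_mode = 120,
                                                     missing_rate = 0.02),
                            screen = screen_config(),
                            qc = qc_filter_config(),
                            tol_ppm = 10,
                            water_mass_mg = 0.0920,
                            inclusion_threshold = 0.1,
                            quant_cv = 0.05,
                            norm_method = "median",
                            library_path = NULL,
                            conc_path = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 screen = screen, qc = qc, tol_ppm = tol_ppm,
                 water_mass_mg = water_mass_mg,
                 inclusion_threshold = inclusion_threshold,
                 quant_cv = quant_cv, norm_method = norm_method,
                 library_path = library_path, conc_path = conc_path),
            class = "pipeline_config")
}

#' Give planted features the accurate m/z of their compounds
#'
#' Rewrites the m/z of planted features that carry a CAS number to the
#' expected protonation-adduct m/z of that compound ([M+H]+ in positive
#' mode, [M-H]- in negative mode), recomputing feature ids, so the
#' annotation stage can identify them. Features without a CAS, or with a
#' CAS absent from the library, are left untouched.
#'
#' @param sim A list with `table` and `truth`, as returned by
#'   [simulate_feature_table()].
#' @param library Compound library data.frame
#'   (see [read_compound_library()]).
#' @return The modified `list(table, truth)`.
#' @export
assign_compound_mz <- function(sim, library) {
  truth <- sim$truth
  if (!nrow(truth)) return(sim)
  table <- sim$table
  feats <- table$features
  planted_idx <- unique(truth$feature_index)
  for (i in planted_idx) {
    cas <- truth$cas[truth$feature_index == i][1]
    if (cas == "" || !cas %in% library$cas) next
    mass <- library$monoisotopic_mass[library$cas == cas]
    feats$mz[i] <- mass +
      if (feats$ion_mode[i] == "positive") PROTON_MASS else -PROTON_MASS
  }
  ids <- make_feature_id(feats$mz, feats$rt_seconds)
  # keep ids unique after the overwrite
  while (anyDuplicated(ids)) {
    dup <- setdiff(which(duplicated(ids)), planted_idx)
    if (!length(dup)) break
    feats$rt_seconds[dup] <- feats$rt_seconds[dup] + 1
    ids <- make_feature_id(feats$mz, feats$rt_seconds)
  }
  feats$feature_id <- ids
  new_truth <- truth
  new_truth$feature_id <- ids[new_truth$feature_index]
  list(table = feature_table(feats, table$samples, table$intensities),
       truth = new_truth)
}

write_stage <- function(x, out_dir, name) {
  utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Executes simulate, QC filter, imputation, normalization, the screening
#' cascade, annotation with nutrient exclusion, in-situ quantification,
#' cocktail formulation with its dose series, germination/growth bioassays,
#' and the survival comparison, in that order. Every intermediate table is
#' written under `config$out_dir`, a manifest (seeds, configuration hash,
#' feature counts per stage) is written as JSON, and the stage results are
#' returned invisibly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$library_path) && !file.exists(config$library_path))
    stop("annotation stage: compound library not found: ",
         config$library_path)
  library <- if (is.null(config$library_path)) read_compound_library()
             else read_compound_library(config$library_path)
  conc_pub <- if (is.null(config$conc_path)) read_surface_concentrations()
              else read_surface_concentrations(config$conc_path)

  # --- simulate the two ion-mode feature tables with planted candidates
  candidates_lib <- library[!library$is_nutrient, , drop = FALSE]
  strains <- setdiff(config$sim$groups, c("LB", "QC", "B313"))
  planted <- lapply(seq_len(min(5, nrow(candidates_lib))), function(i) {
    planted_candidate(feature_index = i,
                      target_strains = strains[1 + (i - 1) %% length(strains)],
                      fc_vs_lb = 50, fc_vs_b313 = 40,
                      compound_cas = candidates_lib$cas[i])
  })
  counts <- list()
  tables <- list()
  truths <- list()
  for (k in seq_along(c("positive", "negative"))) {
    mode <- c("positive", "negative")[k]
    cfg <- config$sim
    cfg$seed <- config$seed + k
    sim <- simulate_feature_table(cfg, planted, ion_mode = mode)
    sim <- assign_compound_mz(sim, library)
    write_feature_table(sim$table,
                        file.path(config$out_dir,
                                  paste0("features_", mode, ".tsv")))
    t0 <- nrow(sim$table$features)
    filt <- qc_filter(sim$table, config$qc)
    norm <- normalize_intensities(impute_missing(filt), config$norm_method)
    counts[[mode]] <- c(simulated = t0, qc_filtered = nrow(filt$features),
                        analyzed = nrow(norm$features))
    tables[[mode]] <- norm
    truths[[mode]] <- sim$truth
    message(sprintf("[%s] %d features simulated, %d after QC filter",
                    mode, t0, nrow(filt$features)))
  }

  # --- screening cascade and annotation
  candidates <- run_cascade(tables, config = config$screen)
  write_stage(candidates, config$out_dir, "candidates")
  ann <- annotate_features(candidates, library, config$tol_ppm)
  ann <- exclude_nutrients(ann)
  final <- finalize_candidates(candidates, ann)
  write_stage(final[setdiff(names(final), "support")],
              config$out_dir, "final_compounds")
  message(nrow(candidates), " candidate rows -> ",
          nrow(final), " unique compounds")

  # --- in-situ quantification
  quant <- simulate_quant_dataset(conc_long_to_wide(conc_pub),
                                  cv = config$quant_cv, n_reps = 5,
                                  seed = config$seed + 11,
                                  water_mass_mg = config$water_mass_mg)
  conc_tab <- surface_concentration_table(quant, config$water_mass_mg)
  # detection is a property of the instrument, carried over from the truth
  conc_tab$detected <- conc_pub$detected[match(
    paste(conc_tab$metabolite, conc_tab$group),
    paste(conc_pub$metabolite, conc_pub$group))]
  comparisons <- compare_quant_groups(quant, config$water_mass_mg)
  write_stage(conc_tab, config$out_dir, "surface_concentrations")
  write_stage(comparisons, config$out_dir, "group_comparisons")

  # --- cocktail and dose series
  recipe <- build_recipe(conc_tab, "nonaxenic", config$inclusion_threshold)
  doses <- dose_series(recipe)
  write_stage(doses, config$out_dir, "dose_series")
  message("cocktail recipe: ", length(recipe), " components")

  # --- bioassays: inhibition grows with dose
  effect <- function(d) 1 / (1 + 4 * d)
  germ <- simulate_bioassay(doses$dose_multiplier, effect,
                            seed = config$seed + 21, assay = "germination")
  growth <- simulate_bioassay(doses$dose_multiplier, effect,
                              seed = config$seed + 22, assay = "growth")
  germ_rates <- relative_rate(germ)
  growth_rates <- relative_rate(growth)
  germ_summary <- dose_response_summary(germ)
  growth_summary <- dose_response_summary(growth)
  write_stage(germ_rates, config$out_dir, "germination_rates")
  write_stage(growth_rates, config$out_dir, "growth_rates")

  # --- survival: infected larvae with and without the cocktail
  surv <- simulate_survival(
    c("Bb" = 0.12, "Bb+Cocktail" = 0.03, "Blank" = 0.002),
    n_per_group = 45, horizon_days = 20, seed = config$seed + 31)
  km <- lapply(stats::setNames(nm = unique(surv$group)),
               function(g) km_estimate(surv, g))
  lr <- logrank_test(surv, "Bb", "Bb+Cocktail")
  write_stage(surv, config$out_dir, "survival_records")
  write_stage(lr, config$out_dir, "logrank")

  # --- manifest
  cfg_json <- file.path(config$out_dir, "config.json")
  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    feature_counts = counts,
    n_candidate_rows = nrow(candidates),
    n_unique_compounds = nrow(final),
    recipe = as.list(unclass(recipe)),
    logrank_chi_square = lr$chi_square,
    final_survival = vapply(km, attr, numeric(1), "final_survival")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tables = tables, truth = truths, candidates = candidates,
                 annotations = ann, final_compounds = final,
                 quant = quant, concentrations = conc_tab,
                 comparisons = comparisons, recipe = recipe, doses = doses,
                 germination = list(data = germ, rates = germ_rates,
                                    summary = germ_summary),
                 growth = list(data = growth, rates = growth_rates,
                               summary = growth_summary),
                 survival = list(data = surv, km = km, logrank = lr),
                 manifest = manifest))
}
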