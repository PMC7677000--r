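# Cocktail formulation from in-situ concentrations, the serial dose design,
# and dose-response bioassay summaries (relative rates, omnibus test
# selection, post-hoc letters).

#' Build a metabolite cocktail recipe from surface concentrations
#'
#' Includes every metabolite whose mean body-surface concentration in the
#' chosen group is at least `inclusion_threshold` mg/liter; undetected
#' metabolites are excluded regardless. Concentrations are copied verbatim.
#' With the published nonaxenic means and the default threshold this yields
#' the seven-organic-acid cocktail (ketoisocaproic, glutaric, adipic,
#' phenyllactic, indoleacetic, kynurenic and picolinic acids).
#'
#' @param conc data.frame with columns `metabolite`, `group`,
#'   `mean_conc_mg_per_l` and `detected` (as from
#'   [surface_concentration_table()]).
#' @param source_group `"axenic"` or `"nonaxenic"`.
#' @param inclusion_threshold Minimum concentration, mg/liter (default 0.1).
#' @return A `cocktail_recipe`: named numeric vector of component
#'   concentrations (mg/liter) with the source group and threshold attached.
#' @export
build_recipe <- function(conc, source_group = c("nonaxenic", "axenic"),
                         inclusion_threshold = 0.1) {
  source_group <- match.arg(source_group)
  stopifnot(all(c("metabolite", "group", "mean_conc_mg_per_l",
                  "detected") %in% names(conc)))
  rows <- conc[conc$group == source_group, , drop = FALSE]
  keep <- rows$detected & rows$mean_conc_mg_per_l >= inclusion_threshold
  if (!any(keep))
    stop("no components above threshold ", inclusion_threshold,
         " mg/liter for group '", source_group, "'")
  components <- stats::setNames(rows$mean_conc_mg_per_l[keep],
                                rows$metabolite[keep])
  structure(components, source_group = source_group,
            inclusion_threshold = inclusion_threshold,
            class = "cocktail_recipe")
}

#' @export
print.cocktail_recipe <- function(x, ...) {
  cat("cocktail recipe (", attr(x, "source_group"), " body surface, ",
      length(x), " components):\n", sep = "")
  for (m in names(x)) cat(sprintf("  %-20s %g mg/liter\n", m, x[[m]]))
  invisible(x)
}

#' Serial dose series of a cocktail
#'
#' Per-dose concentration is `multiplier * recipe concentration`; the
#' default series is 2^1, 2^0, ..., 2^-6 times the in-situ recipe, plus a
#' zero-concentration control (appended when absent). Multipliers must be
#' strictly decreasing.
#'
#' @param recipe A [build_recipe()] result.
#' @param multipliers Ordered dose multipliers (default `2^(1:-6)` plus 0).
#' @return data.frame, one row per dose: `dose_multiplier` plus one column
#'   per component (mg/liter).
#' @export
dose_series <- function(recipe, multipliers = c(2^(1:-6), 0)) {
  stopifnot(inherits(recipe, "cocktail_recipe"))
  if (any(multipliers < 0)) stop("dose multipliers must be >= 0")
  if (any(diff(multipliers) >= 0))
    stop("dose multipliers must be strictly decreasing")
  if (!0 %in% multipliers) multipliers <- c(multipliers, 0)
  conc <- outer(multipliers, unclass(recipe))
  out <- data.frame(dose_multiplier = multipliers, conc,
                    check.names = FALSE)
  names(out)[-1] <- names(recipe)
  out
}

bioassay_net_values <- function(dataset) {
  v <- dataset$value
  if (dataset$assay[1] == "growth") {
    plug <- if ("plug_diameter" %in% names(dataset)) dataset$plug_diameter
            else 3
    v <- v - plug
  }
  v
}

#' Per-dose response relative to the control
#'
#' Germination uses germinated fractions directly; growth uses net colony
#' growth (diameter minus the agar plug). The relative rate of a dose is
#' `100 * mean(dose) / mean(control)` percent.
#'
#' @param dataset Bioassay data.frame (see [simulate_bioassay()]): columns
#'   `assay`, `dose_multiplier`, `replicate`, `value`, and
#'   `plug_diameter` for growth assays.
#' @return data.frame: `dose_multiplier`, `relative_rate_pct`, `n`.
#' @export
relative_rate <- function(dataset) {
  if (!0 %in% dataset$dose_multiplier)
    stop("control dose (multiplier 0) is required")
  v <- bioassay_net_values(dataset)
  ctrl <- mean(v[dataset$dose_multiplier == 0])
  if (ctrl == 0) stop("control mean response is zero")
  doses <- sort(unique(dataset$dose_multiplier), decreasing = TRUE)
  out <- do.call(rbind, lapply(doses, function(d) {
    sel <- dataset$dose_multiplier == d
    data.frame(dose_multiplier = d,
               relative_rate_pct = 100 * mean(v[sel]) / ctrl,
               n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

# Dunnett's T3: pairwise Welch statistics judged against a
# studentized-maximum-modulus bound in its Sidak product form.
dunnett_t3 <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  nm <- names(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  n <- vapply(g, length, numeric(1))
  n_pairs <- k * (k - 1) / 2
  out <- data.frame(group_a = character(), group_b = character(),
                    statistic = numeric(), df = numeric(),
                    p_value = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    p_raw <- 2 * stats::pt(-abs(tstat), df)
    p_adj <- 1 - (1 - p_raw)^n_pairs
    out <- rbind(out, data.frame(group_a = nm[i], group_b = nm[j],
                                 statistic = tstat, df = df,
                                 p_value = min(1, p_adj),
                                 stringsAsFactors = FALSE))
  }
  out
}

# Compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different. `sig` is a symmetric logical matrix.
compact_letters <- function(group_names, sig) {
  k <- length(group_names)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    for (s_idx in rev(seq_along(sets))) {
      s <- sets[[s_idx]]
      if (i %in% s && j %in% s) {
        sets[[s_idx]] <- NULL
        sets <- c(sets, list(setdiff(s, i)), list(setdiff(s, j)))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]]))
        keep[a] <- FALSE
    }
    sets <- unique(sets[keep])
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  lab <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(lab, group_names)
}

#' Dose-response summary with test selection and letters
#'
#' Decision tree over the per-dose groups: if every group passes the
#' Lilliefors normality check (alpha = `alpha`), homogeneous variances
#' (Levene) give one-way ANOVA with Tukey HSD, heterogeneous variances give
#' Welch's ANOVA with Dunnett's T3; any normality failure gives
#' Kruskal-Wallis with pairwise Mann-Whitney tests under Bonferroni
#' correction. Groups are labelled with a compact letter display (shared
#' letter = not significantly different), ordered by decreasing mean so the
#' highest-response dose carries `a`.
#'
#' @param dataset Bioassay data.frame (see [relative_rate()]); growth values
#'   are reduced to net growth first.
#' @param alpha Significance level (default 0.05).
#' @return A list: `omnibus` (data.frame: `method`, `statistic`, `df1`,
#'   `df2`, `p_value`), `pairwise` (data.frame of pairwise comparisons),
#'   `groups` (data.frame: `dose_multiplier`, `mean`, `sd`, `n`,
#'   `letters`).
#' @export
dose_response_summary <- function(dataset, alpha = 0.05) {
  v <- bioassay_net_values(dataset)
  dose <- factor(dataset$dose_multiplier)
  if (nlevels(dose) < 2) stop("at least two doses are required")
  if (any(table(dose) < 2)) stop("each dose needs >= 2 replicates")
  by_dose <- split(v, dose)
  normal_ok <- all(vapply(by_dose, function(g) {
    if (stats::sd(g) == 0) return(FALSE)
    nortest::lillie.test(g)$p.value > alpha
  }, logical(1)))
  if (!normal_ok) {
    kw <- stats::kruskal.test(v, dose)
    omnibus <- data.frame(method = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          df1 = unname(kw$parameter), df2 = NA_real_,
                          p_value = kw$p.value, stringsAsFactors = FALSE)
    pw_mat <- suppressWarnings(
      stats::pairwise.wilcox.test(v, dose, p.adjust.method = "bonferroni",
                                  exact = FALSE)$p.value)
    pairwise <- do.call(rbind, lapply(rownames(pw_mat), function(a) {
      cols <- colnames(pw_mat)[!is.na(pw_mat[a, ])]
      if (!length(cols)) return(NULL)
      data.frame(group_a = cols, group_b = a,
                 p_value = pw_mat[a, cols], stringsAsFactors = FALSE)
    }))
  } else {
    lev_p <- car::leveneTest(v ~ dose)[1, "Pr(>F)"]
    if (lev_p > alpha) {
      fit <- stats::aov(v ~ dose)
      an <- stats::anova(fit)
      omnibus <- data.frame(method = "anova",
                            statistic = an[1, "F value"],
                            df1 = an[1, "Df"], df2 = an[2, "Df"],
                            p_value = an[1, "Pr(>F)"],
                            stringsAsFactors = FALSE)
      tk <- stats::TukeyHSD(fit)$dose
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(group_a = vapply(pairs, `[`, "", 1),
                             group_b = vapply(pairs, `[`, "", 2),
                             p_value = tk[, "p adj"],
                             stringsAsFactors = FALSE)
    } else {
      wa <- stats::oneway.test(v ~ dose, var.equal = FALSE)
      omnibus <- data.frame(method = "welch_anova",
                            statistic = unname(wa$statistic),
                            df1 = unname(wa$parameter[1]),
                            df2 = unname(wa$parameter[2]),
                            p_value = wa$p.value, stringsAsFactors = FALSE)
      t3 <- dunnett_t3(v, dose)
      pairwise <- t3[c("group_a", "group_b", "p_value")]
    }
  }
  rownames(pairwise) <- NULL
  means <- vapply(by_dose, mean, numeric(1))
  ord <- order(means, decreasing = TRUE)
  lev_ord <- levels(dose)[ord]
  sig <- matrix(FALSE, length(lev_ord), length(lev_ord),
                dimnames = list(lev_ord, lev_ord))
  for (r in seq_len(nrow(pairwise))) {
    a <- pairwise$group_a[r]; b <- pairwise$group_b[r]
    s <- !is.na(pairwise$p_value[r]) && pairwise$p_value[r] < alpha
    sig[a, b] <- sig[b, a] <- s
  }
  lab <- compact_letters(lev_ord, sig)
  groups <- data.frame(dose_multiplier = as.numeric(lev_ord),
                       mean = means[ord],
                       sd = vapply(by_dose, stats::sd, numeric(1))[ord],
                       n = vapply(by_dose, length, integer(1))[ord],
                       letters = unname(lab), stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(omnibus = omnibus, pairwise = pairwise, groups = groups)
}
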