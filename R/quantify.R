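# In-situ quantification: convert pooled-larvae extract measurements to
# per-larva quantities and body-surface concentrations, and compare axenic
# versus nonaxenic groups with a normality/homogeneity test-selection tree.

#' Metabolite quantity per larva from a pooled extract
#'
#' A pooled wash of `n_larvae` larvae in `extract_volume` liters at
#' concentration `extract_conc` mg/liter carries
#' `extract_conc * extract_volume / n_larvae` mg of metabolite per larva.
#'
#' @param extract_conc Extract concentration, mg/liter (>= 0).
#' @param extract_volume Wash volume in liters (default 0.0015, i.e. 1.5 ml).
#' @param n_larvae Larvae per pool (default 20).
#' @return Metabolite mass per larva, mg.
#' @export
per_larva_quantity <- function(extract_conc, extract_volume = 0.0015,
                               n_larvae = 20) {
  stopifnot(all(extract_conc >= 0), extract_volume > 0, n_larvae >= 1)
  extract_conc * extract_volume / n_larvae
}

#' Body-surface concentration from a per-larva quantity
#'
#' The metabolite sits in the thin water film on the larval cuticle
#' (`water_mass_mg` mg of water per larva; 0.0920 mg for second-instar
#' onion maggot larvae). At water density 1 g/ml that film is
#' `water_mass_mg * 1e-6` liters, so the in-situ concentration is
#' `per_larva_mass / (water_mass_mg * 1e-6)` mg/liter.
#'
#' @param per_larva_mass Metabolite mass per larva, mg (>= 0).
#' @param water_mass_mg Body-surface water mass per larva, mg
#'   (default 0.0920; must be positive).
#' @return In-situ concentration, mg/liter.
#' @examples
#' surface_concentration(5.4050e-5)  # 587.5 mg/liter
#' @export
surface_concentration <- function(per_larva_mass, water_mass_mg = 0.0920) {
  stopifnot(all(per_larva_mass >= 0))
  if (water_mass_mg <= 0) stop("water_mass_mg must be positive")
  per_larva_mass / (water_mass_mg * 1e-6)
}

#' Summarize a quantification dataset to surface concentrations
#'
#' Applies [per_larva_quantity()] then [surface_concentration()] to every
#' replicate and averages per metabolite and group.
#'
#' @param quant data.frame as produced by [simulate_quant_dataset()]:
#'   `metabolite`, `group`, `replicate`, `extract_conc_mg_per_l`,
#'   `n_larvae`, `extract_volume`.
#' @param water_mass_mg Body-surface water mass per larva, mg.
#' @return data.frame: `metabolite`, `group`, `mean_conc_mg_per_l`,
#'   `sd_conc_mg_per_l`, `n`, `detected` (any replicate above zero).
#' @export
surface_concentration_table <- function(quant, water_mass_mg = 0.0920) {
  per_larva <- per_larva_quantity(quant$extract_conc_mg_per_l,
                                  quant$extract_volume, quant$n_larvae)
  conc <- surface_concentration(per_larva, water_mass_mg)
  agg <- split(conc, list(quant$metabolite, quant$group), drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- agg[[key]]
    data.frame(metabolite = paste(parts[-length(parts)], collapse = "."),
               group = parts[length(parts)],
               mean_conc_mg_per_l = mean(v),
               sd_conc_mg_per_l = stats::sd(v),
               n = length(v), detected = any(v > 0),
               stringsAsFactors = FALSE)
  }))
  out[order(out$metabolite, out$group), , drop = FALSE]
}

#' Compare a metabolite between two groups with test selection
#'
#' Decision tree: if both groups pass a Kolmogorov-Smirnov normality check
#' (Lilliefors form, against the fitted normal, alpha 0.05), variances are
#' compared with Levene's test; equal variances give a pooled two-sample t
#' test, unequal variances a Welch t test. Any normality failure (or a
#' degenerate all-identical group) falls back to the Mann-Whitney U test
#' (normal approximation with tie correction). The branch taken is
#' reported.
#'
#' @param values Numeric measurements (one metabolite).
#' @param groups Two-level grouping vector aligned with `values`.
#' @param alpha Significance level of the normality/homogeneity checks
#'   (default 0.05).
#' @return data.frame: `test_used` (`"t_equal_var"`, `"t_welch"` or
#'   `"mann_whitney"`), `statistic`, `df` (`NA` for Mann-Whitney),
#'   `p_value`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("compare_groups requires exactly two groups")
  a <- values[groups == lev[1]]
  b <- values[groups == lev[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 replicates")
  if (stats::sd(c(a, b)) == 0) {
    # no variation anywhere: no evidence of any difference
    warning("all values identical in both groups; p = 1")
    return(data.frame(test_used = "mann_whitney",
                      statistic = length(a) * length(b) / 2, df = NA_real_,
                      p_value = 1, mean_a = mean(a), mean_b = mean(b),
                      stringsAsFactors = FALSE))
  }
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  normal_ok <- !degenerate && all(vapply(list(a, b), function(v) {
    nortest::lillie.test(v)$p.value > alpha
  }, logical(1)))
  if (!normal_ok) {
    if (degenerate)
      warning("zero-variance group; falling back to Mann-Whitney U")
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- data.frame(test_used = "mann_whitney",
                      statistic = unname(wt$statistic), df = NA_real_,
                      p_value = wt$p.value, stringsAsFactors = FALSE)
  } else {
    lev_p <- car::leveneTest(values ~ factor(groups))[1, "Pr(>F)"]
    equal_var <- lev_p > alpha
    tt <- stats::t.test(a, b, var.equal = equal_var)
    res <- data.frame(test_used = if (equal_var) "t_equal_var" else "t_welch",
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p_value = tt$p.value,
                      stringsAsFactors = FALSE)
  }
  res$mean_a <- mean(a)
  res$mean_b <- mean(b)
  res
}

#' Compare every metabolite of a quantification dataset between groups
#'
#' Runs [compare_groups()] per metabolite on surface-concentration
#' replicates.
#'
#' @inheritParams surface_concentration_table
#' @param alpha Significance level of the pre-tests (default 0.05).
#' @return data.frame, one row per metabolite, with the comparison fields of
#'   [compare_groups()].
#' @export
compare_quant_groups <- function(quant, water_mass_mg = 0.0920,
                                 alpha = 0.05) {
  per_larva <- per_larva_quantity(quant$extract_conc_mg_per_l,
                                  quant$extract_volume, quant$n_larvae)
  conc <- surface_concentration(per_larva, water_mass_mg)
  mets <- unique(quant$metabolite)
  out <- do.call(rbind, lapply(mets, function(m) {
    sel <- quant$metabolite == m
    cmp <- suppressWarnings(
      compare_groups(conc[sel], quant$group[sel], alpha))
    cbind(metabolite = m, cmp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
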