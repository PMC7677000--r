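# Two-step candidate screening cascade: per-strain differential features
# versus the LB medium blank (fold change + Welch p + VIP), union with the
# non-protective control strain's differential set, then a >= 10x ratio
# filter versus that control strain (B313).

#' Screening thresholds
#'
#' @param fc_lb_min Minimum fold change versus the LB blank in step I
#'   (default 2).
#' @param alpha Significance level for the per-feature Welch test
#'   (default 0.05).
#' @param vip_min Minimum VIP score (default 2).
#' @param ratio_b313_min Minimum fold change versus the control strain B313
#'   in step II (default 10).
#' @param p_adjust `"none"` (raw p-values, the default) or `"BH"` for
#'   Benjamini-Hochberg adjustment within each contrast.
#' @return A `screen_config` list.
#' @export
screen_config <- function(fc_lb_min = 2, alpha = 0.05, vip_min = 2,
                          ratio_b313_min = 10, p_adjust = c("none", "BH")) {
  stopifnot(fc_lb_min > 0, vip_min > 0, ratio_b313_min > 0)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(fc_lb_min = fc_lb_min, alpha = alpha, vip_min = vip_min,
                 ratio_b313_min = ratio_b313_min,
                 p_adjust = match.arg(p_adjust)),
            class = "screen_config")
}

# Vectorized per-feature Welch t-test on log10 intensities.
welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate: identical constant groups carry no evidence
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  p
}

group_cols <- function(table, group) {
  idx <- which(table$samples$group == group)
  if (!length(idx)) stop("group '", group, "' not present in table")
  idx
}

# Fit a two-group PLS-DA on the table and return per-feature VIPs aligned to
# the full feature set (features dropped for zero variance get VIP 0).
contrast_vip <- function(table, group_a, group_b, n_components = 2) {
  ia <- group_cols(table, group_a)
  ib <- group_cols(table, group_b)
  m <- t(log10(table$intensities[, c(ia, ib), drop = FALSE]))
  labels <- table$samples$group[c(ia, ib)]
  fit <- suppressWarnings(
    plsda_fit(m, labels, n_components, log10_transform = FALSE))
  v <- vip_scores(fit)
  out <- stats::setNames(rep(0, nrow(table$features)),
                         table$features$feature_id)
  out[names(v)] <- v
  out
}

differential_records <- function(table, strain, ref, config, n_components = 2,
                                 fc_min, features = NULL) {
  is_ <- group_cols(table, strain)
  ir <- group_cols(table, ref)
  x <- table$intensities
  if (anyNA(x)) stop("screening requires an imputed, normalized table")
  ratio <- rowMeans(x[, is_, drop = FALSE]) / rowMeans(x[, ir, drop = FALSE])
  p <- welch_p(log10(x[, is_, drop = FALSE]), log10(x[, ir, drop = FALSE]))
  if (config$p_adjust == "BH") p <- stats::p.adjust(p, "BH")
  vip <- contrast_vip(table, strain, ref, n_components)
  out <- data.frame(feature_id = table$features$feature_id,
                    ratio_vs_ref = unname(ratio), p_value = unname(p),
                    vip = unname(vip), stringsAsFactors = FALSE)
  if (!is.null(features)) {
    out <- out[match(features, out$feature_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$passes <- out$ratio_vs_ref >= fc_min & out$p_value < config$alpha &
    out$vip >= config$vip_min
  attr(out, "ion_mode") <- table$features$ion_mode[1]
  attr(out, "contrast") <- paste0(strain, ":", ref)
  out
}

#' Step I: differential features of a strain versus the LB blank
#'
#' Per feature: the fold change is the ratio of arithmetic group means on
#' normalized linear intensities, the p-value is a Welch t-test on log10
#' intensities, and the VIP score comes from the strain-versus-LB PLS-DA.
#' A feature passes when `ratio >= fc_lb_min`, `p < alpha` and
#' `vip >= vip_min`.
#'
#' @param table QC-filtered, imputed, normalized [feature_table()].
#' @param strain Strain group label.
#' @param config A [screen_config()].
#' @param n_components PLS-DA components (default 2).
#' @return data.frame of differential records (`feature_id`, `ratio_vs_ref`,
#'   `p_value`, `vip`, `passes`), carrying the ion mode as an attribute.
#' @export
differential_vs_medium <- function(table, strain, config = screen_config(),
                                   n_components = 2) {
  differential_records(table, strain, "LB", config, n_components,
                       fc_min = config$fc_lb_min)
}

#' Merge a strain's differential set with the control strain's set
#'
#' Stable set union: the strain's features in order, then novel features
#' from the control set. Both sets must come from the same ion mode.
#'
#' @param set_strain,set_b313 Character vectors of feature ids (or
#'   differential-record data.frames, whose passing ids are used), each
#'   carrying an `ion_mode` attribute.
#' @return Character vector of feature ids with the shared `ion_mode`
#'   attribute.
#' @export
merge_union <- function(set_strain, set_b313) {
  ids <- lapply(list(set_strain, set_b313), function(s) {
    mode <- attr(s, "ion_mode")
    if (is.data.frame(s)) s <- s$feature_id[s$passes]
    structure(as.character(s), ion_mode = mode)
  })
  modes <- unique(unlist(lapply(ids, attr, "ion_mode")))
  if (length(modes) > 1)
    stop("cannot merge feature sets from different ion modes: ",
         paste(modes, collapse = " vs "))
  structure(unique(c(ids[[1]], ids[[2]])), ion_mode = modes)
}

#' Step II: ratio filter versus the control strain B313
#'
#' For every feature in the union set, computes the strain/B313 fold change
#' on normalized linear means, the Welch p-value and the VIP from the
#' strain-versus-B313 PLS-DA; a feature is retained when
#' `ratio >= ratio_b313_min`, `p < alpha` and `vip >= vip_min`.
#'
#' @param table QC-filtered, imputed, normalized [feature_table()].
#' @param union_set Feature ids from [merge_union()].
#' @param strain Strain group label.
#' @param config A [screen_config()].
#' @param n_components PLS-DA components (default 2).
#' @return data.frame of differential records restricted to the union set,
#'   with `passes` marking retained features.
#' @export
ratio_filter_vs_control <- function(table, union_set, strain,
                                    config = screen_config(),
                                    n_components = 2) {
  mode_u <- attr(union_set, "ion_mode")
  if (!is.null(mode_u) && mode_u != table$features$ion_mode[1])
    stop("union set ion mode does not match the table")
  differential_records(table, strain, "B313", config, n_components,
                       fc_min = config$ratio_b313_min,
                       features = as.character(union_set))
}

#' Run the full candidate-screening cascade
#'
#' For each ion-mode table and each strain: step I versus LB for the strain
#' and for the control strain B313, the union of the two passing sets, then
#' the step II ratio filter versus B313. Retained rows become candidate
#' records carrying the strain, ion mode, m/z and retention time.
#'
#' @param tables A single [feature_table()] or a list of them (one per ion
#'   mode), each QC-filtered, imputed and normalized.
#' @param strains Strains to screen; default: every group except LB, QC and
#'   B313.
#' @param config A [screen_config()].
#' @param n_components PLS-DA components (default 2).
#' @return A candidate table: data.frame with columns `feature_id`,
#'   `rt_seconds`, `mz`, `ion_mode`, `ratio_vs_b313`, `p_value`, `vip`,
#'   `strain`.
#' @export
run_cascade <- function(tables, strains = NULL, config = screen_config(),
                        n_components = 2) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  rows <- list()
  for (table in tables) {
    all_strains <- setdiff(unique(table$samples$group),
                           c("LB", "QC", "B313"))
    use <- if (is.null(strains)) all_strains else
      intersect(strains, all_strains)
    b313_step1 <- differential_vs_medium(table, "B313", config, n_components)
    for (strain in use) {
      step1 <- differential_vs_medium(table, strain, config, n_components)
      u <- merge_union(step1, b313_step1)
      step2 <- ratio_filter_vs_control(table, u, strain, config, n_components)
      hit <- step2[step2$passes, , drop = FALSE]
      if (!nrow(hit)) next
      fi <- match(hit$feature_id, table$features$feature_id)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = hit$feature_id,
        rt_seconds = table$features$rt_seconds[fi],
        mz = table$features$mz[fi],
        ion_mode = table$features$ion_mode[fi],
        ratio_vs_b313 = hit$ratio_vs_ref,
        p_value = hit$p_value,
        vip = hit$vip,
        strain = strain,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(), rt_seconds = numeric(),
                      mz = numeric(), ion_mode = character(),
                      ratio_vs_b313 = numeric(), p_value = numeric(),
                      vip = numeric(), strain = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
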