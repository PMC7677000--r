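#' Feature identifier from m/z and retention time
#'
#' Builds the conventional `M<mz>T<rt>` identifier used for untargeted LC-MS
#' features, with the nominal m/z and the retention time in seconds both
#' rounded half-up to integers (so `(190.0499, 192.2)` gives `"M190T192"`).
#'
#' @param mz Mass-to-charge ratio in Da; must be positive and finite.
#' @param rt_seconds Retention time in seconds; must be non-negative and finite.
#' @return Character vector of feature identifiers.
#' @examples
#' make_feature_id(190.0499, 192.2)
#' make_feature_id(124.0393, 64.8)
#' @export
make_feature_id <- function(mz, rt_seconds) {
  if (any(!is.finite(mz)) || any(!is.finite(rt_seconds)))
    stop("mz and rt_seconds must be finite")
  if (any(mz <= 0)) stop("mz must be positive")
  if (any(rt_seconds < 0)) stop("rt_seconds must be non-negative")
  # round half-up (base round() is half-to-even)
  rhu <- function(x) floor(x + 0.5)
  paste0("M", rhu(mz), "T", rhu(rt_seconds))
}

#' Construct a feature table
#'
#' A `feature_table` holds an intensity matrix (features x samples) with
#' per-feature metadata (feature_id, mz, rt_seconds, ion_mode) and per-sample
#' metadata (sample_id, group, replicate). Absent measurements are `NA`;
#' all present intensities must be positive, and a table carries exactly one
#' ion mode.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt_seconds`,
#'   `ion_mode`.
#' @param samples data.frame with columns `sample_id`, `group`, `replicate`.
#' @param intensities numeric matrix, `nrow(features)` x `nrow(samples)`,
#'   positive or `NA`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, intensities) {
  stopifnot(is.data.frame(features), is.data.frame(samples))
  req_f <- c("feature_id", "mz", "rt_seconds", "ion_mode")
  req_s <- c("sample_id", "group", "replicate")
  if (!all(req_f %in% names(features)))
    stop("features must have columns: ", paste(req_f, collapse = ", "))
  if (!all(req_s %in% names(samples)))
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) || ncol(intensities) != nrow(samples))
    stop("intensity matrix dimensions (", nrow(intensities), " x ",
         ncol(intensities), ") do not match metadata (", nrow(features),
         " features, ", nrow(samples), " samples)")
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id")
  modes <- unique(features$ion_mode)
  if (length(modes) != 1L || !modes %in% c("positive", "negative"))
    stop("a feature table must carry exactly one ion_mode ",
         "('positive' or 'negative'); found: ", paste(modes, collapse = ", "))
  present <- intensities[!is.na(intensities)]
  if (any(present <= 0))
    stop("present intensities must be positive (found value <= 0)")
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(features = features, samples = samples, intensities = intensities),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$features), " features x ",
      nrow(x$samples), " samples (", x$features$ion_mode[1], " mode)\n",
      sep = "")
  cat("groups:", paste(sort(unique(x$samples$group)), collapse = ", "), "\n")
  n_missing <- sum(is.na(x$intensities))
  cat(sprintf("missing entries: %d (%.1f%%)\n", n_missing,
              100 * n_missing / length(x$intensities)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Write a feature table to delimited text
#'
#' One feature per row: `feature_id`, `mz`, `rt_seconds`, `ion_mode`, then one
#' column per sample. Missing intensities are written as `NA`. The sample-group
#' map (`sample_id`, `group`, `replicate`) is written alongside.
#'
#' @param table A `feature_table`.
#' @param path Output path for the intensity table.
#' @param groups_path Output path for the sample-group map; defaults to
#'   `<path>` with a `.groups.tsv` suffix.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                groups_path = paste0(path, ".groups.tsv"),
                                sep = "\t") {
  stopifnot(inherits(table, "feature_table"))
  out <- cbind(table$features[c("feature_id", "mz", "rt_seconds", "ion_mode")],
               as.data.frame(table$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples[c("sample_id", "group", "replicate")],
                     groups_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from delimited text
#'
#' Expects the layout written by [write_feature_table()]: metadata columns
#' `feature_id`, `mz`, `rt_seconds`, `ion_mode` followed by one intensity
#' column per sample. The delimiter (comma or tab) is sniffed from the header
#' line. Empty cells and `NA` are treated as absent; a literal `0` intensity
#' is an error, since present intensities must be positive.
#'
#' @param path Path to the intensity table.
#' @param groups_path Path to the two-or-three-column sample map
#'   (`sample_id`, `group`, optional `replicate`).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, groups_path = paste0(path, ".groups.tsv")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  meta_cols <- c("feature_id", "mz", "rt_seconds", "ion_mode")
  if (!all(meta_cols %in% names(raw)))
    stop("feature table must start with columns: ",
         paste(meta_cols, collapse = ", "))
  gheader <- readLines(groups_path, n = 1L)
  gsep <- if (grepl("\t", gheader)) "\t" else ","
  smap <- utils::read.table(groups_path, header = TRUE, sep = gsep,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(smap)))
    stop("group map must have columns sample_id, group")
  if (is.null(smap$replicate))
    smap$replicate <- stats::ave(seq_len(nrow(smap)), smap$group,
                                 FUN = seq_along)
  sample_cols <- setdiff(names(raw), meta_cols)
  missing_map <- setdiff(sample_cols, smap$sample_id)
  if (length(missing_map))
    stop("samples missing from group map: ", paste(missing_map, collapse = ", "))
  smap <- smap[match(sample_cols, smap$sample_id), , drop = FALSE]
  rownames(smap) <- NULL
  intens <- as.matrix(raw[sample_cols])
  if (!is.numeric(intens)) stop("non-numeric intensity values")
  if (any(intens <= 0, na.rm = TRUE)) {
    bad <- which(intens <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive intensity at feature '", raw$feature_id[bad[1]],
         "', sample '", sample_cols[bad[2]],
         "': intensities must be positive or absent")
  }
  feature_table(raw[meta_cols], smap, intens)
}

#' QC filter configuration
#'
#' @param max_qc_rsd Maximum relative standard deviation (sample SD / mean,
#'   linear scale) across QC injections for a feature to be retained
#'   (default 0.30).
#' @param min_presence_fraction Minimum fraction of non-QC samples in which a
#'   feature must be present (default 0.5).
#' @return A `qc_filter_config` list.
#' @export
qc_filter_config <- function(max_qc_rsd = 0.30, min_presence_fraction = 0.5) {
  if (!(max_qc_rsd > 0 && max_qc_rsd <= 1))
    stop("max_qc_rsd must be in (0, 1]")
  if (!(min_presence_fraction > 0 && min_presence_fraction <= 1))
    stop("min_presence_fraction must be in (0, 1]")
  structure(list(max_qc_rsd = max_qc_rsd,
                 min_presence_fraction = min_presence_fraction),
            class = "qc_filter_config")
}

#' Retain high-quality features using pooled-QC replicates
#'
#' A feature is kept when (i) its relative standard deviation (sample SD over
#' mean, linear intensities) across the pooled-QC injections is at most
#' `max_qc_rsd`, and (ii) it is present (non-missing) in at least
#' `min_presence_fraction` of the non-QC samples. Features with fewer than two
#' present QC values are dropped (their technical variance cannot be
#' assessed). Feature order is preserved; the operation is idempotent.
#'
#' @param table A `feature_table` containing at least two QC samples.
#' @param config A [qc_filter_config()].
#' @return The filtered `feature_table`.
#' @export
qc_filter <- function(table, config = qc_filter_config()) {
  stopifnot(inherits(table, "feature_table"))
  qc_idx <- which(table$samples$group == "QC")
  if (length(qc_idx) < 2L)
    stop("qc_filter requires at least 2 QC samples")
  bio_idx <- setdiff(seq_len(nrow(table$samples)), qc_idx)
  qc <- table$intensities[, qc_idx, drop = FALSE]
  bio <- table$intensities[, bio_idx, drop = FALSE]
  n_qc_present <- rowSums(!is.na(qc))
  qc_mean <- rowMeans(qc, na.rm = TRUE)
  qc_sd <- apply(qc, 1L, stats::sd, na.rm = TRUE)
  rsd <- qc_sd / qc_mean
  presence <- rowMeans(!is.na(bio))
  keep <- n_qc_present >= 2L &
    !is.na(rsd) & rsd <= config$max_qc_rsd &
    presence >= config$min_presence_fraction
  subset_features(table, which(keep))
}

subset_features <- function(table, idx) {
  feature_table(table$features[idx, , drop = FALSE],
                table$samples,
                table$intensities[idx, , drop = FALSE])
}

#' Impute missing intensities
#'
#' Replaces each absent entry by half the minimum present intensity of that
#' feature (a surrogate for a value below the detection limit). Features
#' absent in every sample are removed with a warning.
#'
#' @param table A `feature_table`.
#' @return A `feature_table` with no missing entries.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  all_absent <- rowSums(!is.na(x)) == 0L
  if (any(all_absent)) {
    warning(sum(all_absent), " feature(s) absent in all samples removed")
    table <- subset_features(table, which(!all_absent))
    x <- table$intensities
  }
  if (anyNA(x)) {
    fill <- apply(x, 1L, min, na.rm = TRUE) / 2
    na_pos <- which(is.na(x), arr.ind = TRUE)
    x[na_pos] <- fill[na_pos[, 1L]]
  }
  feature_table(table$features, table$samples, x)
}

#' Normalize sample intensities
#'
#' Scales each sample so that its summary statistic (total intensity or
#' median) equals the across-sample mean of that statistic, making ratios of
#' group means comparable. `"none"` is the identity.
#'
#' @param table An imputed `feature_table` (no missing entries).
#' @param method One of `"total_intensity"`, `"median"`, `"none"`.
#' @return The normalized `feature_table`.
#' @export
normalize_intensities <- function(table,
                                  method = c("total_intensity", "median",
                                             "none")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (method == "none") return(table)
  if (anyNA(table$intensities))
    stop("normalize_intensities requires an imputed table (no missing values)")
  stat <- switch(method,
                 total_intensity = colSums(table$intensities),
                 median = apply(table$intensities, 2L, stats::median))
  if (any(stat == 0)) stop("sample with zero ", method, " cannot be normalized")
  scale_to <- mean(stat)
  x <- sweep(table$intensities, 2L, scale_to / stat, `*`)
  feature_table(table$features, table$samples, x)
}
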