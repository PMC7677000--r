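# Shared fixture builders. Everything is generated in code; no binary data.

# A feature_table from a bare intensity matrix and a group vector.
make_table <- function(intensities, groups, mode = "positive",
                       mz = NULL, rt = NULL) {
  intensities <- as.matrix(intensities)
  p <- nrow(intensities)
  if (is.null(mz)) mz <- 100 + seq_len(p)
  if (is.null(rt)) rt <- 60 + 10 * seq_len(p)
  features <- data.frame(feature_id = make_feature_id(mz, rt),
                         mz = mz, rt_seconds = rt, ion_mode = mode,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                               FUN = seq_along)),
    group = groups,
    replicate = stats::ave(seq_along(groups), groups, FUN = seq_along),
    stringsAsFactors = FALSE)
  feature_table(features, samples, intensities)
}

# A near-noiseless screening table: background features at a flat baseline,
# selected features raised by known fold changes for one strain relative to
# LB and B313. Tiny deterministic jitter keeps per-feature variances
# positive without moving group means.
make_screen_table <- function(n_features, planted, groups = c("LB", "QC",
                                                              "B108", "B313"),
                              n_reps = 6, baseline = 1e5, jitter = 1e-3,
                              seed = 1) {
  set.seed(seed)
  grp <- rep(groups, each = n_reps)
  x <- matrix(baseline, n_features, length(grp))
  for (pl in planted) {
    i <- pl$feature_index
    x[i, grp == pl$strain] <- baseline * pl$fc_vs_lb
    x[i, grp == "B313"] <- baseline * pl$fc_vs_lb / pl$fc_vs_b313
  }
  bio <- grp != "QC"
  x[, grp == "QC"] <- rowMeans(x[, bio, drop = FALSE])
  x <- x * (1 + matrix(stats::rnorm(length(x), 0, jitter), nrow(x)))
  make_table(x, grp)
}

table1_path <- function() {
  system.file("extdata", "table1_candidates.tsv", package = "symbioscreen")
}
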