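test_that("feature ids encode rounded-half-up nominal m/z and RT", {
  expect_identical(make_feature_id(190.0499, 192.2), "M190T192")
  expect_identical(make_feature_id(124.0393, 64.8), "M124T65")
  expect_identical(make_feature_id(0.4, 0), "M0T0")
  # half-up, not banker's rounding
  expect_identical(make_feature_id(2.5, 1.5), "M3T2")
  expect_error(make_feature_id(NaN, 10), "finite")
  expect_error(make_feature_id(-1, 10), "positive")
})

test_that("feature tables round-trip through delimited text", {
  sim <- simulate_feature_table(
    sim_feature_config(n_features_per_mode = 30, missing_rate = 0.1,
                       seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$table, path)
  back <- read_feature_table(path)
  expect_equal(back$features$feature_id, sim$table$features$feature_id)
  expect_equal(back$samples$group, sim$table$samples$group)
  expect_equal(back$intensities, sim$table$intensities, tolerance = 1e-12)
})

test_that("invalid tables are rejected with context", {
  tab <- make_table(matrix(1:4 * 10, 2, 2), c("LB", "QC"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  txt <- readLines(path)
  # a literal zero intensity is neither positive nor absent
  writeLines(sub("\t10\t", "\t0\t", txt), path)
  expect_error(read_feature_table(path), "positive")
  # mixed ion modes in one table
  feats <- data.frame(feature_id = c("M1T1", "M2T2"), mz = 1:2,
                      rt_seconds = 1:2,
                      ion_mode = c("positive", "negative"))
  samp <- data.frame(sample_id = "s1", group = "LB", replicate = 1)
  expect_error(feature_table(feats, samp, matrix(1:2, 2, 1)),
               "exactly one ion_mode")
  # dimension mismatch and duplicated ids
  expect_error(feature_table(feats[1, ], samp, matrix(1:2, 2, 1)),
               "dimensions")
  feats2 <- feats; feats2$feature_id <- "M1T1"; feats2$ion_mode <- "positive"
  expect_error(feature_table(feats2, samp, matrix(1:2, 2, 1)), "duplicate")
})

test_that("QC filter applies RSD and presence rules", {
  # f1: QC RSD 0 -> kept; f2: QC {100, 200}, RSD = sd/mean ~ 0.471 -> dropped;
  # f3: present in 1 of 4 biological samples -> dropped by presence rule
  x <- rbind(c(100, 100, 100, 50, 60, 70, 80),
             c(100, 200, 150, 50, 60, 70, 80),
             c(100, 100, 100, 50, NA, NA, NA))
  tab <- make_table(x, c("QC", "QC", "QC", "LB", "LB", "B108", "B108"))
  kept <- qc_filter(tab, qc_filter_config(max_qc_rsd = 0.30,
                                          min_presence_fraction = 0.5))
  expect_identical(kept$features$feature_id, tab$features$feature_id[1])
  expect_error(qc_filter(make_table(matrix(1, 1, 1), "LB")), "QC")
})

test_that("QC filter is idempotent, subsetting, and monotone in the RSD cut", {
  for (seed in 1:5) {
    sim <- simulate_feature_table(
      sim_feature_config(n_features_per_mode = 40, qc_noise_sd = 0.2,
                         missing_rate = 0.2, seed = seed))
    t1 <- qc_filter(sim$table)
    expect_true(all(t1$features$feature_id %in% sim$table$features$feature_id))
    expect_identical(qc_filter(t1)$features$feature_id,
                     t1$features$feature_id)
    loose <- qc_filter(sim$table, qc_filter_config(max_qc_rsd = 0.6))
    expect_true(all(t1$features$feature_id %in% loose$features$feature_id))
  }
})

test_that("imputation fills absent values with half the feature minimum", {
  x <- rbind(c(10, NA, 30), c(5, 6, 7))
  tab <- make_table(x, c("LB", "LB", "QC"))
  imp <- impute_missing(tab)
  expect_equal(unname(imp$intensities[1, ]), c(10, 5, 30))
  expect_equal(imp$intensities[2, ], tab$intensities[2, ])
  # a feature absent everywhere is dropped with a warning
  x2 <- rbind(c(NA, NA, NA), c(5, 6, 7))
  expect_warning(imp2 <- impute_missing(make_table(x2, c("LB", "LB", "QC"))),
                 "absent in all")
  expect_equal(nrow(imp2$features), 1L)
  # identity on complete tables
  expect_equal(impute_missing(tab)$intensities[2, ], tab$intensities[2, ])
})

test_that("normalization equalizes the sample statistic, preserving ratios", {
  x <- rbind(c(30, 100), c(70, 200))
  tab <- make_table(x, c("LB", "QC"))
  norm <- normalize_intensities(tab, "total_intensity")
  expect_equal(unname(colSums(norm$intensities)), c(200, 200))
  # within-sample ratios unchanged
  expect_equal(norm$intensities[2, ] / norm$intensities[1, ],
               tab$intensities[2, ] / tab$intensities[1, ])
  expect_identical(normalize_intensities(tab, "none"), tab)
  med <- normalize_intensities(tab, "median")
  expect_equal(unname(apply(med$intensities, 2, median)),
               rep(mean(apply(x, 2, median)), 2))
})
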