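test_that("feature-table generator is deterministic and validates input", {
  cfg <- sim_feature_config(n_features_per_mode = 25, seed = 11)
  pl <- list(planted_candidate(3, "B108", 8, 16))
  a <- simulate_feature_table(cfg, pl)
  b <- simulate_feature_table(cfg, pl)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth, b$truth)

  expect_error(simulate_feature_table(cfg, list(planted_candidate(26, "B108",
                                                                  2, 2))),
               "out of range")
  expect_error(simulate_feature_table(cfg, list(planted_candidate(1, "B999",
                                                                  2, 2))),
               "unknown group")
  expect_error(sim_feature_config(missing_rate = 1), "missing_rate")
  expect_silent(sim_feature_config(missing_rate = 0.99))
  expect_error(sim_feature_config(groups = c("LB", "B108")), "QC")
  expect_error(planted_candidate(1, character(), 2, 2), "nonempty")
  expect_error(planted_candidate(1, "B108", -2, 2), "positive")
})

test_that("planted fold changes are recovered in the generator's moments", {
  # Monte-Carlo over 200 seeds: one feature planted at fc 8 vs LB and 16 vs
  # B313; the empirical ratio of group means must sit within 20% of truth.
  ratios_lb <- ratios_b313 <- numeric(200)
  for (s in 1:200) {
    cfg <- sim_feature_config(n_features_per_mode = 100,
                              groups = c("LB", "QC", "B108", "B313"),
                              qc_noise_sd = 1e-6, missing_rate = 0, seed = s)
    sim <- simulate_feature_table(cfg, list(planted_candidate(7, "B108",
                                                              8, 16)))
    grp <- sim$table$samples$group
    x <- sim$table$intensities[7, ]
    ratios_lb[s] <- mean(x[grp == "B108"]) / mean(x[grp == "LB"])
    ratios_b313[s] <- mean(x[grp == "B108"]) / mean(x[grp == "B313"])
  }
  expect_lt(abs(mean(ratios_lb) - 8) / 8, 0.2)
  expect_lt(abs(mean(ratios_b313) - 16) / 16, 0.2)
  # QC entries of planted features are never made absent
  cfg <- sim_feature_config(n_features_per_mode = 50, missing_rate = 0.5,
                            seed = 2)
  sim <- simulate_feature_table(cfg, list(planted_candidate(5, "B108", 8, 16)))
  qc <- sim$table$samples$group == "QC"
  expect_false(anyNA(sim$table$intensities[5, qc]))
})

test_that("quant generator inverts the surface-concentration model", {
  conc <- data.frame(metabolite = c("adipic acid", "thymine"),
                     axenic = c(2.4, 0), nonaxenic = c(587.5, 0))
  q <- simulate_quant_dataset(conc, cv = 0, n_reps = 3, seed = 1)
  non <- q[q$metabolite == "adipic acid" & q$group == "nonaxenic", ]
  # 587.5 mg/l on a 0.0920 mg film -> 5.4050e-5 mg/larva -> 0.72067 mg/l
  # in a 20-larva, 1.5 ml pooled wash
  expect_equal(unique(non$extract_conc_mg_per_l), 0.7206667,
               tolerance = 1e-6)
  expect_true(all(q$extract_conc_mg_per_l[q$metabolite == "thymine"] == 0))
  q1 <- simulate_quant_dataset(conc, cv = 0.1, n_reps = 5, seed = 9)
  q2 <- simulate_quant_dataset(conc, cv = 0.1, n_reps = 5, seed = 9)
  expect_identical(q1, q2)
  expect_error(simulate_quant_dataset(
    data.frame(metabolite = "x", axenic = -1, nonaxenic = 1), seed = 1),
    ">= 0")
})

test_that("bioassay generator respects the effect model", {
  doses <- c(2, 1, 0.5, 0)
  flat <- simulate_bioassay(doses, function(d) 1, seed = 4)
  rr <- relative_rate(flat)
  expect_true(all(abs(rr$relative_rate_pct - 100) < 15))
  # monotone effect -> mean response non-increasing in dose (200 seeds)
  acc <- matrix(0, 200, length(doses))
  for (s in 1:200) {
    d <- simulate_bioassay(doses, function(x) 1 / (1 + x), seed = s)
    acc[s, ] <- tapply(d$value, d$dose_multiplier, mean)[
      as.character(sort(doses))]
  }
  mean_by_dose <- colMeans(acc)  # ascending dose order
  expect_true(all(diff(mean_by_dose) <= 0))
  expect_identical(simulate_bioassay(doses, function(d) 1 / (1 + d), seed = 2),
                   simulate_bioassay(doses, function(d) 1 / (1 + d), seed = 2))
  expect_error(simulate_bioassay(doses, function(d) 0.5), "effect_model\\(0\\)")
  expect_error(simulate_bioassay(doses, function(d) 1 + d), "\\[0, 1\\]")
  grow <- simulate_bioassay(doses, function(d) 1 / (1 + d), assay = "growth",
                            seed = 5)
  expect_true(all(grow$value >= grow$plug_diameter))
})

test_that("survival generator matches the exponential survivor function", {
  surv0 <- simulate_survival(c(A = 0), n_per_group = 20, horizon_days = 10,
                             seed = 1)
  expect_true(all(surv0$event == 0))
  expect_true(all(surv0$time_days == 10))
  expect_equal(attr(km_estimate(surv0, "A"), "final_survival"), 1.0)
  # interval-censored exponential: S(t) = exp(-h t) at grid times
  h <- 0.05
  surv <- simulate_survival(c(A = h), n_per_group = 4000, horizon_days = 40,
                            seed = 42)
  km <- km_estimate(surv, "A")
  s10 <- km$survival[km$time == 10]
  expect_lt(abs(s10 - exp(-h * 10)), 3 * sqrt(exp(-h * 10) *
                                                (1 - exp(-h * 10)) / 4000))
  expect_identical(simulate_survival(c(A = 0.1, B = 0.2), seed = 7),
                   simulate_survival(c(A = 0.1, B = 0.2), seed = 7))
  expect_error(simulate_survival(c(A = -1), seed = 1), ">= 0")
  expect_error(simulate_survival(c(0.1), seed = 1), "named")
})
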