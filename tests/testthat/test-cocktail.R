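conc_pub <- read_surface_concentrations()

test_that("the inclusion rule reproduces the seven-component cocktail", {
  recipe <- build_recipe(conc_pub, "nonaxenic", 0.1)
  expect_setequal(names(recipe),
                  c("ketoisocaproic acid", "glutaric acid", "adipic acid",
                    "phenyllactic acid", "indoleacetic acid",
                    "kynurenic acid", "picolinic acid"))
  expect_equal(recipe[["adipic acid"]], 587.5)
  expect_equal(recipe[["kynurenic acid"]], 0.1)  # sits exactly on the cut
  expect_error(build_recipe(conc_pub, "nonaxenic", 1000), "no components")
  # threshold 0 admits everything detected (thymine stays out)
  all_detected <- build_recipe(conc_pub, "nonaxenic", 0)
  expect_equal(length(all_detected), 9L)
  expect_false("thymine" %in% names(all_detected))
})

test_that("dose series scales the recipe exactly", {
  recipe <- build_recipe(conc_pub, "nonaxenic", 0.1)
  ds <- dose_series(recipe)
  expect_equal(nrow(ds), 9L)  # 8 treatment doses + control
  expect_equal(ds$dose_multiplier, c(2^(1:-6), 0))
  expect_equal(ds[ds$dose_multiplier == 0.5, "adipic acid"], 293.75)
  expect_equal(unlist(ds[ds$dose_multiplier == 1, names(recipe)]),
               unclass(recipe), ignore_attr = TRUE)
  expect_true(all(ds[ds$dose_multiplier == 0, names(recipe)] == 0))
  # linear in the recipe
  scaled <- recipe; scaled[] <- unclass(recipe) * 3
  expect_equal(as.matrix(dose_series(scaled)[-1]),
               3 * as.matrix(ds[-1]))
  expect_error(dose_series(recipe, c(2, -1)), ">= 0")
  expect_error(dose_series(recipe, c(1, 2)), "decreasing")
})

test_that("relative rates are percent of the control mean", {
  germ <- data.frame(assay = "germination",
                     dose_multiplier = rep(c(0, 1), each = 3),
                     replicate = rep(1:3, 2),
                     value = c(0.8, 0.8, 0.8, 0.10, 0.12, 0.14))
  rr <- relative_rate(germ)
  expect_equal(rr$relative_rate_pct[rr$dose_multiplier == 1], 15.0)
  expect_equal(rr$relative_rate_pct[rr$dose_multiplier == 0], 100)
  # growth subtracts the 3-mm plug before forming the ratio
  grow <- data.frame(assay = "growth",
                     dose_multiplier = rep(c(0, 1), each = 2),
                     replicate = rep(1:2, 2),
                     value = c(43, 43, 9.52, 9.52), plug_diameter = 3)
  rg <- relative_rate(grow)
  expect_equal(rg$relative_rate_pct[rg$dose_multiplier == 1],
               100 * 6.52 / 40)
  expect_error(relative_rate(germ[germ$dose_multiplier == 1, ]), "control")
  zero <- germ; zero$value[zero$dose_multiplier == 0] <- 0
  expect_error(relative_rate(transform(zero, assay = "germination")),
               "zero")
})

test_that("well-separated tight doses earn distinct, ordered letters", {
  set.seed(5)
  d <- data.frame(assay = "germination",
                  dose_multiplier = rep(c(0, 0.5, 1, 2), each = 6),
                  replicate = rep(1:6, 4),
                  value = rep(c(0.9, 0.6, 0.3, 0.1), each = 6) +
                    rnorm(24, 0, 0.01))
  s <- dose_response_summary(d)
  expect_lt(s$omnibus$p_value, 1e-6)
  expect_equal(s$groups$letters, c("a", "b", "c", "d"))
  expect_equal(s$groups$dose_multiplier, c(0, 0.5, 1, 2))
  expect_error(dose_response_summary(d[d$dose_multiplier == 0, ]),
               "two doses")
})

test_that("heteroscedastic normal doses select Welch's ANOVA", {
  picks <- character(200)
  for (s in 1:200) {
    set.seed(s)
    d <- data.frame(assay = "germination",
                    dose_multiplier = rep(c(0, 1, 2), each = 10),
                    replicate = rep(1:10, 3),
                    value = c(rnorm(10, 0.9, 0.005), rnorm(10, 0.6, 0.02),
                              rnorm(10, 0.3, 0.12)))
    picks[s] <- dose_response_summary(d)$omnibus$method
  }
  # Levene must always catch the variance ratio: plain ANOVA never fires.
  # The per-group normality checks at alpha 0.05 send ~1 - 0.95^3 of runs
  # to Kruskal-Wallis by construction, so Welch carries the rest.
  expect_equal(sum(picks == "anova"), 0L)
  expect_gte(mean(picks == "welch_anova"), 1 - 3 * 0.05 - 0.05)
})

test_that("letter display respects a total ordering when all pairs differ", {
  sig <- matrix(TRUE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(sig) <- FALSE
  cl <- symbioscreen:::compact_letters(letters[1:4], sig)
  expect_equal(unname(cl), c("a", "b", "c", "d"))
  none <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(symbioscreen:::compact_letters(letters[1:3], none) == "a"))
})
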