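test_that("PCA matches the eigendecomposition oracle and reconstructs", {
  set.seed(10)
  for (dims in list(c(5, 4), c(8, 8), c(6, 3))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    res <- pca(x, n_components = min(dims) - 1, unit_variance = FALSE)
    # oracle: eigenvalues of the covariance matrix
    ev_oracle <- eigen(stats::cov(x), symmetric = TRUE)$values
    ev_oracle <- ev_oracle / sum(ev_oracle)
    expect_equal(res$explained_variance_fraction,
                 ev_oracle[seq_along(res$explained_variance_fraction)],
                 tolerance = 1e-6)
    # scores orthogonal
    ss <- crossprod(res$scores)
    expect_equal(ss, diag(diag(ss), nrow(ss)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # loadings orthonormal
    expect_equal(crossprod(res$loadings),
                 diag(1, ncol(res$loadings)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # full reconstruction of the centered matrix
    full <- pca(x, n_components = min(dims), unit_variance = FALSE)
    xc <- sweep(x, 2, colMeans(x))
    expect_equal(full$scores %*% t(full$loadings), unname(xc),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(pca(matrix(rnorm(12), 3, 4), n_components = 4), "n_components")
})

test_that("PCA separates well-separated simulated groups on PC1", {
  sim <- simulate_feature_table(
    sim_feature_config(n_features_per_mode = 40,
                       groups = c("LB", "QC", "B108"), missing_rate = 0,
                       seed = 5),
    lapply(1:10, function(i) planted_candidate(i, "B108", 20, 20)))
  tab <- normalize_intensities(impute_missing(sim$table), "median")
  res <- pca(tab, 2)
  grp <- tab$samples$group
  pc1 <- res$scores[, 1]
  between <- abs(mean(pc1[grp == "B108"]) - mean(pc1[grp == "LB"]))
  within <- max(stats::sd(pc1[grp == "B108"]), stats::sd(pc1[grp == "LB"]))
  expect_gt(between, within)
})

test_that("PLS-DA reproduces an independent NIPALS oracle to 1e-8", {
  # fixed 6 x 5 instance; expected values frozen from an independent
  # NIPALS implementation (2 components, centered + unit-variance scaling)
  X <- matrix(c(7.9656, 9.7806, 4.3372, 3.0451, 7.8228, 2.7517, 4.9499,
                7.8503, 9.3409, 5.9913, 4.1907, 5.2005, 8.7274, 8.0746,
                6.7948, 1.5744, 9.7363, 1.3942, 7.2763, 2.153, 8.4049,
                8.4487, 9.0381, 2.3886, 1.8476, 5.0535, 4.9907, 6.685,
                8.0055, 7.1474), nrow = 6)
  labels <- c("a", "a", "a", "b", "b", "b")
  fit <- plsda_fit(X, labels, 2, log10_transform = FALSE)
  expect_equal(predict(fit, X)$y_hat,
               c(0.0422593691, -0.0675126568, 0.0362360372, 0.9514608104,
                 1.0072762638, 1.0302801763), tolerance = 1e-8)
  expect_equal(unname(vip_scores(fit)),
               c(0.9459692270, 1.1075854157, 0.9561925995, 0.2189044091,
                 1.3842591306), tolerance = 1e-8)
})

test_that("PLS-DA at full rank reproduces least-squares predictions", {
  set.seed(21)
  X <- matrix(rnorm(24), 8, 3)
  labels <- rep(c("a", "b"), each = 4)
  y <- as.numeric(labels == "b")
  fit <- plsda_fit(X, labels, n_components = 3, log10_transform = FALSE)
  Xs <- scale(X)
  ols <- stats::lm.fit(cbind(1, Xs), y)
  expect_equal(predict(fit, X)$y_hat,
               unname(drop(cbind(1, Xs) %*% ols$coefficients)),
               tolerance = 1e-6)
})

test_that("PLS-DA input validation and degenerate handling", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(plsda_fit(X, rep("a", 5), 1, log10_transform = FALSE),
               "two classes")
  expect_error(plsda_fit(X, c("a", "a", "b", "b", "c"), 1,
                         log10_transform = FALSE), "two classes")
  # constant feature is dropped with a warning
  X2 <- cbind(X, 1)
  expect_warning(fit <- plsda_fit(X2, c("a", "a", "a", "b", "b"), 1,
                                  log10_transform = FALSE), "zero-variance")
  expect_equal(nrow(fit$weights), 4L)
  # a noiseless perfect predictor dominates the weights
  set.seed(3)
  y <- rep(c(0, 1), each = 5)
  Xp <- cbind(y, matrix(rnorm(50), 10, 5))
  fitp <- plsda_fit(Xp, letters[y + 1], 1, log10_transform = FALSE)
  expect_equal(which.max(abs(fitp$weights[, 1])), 1L, ignore_attr = TRUE)
})

test_that("VIP follows its formula and the mean-square identity", {
  # hand-computed: unit-norm weights (0.8, 0.6, 0), one component
  model <- structure(list(weights = matrix(c(0.8, 0.6, 0), 3, 1),
                          y_explained_ss = 1),
                     class = "plsda_model")
  expect_equal(unname(vip_scores(model)),
               c(sqrt(3 * 0.64), sqrt(3 * 0.36), 0), tolerance = 1e-12)
  # symmetric equal weights -> all VIPs 1
  yv <- rep(c(0, 1), each = 3)
  Xeq <- matrix(rep(yv, 4), 6, 4) + 1e-9 * matrix(seq_len(24), 6, 4)
  fit_eq <- plsda_fit(Xeq, letters[yv + 1], 1, log10_transform = FALSE)
  expect_equal(unname(vip_scores(fit_eq)), rep(1, 4), tolerance = 1e-4)
  # identity mean(VIP^2) = 1 on arbitrary fitted models
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:12, 1); p <- sample(3:20, 1)
    X <- matrix(rnorm(n * p), n, p)
    labels <- sample(rep(c("a", "b"), length.out = n))
    fit <- plsda_fit(X, labels, sample(1:2, 1), log10_transform = FALSE)
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-8)
  }
  expect_error(vip_scores(structure(list(weights = matrix(1),
                                         y_explained_ss = 0),
                                    class = "plsda_model")), "degenerate")
})

test_that("permutation diagnostic passes on strong signal, rejects tiny n_perm", {
  set.seed(8)
  y <- rep(c(0, 1), each = 6)
  X <- cbind(y, matrix(rnorm(12 * 7), 12, 7))
  res <- permutation_test(10^X, letters[y + 1], n_components = 2,
                          n_perm = 50, seed = 2, k_folds = 6)
  expect_true(res$pass)
  expect_lt(res$q2_intercept, 0)
  expect_true(all(res$q2_perm < res$q2_orig))
  expect_error(permutation_test(10^X, letters[y + 1], n_perm = 5), "n_perm")
})

test_that("permutation diagnostic rarely endorses label-independent data", {
  # pass rate must stay at or below 10% over 100 null datasets
  passes <- logical(100)
  for (s in 1:100) {
    set.seed(1000 + s)
    X <- matrix(rnorm(12 * 8), 12, 8)
    labels <- rep(c("a", "b"), each = 6)
    res <- suppressWarnings(
      permutation_test(10^X, labels, n_components = 2, n_perm = 20,
                       seed = s, k_folds = 3))
    passes[s] <- res$pass
  }
  expect_lte(mean(passes), 0.10)
})
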