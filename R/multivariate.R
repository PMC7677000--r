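# Multivariate models for untargeted metabolomics screening: PCA for
# overview/outlier inspection, two-class PLS-DA (NIPALS, PLS1) with VIP
# scores, and the label-permutation overfitting diagnostic.

# Build the samples x features log10 matrix from a feature_table, or pass a
# plain numeric matrix through untouched (rows = samples).
as_sample_matrix <- function(x, log10_transform = TRUE) {
  if (inherits(x, "feature_table")) {
    if (anyNA(x$intensities))
      stop("multivariate analysis requires an imputed table")
    m <- t(x$intensities)
    if (log10_transform) m <- log10(m)
    return(m)
  }
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be a feature_table or numeric matrix")
  m
}

scale_columns <- function(x, unit_variance = TRUE) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, `-`)
  scl <- rep(1, ncol(x))
  dropped <- integer()
  if (unit_variance) {
    scl <- apply(xc, 2L, stats::sd)
    dropped <- which(scl == 0 | !is.finite(scl))
    if (length(dropped)) {
      warning(length(dropped), " zero-variance feature(s) dropped")
      xc <- xc[, -dropped, drop = FALSE]
      ctr <- ctr[-dropped]
      scl <- scl[-dropped]
    }
    xc <- sweep(xc, 2L, scl, `/`)
  }
  list(x = xc, center = ctr, scale = scl, dropped = dropped)
}

#' Principal-component analysis of a feature table
#'
#' Log10-transforms intensities (for feature tables), column-centers, and by
#' default scales features to unit variance, then takes the singular-value
#' decomposition. Components use a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x A [feature_table()] (imputed) or a numeric samples x features
#'   matrix.
#' @param n_components Number of components to return.
#' @param unit_variance Scale features to unit variance (default `TRUE`).
#' @param log10_transform Log10-transform feature-table intensities
#'   (default `TRUE`; ignored for plain matrices).
#' @return A `pca_result`: `scores` (samples x A), `loadings` (features x A,
#'   orthonormal columns), `explained_variance_fraction`, plus the centering
#'   and scaling used.
#' @export
pca <- function(x, n_components = 2, unit_variance = TRUE,
                log10_transform = TRUE) {
  m <- as_sample_matrix(x, log10_transform)
  if (nrow(m) < 2) stop("pca requires >= 2 samples")
  sc <- scale_columns(m, unit_variance)
  if (n_components > min(dim(sc$x)))
    stop("n_components exceeds min(n_samples, n_features) = ",
         min(dim(sc$x)))
  sv <- svd(sc$x)
  a <- seq_len(n_components)
  loadings <- sv$v[, a, drop = FALSE]
  scores <- sv$u[, a, drop = FALSE] %*% diag(sv$d[a], n_components)
  # sign convention: largest |loading| positive per component
  for (k in a) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(sc$x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", a)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = ev[a],
                 center = sc$center, scale = sc$scale,
                 singular_values = sv$d),
            class = "pca_result")
}

#' Fit a two-class PLS-DA model (NIPALS PLS1)
#'
#' X is log10-transformed (for feature tables), centered, and unit-variance
#' scaled; the class label is coded 0/1 (first factor level = 0) and
#' centered. Components are extracted sequentially by NIPALS with deflation:
#' per component the unit-norm weight vector `w = X'y / ||X'y||`, score
#' `t = Xw`, X-loading `p = X't / t't`, y-loading `q = y't / t't`, and the
#' explained Y sum of squares `SS = q^2 t't` (used by VIP); then
#' `X <- X - t p'`, `y <- y - t q`.
#'
#' @param x A [feature_table()] (imputed) or numeric samples x features
#'   matrix.
#' @param labels Vector of class labels, exactly two distinct values, each
#'   with at least two samples.
#' @param n_components Number of latent components (default 2).
#' @param log10_transform See [pca()].
#' @return A `plsda_model` with weights, scores, loadings, per-component
#'   explained Y sum of squares, and the preprocessing vectors; supports
#'   [predict()][predict.plsda_model] and [vip_scores()].
#' @export
plsda_fit <- function(x, labels, n_components = 2, log10_transform = TRUE) {
  m <- as_sample_matrix(x, log10_transform)
  labels <- as.character(labels)
  if (length(labels) != nrow(m))
    stop("labels length must match the number of samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2)
    stop("plsda_fit requires exactly two classes, got ", length(lev))
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")
  y_raw <- as.numeric(labels == lev[2])
  y_mean <- mean(y_raw)
  y <- y_raw - y_mean
  sc <- scale_columns(m, unit_variance = TRUE)
  X <- sc$x
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- ss <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      n_components <- a - 1L
      break
    }
    w <- w / nw
    t_a <- X %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(X, t_a) / tt
    q_a <- sum(y * t_a) / tt
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    ss[a] <- q_a^2 * tt
    X <- X - t_a %*% t(p_a)
    y <- y - t_a * q_a
  }
  if (n_components < 1) stop("degenerate model: X carries no Y covariance")
  keep <- seq_len(n_components)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  q <- q[keep]
  ss <- ss[keep]
  # regression vector on the scaled X scale
  B <- W %*% solve(crossprod(P, W), q)
  rownames(W) <- rownames(P) <- colnames(sc$x)
  structure(list(n_components = n_components, weights = W, x_loadings = P,
                 x_scores = Tm, y_loadings = q, y_explained_ss = ss,
                 coefficients = B, center = sc$center, scale = sc$scale,
                 dropped_features = sc$dropped, y_mean = y_mean,
                 levels = lev, log10_transform = log10_transform),
            class = "plsda_model")
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata A [feature_table()] or samples x features matrix with the
#'   same features the model was fitted on.
#' @param ... Unused.
#' @return data.frame with the continuous response `y_hat` (0/1 coding of
#'   the second class level) and the thresholded `class`.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  m <- as_sample_matrix(newdata, object$log10_transform)
  if (length(object$dropped_features))
    m <- m[, -object$dropped_features, drop = FALSE]
  Xs <- sweep(sweep(m, 2L, object$center, `-`), 2L, object$scale, `/`)
  y_hat <- drop(Xs %*% object$coefficients) + object$y_mean
  data.frame(y_hat = y_hat,
             class = object$levels[(y_hat > 0.5) + 1L],
             stringsAsFactors = FALSE)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )` with unit-norm
#' per-component weights, so the mean of squared VIPs over features is
#' exactly 1.
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of VIP scores (one per retained feature).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  ss <- model$y_explained_ss
  if (sum(ss) <= 0) stop("degenerate model: explained Y sum of squares is 0")
  p <- nrow(model$weights)
  vip <- sqrt(p * drop(model$weights^2 %*% ss) / sum(ss))
  names(vip) <- rownames(model$weights)
  vip
}

# Stratified, seed-deterministic K-fold Q2 (1 - PRESS/TSS).
plsda_q2 <- function(m, labels, n_components, k_folds, seed) {
  n <- nrow(m)
  lev <- sort(unique(labels))
  y <- as.numeric(labels == lev[2])
  min_class <- min(table(labels))
  k <- k_folds
  if (min_class < k) {
    k <- max(2L, min_class)
    warning("K reduced to ", k, " (smallest class has ", min_class,
            " samples)")
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in lev) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  press <- 0
  for (f in seq_len(k)) {
    test <- which(fold == f)
    fit <- plsda_fit(m[-test, , drop = FALSE], labels[-test],
                     n_components, log10_transform = FALSE)
    pred <- predict(fit, m[test, , drop = FALSE])$y_hat
    press <- press + sum((y[test] - pred)^2)
  }
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

plsda_r2 <- function(m, labels, n_components) {
  lev <- sort(unique(labels))
  y <- as.numeric(labels == lev[2])
  fit <- plsda_fit(m, labels, n_components, log10_transform = FALSE)
  pred <- predict(fit, m)$y_hat
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Permutation overfitting diagnostic for a PLS-DA model
#'
#' Refits the model under `n_perm` random permutations of the class labels,
#' recording R2 and K-fold cross-validated Q2 each time, and regresses the
#' permuted Q2 values (together with the original model at label correlation
#' 1) on the absolute correlation between permuted and original labels. The
#' model passes when every permuted Q2 falls below the original Q2 and the
#' regression line crosses the vertical axis below zero.
#'
#' @param x A [feature_table()] (imputed) or samples x features matrix.
#' @param labels Two-class label vector.
#' @param n_components Latent components (default 2).
#' @param n_perm Number of permutations (minimum 20; default 200).
#' @param seed Integer seed driving both fold assignment and permutations.
#' @param k_folds Cross-validation folds, stratified by class (default 7;
#'   reduced with a warning when a class is smaller, never below 2).
#' @return A `permutation_result` with `q2_orig`, `r2_orig`, per-permutation
#'   `q2_perm`/`r2_perm`, `y_correlations`, the `q2_intercept`, and `pass`.
#' @export
permutation_test <- function(x, labels, n_components = 2, n_perm = 200,
                             seed = 1, k_folds = 7) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  m <- as_sample_matrix(x, log10_transform = TRUE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("permutation_test requires exactly two classes")
  y <- as.numeric(labels == lev[2])
  q2_orig <- plsda_q2(m, labels, n_components, k_folds, seed)
  r2_orig <- plsda_r2(m, labels, n_components)
  q2_perm <- r2_perm <- ycor <- numeric(n_perm)
  set.seed(seed + 1L)
  perms <- replicate(n_perm, sample(labels), simplify = FALSE)
  for (i in seq_len(n_perm)) {
    lp <- perms[[i]]
    yp <- as.numeric(lp == lev[2])
    ycor[i] <- abs(stats::cor(yp, y))
    q2_perm[i] <- suppressWarnings(
      plsda_q2(m, lp, n_components, k_folds, seed))
    r2_perm[i] <- plsda_r2(m, lp, n_components)
  }
  reg <- stats::lm(q2 ~ cor,
                   data = data.frame(q2 = c(q2_perm, q2_orig),
                                     cor = c(ycor, 1)))
  intercept <- unname(stats::coef(reg)[1])
  structure(list(n_perm = n_perm, q2_orig = q2_orig, r2_orig = r2_orig,
                 q2_perm = q2_perm, r2_perm = r2_perm,
                 y_correlations = ycor, q2_intercept = intercept,
                 pass = all(q2_perm < q2_orig) && intercept < 0),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation diagnostic: %d permutations\n", x$n_perm))
  cat(sprintf("  R2 = %.3f, Q2 = %.3f\n", x$r2_orig, x$q2_orig))
  cat(sprintf("  max permuted Q2 = %.3f, Q2 intercept = %.3f\n",
              max(x$q2_perm), x$q2_intercept))
  cat("  overfitting check:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
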