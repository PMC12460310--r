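# Chemometrics baseline: NIPALS PLS2 discriminant analysis with one-hot class
# responses, Wold VIP scores, PCA scores, and the 50/25/15 random split.

#' Fit a PLS-DA model (NIPALS PLS2 on one-hot responses)
#'
#' Iterative latent-variable extraction maximizing the covariance between the
#' (auto-scaled) predictor matrix and the one-hot class indicator matrix,
#' with the usual X/Y deflation after each latent variable. Deterministic for
#' a fixed input order.
#'
#' @param X samples x variables numeric matrix.
#' @param labels class labels, one per row of `X` (>= 2 classes).
#' @param n_lv number of latent variables (<= min(n-1, p)).
#' @param scale autoscale predictors (mean-center + unit variance, the
#'   chemometrics default). Constant columns get a unit-variance guard.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return A `pls_model`: weights `W`, loadings `P`, Y-loadings `Q`, scores
#'   `T`, centering/scaling vectors, class levels, explained-Y variance per
#'   LV (`ssy`), and the regression coefficients implied by the model.
#' @export
plsda_fit <- function(X, labels, n_lv = 2L, scale = TRUE,
                      max_iter = 500L, tol = 1e-10) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("PLS-DA needs at least 2 classes")
  if (nrow(X) != length(labels)) stopf("X rows and labels length differ")
  n <- nrow(X); p <- ncol(X); k <- nlevels(labels)
  if (!is_count(n_lv) || n_lv > min(n - 1, p)) {
    stopf("n_lv must be a count <= min(n_samples - 1, n_variables)")
  }
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  x_center <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1  # constant-variable guard
    s
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_center, "-"), 2, x_scale, "/")
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center, "-")
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, k, n_lv); Tm <- matrix(0, n, n_lv)
  ssy <- numeric(n_lv)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(n_lv)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)  # Y-variance explained by this LV
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, q)
  }
  # regression coefficients on the scaled X: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_lv = n_lv, W = W, P = P, Q = Q, scores = Tm,
                 ssy = ssy, coef = B,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, levels = levels(labels),
                 scaled = scale),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs, %d variables, classes: %s\n",
              x$n_lv, nrow(x$W), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Predicted class = argmax of the predicted one-hot responses; ties are
#' broken toward the lowest class index (the first level), which
#' `which.max()` implements.
#'
#' @param model a [plsda_fit()] model.
#' @param X new samples x variables matrix with the same variable count.
#' @return List with factor `class` and matrix `scores` (per-class predicted
#'   responses).
#' @export
plsda_predict <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_center)) {
    stopf("X has %d variables but the model was fitted on %d",
          ncol(X), length(model$x_center))
  }
  Xs <- sweep(sweep(X, 2, model$x_center, "-"), 2, model$x_scale, "/")
  Yhat <- Xs %*% model$coef
  Yhat <- sweep(Yhat, 2, model$y_center, "+")
  colnames(Yhat) <- model$levels
  cls <- factor(model$levels[apply(Yhat, 1, which.max)],
                levels = model$levels)
  list(class = cls, scores = Yhat)
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP: `VIP_j = sqrt(p * sum_a ssy_a (w_ja / ||w_a||)^2 / sum_a
#' ssy_a)`, where `ssy_a` is the Y-variance explained by latent variable `a`.
#' Squared VIPs average to 1 over variables.
#'
#' @param model a fitted [plsda_fit()] model.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$n_lv < 1) stopf("model has no latent variables")
  ssy <- model$ssy
  if (sum(ssy) <= 0) stopf("model explains no Y variance; VIP undefined")
  W2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  p <- nrow(model$W)
  sqrt(p * as.vector(W2 %*% ssy) / sum(ssy))
}

#' PCA scores via centered singular value decomposition
#'
#' Thin wrapper around the SVD of the centered (optionally scaled) data with
#' a fixed sign convention: within each component, the loading with the
#' largest magnitude is made positive.
#'
#' @param X samples x variables matrix.
#' @param k number of components (<= rank).
#' @param scale divide columns by their standard deviation.
#' @return List with `scores` (n x k), `loadings` (p x k), and
#'   `explained` (fractions of total variance, length k).
#' @export
pca_scores <- function(X, k = 2L, scale = FALSE) {
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = scale)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (!is_count(k) || k > rank) stopf("k must be <= rank (%d)", rank)
  load <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {  # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, loadings = load, explained = expl[seq_len(k)])
}

#' Random train/test/external split
#'
#' Uniform random partition of `n` samples into the three sets (the study's
#' design is 50/25/15 over 90 bulbs), reproducible by seed. Optional
#' stratification allocates each class proportionally.
#'
#' @param n total number of samples.
#' @param sizes length-3 integer vector `(train, test, external)`; must sum
#'   to `n`.
#' @param seed integer seed or `NULL`.
#' @param labels class labels for stratified allocation, or `NULL` for fully
#'   random sampling (the study's choice).
#' @return A `split_spec`: list of index vectors `train`, `test`,
#'   `external`, plus `seed` and `sizes`.
#' @export
split_dataset <- function(n, sizes = c(50L, 25L, 15L), seed = NULL,
                          labels = NULL) {
  if (length(sizes) != 3 || any(sizes < 0)) stopf("sizes must be 3 non-negative counts")
  if (sum(sizes) != n) stopf("sizes must sum to n (%d != %d)", sum(sizes), n)
  idx <- with_seed(seed, {
    if (is.null(labels)) {
      sample.int(n)
    } else {
      if (length(labels) != n) stopf("labels length mismatch")
      # shuffle within class, then round-robin interleave so any prefix cut
      # is near-proportional across classes
      byclass <- lapply(split(seq_len(n), labels), sample)
      unlist(lapply(seq_len(max(lengths(byclass))), function(i)
        unlist(lapply(byclass, function(v) if (i <= length(v)) v[i]),
               use.names = FALSE)), use.names = FALSE)
    }
  })
  structure(list(train = sort(idx[seq_len(sizes[1])]),
                 test = sort(idx[sizes[1] + seq_len(sizes[2])]),
                 external = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]),
                 sizes = as.integer(sizes), seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> train %d / test %d / external %d (seed %s)\n",
              length(x$train), length(x$test), length(x$external),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
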