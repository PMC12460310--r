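# Independent oracles used to cross-check the package's implementations.
# These are deliberately literal, loop-based textbook versions, kept separate
# from the code paths they verify.

# brute-force synchronous map: explicit double loop over wavelength pairs
oracle_sync_map <- function(dyn_mat) {
  m <- nrow(dyn_mat); p <- ncol(dyn_mat)
  phi <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      phi[i, j] <- sum(dyn_mat[, i] * dyn_mat[, j]) / (m - 1)
    }
  }
  phi
}

# textbook NIPALS PLS2 (autoscaled X, centered one-hot Y), written
# independently of the package implementation
oracle_nipals <- function(X, labels, n_lv) {
  X <- as.matrix(X)
  Y <- outer(as.integer(factor(labels)), seq_len(nlevels(factor(labels))),
             function(a, b) as.numeric(a == b))
  xm <- colMeans(X); xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  E <- sweep(sweep(X, 2, xm), 2, xs, "/")
  F_ <- sweep(Y, 2, colMeans(Y))
  W <- NULL; P <- NULL; Q <- NULL; Tm <- NULL
  for (a in seq_len(n_lv)) {
    u <- F_[, which.max(apply(F_, 2, function(col) sum(col^2)))]
    repeat {
      w <- t(E) %*% u
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- t(F_) %*% t_ / sum(t_^2)
      u_new <- F_ %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * max(1, sqrt(sum(u^2)))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    p_ <- t(E) %*% t_ / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p_); Q <- cbind(Q, q)
    Tm <- cbind(Tm, t_)
  }
  list(W = W, P = P, Q = Q, scores = Tm)
}

# per-sample tally: expand a confusion count matrix into individual
# (true, predicted) pairs and recount metrics one sample at a time
oracle_metrics <- function(conf) {
  k <- nrow(conf)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    truth <- c(truth, rep(i, conf[i, j]))
    pred <- c(pred, rep(j, conf[i, j]))
  }
  n <- length(truth)
  acc <- sum(truth == pred) / n
  pre <- sen <- spe <- numeric(k)
  for (c in seq_len(k)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    tn <- sum(truth != c & pred != c)
    pre[c] <- if (tp + fp == 0) NaN else tp / (tp + fp)
    sen[c] <- if (tp + fn == 0) NaN else tp / (tp + fn)
    spe[c] <- if (tn + fp == 0) NaN else tn / (tn + fp)
  }
  list(accuracy = acc, precision = pre, sensitivity = sen, specificity = spe)
}

# a small labeled spectra set with deterministic values
tiny_spectra <- function(n = 6, p = 10, seed = 1) {
  set.seed(seed)
  spectra_set(matrix(runif(n * p, 0.2, 0.8), n, p),
              seq(400, 400 + 2 * (p - 1), by = 2),
              labels = rep(c("a", "b"), length.out = n))
}

# panel config with identical ranges in every class (no between-class
# structure) - the pure-independence / latent-only test bed
flat_panel_config <- function(sign_matrix = matrix(0, 8, 4,
                                                   dimnames = list(
                                                     fcbtrace:::ELEMENTS,
                                                     fcbtrace:::ALKALOIDS)),
                              strength = 0.8, seed = NULL) {
  lows_a <- matrix(50, 5, 4); highs_a <- matrix(150, 5, 4)
  lows_e <- matrix(10, 5, 8); highs_e <- matrix(40, 5, 8)
  cls <- fcbtrace:::FCB_CLASSES
  panel_config(
    alkaloid_ranges = array(c(lows_a, highs_a), c(5, 4, 2),
                            dimnames = list(cls, fcbtrace:::ALKALOIDS,
                                            c("low", "high"))),
    element_ranges = array(c(lows_e, highs_e), c(5, 8, 2),
                           dimnames = list(cls, fcbtrace:::ELEMENTS,
                                           c("low", "high"))),
    sign_matrix = sign_matrix, strength = strength, seed = seed)
}
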