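test_that("exact-line standards recover slope, intercept and R2 = 1", {
  conc <- c(0.5, 1, 2, 5, 10)
  curve <- fit_calibration(conc, 2 * conc + 1, "peimisine")
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 1, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy standards match the closed-form normal equations", {
  set.seed(21)
  conc <- rep(c(0.5, 1, 2, 5, 10), each = 2)
  sig <- 3.2 * conc + 0.7 + rnorm(10, sd = 0.2)
  curve <- fit_calibration(conc, sig)
  sxx <- sum((conc - mean(conc))^2)
  sxy <- sum((conc - mean(conc)) * (sig - mean(sig)))
  expect_equal(curve$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(curve$intercept, mean(sig) - curve$slope * mean(conc),
               tolerance = 1e-12)
})

test_that("duplicate standards equal the weighted fit on unique levels", {
  set.seed(22)
  lv <- c(1, 2, 4, 8)
  sig_u <- 5 * lv + 2 + rnorm(4, sd = 0.1)
  reps <- c(3, 1, 2, 2)
  conc <- rep(lv, times = reps)
  sig <- rep(sig_u, times = reps)
  curve <- fit_calibration(conc, sig)
  wfit <- lm(sig_u ~ lv, weights = reps)
  expect_equal(curve$slope, unname(coef(wfit)[2]), tolerance = 1e-10)
  expect_equal(curve$intercept, unname(coef(wfit)[1]), tolerance = 1e-10)
})

test_that("degenerate calibrations are rejected or flagged", {
  expect_error(fit_calibration(c(1, 1), c(2, 3)), "3 standards")
  expect_error(fit_calibration(c(1, 1, 1), c(2, 3, 4)), "identical")
  expect_warning(fit_calibration(c(1, 2, 3), c(9, 6, 3)), "negative")
})

test_that("quantification converts solution concentration to tissue content", {
  curve <- fit_calibration(c(0.5, 1, 2, 4), 2 * c(0.5, 1, 2, 4))
  # signal 4 -> 2 ug/mL; x 1.2 mL / 0.1 g -> 24 ug/g
  q <- quantify(4, curve, extract_volume_mL = 1.2, sample_mass_g = 0.1,
                dilution = 1)
  expect_equal(q$content, 24, tolerance = 1e-12)
  expect_false(q$below_lod)
  # blank signal reports exact 0 with the LOD flag
  q0 <- quantify(curve$intercept, curve)
  expect_equal(q0$content, 0)
  expect_true(q0$below_lod)
})

test_that("quantify inverts signal generation within the calibrated range", {
  curve <- fit_calibration(c(0.5, 1, 2, 5, 10), 1.7 * c(0.5, 1, 2, 5, 10) + 0.3)
  content <- c(12, 30, 75)         # ug/g tissue
  vol <- 1.2; mass <- 0.1; dil <- 2
  conc <- content * mass / (vol * dil)
  sig <- 1.7 * conc + 0.3
  q <- quantify(sig, curve, vol, mass, dil)
  expect_equal(q$content, content, tolerance = 1e-9)
  expect_true(any(q$extrapolated))  # 75 ug/g is outside the curve range
})

test_that("element content reproduces the blank-corrected formula exactly", {
  rec <- digest_record(C = 1.0, C0 = 0.1, V = 25, f = 1, mass = 0.2)
  expect_equal(element_content(rec), 112.5, tolerance = 1e-12)
  expect_equal(element_content(digest_record(C = 0.3, C0 = 0.3, V = 25,
                                             f = 1, mass = 0.2)), 0)
  expect_warning(
    x <- element_content(digest_record(C = 0.1, C0 = 0.3, V = 25,
                                       f = 1, mass = 0.2)),
    "negative")
  expect_lt(x, 0)
})

test_that("element content is linear in (C - C0), V, f and 1/mass", {
  set.seed(23)
  for (i in 1:1000) {
    C <- runif(1, 0.1, 5); C0 <- runif(1, 0, 0.1)
    V <- runif(1, 10, 50); f <- runif(1, 1, 10); m <- runif(1, 0.05, 1)
    base <- element_content(digest_record(C, C0, V, f, m))
    expect_equal(element_content(digest_record(C, C0, V, 2 * f, m)),
                 2 * base, tolerance = 1e-9)
    expect_equal(element_content(digest_record(C, C0, 2 * V, f, m)),
                 2 * base, tolerance = 1e-9)
    expect_equal(element_content(digest_record(C, C0, V, f, 2 * m)),
                 base / 2, tolerance = 1e-9)
    shifted <- element_content(digest_record(C + 1, C0, V, f, m))
    expect_equal(shifted - base, V * f / m, tolerance = 1e-9)
  }
  expect_error(digest_record(1, 0, -5, 1, 0.2), "positive")
  expect_error(digest_record(1, 0, 25, 0.5, 0.2), ">= 1")
})

test_that("perfect correlation reports r = 1 with a vanishing p-value", {
  x <- 1:20
  cr <- correlate_panels(cbind(e = x), cbind(a = x))
  expect_equal(cr$r[1, 1], 1)
  expect_lt(cr$p[1, 1], 1e-12)
  expect_equal(cr$stars[1, 1], "***")
})

test_that("vectorized p-values agree with cor.test for both methods", {
  set.seed(24)
  E <- matrix(rnorm(60), 15, 4)
  A <- matrix(rnorm(45), 15, 3)
  for (method in c("pearson", "spearman")) {
    cr <- correlate_panels(E, A, method = method)
    for (i in 1:4) for (j in 1:3) {
      ct <- suppressWarnings(cor.test(E[, i], A[, j], method = method))
      expect_equal(cr$r[i, j], unname(ct$estimate), tolerance = 1e-10)
      if (method == "pearson") {
        expect_equal(cr$p[i, j], ct$p.value, tolerance = 1e-10)
      } else {
        # cor.test uses an exact/AS89 Spearman null; the t transform is the
        # standard large-sample approximation
        expect_equal(cr$p[i, j], ct$p.value, tolerance = 0.05)
      }
    }
  }
})

test_that("correlation output is orientation-consistent and flags constants", {
  set.seed(25)
  E <- matrix(rnorm(40), 10, 4); A <- matrix(rnorm(20), 10, 2)
  ab <- correlate_panels(E, A)
  ba <- correlate_panels(A, E)
  expect_equal(ab$r, t(ba$r), tolerance = 1e-12)
  E2 <- E; E2[, 2] <- 3
  cr <- correlate_panels(E2, A)
  expect_true(all(is.na(cr$r[2, ])))
  expect_true(all(cr$undefined[2, ]))
  expect_error(correlate_panels(E[1:3, ], A[1:3, ]), "4 matched samples")
})

test_that("Benjamini-Hochberg adjustment only enlarges p-values", {
  set.seed(26)
  E <- matrix(rnorm(200), 20, 10); A <- matrix(rnorm(80), 20, 4)
  raw <- correlate_panels(E, A)
  adj <- correlate_panels(E, A, adjust = TRUE)
  expect_true(all(adj$p >= raw$p - 1e-12))
})
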