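test_that("default design yields 90 balanced spectra on the 400-1000 nm grid", {
  set <- generate_spectra_set(generator_config(seed = 42))
  expect_equal(dim(set), c(90L, 300L))
  expect_equal(as.vector(table(set$labels)), rep(18L, 5))
  expect_equal(levels(set$labels),
               c("AH-AC", "CZS-FC", "BM-TC", "SK-FC", "YM-AC"))
  expect_equal(set$wavelengths_nm[1], 400)
  expect_equal(set$wavelengths_nm[300], 1000)
  expect_true(all(diff(set$wavelengths_nm) > 0))
})

test_that("fixed seed reproduces bit-identical spectra and panels", {
  a <- generate_spectra_set(generator_config(seed = 7))
  b <- generate_spectra_set(generator_config(seed = 7))
  expect_identical(a$reflectance, b$reflectance)
  pa <- generate_panels(panel_config(seed = 7))
  pb <- generate_panels(panel_config(seed = 7))
  expect_identical(pa$alkaloids$values, pb$alkaloids$values)
  expect_identical(pa$elements$values, pb$elements$values)
})

test_that("equal band depths and zero noise collapse all class means", {
  depths <- matrix(0.1, 5, 4)
  cfg <- generator_config(band_depths = depths, noise_sd = 0,
                          depressed_class = NA, seed = 1)
  set <- generate_spectra_set(cfg)
  mu <- class_mean_spectra(cfg)
  for (k in 2:5) expect_equal(mu[k, ], mu[1, ])
  # every generated spectrum equals the closed-form mean exactly
  expect_equal(max(abs(sweep(set$reflectance, 2, mu[1, ]))), 0)
})

test_that("zero-noise between-class distances match the closed-form means", {
  cfg <- generator_config(noise_sd = 0, seed = 3)
  set <- generate_spectra_set(cfg)
  mu <- class_mean_spectra(cfg)
  emp <- rowsum(set$reflectance, set$labels) / 18
  expect_equal(unname(emp), unname(mu), tolerance = 1e-12)
  d_emp <- as.matrix(dist(emp))
  d_form <- as.matrix(dist(mu))
  expect_equal(d_emp, d_form, tolerance = 1e-12)
  expect_true(all(d_form[upper.tri(d_form)] > 0))
})

test_that("generated class means converge to the closed form under noise", {
  cfg <- generator_config(n_per_class = 200L, noise_sd = 0.02, seed = 5)
  set <- generate_spectra_set(cfg)
  mu <- class_mean_spectra(cfg)
  emp <- rowsum(set$reflectance, set$labels) / 200
  # jitter is uniform on a 0.02-wide band, channel noise sd 0.02:
  # per-channel sd of a class mean is well under 0.02/sqrt(200) * 5
  expect_lt(max(abs(emp - mu)), 5 * 0.02 / sqrt(200))
})

test_that("zero noise with distinct depths gives perfect nearest-mean classes", {
  cfg <- generator_config(noise_sd = 0, seed = 2)
  set <- generate_spectra_set(cfg)
  mu <- class_mean_spectra(cfg)
  d <- outer(rowSums(set$reflectance^2), rowSums(mu^2), "+") -
    2 * set$reflectance %*% t(mu)
  pred <- rownames(mu)[max.col(-d)]
  expect_equal(pred, as.character(set$labels))
})

test_that("the depressed class sits below the others over 460-750 nm", {
  cfg <- generator_config(noise_sd = 0)
  mu <- class_mean_spectra(cfg)
  w <- seq(400, 1000, length.out = 300)
  win <- w >= 470 & w <= 740 & !(abs(w - 750) < 60)  # away from band edges
  others <- colMeans(mu[-3, win])
  expect_true(all(mu[3, win] < others))
})

test_that("invalid generator settings are rejected", {
  expect_error(generator_config(wavelength_start_nm = 1000,
                                wavelength_end_nm = 400), "increasing")
  expect_error(generator_config(band_centers_nm = c(750, 1200)), "within")
  expect_error(generator_config(band_depths = matrix(-0.1, 5, 4)), ">= 0")
  expect_error(generator_config(band_depths = matrix(2, 5, 4)),
               "mean reflectance")
})

test_that("zero sign matrix gives near-independent panels at n = 90", {
  pan <- generate_panels(flat_panel_config(seed = 11), n_per_class = 18L)
  cr <- correlate_panels(pan$elements, pan$alkaloids)
  expect_true(all(abs(cr$r) < 0.3))
})

test_that("a '+' Fe-peiminine sign yields positive significant correlation", {
  sgn <- matrix(0, 8, 4, dimnames = list(fcbtrace:::ELEMENTS,
                                         fcbtrace:::ALKALOIDS))
  sgn["Fe", "peiminine"] <- 1
  pos <- 0
  for (sd in 1:25) {
    pan <- generate_panels(flat_panel_config(sign_matrix = sgn,
                                             strength = 1.5, seed = sd),
                           n_per_class = 18L)
    cr <- correlate_panels(pan$elements, pan$alkaloids)
    if (cr$r["Fe", "peiminine"] > 0 && cr$p["Fe", "peiminine"] < 0.05) {
      pos <- pos + 1
    }
  }
  expect_gte(pos, 24)  # >= 95% of seeds
})

test_that("peimine is exactly zero and LOD-flagged outside tissue culture", {
  pan <- generate_panels(panel_config(seed = 4))
  v <- pan$alkaloids$values[, "peimine"]
  lab <- pan$alkaloids$labels
  expect_true(all(v[lab != "BM-TC"] == 0))
  expect_true(all(pan$alkaloids$below_lod[lab != "BM-TC", "peimine"]))
  expect_true(all(v[lab == "BM-TC"] > 0))
})

test_that("default panel ranges are respected for latent-free analytes", {
  cfg <- panel_config(strength = 0, seed = 9)
  pan <- generate_panels(cfg)
  sk <- pan$alkaloids$labels == "SK-FC"
  peimisine <- pan$alkaloids$values[sk, "peimisine"]
  expect_true(all(peimisine >= 120.69 & peimisine <= 197.36))
  bm <- pan$elements$labels == "BM-TC"
  expect_true(all(pan$elements$values[bm, "K"] >= 13500))
})

test_that("infeasible sign matrices and bad ranges are rejected", {
  sgn <- fcbtrace:::default_sign_matrix()
  ar <- fcbtrace:::default_alkaloid_ranges()
  ar[, "peiminine", ] <- 5  # constant in every class
  expect_error(panel_config(alkaloid_ranges = ar, sign_matrix = sgn),
               "infeasible")
  ar2 <- fcbtrace:::default_alkaloid_ranges()
  ar2[1, 1, ] <- c(10, 5)
  expect_error(panel_config(alkaloid_ranges = ar2), "low")
  ar3 <- fcbtrace:::default_alkaloid_ranges()
  ar3[1, 1, 1] <- -1
  expect_error(panel_config(alkaloid_ranges = ar3), "non-negative")
  expect_error(panel_config(sign_matrix = matrix(2, 8, 4)), "-1, 0 or 1")
})

test_that("the external-validation fixture matches the reported outcome", {
  conf <- fixture_confusion()
  expect_equal(sum(conf), 15L)
  expect_equal(sum(diag(conf)), 13L)
  expect_equal(unname(rowSums(conf)), rep(3L, 5))
  off <- conf; diag(off) <- 0L
  expect_equal(sum(off != 0), 2L)
  expect_equal(conf["CZS-FC", "YM-AC"], 1L)
  expect_equal(conf["BM-TC", "CZS-FC"], 1L)
})
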