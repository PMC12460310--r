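test_that("set-mean dynamic spectra have exactly zero column sums", {
  set <- tiny_spectra(n = 5, p = 12, seed = 2)
  dyn <- dynamic_spectra(set)
  expect_lt(max(abs(colSums(dyn$reflectance))), 1e-12)
  # identical spectra self-center to zero
  same <- spectra_set(matrix(0.5, 4, 6), seq(400, 410, by = 2))
  expect_equal(max(abs(dynamic_spectra(same)$reflectance)), 0)
  # two spectra: dynamics are +/- half the difference
  two <- spectra_set(rbind(a = 1:6 / 10, b = 6:1 / 10), seq(400, 410, by = 2))
  dyn2 <- dynamic_spectra(two)
  d <- (two$reflectance[1, ] - two$reflectance[2, ]) / 2
  expect_equal(unname(dyn2$reflectance[1, ]), unname(d))
  expect_equal(unname(dyn2$reflectance[2, ]), unname(-d))
})

test_that("an explicit reference must live on the same grid", {
  set <- tiny_spectra(n = 3, p = 8)
  expect_error(dynamic_spectra(set, reference = rep(0.5, 7)), "length")
  ref <- structure(list(wavelengths_nm = set$wavelengths_nm + 5,
                        reflectance = rep(0.5, 8), sample_id = "r"),
                   class = "spectrum")
  expect_error(dynamic_spectra(set, reference = ref), "grids")
})

test_that("synchronous map reproduces the brute-force double loop", {
  for (seed in 1:5) {
    set <- tiny_spectra(n = 6, p = 15, seed = seed)
    dyn <- dynamic_spectra(set)
    sm <- synchronous_map(dyn)
    expect_lt(max(abs(sm$phi - oracle_sync_map(dyn$reflectance))), 1e-10)
    # with set-mean centering the map is the sample covariance
    expect_lt(max(abs(sm$phi - cov(set$reflectance))), 1e-10)
    expect_lt(max(abs(sm$phi - t(sm$phi))), 1e-9)
  }
})

test_that("m = 2 centered pair gives outer(d, d)/2 per the hand expansion", {
  d <- c(0.1, -0.3, 0.2, 0)
  pair <- spectra_set(rbind(d / 2, -d / 2), c(400, 410, 420, 430))
  sm <- synchronous_map(pair)
  expect_equal(sm$phi, outer(d, d) / 2, tolerance = 1e-14)
})

test_that("degenerate synchronous-map inputs error or vanish", {
  z <- spectra_set(matrix(0, 3, 4), c(400, 410, 420, 430))
  expect_equal(max(abs(synchronous_map(z)$phi)), 0)
  one <- spectra_set(matrix(1, 1, 4), c(400, 410, 420, 430))
  expect_error(synchronous_map(one), "1/\\(m-1\\)")
})

test_that("scaling dynamic spectra by c scales the map by c^2", {
  set <- tiny_spectra(n = 5, p = 10, seed = 4)
  dyn <- dynamic_spectra(set)
  sm1 <- synchronous_map(dyn)
  dyn3 <- dyn; dyn3$reflectance <- 3 * dyn$reflectance
  sm3 <- synchronous_map(dyn3)
  expect_equal(sm3$phi, 9 * sm1$phi, tolerance = 1e-12)
})

test_that("per-sample maps are rank-1, PSD, and sparse for sparse deviations", {
  w <- seq(400, 418, by = 2)
  ref <- rep(0.5, 10)
  expect_equal(max(abs(sample_sync_map(ref, ref, w)$phi)), 0)
  s <- ref; s[4] <- 0.9
  phi <- sample_sync_map(s, ref, w)$phi
  nz <- which(phi != 0, arr.ind = TRUE)
  expect_equal(unname(nz), matrix(c(4, 4), 1))
  set.seed(9)
  d <- rnorm(10)
  phi2 <- sample_sync_map(ref + d, ref, w)$phi
  ev <- eigen(phi2, symmetric = TRUE)$values
  expect_equal(ev[1], sum(d^2), tolerance = 1e-9)
  expect_lt(max(abs(ev[-1])), 1e-9)
})

test_that("averaged per-sample maps recover the full-set map", {
  set <- tiny_spectra(n = 8, p = 12, seed = 6)
  ref <- colMeans(set$reflectance)
  acc <- 0
  for (i in 1:8) {
    acc <- acc + sample_sync_map(set$reflectance[i, ], ref,
                                 set$wavelengths_nm)$phi
  }
  full <- synchronous_map(dynamic_spectra(set))$phi
  expect_lt(max(abs(acc / 8 * 8 / 7 - full)), 1e-10)
})

test_that("rendering is deterministic, sized, and symmetric in the map", {
  set <- tiny_spectra(n = 5, p = 20, seed = 3)
  sm <- synchronous_map(dynamic_spectra(set))
  spec <- render_spec(64, 48, normalization = "per-image")
  img1 <- render_map(sm, spec)
  img2 <- render_map(sm, spec)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(48L, 64L))
  expect_true(all(img1 >= 0 & img1 <= 1))
  smt <- sm; smt$phi <- t(sm$phi)
  expect_equal(render_map(smt, spec), img1, tolerance = 1e-12)
  zero <- sm; zero$phi[] <- 0
  expect_equal(length(unique(as.vector(render_map(zero, spec)))), 1L)
  bad <- sm; bad$phi[1, 1] <- NaN
  expect_error(render_map(bad, spec), "non-finite")
})

test_that("global normalization clamps to the supplied limits", {
  set <- tiny_spectra(n = 4, p = 10, seed = 5)
  sm <- synchronous_map(dynamic_spectra(set))
  spec <- render_spec(10, 10, normalization = "global",
                      limits = c(0, max(sm$phi) / 2))
  img <- render_map(sm, spec)
  expect_true(any(img == 1))  # values above the cap saturate
  expect_true(all(img >= 0 & img <= 1))
})

test_that("downsampled rendering preserves class separability", {
  set <- generate_spectra_set(generator_config(seed = 21))
  ref <- colMeans(set$reflectance)
  # nearest-centroid accuracy on raw rank-1 maps
  dev <- sweep(set$reflectance, 2, ref)
  raws <- t(apply(dev, 1, function(d) as.vector(outer(d, d))))
  ncm_acc <- function(X, lab) {
    cent <- rowsum(X, lab) / as.vector(table(lab))
    d <- outer(rowSums(X^2), rowSums(cent^2), "+") - 2 * X %*% t(cent)
    mean(rownames(cent)[max.col(-d)] == as.character(lab))
  }
  acc_raw <- ncm_acc(raws, set$labels)
  imgs <- cos_images(set, ref, size = 128L)
  acc_img <- ncm_acc(t(apply(imgs$images, 3, c)), set$labels)
  expect_gte(acc_img, acc_raw - 0.05)
})

test_that("PNG export writes grayscale and pseudocolor files", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  export_map_png(img, p1)
  export_map_png(img, p2, colormap = "viridis")
  expect_true(file.exists(p1) && file.size(p1) > 0)
  back <- png::readPNG(p1)
  expect_equal(dim(back), c(8L, 8L))
  expect_equal(length(dim(png::readPNG(p2))), 3L)
  unlink(c(p1, p2))
})
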