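# Synthetic study-design generator: five bulb sources x 18 samples, with
# class-dependent absorption bands and paper-like alkaloid/element panels.

FCB_CLASSES <- c("AH-AC", "CZS-FC", "BM-TC", "SK-FC", "YM-AC")
ALKALOIDS   <- c("peimisine", "imperialine", "peiminine", "peimine")
ELEMENTS    <- c("K", "Na", "Mn", "Fe", "Al", "Cu", "Mg", "Zn")

# Default per-class Gaussian band depths (reflectance units) at the four
# characteristic absorption centers 750/800/840/970 nm. Rows are classes.
# Patterns are distinct and no row is the negation of another about the
# column means, so rank-1 correlation images remain class-separable.
default_band_depths <- function(n_classes = 5L) {
  base <- matrix(c(
    0.10, 0.06, 0.08, 0.12,   # AH-AC
    0.14, 0.10, 0.06, 0.08,   # CZS-FC
    0.06, 0.12, 0.10, 0.06,   # BM-TC (also has the broadband 460-750 dip)
    0.08, 0.14, 0.12, 0.10,   # SK-FC
    0.12, 0.08, 0.14, 0.14),  # YM-AC
    nrow = 5, byrow = TRUE)
  if (n_classes <= 5L) return(base[seq_len(n_classes), , drop = FALSE])
  extra <- outer(seq_len(n_classes - 5L), 1:4,
                 function(i, j) 0.06 + 0.02 * ((i + j) %% 4))
  rbind(base, extra)
}

#' Configuration for the synthetic hyperspectral generator
#'
#' Describes a five-source bulb study: reflectance spectra on a 400-1000 nm
#' grid with 300 channels, class-specific Gaussian absorption bands centred at
#' 750, 800, 840 and 970 nm, and one designated class (the tissue-culture
#' source, by default class 3) whose reflectance is depressed over
#' 460-750 nm. With `noise_sd = 0` the generator is fully deterministic and
#' every spectrum equals its class's closed-form mean (see
#' [class_mean_spectra()]).
#'
#' @param n_classes number of source classes (default 5).
#' @param n_per_class samples per class (default 18; the study design).
#' @param wavelength_start_nm,wavelength_end_nm grid limits in nm.
#' @param n_channels number of equally spaced channels (default 300).
#' @param band_centers_nm absorption band centres in nm.
#' @param band_depths `n_classes x length(band_centers_nm)` matrix of
#'   non-negative Gaussian band depths (reflectance units). Defaults to a
#'   distinct per-class pattern.
#' @param band_sigma_nm Gaussian band width (standard deviation, nm).
#' @param effect_size scalar multiplying each class's deviation of band depth
#'   from the across-class mean depth; 0 removes all band-driven class
#'   signal, 1 is the default separable design.
#' @param noise_sd standard deviation of i.i.d. channel noise (reflectance
#'   units); also switches on per-sample baseline jitter.
#' @param baseline_range length-2 range of the per-sample baseline level;
#'   class means use its midpoint.
#' @param depressed_class index of the class with reduced visible
#'   reflectance, or `NA` for none.
#' @param depressed_offset reflectance reduction applied to that class.
#' @param depressed_window_nm wavelength window of the reduction.
#' @param class_names class labels; defaults to the five source codes.
#' @param seed integer seed for reproducibility, or `NULL`.
#'
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_classes = 5L, n_per_class = 18L,
                             wavelength_start_nm = 400,
                             wavelength_end_nm = 1000,
                             n_channels = 300L,
                             band_centers_nm = c(750, 800, 840, 970),
                             band_depths = NULL,
                             band_sigma_nm = 20,
                             effect_size = 1,
                             noise_sd = 0.01,
                             baseline_range = c(0.615, 0.635),
                             depressed_class = 3L,
                             depressed_offset = 0.06,
                             depressed_window_nm = c(460, 750),
                             class_names = NULL,
                             seed = NULL) {
  if (!is_count(n_classes) || n_classes < 2) stopf("n_classes must be >= 2")
  if (!is_count(n_per_class)) stopf("n_per_class must be a positive count")
  if (!is_count(n_channels) || n_channels < 2) stopf("n_channels must be >= 2")
  if (wavelength_end_nm <= wavelength_start_nm) {
    stopf("wavelength grid must be increasing: end <= start")
  }
  if (any(band_centers_nm < wavelength_start_nm |
          band_centers_nm > wavelength_end_nm)) {
    stopf("band centers must lie within the wavelength range")
  }
  if (is.null(band_depths)) band_depths <- default_band_depths(n_classes)
  band_depths <- as.matrix(band_depths)
  if (nrow(band_depths) != n_classes ||
      ncol(band_depths) != length(band_centers_nm)) {
    stopf("band_depths must be n_classes x n_bands")
  }
  if (any(band_depths < 0)) stopf("band_depths must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(baseline_range) != 2 || diff(baseline_range) < 0) {
    stopf("baseline_range must be an increasing length-2 range")
  }
  if (is.null(class_names)) {
    class_names <- if (n_classes == 5L) FCB_CLASSES else
      sprintf("class%02d", seq_len(n_classes))
  }
  if (length(class_names) != n_classes) stopf("class_names length mismatch")
  cfg <- list(
    n_classes = as.integer(n_classes), n_per_class = as.integer(n_per_class),
    wavelength_start_nm = wavelength_start_nm,
    wavelength_end_nm = wavelength_end_nm,
    n_channels = as.integer(n_channels),
    band_centers_nm = band_centers_nm, band_depths = band_depths,
    band_sigma_nm = band_sigma_nm, effect_size = effect_size,
    noise_sd = noise_sd, baseline_range = baseline_range,
    depressed_class = depressed_class, depressed_offset = depressed_offset,
    depressed_window_nm = depressed_window_nm,
    class_names = class_names, seed = seed)
  class(cfg) <- "generator_config"
  # reject depth settings that drive any class mean non-positive
  mu <- class_mean_spectra(cfg)
  if (any(mu <= 0)) stopf("band_depths produce non-positive mean reflectance")
  if (any(mu >= 1.5)) stopf("class mean reflectance must stay below 1.5")
  cfg
}

generator_grid <- function(config) {
  seq(config$wavelength_start_nm, config$wavelength_end_nm,
      length.out = config$n_channels)
}

#' Closed-form class mean spectra of the generator
#'
#' The noiseless generating curve for each class: baseline midpoint plus a
#' gentle tilt, minus the class's Gaussian absorption bands (scaled by the
#' effect size about the across-class mean depth), minus the broadband
#' visible-range offset for the depressed class.
#'
#' @param config a [generator_config()].
#' @return `n_classes x n_channels` matrix of mean reflectance.
#' @export
class_mean_spectra <- function(config) {
  w <- generator_grid(config)
  level <- mean(config$baseline_range)
  tilt <- 0.03 * (w - mean(w)) / diff(range(w))
  baseline <- level + tilt
  depth_bar <- colMeans(config$band_depths)
  depths <- sweep(config$band_depths, 2, depth_bar, "-") *
    config$effect_size
  depths <- sweep(depths, 2, depth_bar, "+")
  gauss <- vapply(config$band_centers_nm, function(c0)
    exp(-0.5 * ((w - c0) / config$band_sigma_nm)^2), numeric(length(w)))
  mu <- matrix(baseline, config$n_classes, config$n_channels, byrow = TRUE)
  mu <- mu - depths %*% t(gauss)
  if (!is.na(config$depressed_class)) {
    win <- w >= config$depressed_window_nm[1] &
      w <= config$depressed_window_nm[2]
    mu[config$depressed_class, win] <-
      mu[config$depressed_class, win] - config$depressed_offset
  }
  rownames(mu) <- config$class_names
  mu
}

#' Generate a labeled synthetic spectra set
#'
#' Draws `n_classes * n_per_class` reflectance spectra: the class's
#' closed-form mean (see [class_mean_spectra()]) plus, when `noise_sd > 0`, a
#' per-sample uniform baseline offset within `baseline_range` and i.i.d.
#' Gaussian channel noise. Reproducible under a fixed `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A [spectra_set()] with balanced class labels.
#' @export
generate_spectra_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mu <- class_mean_spectra(config)
  n <- config$n_classes * config$n_per_class
  p <- config$n_channels
  labels <- factor(rep(config$class_names, each = config$n_per_class),
                   levels = config$class_names)
  with_seed(config$seed, {
    refl <- mu[as.integer(labels), , drop = FALSE]
    if (config$noise_sd > 0) {
      jitter <- stats::runif(n, config$baseline_range[1],
                             config$baseline_range[2]) -
        mean(config$baseline_range)
      refl <- refl + jitter +
        matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    }
    spectra_set(refl, generator_grid(config), labels = labels)
  })
}

range_table <- function(lows, highs, classes, analytes) {
  lows <- as.matrix(lows); highs <- as.matrix(highs)
  arr <- array(c(lows, highs), dim = c(nrow(lows), ncol(lows), 2),
               dimnames = list(classes, analytes, c("low", "high")))
  arr
}

default_alkaloid_ranges <- function() {
  lows <- rbind(
    `AH-AC`  = c(60,    40,    0.5,  0),
    `CZS-FC` = c(70,    50,    0.5,  0),
    `BM-TC`  = c(40,    70,    1,    64.13),
    `SK-FC`  = c(120.69, 64.71, 1.53, 0),
    `YM-AC`  = c(60,    40,    0,    0))
  highs <- rbind(
    `AH-AC`  = c(100,    80,     5,     0),
    `CZS-FC` = c(110,    90,     5,     0),
    `BM-TC`  = c(70,     110,    10,    107.42),
    `SK-FC`  = c(197.36, 253.62, 17.17, 0),
    `YM-AC`  = c(100,    80,     0,     0))
  range_table(lows, highs, FCB_CLASSES, ALKALOIDS)
}

default_element_ranges <- function() {
  lows <- rbind(
    `AH-AC`  = c(7239.18, 8,     8,     40,     25,    2.35, 518.71, 12.86),
    `CZS-FC` = c(5000,    15.09, 13.65, 70.30,  43.85, 1.5,  350,    8),
    `BM-TC`  = c(13500,   22,    16.1,  116,    53,    3.7,  820,    18.2),
    `SK-FC`  = c(5000,    8,     8,     40,     25,    1.5,  350,    8),
    `YM-AC`  = c(5000,    8,     8,     40,     25,    1.5,  350,    8))
  highs <- rbind(
    `AH-AC`  = c(13342.10, 15,    13,    80,     45,    3.68, 818.63, 18.11),
    `CZS-FC` = c(9000,     21.63, 16.06, 115.85, 52.94, 3.0,  600,    14),
    `BM-TC`  = c(16000,    30,    20,    150,    70,    5.0,  1100,   25),
    `SK-FC`  = c(9000,     15,    13,    80,     45,    3.0,  600,    14),
    `YM-AC`  = c(9000,     15,    13,    80,     45,    3.0,  600,    14))
  range_table(lows, highs, FCB_CLASSES, ELEMENTS)
}

default_sign_matrix <- function() {
  # most elements correlate negatively with peimisine/imperialine and
  # positively with peiminine/peimine; covers the specifically reported
  # Fe/Mn/Al (+) peiminine and Mn (-) peimisine pairs
  m <- matrix(rep(c(-1, -1, 1, 1), each = length(ELEMENTS)),
              nrow = length(ELEMENTS),
              dimnames = list(ELEMENTS, ALKALOIDS))
  m
}

#' Configuration for the synthetic alkaloid/element panel generator
#'
#' Per-class concentration ranges for the four steroidal alkaloids (ug/g) and
#' eight mineral elements (mg/kg), plus an element x alkaloid correlation-sign
#' matrix realized via shared latent factors. Default ranges follow the
#' study's reported top-class ranges (SK-FC alkaloids; CZS-FC Al/Fe/Mn/Na;
#' AH-AC K/Mg/Cu/Zn; BM-TC peimine, which is 0 everywhere else).
#'
#' @param alkaloid_ranges `n_class x 4 x 2` array (`low`/`high`, ug/g).
#' @param element_ranges `n_class x 8 x 2` array (`low`/`high`, mg/kg).
#' @param sign_matrix element x alkaloid matrix with entries in `{-1, 0, 1}`.
#' @param strength non-negative scalar scaling the shared latent factors that
#'   realize the requested within-class correlation signs.
#' @param class_names class labels (rownames of the range arrays).
#' @param seed integer seed or `NULL`.
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(alkaloid_ranges = default_alkaloid_ranges(),
                         element_ranges = default_element_ranges(),
                         sign_matrix = default_sign_matrix(),
                         strength = 0.8,
                         class_names = NULL,
                         seed = NULL) {
  if (is.null(class_names)) class_names <- rownames(alkaloid_ranges)
  if (is.null(class_names)) stopf("class_names required")
  for (arr in list(alkaloid_ranges, element_ranges)) {
    if (length(dim(arr)) != 3 || dim(arr)[3] != 2) {
      stopf("range tables must be n_class x n_analyte x 2 arrays")
    }
    if (any(arr < 0)) stopf("concentration ranges must be non-negative")
    if (any(arr[, , 2] < arr[, , 1])) stopf("range low must be <= high")
  }
  if (!all(sign_matrix %in% c(-1, 0, 1))) {
    stopf("sign_matrix entries must be -1, 0 or 1")
  }
  if (nrow(sign_matrix) != dim(element_ranges)[2] ||
      ncol(sign_matrix) != dim(alkaloid_ranges)[2]) {
    stopf("sign_matrix must be n_elements x n_alkaloids")
  }
  if (strength < 0) stopf("strength must be >= 0")
  # infeasible sign: a requested correlation with a globally constant column
  const_alk <- apply(alkaloid_ranges, 2, function(r)
    all(r[, 2] == r[, 1]) && length(unique(r[, 1])) == 1)
  const_ele <- apply(element_ranges, 2, function(r)
    all(r[, 2] == r[, 1]) && length(unique(r[, 1])) == 1)
  bad <- which(sign_matrix != 0 &
                 (matrix(const_ele, nrow(sign_matrix), ncol(sign_matrix)) |
                    matrix(const_alk, nrow(sign_matrix), ncol(sign_matrix),
                           byrow = TRUE)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("infeasible sign matrix: correlation requested with constant analyte (e.g. %s ~ %s)",
          rownames(sign_matrix)[bad[1, 1]], colnames(sign_matrix)[bad[1, 2]])
  }
  structure(list(alkaloid_ranges = alkaloid_ranges,
                 element_ranges = element_ranges,
                 sign_matrix = sign_matrix, strength = strength,
                 class_names = class_names, seed = seed),
            class = "panel_config")
}

#' Generate paired alkaloid and element concentration panels
#'
#' Draws per-sample concentrations uniformly within each class's range, then
#' adds shared standard-normal latent factors to each (element, alkaloid)
#' pair with a non-zero requested sign so that within-class correlations have
#' that sign in expectation. Values pushed below zero are clamped to exact 0
#' and flagged below the limit of detection, matching how undetectable
#' analytes are reported.
#'
#' @param config a [panel_config()].
#' @param n_per_class samples per class.
#' @return A list with elements `alkaloids` and `elements`, each an
#'   `analyte_panel`: list of `values` (samples x analytes matrix),
#'   `below_lod` (logical matrix), `labels`, `sample_id`.
#' @export
generate_panels <- function(config, n_per_class = 18L) {
  stopifnot(inherits(config, "panel_config"))
  if (!is_count(n_per_class)) stopf("n_per_class must be a positive count")
  classes <- config$class_names
  k <- length(classes)
  n <- k * n_per_class
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  ci <- as.integer(labels)
  draw_base <- function(ranges) {
    p <- dim(ranges)[2]
    v <- matrix(0, n, p, dimnames = list(NULL, dimnames(ranges)[[2]]))
    for (j in seq_len(p)) {
      lo <- ranges[ci, j, 1]; hi <- ranges[ci, j, 2]
      v[, j] <- lo + stats::runif(n) * (hi - lo)
    }
    v
  }
  with_seed(config$seed, {
    alk <- draw_base(config$alkaloid_ranges)
    ele <- draw_base(config$element_ranges)
    wA <- (config$alkaloid_ranges[, , 2] -
             config$alkaloid_ranges[, , 1]) / sqrt(12)
    wE <- (config$element_ranges[, , 2] -
             config$element_ranges[, , 1]) / sqrt(12)
    s <- config$strength
    if (s > 0 && any(config$sign_matrix != 0)) {
      uv <- rank1_signs(config$sign_matrix)
      if (!is.null(uv)) {
        # sign matrix factors as outer(u, v): one shared latent per sample
        # realizes every requested sign coherently (within-class correlation
        # u_e * v_a * s^2 / (1 + s^2) in expectation)
        z <- stats::rnorm(n)
        for (e in seq_along(uv$u)) {
          if (uv$u[e] != 0) {
            ele[, e] <- ele[, e] + s * wE[ci, e] * uv$u[e] * z
          }
        }
        for (a in seq_along(uv$v)) {
          if (uv$v[a] != 0) {
            alk[, a] <- alk[, a] + s * wA[ci, a] * uv$v[a] * z
          }
        }
      } else {
        # general sign matrices: one latent per requested pair (weaker:
        # latents for other pairs dilute each column's share)
        for (e in seq_len(nrow(config$sign_matrix))) {
          for (a in seq_len(ncol(config$sign_matrix))) {
            sgn <- config$sign_matrix[e, a]
            if (sgn == 0) next
            z <- stats::rnorm(n)
            ele[, e] <- ele[, e] + s * wE[ci, e] * z
            alk[, a] <- alk[, a] + sgn * s * wA[ci, a] * z
          }
        }
      }
    }
    make_panel <- function(v) {
      lod <- v <= 0
      v[lod] <- 0
      structure(list(values = v, below_lod = lod, labels = labels,
                     sample_id = sprintf("S%03d", seq_len(n))),
                class = "analyte_panel")
    }
    list(alkaloids = make_panel(alk), elements = make_panel(ele))
  })
}

# try to factor a {-1,0,1} matrix as outer(u, v); NULL when not rank-1
rank1_signs <- function(S) {
  nz_rows <- which(rowSums(S != 0) > 0)
  if (length(nz_rows) == 0) return(NULL)
  v <- S[nz_rows[1], ]
  u <- integer(nrow(S))
  for (e in seq_len(nrow(S))) {
    row <- S[e, ]
    if (all(row == 0)) next
    if (all(row == v)) u[e] <- 1L
    else if (all(row == -v)) u[e] <- -1L
    else return(NULL)
  }
  list(u = u, v = v)
}

#' The study's external-validation confusion matrix
#'
#' The 5 x 5 confusion outcome over the 15-sample external validation set
#' (3 bulbs per source): 13 correct, one CZS-FC bulb predicted as YM-AC and
#' one BM-TC bulb predicted as CZS-FC. Rows are true classes, columns
#' predicted.
#'
#' @return Integer 5 x 5 matrix with the source codes as dimnames.
#' @export
fixture_confusion <- function() {
  conf <- diag(3L, 5L)
  dimnames(conf) <- list(truth = FCB_CLASSES, predicted = FCB_CLASSES)
  conf["CZS-FC", "CZS-FC"] <- 2L
  conf["CZS-FC", "YM-AC"] <- 1L
  conf["BM-TC", "BM-TC"] <- 2L
  conf["BM-TC", "CZS-FC"] <- 1L
  storage.mode(conf) <- "integer"
  conf
}
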