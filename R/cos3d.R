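# Generalized synchronous correlation spectroscopy (3DCOS): dynamic spectra,
# the synchronous map phi(v1, v2) = S(v1)' S(v2) / (m - 1), per-sample rank-1
# maps, and deterministic image rendering for the classifier.

#' Dynamic spectra (deviation from a reference)
#'
#' Replaces each spectrum by its deviation from a reference spectrum. With the
#' default set-mean reference the columns of the result sum exactly to zero,
#' which makes the synchronous map of [synchronous_map()] the sample
#' covariance matrix of the set.
#'
#' @param set a [spectra_set()] with `m >= 1` spectra.
#' @param reference `"set-mean"` (default) or a numeric spectrum on the same
#'   wavelength grid (or a `spectrum` object).
#' @return A `spectra_set` of dynamic spectra, with attribute
#'   `"reference"` storing the reference used.
#' @export
dynamic_spectra <- function(set, reference = "set-mean") {
  stopifnot(inherits(set, "spectra_set"))
  ref <- resolve_reference(set, reference)
  dyn <- sweep(set$reflectance, 2, ref, "-")
  out <- set
  out$reflectance <- dyn
  attr(out, "reference") <- ref
  out
}

resolve_reference <- function(set, reference) {
  if (identical(reference, "set-mean")) {
    return(colMeans(set$reflectance))
  }
  if (inherits(reference, "spectrum")) {
    check_same_grid(set$wavelengths_nm, reference$wavelengths_nm)
    return(reference$reflectance)
  }
  if (is.numeric(reference)) {
    if (length(reference) != length(set$wavelengths_nm)) {
      stopf("reference spectrum length does not match wavelength grid")
    }
    return(as.numeric(reference))
  }
  stopf("reference must be \"set-mean\", a numeric vector or a spectrum")
}

#' Synchronous correlation map of a dynamic spectra set
#'
#' The generalized synchronous correlation intensity over wavelength pairs:
#' `phi(v1, v2) = (1/(m-1)) * sum_k s(v1, t_k) s(v2, t_k)`, where the k-th
#' dynamic spectrum plays the role of the k-th perturbation observation.
#' When the dynamic spectra were set-mean centered, `phi` equals the sample
#' covariance matrix of the original spectra and is positive semi-definite.
#'
#' @param dynamic a [spectra_set()] of dynamic (reference-subtracted)
#'   spectra with `m >= 2` rows.
#' @return A `sync_map`: list of `wavelengths_nm`, symmetric matrix `phi`,
#'   `m_used`, and `provenance = "full-set"`.
#' @export
synchronous_map <- function(dynamic) {
  stopifnot(inherits(dynamic, "spectra_set"))
  m <- nrow(dynamic$reflectance)
  if (m < 2) {
    stopf("need m >= 2 spectra: the 1/(m-1) normalization is undefined for m = %d", m)
  }
  phi <- crossprod(dynamic$reflectance) / (m - 1)
  phi <- (phi + t(phi)) / 2  # remove float asymmetry
  new_sync_map(phi, dynamic$wavelengths_nm, "full-set", m)
}

new_sync_map <- function(phi, wavelengths_nm, provenance, m_used) {
  structure(list(wavelengths_nm = wavelengths_nm, phi = phi,
                 provenance = provenance, m_used = m_used),
            class = "sync_map")
}

#' @export
print.sync_map <- function(x, ...) {
  cat(sprintf("<sync_map> %d x %d (%s, m = %d), intensity range [%.3g, %.3g]\n",
              nrow(x$phi), ncol(x$phi), x$provenance, x$m_used,
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Per-sample synchronous map (rank-1)
#'
#' The per-sample specialization used to obtain one correlation image per
#' bulb: with deviation `s = spectrum - reference`, the map is the outer
#' product `s s'` - symmetric, positive semi-definite, rank <= 1. Averaging
#' these maps over a set (with the set mean as reference) and multiplying by
#' `m/(m-1)` recovers the full-set map of [synchronous_map()].
#'
#' @param spectrum numeric reflectance vector or a `spectrum` object.
#' @param reference reference spectrum on the same grid (numeric or
#'   `spectrum`), typically the training-set mean.
#' @param wavelengths_nm wavelength grid, required when `spectrum` is a bare
#'   numeric vector.
#' @return A `sync_map` with `provenance = "per-sample"`.
#' @export
sample_sync_map <- function(spectrum, reference, wavelengths_nm = NULL) {
  if (inherits(spectrum, "spectrum")) {
    wavelengths_nm <- spectrum$wavelengths_nm
    spectrum <- spectrum$reflectance
  }
  if (inherits(reference, "spectrum")) {
    check_same_grid(wavelengths_nm, reference$wavelengths_nm)
    reference <- reference$reflectance
  }
  if (is.null(wavelengths_nm)) stopf("wavelengths_nm required")
  if (length(spectrum) != length(reference) ||
      length(spectrum) != length(wavelengths_nm)) {
    stopf("spectrum, reference and wavelength grid lengths must match")
  }
  s <- as.numeric(spectrum) - as.numeric(reference)
  new_sync_map(tcrossprod(s), wavelengths_nm, "per-sample", 1L)
}

#' Rendering specification for correlation images
#'
#' @param width_px,height_px output image size in pixels. The acquisition
#'   convention in the source study is 875 x 656; classifier inputs default to
#'   a reduced square size set elsewhere.
#' @param colormap palette name passed to [grDevices::hcl.colors()] for PNG
#'   export (rendered arrays themselves are grayscale intensities).
#' @param normalization `"global"` (intensity limits supplied via `limits`,
#'   so the scale is shared - and class-informative - across a whole image
#'   set) or `"per-image"` (each map scaled to its own range).
#' @param limits length-2 intensity limits used by global normalization.
#' @return A `render_spec` list.
#' @export
render_spec <- function(width_px = 875L, height_px = 656L,
                        colormap = "viridis",
                        normalization = c("global", "per-image"),
                        limits = NULL) {
  normalization <- match.arg(normalization)
  if (width_px < 1 || height_px < 1) stopf("image dimensions must be positive")
  if (normalization == "global" && !is.null(limits)) {
    if (length(limits) != 2 || limits[2] <= limits[1]) {
      stopf("limits must be an increasing length-2 range")
    }
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 colormap = colormap, normalization = normalization,
                 limits = limits),
            class = "render_spec")
}

rf_c <- function(v, nc) matrix(v, length(v), nc)

# separable bilinear resample of a matrix to nr x nc (deterministic)
resize_bilinear <- function(m, nr, nc) {
  src_r <- nrow(m); src_c <- ncol(m)
  # map target pixel centers onto source pixel-center coordinates
  rx <- if (nr == 1) (src_r + 1) / 2 else seq(1, src_r, length.out = nr)
  cx <- if (nc == 1) (src_c + 1) / 2 else seq(1, src_c, length.out = nc)
  r0 <- pmin(floor(rx), src_r - 1L); rf <- rx - r0
  c0 <- pmin(floor(cx), src_c - 1L); cf <- cx - c0
  if (src_r == 1) { r0 <- rep(1, nr); rf <- rep(0, nr) }
  if (src_c == 1) { c0 <- rep(1, nc); cf <- rep(0, nc) }
  top <- m[r0, , drop = FALSE]
  bot <- m[pmin(r0 + 1, src_r), , drop = FALSE]
  rows <- top * rf_c(1 - rf, src_c) + bot * rf_c(rf, src_c)
  left <- rows[, c0, drop = FALSE]
  right <- rows[, pmin(c0 + 1, src_c), drop = FALSE]
  left * matrix(1 - cf, nr, nc, byrow = TRUE) +
    right * matrix(cf, nr, nc, byrow = TRUE)
}

#' Render a synchronous map as a deterministic intensity image
#'
#' Maps correlation intensity to `[0, 1]` under the chosen normalization and
#' resamples the square map to the requested image size with separable
#' bilinear interpolation. Pure arithmetic: identical inputs yield identical
#' arrays.
#'
#' @param map a `sync_map`.
#' @param spec a [render_spec()].
#' @return Numeric `height_px x width_px` matrix of intensities in `[0, 1]`.
#' @export
render_map <- function(map, spec = render_spec()) {
  stopifnot(inherits(map, "sync_map"), inherits(spec, "render_spec"))
  phi <- map$phi
  if (!all(is.finite(phi))) stopf("sync map contains non-finite intensities")
  lim <- switch(spec$normalization,
                "per-image" = range(phi),
                "global" = if (is.null(spec$limits)) range(phi) else spec$limits)
  den <- lim[2] - lim[1]
  z <- if (den > 0) (phi - lim[1]) / den else matrix(0.5, nrow(phi), ncol(phi))
  z[z < 0] <- 0; z[z > 1] <- 1
  resize_bilinear(z, spec$height_px, spec$width_px)
}

#' Export a rendered map (or any intensity matrix) as a PNG file
#'
#' @param img intensity matrix in `[0, 1]` (e.g. from [render_map()]).
#' @param path output PNG path.
#' @param colormap `NULL` for grayscale, or a palette name for
#'   [grDevices::hcl.colors()] pseudocolor.
#' @return `path`, invisibly.
#' @export
export_map_png <- function(img, path, colormap = NULL) {
  img[img < 0] <- 0; img[img > 1] <- 1
  if (is.null(colormap)) {
    png::writePNG(img, path)
  } else {
    pal <- grDevices::hcl.colors(256L, palette = colormap)
    idx <- pmin(255L, as.integer(img * 255)) + 1L
    rgb <- grDevices::col2rgb(pal[idx]) / 255
    arr <- array(0, c(nrow(img), ncol(img), 3))
    arr[, , 1] <- matrix(rgb[1, ], nrow(img))
    arr[, , 2] <- matrix(rgb[2, ], nrow(img))
    arr[, , 3] <- matrix(rgb[3, ], nrow(img))
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' Per-sample 3DCOS images for a whole spectra set
#'
#' Convenience wrapper used by the traceability pipeline: computes each
#' sample's rank-1 synchronous map against a common reference (typically the
#' training-set mean spectrum) and renders all maps under a shared global
#' intensity scale.
#'
#' @param set a [spectra_set()].
#' @param reference common reference spectrum (numeric vector); defaults to
#'   the mean spectrum of `set`.
#' @param size square image side in pixels (default 224).
#' @param limits global intensity limits; computed from the rendered set when
#'   `NULL` (pass training-set limits when rendering test data).
#' @return List with `images` (array `size x size x n`), `limits`, and
#'   `reference`.
#' @export
cos_images <- function(set, reference = NULL, size = 224L, limits = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(reference)) reference <- colMeans(set$reflectance)
  n <- n_spectra(set)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    maps[[i]] <- sample_sync_map(set$reflectance[i, ], reference,
                                 set$wavelengths_nm)
  }
  if (is.null(limits)) {
    limits <- range(vapply(maps, function(m) range(m$phi), numeric(2)))
    if (limits[2] <= limits[1]) limits <- limits + c(-0.5, 0.5)
  }
  spec <- render_spec(size, size, normalization = "global", limits = limits)
  imgs <- array(0, c(size, size, n))
  for (i in seq_len(n)) imgs[, , i] <- render_map(maps[[i]], spec)
  list(images = imgs, limits = limits, reference = reference)
}
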