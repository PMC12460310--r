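# Spectra and hyperspectral-cube I/O: radiometric calibration against a
# 20%-reflectance panel, ROI mean spectra, and the CSV interchange format.

#' Hyperspectral cube container
#'
#' A raw (or calibrated) image cube: `rows x cols x channels` intensities with
#' a wavelength axis and optional logical masks marking the calibration-panel
#' pixels and per-sample regions of interest.
#'
#' @param data numeric 3-D array, `rows x cols x channels`.
#' @param wavelengths_nm strictly increasing grid, length = third dimension.
#' @param panel_mask optional logical `rows x cols` matrix marking the
#'   reference-panel pixels.
#' @param calibrated logical; `TRUE` once converted to reflectance.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths_nm, panel_mask = NULL,
                       calibrated = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stopf("cube data must be rows x cols x channels")
  check_wavelength_grid(wavelengths_nm)
  if (dim(data)[3] != length(wavelengths_nm)) {
    stopf("cube has %d channels but wavelength grid has %d",
          dim(data)[3], length(wavelengths_nm))
  }
  if (!is.null(panel_mask)) {
    panel_mask <- as.matrix(panel_mask)
    if (!is.logical(panel_mask) ||
        !identical(dim(panel_mask), dim(data)[1:2])) {
      stopf("panel_mask must be a logical rows x cols matrix")
    }
    if (!any(panel_mask)) stopf("panel_mask is empty")
  }
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 panel_mask = panel_mask, calibrated = isTRUE(calibrated)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d channels (%s)\n",
              d[1], d[2], d[3],
              if (x$calibrated) "reflectance" else "raw counts"))
  invisible(x)
}

#' Radiometric calibration against a reference panel
#'
#' Converts raw counts to reflectance using the pixels of a reference panel of
#' known reflectance (20% in this study):
#' `reflectance = (raw - dark) / (panel_mean - dark) * panel_reflectance`,
#' per channel. The dark frame is optional and defaults to zero (vendor
#' software handles dark current upstream; the term is exposed for
#' completeness).
#'
#' @param raw an uncalibrated [hyper_cube()] with a `panel_mask`.
#' @param panel_reflectance known panel reflectance as a fraction
#'   (default 0.20).
#' @param dark optional dark-current cube of the same dimensions, or a single
#'   scalar offset.
#' @return A calibrated `hyper_cube` (flagged, so calibration cannot be
#'   applied twice).
#' @export
calibrate_reflectance <- function(raw, panel_reflectance = 0.20, dark = NULL) {
  stopifnot(inherits(raw, "hyper_cube"))
  if (raw$calibrated) stopf("cube is already calibrated; refusing to recalibrate")
  if (is.null(raw$panel_mask)) stopf("panel_mask missing: cannot calibrate")
  if (panel_reflectance <= 0 || panel_reflectance > 1) {
    stopf("panel_reflectance must be in (0, 1]")
  }
  d <- dim(raw$data)
  x <- raw$data
  if (!is.null(dark)) {
    dk <- if (inherits(dark, "hyper_cube")) dark$data else dark
    x <- x - dk
  }
  npanel <- sum(raw$panel_mask)
  mask_idx <- which(raw$panel_mask)
  flat <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  panel_mean <- colSums(flat[mask_idx, , drop = FALSE]) / npanel
  bad <- which(panel_mean <= 0)
  if (length(bad) > 0) {
    stopf("non-positive panel intensity at channel %d (%.1f nm)",
          bad[1], raw$wavelengths_nm[bad[1]])
  }
  refl <- sweep(flat, 2, panel_mean, "/") * panel_reflectance
  hyper_cube(array(refl, d), raw$wavelengths_nm,
             panel_mask = raw$panel_mask, calibrated = TRUE)
}

#' Mean spectrum over a region of interest
#'
#' Per-channel arithmetic mean of the masked pixels of a calibrated cube;
#' each ROI yields one sample spectrum.
#'
#' @param cube a calibrated [hyper_cube()].
#' @param roi_mask logical `rows x cols` matrix; must select at least one
#'   pixel.
#' @param sample_id identifier attached to the resulting spectrum.
#' @return A list of class `spectrum`: `wavelengths_nm`, `reflectance`,
#'   `sample_id`.
#' @export
roi_mean_spectrum <- function(cube, roi_mask, sample_id = "ROI") {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!cube$calibrated) stopf("cube must be calibrated before ROI extraction")
  roi_mask <- as.matrix(roi_mask)
  d <- dim(cube$data)
  if (!is.logical(roi_mask) || !identical(dim(roi_mask), d[1:2])) {
    stopf("roi_mask must be a logical rows x cols matrix")
  }
  if (!any(roi_mask)) stopf("roi_mask is empty")
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  m <- colMeans(flat[which(roi_mask), , drop = FALSE])
  structure(list(wavelengths_nm = cube$wavelengths_nm, reflectance = m,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' Write a spectra set to CSV
#'
#' The interchange layout: a spectra table whose first column is
#' `wavelength_nm` and remaining columns are one sample each, plus an optional
#' labels table (`sample_id`, `class`) written alongside as
#' `<stem>_labels.csv`.
#'
#' @param set a [spectra_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.frame(wavelength_nm = set$wavelengths_nm,
                   t(set$reflectance), check.names = FALSE)
  colnames(df) <- c("wavelength_nm", set$sample_id)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(set$labels)) {
    lab <- data.frame(sample_id = set$sample_id,
                      class = as.character(set$labels))
    utils::write.csv(lab, labels_path(path), row.names = FALSE)
  }
  invisible(path)
}

labels_path <- function(path) {
  sub("\\.csv$", "_labels.csv", path)
}

#' Read a spectra set from CSV
#'
#' Inverse of [write_spectra_csv()]; reads the labels table when present.
#' Ragged rows, non-monotone wavelength grids and duplicated sample ids are
#' rejected with named errors.
#'
#' @param path CSV path written by [write_spectra_csv()] (or matching its
#'   layout).
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stopf("malformed CSV '%s': %s",
                                           path, conditionMessage(e)))
  if (ncol(df) < 2 || names(df)[1] != "wavelength_nm") {
    stopf("expected first column 'wavelength_nm' in '%s'", path)
  }
  w <- df[[1]]
  if (any(diff(w) <= 0)) stopf("non-monotone wavelength grid in '%s'", path)
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) stopf("duplicated sample ids in '%s'", path)
  refl <- t(as.matrix(df[, -1, drop = FALSE]))
  if (!all(is.finite(refl))) stopf("non-finite reflectance values in '%s'", path)
  labels <- NULL
  lp <- labels_path(path)
  if (file.exists(lp)) {
    lab <- utils::read.csv(lp)
    labels <- lab$class[match(ids, lab$sample_id)]
  }
  spectra_set(refl, w, labels = labels, sample_id = ids)
}

#' Write an analyte panel to CSV
#'
#' Tidy layout: one row per (sample, analyte) with the value and the
#' below-LOD flag.
#'
#' @param panel an `analyte_panel` from [generate_panels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  v <- panel$values
  df <- data.frame(
    sample_id = rep(panel$sample_id, times = ncol(v)),
    class = rep(as.character(panel$labels), times = ncol(v)),
    analyte = rep(colnames(v), each = nrow(v)),
    value = as.vector(v),
    below_lod = as.vector(panel$below_lod))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
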