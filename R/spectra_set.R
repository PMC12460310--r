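#' Spectra set container
#'
#' A `spectra_set` holds a samples x channels reflectance matrix together with
#' its shared wavelength grid, per-sample class labels, and sample ids. It is
#' the common currency of the pipeline: the synthetic generator emits one, the
#' CSV reader/writer round-trips one, and the correlation-spectroscopy and
#' chemometrics stages consume one.
#'
#' @param reflectance numeric matrix, one row per sample, one column per
#'   spectral channel (unitless reflectance).
#' @param wavelengths_nm strictly increasing numeric wavelength grid whose
#'   length equals `ncol(reflectance)`.
#' @param labels factor or character vector of class labels, one per sample,
#'   or `NULL` for unlabeled spectra.
#' @param sample_id character vector of unique sample identifiers; generated
#'   as `S001, S002, ...` when omitted.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths_nm`, `reflectance`, `labels`, `sample_id`.
#' @export
spectra_set <- function(reflectance, wavelengths_nm, labels = NULL,
                        sample_id = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  check_wavelength_grid(wavelengths_nm)
  if (ncol(reflectance) != length(wavelengths_nm)) {
    stopf("reflectance has %d channels but wavelength grid has %d",
          ncol(reflectance), length(wavelengths_nm))
  }
  if (!all(is.finite(reflectance))) stopf("reflectance must be finite")
  n <- nrow(reflectance)
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicated sample ids")
  if (length(sample_id) != n) stopf("sample_id length mismatch")
  if (!is.null(labels)) {
    if (length(labels) != n) stopf("labels length mismatch")
    labels <- as.factor(labels)
  }
  rownames(reflectance) <- sample_id
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         reflectance = reflectance,
         labels = labels,
         sample_id = sample_id),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d channels, %.1f-%.1f nm\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

n_spectra <- function(x) nrow(x$reflectance)

check_same_grid <- function(a_nm, b_nm) {
  if (length(a_nm) != length(b_nm) ||
      max(abs(a_nm - b_nm)) > 1e-8) {
    stopf("wavelength grids do not match (no silent interpolation)")
  }
  invisible(TRUE)
}

#' Subset a spectra set by sample index
#'
#' @param x a [spectra_set()].
#' @param i integer or logical index over samples.
#' @return A `spectra_set` with the selected samples.
#' @export
subset_spectra <- function(x, i) {
  stopifnot(inherits(x, "spectra_set"))
  spectra_set(x$reflectance[i, , drop = FALSE], x$wavelengths_nm,
              labels = if (!is.null(x$labels)) x$labels[i] else NULL,
              sample_id = x$sample_id[i])
}
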