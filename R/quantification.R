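# Calibration-curve alkaloid quantification, blank-corrected mineral-element
# content from digestion records, and element-alkaloid correlation analysis.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of instrument signal on standard concentration:
#' `signal = slope * concentration + intercept`, with the coefficient of
#' determination reported. At least three standards at two or more distinct
#' concentrations are required; a negative fitted slope is flagged with a
#' warning (inverted response), not an error.
#'
#' @param concentration standard concentrations (ug/mL).
#' @param signal measured signals (instrument units).
#' @param analyte analyte name carried in the result.
#' @return A `calibration_curve`: `analyte`, `slope`, `intercept`,
#'   `r_squared`, `range` (calibrated concentration range), `n_standards`.
#' @export
fit_calibration <- function(concentration, signal, analyte = "analyte") {
  if (length(concentration) != length(signal)) {
    stopf("concentration and signal lengths differ")
  }
  if (length(concentration) < 3) stopf("need at least 3 standards")
  if (length(unique(concentration)) < 2) {
    stopf("all standard concentrations identical; cannot fit a line")
  }
  fit <- stats::lm(signal ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) stopf("fitted slope is zero; curve is not invertible")
  if (slope < 0) warnf("negative calibration slope for %s", analyte)
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r2,
                 range = range(concentration),
                 signal_range = range(signal),
                 n_standards = length(concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: signal = %.6g * conc + %.6g (R2 = %.5f)\n",
              x$analyte, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify tissue content from a sample signal
#'
#' Inverts the calibration curve to a solution concentration
#' (`(signal - intercept)/slope`, ug/mL) and converts to tissue content:
#' `ug/g = conc_solution * extract_volume_mL * dilution / sample_mass_g`.
#' Defaults follow the extraction protocol (1.2 mL of 70% methanol per 0.1 g
#' of bulb powder). Signals at or below the calibration intercept are
#' reported as exact 0 with `below_lod = TRUE`; signals outside the
#' calibrated concentration range are flagged `extrapolated`.
#'
#' @param signal measured signal(s).
#' @param curve a [fit_calibration()] curve.
#' @param extract_volume_mL extraction solvent volume (mL).
#' @param sample_mass_g weighed sample mass (g).
#' @param dilution dilution factor applied to the extract (>= 1),
#'   user-supplied because the protocol's final dilution is not fixed.
#' @return Data frame with `signal`, `conc_solution` (ug/mL), `content`
#'   (ug/g), `below_lod`, `extrapolated`.
#' @export
quantify <- function(signal, curve, extract_volume_mL = 1.2,
                     sample_mass_g = 0.1, dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stopf("calibration slope is zero")
  if (extract_volume_mL <= 0 || sample_mass_g <= 0 || dilution < 1) {
    stopf("volume/mass must be positive and dilution >= 1")
  }
  conc <- (signal - curve$intercept) / curve$slope
  below <- conc <= 0
  conc[below] <- 0
  extrapolated <- conc > curve$range[2] | (conc < curve$range[1] & !below)
  content <- conc * extract_volume_mL * dilution / sample_mass_g
  data.frame(signal = signal, conc_solution = conc, content = content,
             below_lod = below, extrapolated = extrapolated)
}

#' A single digestion measurement record
#'
#' @param C measured element concentration in the sample solution (mg/L).
#' @param C0 concentration in the reagent blank solution (mg/L).
#' @param V constant volume of the digest (mL).
#' @param f dilution multiple (>= 1).
#' @param mass sample weight (g).
#' @param element element name.
#' @return A `digest_record` list.
#' @export
digest_record <- function(C, C0, V, f = 1, mass, element = "element") {
  if (V <= 0) stopf("digest volume V must be positive")
  if (mass <= 0) stopf("sample mass must be positive")
  if (f < 1) stopf("dilution multiple f must be >= 1")
  if (C < 0 || C0 < 0) stopf("concentrations must be non-negative")
  structure(list(element = element, C = C, C0 = C0, V = V, f = f,
                 mass = mass),
            class = "digest_record")
}

#' Mineral element content of a sample (mg/kg)
#'
#' Blank-corrected content per the national-standard formula:
#' `X = (C - C0) * V * 1000 * f / (mass * 1000)`, i.e. mg/kg of dry sample.
#' A blank exceeding the sample reading yields a negative content, which is
#' returned as-is with a warning rather than clipped.
#'
#' @param rec a [digest_record()], or the individual fields as named
#'   arguments via `...` for convenience.
#' @return Numeric content in mg/kg.
#' @export
element_content <- function(rec) {
  stopifnot(inherits(rec, "digest_record"))
  x <- (rec$C - rec$C0) * rec$V * 1000 * rec$f / (rec$mass * 1000)
  if (x < 0) {
    warnf("blank exceeds sample reading for %s: negative content %.4g mg/kg",
          rec$element, x)
  }
  x
}

#' Element-alkaloid correlation analysis
#'
#' Pairwise correlation between every element and every alkaloid column, with
#' two-sided p-values from the t transform of the correlation coefficient
#' (Pearson default, Spearman optional) and significance stars. The study
#' reports unadjusted stars, so Benjamini-Hochberg adjustment is off by
#' default and available via `adjust`.
#'
#' @param elements samples x elements numeric matrix (or `analyte_panel`).
#' @param alkaloids samples x alkaloids numeric matrix (or `analyte_panel`).
#' @param method `"pearson"` or `"spearman"`.
#' @param adjust apply Benjamini-Hochberg adjustment to the p-values.
#' @return List with matrices `r`, `p`, `stars` (elements x alkaloids) and
#'   the logical matrix `undefined` flagging zero-variance pairs.
#' @export
correlate_panels <- function(elements, alkaloids,
                             method = c("pearson", "spearman"),
                             adjust = FALSE) {
  method <- match.arg(method)
  E <- panel_values(elements)
  A <- panel_values(alkaloids)
  if (nrow(E) != nrow(A)) stopf("panels have different sample counts")
  n <- nrow(E)
  if (n < 4) stopf("need at least 4 matched samples")
  if (method == "spearman") {
    E <- apply(E, 2, rank)
    A <- apply(A, 2, rank)
  }
  sdE <- apply(E, 2, stats::sd)
  sdA <- apply(A, 2, stats::sd)
  r <- suppressWarnings(stats::cor(E, A))
  undefined <- outer(sdE == 0, sdA == 0, "|")
  r[undefined] <- NA_real_
  # two-sided p from t = r sqrt((n-2)/(1-r^2)) on n-2 df
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[undefined] <- NA_real_
  if (adjust) {
    p[] <- stats::p.adjust(as.vector(p), method = "BH")
  }
  stars <- matrix(stars_for(p), nrow(p), ncol(p), dimnames = dimnames(r))
  list(r = r, p = p, stars = stars, undefined = undefined,
       method = method, n = n, adjusted = adjust)
}

panel_values <- function(x) {
  if (inherits(x, "analyte_panel")) return(x$values)
  as.matrix(x)
}

stars_for <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}
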