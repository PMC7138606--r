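#' Spectral processing configuration
#'
#' Parameters of the measurement-processing chain applied to raw
#' microspectrophotometry spectra: local-regression smoothing span (fraction
#' of points, default 0.3), clamping of negative values to zero, per-spectrum
#' minimum subtraction, and division by the white-reference correction factor
#' (default 2.5, accounting for a specular scale measured against a diffuse
#' white standard that the scale does not fill).
#'
#' @param smoothing_span smoothing span as a fraction of points, in (0, 1].
#' @param fix_negative clamp negative values to zero after smoothing.
#' @param normalize_minimum subtract the per-spectrum minimum.
#' @param white_reference_correction positive divisor applied last.
#' @return object of class `processing_config`.
#' @export
processing_config <- function(smoothing_span = 0.3, fix_negative = TRUE,
                              normalize_minimum = TRUE,
                              white_reference_correction = 2.5) {
  stopifnot(smoothing_span > 0, smoothing_span <= 1,
            white_reference_correction > 0)
  structure(list(smoothing_span = smoothing_span,
                 fix_negative = isTRUE(fix_negative),
                 normalize_minimum = isTRUE(normalize_minimum),
                 white_reference_correction = white_reference_correction),
            class = "processing_config")
}

# Tricube-weighted local linear regression (lowess with zero robustness
# iterations); span is the fraction of grid points in each local window.
smooth_span <- function(wl, value, span) {
  stats::lowess(wl, value, f = span, iter = 0)$y
}

#' Process a raw reflectance spectrum
#'
#' The processing chain, in order: local-regression smoothing (span as a
#' fraction of points) -> clamp negatives to zero -> subtract the
#' per-spectrum minimum -> divide by the white-reference correction factor.
#' The output therefore has minimum exactly zero.
#'
#' @param raw raw [spectrum()] (at least 10 points).
#' @param cfg a [processing_config()].
#' @return processed reflectance [spectrum()].
#' @export
#' @examples
#' raw <- spectrum(400:700, 0.1 + 0.5 * sin((400:700) / 40)^2)
#' p <- process_reflectance(raw)
#' min(p$value)  # exactly 0
process_reflectance <- function(raw, cfg = processing_config()) {
  stopifnot(inherits(raw, "spectrum"), inherits(cfg, "processing_config"))
  if (length(raw$value) < 10)
    stop("need at least 10 points to smooth a spectrum")
  v <- smooth_span(raw$wavelength_nm, raw$value, cfg$smoothing_span)
  if (cfg$fix_negative) v <- pmax(v, 0)
  if (cfg$normalize_minimum) v <- v - min(v)
  v <- v / cfg$white_reference_correction
  spectrum(raw$wavelength_nm, v, role = "reflectance", meta = raw$meta)
}

#' Absorbance from transmitted-light counts
#'
#' Decadic absorbance of an index-matched scale measured under transmitted
#' light: \eqn{A(\lambda) = -\log_{10}(\mathrm{sample}/\mathrm{reference})}.
#' The fraction of light not transmitted is \eqn{1 - 10^{-A}}; A = 0.2 AU
#' blocks about 37 percent of light.
#'
#' @param sample counts [spectrum()] through the specimen.
#' @param reference counts [spectrum()] without the specimen (values > 0).
#' @return absorbance [spectrum()]; nonpositive sample counts give `NA`
#'   (masked) with a warning.
#' @export
absorbance_from_transmission <- function(sample, reference) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  stopifnot_same_grid(sample, reference)
  if (any(reference$value <= 0)) stop("reference counts must be positive")
  ratio <- sample$value / reference$value
  bad <- sample$value <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive sample count(s) masked as NA")
    ratio[bad] <- NA_real_
  }
  a <- -log10(ratio)
  a[is.na(a)] <- NA_real_
  s <- spectrum(sample$wavelength_nm, ifelse(is.na(a), 0, a),
                role = "absorbance", meta = sample$meta)
  s$value[is.na(a)] <- NA_real_
  s
}

#' Fraction of light not transmitted at a given absorbance
#'
#' @param absorbance_au absorbance in AU.
#' @return fraction in [0, 1): `1 - 10^(-A)`.
#' @export
#' @examples
#' fraction_not_transmitted(0.2)  # ~0.37
fraction_not_transmitted <- function(absorbance_au) {
  stopifnot(all(absorbance_au >= 0))
  1 - 10^(-absorbance_au)
}
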