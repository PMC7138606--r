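# CIE 1931 2-degree color matching functions via the multi-lobe piecewise
# Gaussian fit of Wyman, Sloan & Shirley (2013), accurate to ~1% of peak --
# ample for qualitative hue work, and keeps the package free of tabulated
# CMF data files.
cmf_lobe <- function(wl, mu, s1, s2) {
  s <- ifelse(wl < mu, s1, s2)
  exp(-0.5 * ((wl - mu) / s)^2)
}

cie1931_cmf <- function(wl) {
  x <- 1.056 * cmf_lobe(wl, 599.8, 37.9, 31.0) +
       0.362 * cmf_lobe(wl, 442.0, 16.0, 26.7) -
       0.065 * cmf_lobe(wl, 501.1, 20.4, 26.2)
  y <- 0.821 * cmf_lobe(wl, 568.8, 46.9, 40.5) +
       0.286 * cmf_lobe(wl, 530.9, 16.3, 31.1)
  z <- 1.217 * cmf_lobe(wl, 437.0, 11.8, 36.0) +
       0.681 * cmf_lobe(wl, 459.0, 26.0, 13.8)
  cbind(x = x, y = y, z = z)
}

# CIE standard illuminant D65, relative spectral power at 10 nm intervals
# (560 nm = 100); linearly interpolated onto arbitrary grids.
d65_table <- data.frame(
  wl = seq(380, 700, by = 10),
  S = c(49.98, 54.65, 82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81,
        114.86, 115.92, 108.81, 109.35, 107.80, 104.79, 107.69, 104.41,
        104.05, 100.00, 96.33, 95.79, 88.69, 90.01, 89.60, 87.70, 83.29,
        83.70, 80.03, 80.21, 82.28, 78.28, 69.72, 71.61))

d65_spd <- function(wl) {
  stats::approx(d65_table$wl, d65_table$S, xout = wl, rule = 2)$y
}

# linear XYZ -> linear sRGB (IEC 61966-2-1, D65 white)
xyz_to_linear_srgb <- function(xyz) {
  M <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  drop(M %*% xyz)
}

srgb_gamma <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Render a reflectance spectrum to sRGB
#'
#' Deterministic colorimetric rendering: the spectrum is integrated against
#' the CIE 1931 2-degree observer under the D65 illuminant, normalized to the
#' illuminant white (so a flat spectrum is exactly achromatic), converted to
#' linear sRGB and gamma encoded with gamut clipping to [0, 1].
#'
#' @param spec reflectance [spectrum()] covering at least 400--700 nm.
#' @param scale_brightness if `TRUE`, scale the linear RGB so the largest
#'   channel is 1 before encoding (useful for visualizing dim thin-film
#'   spectra whose peak reflectance is only ~0.2).
#' @return named numeric `c(r, g, b)` in [0, 1]; the pre-clipping linear RGB
#'   is attached as attribute `"linear_rgb"`.
#' @export
#' @examples
#' render_color(cone_averaged_reflectance(thin_film(187)))
render_color <- function(spec, scale_brightness = FALSE) {
  stopifnot(inherits(spec, "spectrum"))
  wl <- spec$wavelength_nm
  if (min(wl) > 400 || max(wl) < 700)
    stop("spectrum must cover at least 400-700 nm")
  cmf <- cie1931_cmf(wl)
  S <- d65_spd(wl)
  w <- S * spec$value
  xyz <- c(sum(w * cmf[, "x"]), sum(w * cmf[, "y"]), sum(w * cmf[, "z"]))
  white <- c(sum(S * cmf[, "x"]), sum(S * cmf[, "y"]), sum(S * cmf[, "z"]))
  # adapt to the computed illuminant white, then rescale to the sRGB D65
  # white point: a flat spectrum maps to exact neutral by construction
  xyz <- xyz / white * c(0.95047, 1.0, 1.08883)
  lin <- xyz_to_linear_srgb(xyz)
  if (scale_brightness && max(lin) > 0) lin <- lin / max(lin)
  out <- srgb_gamma(pmin(pmax(lin, 0), 1))
  names(out) <- c("r", "g", "b")
  attr(out, "linear_rgb") <- lin
  out
}

#' Hue angle of an sRGB color
#'
#' HSV-style hue angle in degrees (red 0, green 120, blue 240) from a linear
#' or encoded RGB triple; used to check that a thickness sweep traverses the
#' thin-film color sequence (Newton's series).
#'
#' @param rgb numeric length-3 RGB.
#' @return hue in [0, 360); `NA` for achromatic input.
#' @export
hue_angle <- function(rgb) {
  stopifnot(length(rgb) == 3)
  mx <- max(rgb); mn <- min(rgb); d <- mx - mn
  if (d <= 0) return(NA_real_)
  h <- if (mx == rgb[1]) ((rgb[2] - rgb[3]) / d) %% 6
       else if (mx == rgb[2]) (rgb[3] - rgb[1]) / d + 2
       else (rgb[1] - rgb[2]) / d + 4
  (h * 60) %% 360
}
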