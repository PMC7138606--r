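#' Spectral grid
#'
#' A strictly increasing wavelength axis. The package default is the visible
#' window used for scale microspectrophotometry, 400--700 nm at 1 nm steps.
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths in
#'   nanometres, or `NULL` to use the default 400--700 nm, 1 nm grid.
#' @return an object of class `spectral_grid` (a numeric vector of
#'   wavelengths with a class attribute).
#' @export
#' @examples
#' g <- spectral_grid()
#' range(g)
spectral_grid <- function(wavelengths_nm = NULL) {
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq(400, 700, by = 1)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) < 2 || any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing with length >= 2")
  if (any(!is.finite(wavelengths_nm)) || any(wavelengths_nm <= 0))
    stop("wavelengths_nm must be finite and positive")
  structure(wavelengths_nm, class = "spectral_grid")
}

#' Spectrum
#'
#' Wavelength-indexed values: reflectance (fraction), absorbance (AU) or raw
#' detector counts, tagged with a role and optional specimen metadata.
#'
#' @param wavelength_nm numeric wavelength axis (or a [spectral_grid()]).
#' @param value numeric values, same length as `wavelength_nm`.
#' @param role one of `"reflectance"`, `"absorbance"`, `"counts"`.
#' @param meta named list of identifiers (specimen, scale, replicate, ...).
#' @return object of class `spectrum`: a list with elements `wavelength_nm`,
#'   `value`, `role`, `meta`.
#' @export
#' @examples
#' s <- spectrum(400:700, rep(0.1, 301))
#' wavrw(s)
spectrum <- function(wavelength_nm, value,
                     role = c("reflectance", "absorbance", "counts"),
                     meta = list()) {
  role <- match.arg(role)
  wl <- as.numeric(unclass(wavelength_nm))
  value <- as.numeric(value)
  if (length(wl) != length(value))
    stop("wavelength_nm and value must have equal length")
  if (any(diff(wl) <= 0)) stop("wavelength axis must be strictly increasing")
  if (any(!is.finite(value))) stop("spectrum values must be finite")
  structure(list(wavelength_nm = wl, value = value, role = role, meta = meta),
            class = "spectrum")
}

#' @exportS3Method base::print
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %g-%g nm, values [%.4g, %.4g]\n",
              x$role, length(x$value), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

# shared-grid check used by binary spectrum operations
stopifnot_same_grid <- function(a, b) {
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(abs(a$wavelength_nm - b$wavelength_nm) > 1e-9))
    stop("spectra are not on the same wavelength grid")
  invisible(TRUE)
}

#' Weighted average reflected wavelength
#'
#' The reflectance-weighted centroid of wavelength,
#' \eqn{\sum_\lambda \lambda R(\lambda) / \sum_\lambda R(\lambda)},
#' the scalar color metric used to group specimens alongside mean lamina
#' thickness. Invariant to positive scaling of the spectrum.
#'
#' @param spec a [spectrum()] with non-negative values and positive total.
#' @return wavelength in nm (scalar).
#' @export
wavrw <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  v <- spec$value
  if (any(v < 0)) stop("weighted average requires non-negative values")
  tot <- sum(v)
  if (tot <= 0) stop("all-zero spectrum: weighted average undefined")
  sum(spec$wavelength_nm * v) / tot
}

#' Read / write a spectrum CSV
#'
#' Two columns `wavelength_nm, value` with a header; values are written at six
#' significant digits so round trips are bit-stable at that precision.
#'
#' @param path file path.
#' @param spec a [spectrum()].
#' @param role role tag given to the spectrum read from disk.
#' @return `read_spectrum_csv` returns a [spectrum()]; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, role = "reflectance") {
  d <- utils::read.csv(path, header = TRUE)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV needs columns 'wavelength_nm' and 'value': ", path)
  spectrum(d$wavelength_nm, d$value, role = role)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  d <- data.frame(wavelength_nm = signif(spec$wavelength_nm, 6),
                  value = signif(spec$value, 6))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
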