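#' Specification of a hierarchical scale-thickness population
#'
#' Describes one treatment's lamina thickness population the way the nested
#' sampling design sees it: a treatment mean with Gaussian between-individual,
#' between-scale (within individual) and within-scale (point) components.
#' Defaults mirror the study design: 3 individuals per treatment, scales and
#' point measures sampled per individual to yield tens of measures each.
#'
#' @param treatment label.
#' @param mean_nm treatment mean thickness in nm.
#' @param sd_individual_nm,sd_scale_nm,sd_point_nm SDs of the three Gaussian
#'   components, nm.
#' @param n_individuals,n_scales_per_individual,n_points_per_scale counts.
#' @param seed RNG seed.
#' @return object of class `scale_population_spec`.
#' @export
scale_population_spec <- function(treatment = "treatment",
                                  mean_nm = 187,
                                  sd_individual_nm = 5, sd_scale_nm = 5,
                                  sd_point_nm = 14,
                                  n_individuals = 3,
                                  n_scales_per_individual = 5,
                                  n_points_per_scale = 10,
                                  seed = 1L) {
  stopifnot(mean_nm > 0, sd_individual_nm >= 0, sd_scale_nm >= 0,
            sd_point_nm >= 0, n_individuals >= 1,
            n_scales_per_individual >= 1, n_points_per_scale >= 1)
  structure(as.list(environment()), class = "scale_population_spec")
}

#' Generate a hierarchical thickness-measure table
#'
#' Draws point measures as treatment mean + individual effect + scale effect
#' + point noise (all Gaussian, truncated at positive thickness). Working
#' distances are drawn near the 9058 um reference and the INVERSE
#' working-distance correction is applied to produce `raw_nm`, so that
#' [correct_working_distance()] recovers the generated true values exactly.
#'
#' @param spec a [scale_population_spec()] or list of them (one per
#'   treatment).
#' @param wd_sd_um SD of the working-distance draw around the reference.
#' @return data.frame in the thickness-table CSV schema plus a `true_nm`
#'   column with the pre-inversion corrected values.
#' @export
#' @examples
#' d <- generate_thickness_dataset(scale_population_spec(seed = 7))
#' summarize_thickness(d)
generate_thickness_dataset <- function(spec, wd_sd_um = 300) {
  if (inherits(spec, "scale_population_spec")) spec <- list(spec)
  stopifnot(all(vapply(spec, inherits, logical(1), "scale_population_spec")))
  do.call(rbind, lapply(spec, function(sp) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(sp$seed)
    rows <- expand.grid(position_id = seq_len(sp$n_points_per_scale),
                        scale_id = seq_len(sp$n_scales_per_individual),
                        individual_id = seq_len(sp$n_individuals))
    ind_eff <- stats::rnorm(sp$n_individuals, 0, sp$sd_individual_nm)
    sc_eff <- matrix(stats::rnorm(sp$n_individuals * sp$n_scales_per_individual,
                                  0, sp$sd_scale_nm),
                     sp$n_individuals, sp$n_scales_per_individual)
    true_nm <- sp$mean_nm + ind_eff[rows$individual_id] +
      sc_eff[cbind(rows$individual_id, rows$scale_id)] +
      stats::rnorm(nrow(rows), 0, sp$sd_point_nm)
    while (any(true_nm <= 0))
      true_nm[true_nm <= 0] <- sp$mean_nm +
        stats::rnorm(sum(true_nm <= 0), 0, sp$sd_point_nm)
    wd <- stats::rnorm(nrow(rows), HIM_REFERENCE_WD_UM, wd_sd_um)
    wd <- pmax(wd, HIM_REFERENCE_WD_UM / 2)
    data.frame(treatment = sp$treatment,
               individual_id = rows$individual_id,
               scale_id = rows$scale_id,
               position_id = rows$position_id,
               raw_nm = true_nm * HIM_REFERENCE_WD_UM / wd,
               working_distance_um = wd,
               true_nm = true_nm)
  }))
}

#' Pigment absorbance profile
#'
#' Parametric stand-ins for the absorbance spectra of scale pigments:
#' Gaussian absorption bands on the 400--700 nm window. `"brown"` is a broad
#' neutral absorber (ommochrome-like), `"yellow"` a short-wavelength
#' absorber (transmits long wavelengths), `"red"` a mid-wavelength absorber.
#' Real pigment chemistry is out of scope; these emulate spectral shape only.
#'
#' @param identity `"brown"`, `"yellow"`, `"red"`, or `"none"`.
#' @param peak_au peak absorbance in AU (default 0.2, the level observed not
#'   to cancel lamina structural color).
#' @param grid a [spectral_grid()].
#' @return absorbance [spectrum()].
#' @export
pigment_profile <- function(identity = c("brown", "yellow", "red", "none"),
                            peak_au = 0.2, grid = spectral_grid()) {
  identity <- match.arg(identity)
  stopifnot(peak_au >= 0)
  wl <- as.numeric(unclass(grid))
  shape <- switch(identity,
    none = rep(0, length(wl)),
    brown = 0.85 + 0.15 * exp(-((wl - 450) / 120)^2),  # broad, near-flat
    yellow = 1 / (1 + exp((wl - 500) / 15)),           # absorbs < ~500 nm
    red = exp(-((wl - 500) / 45)^2))                   # mid band
  spectrum(wl, peak_au * shape / max(c(shape, 1e-12)),
           role = "absorbance", meta = list(identity = identity,
                                            peak_au = peak_au))
}

#' Noise model for synthetic reflectance spectra
#'
#' @param additive_sd additive Gaussian noise SD in reflectance units
#'   (default 0.01, typical of processed microspectrophotometry spectra).
#' @param pigment absorbance [spectrum()] from [pigment_profile()], or
#'   `NULL` for an unpigmented lamina.
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift in
#'   reflectance units (default 0).
#' @param seed RNG seed.
#' @return object of class `spectrum_noise_spec`.
#' @export
spectrum_noise_spec <- function(additive_sd = 0.01, pigment = NULL,
                                drift_amplitude = 0, seed = 1L) {
  stopifnot(additive_sd >= 0, drift_amplitude >= 0)
  structure(list(additive_sd = additive_sd, pigment = pigment,
                 drift_amplitude = drift_amplitude, seed = as.integer(seed)),
            class = "spectrum_noise_spec")
}

#' Generate noisy model reflectance spectra
#'
#' For each thickness: cone-averaged forward-model spectrum, optional
#' pigment filtering (double-pass Beer--Lambert), optional baseline drift,
#' plus additive Gaussian noise. Each spectrum's metadata records the
#' generating parameters so recovery tests can compare against ground truth.
#'
#' @param thicknesses_nm vector of true lamina thicknesses, nm.
#' @param noise a [spectrum_noise_spec()].
#' @param cone an [illumination_cone()].
#' @param film_index refractive index (default 1.56).
#' @param grid a [spectral_grid()].
#' @return list of reflectance [spectrum()] objects.
#' @export
generate_spectra <- function(thicknesses_nm, noise = spectrum_noise_spec(),
                             cone = illumination_cone(0.5),
                             film_index = 1.56, grid = spectral_grid()) {
  stopifnot(all(thicknesses_nm > 0),
            inherits(noise, "spectrum_noise_spec"))
  wl <- as.numeric(unclass(grid))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  M <- cone_reflectance_matrix(thicknesses_nm, wl, cone, film_index)
  lapply(seq_along(thicknesses_nm), function(i) {
    v <- M[i, ]
    if (!is.null(noise$pigment))
      v <- v * 10^(-2 * noise$pigment$value)
    if (noise$drift_amplitude > 0)
      v <- v + noise$drift_amplitude *
        sin(2 * pi * (wl - wl[1]) / diff(range(wl)) + stats::runif(1, 0, 2 * pi))
    if (noise$additive_sd > 0)
      v <- v + stats::rnorm(length(v), 0, noise$additive_sd)
    spectrum(wl, pmax(v, 0), role = "reflectance",
             meta = list(true_thickness_nm = thicknesses_nm[i],
                         additive_sd = noise$additive_sd,
                         pigment = if (is.null(noise$pigment)) "none"
                                   else noise$pigment$meta$identity))
  })
}
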