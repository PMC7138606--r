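#' Thin chitin film
#'
#' A single homogeneous dielectric film (the scale's lower lamina) bounded by
#' ambient medium on both sides. The chitin refractive index defaults to 1.56
#' and is treated as nondispersive.
#'
#' @param thickness_nm film thickness T in nm, > 0.
#' @param film_index refractive index n of the film (> ambient_index).
#' @param ambient_index index of the surrounding medium (default 1, air).
#' @return object of class `thin_film`.
#' @export
#' @examples
#' thin_film(187)
thin_film <- function(thickness_nm, film_index = 1.56, ambient_index = 1.0) {
  stopifnot(is.numeric(thickness_nm), length(thickness_nm) == 1,
            thickness_nm > 0, film_index > ambient_index, ambient_index >= 1)
  structure(list(thickness_nm = thickness_nm, film_index = film_index,
                 ambient_index = ambient_index), class = "thin_film")
}

#' Rough (uneven) film
#'
#' An uneven lamina modelled as an ensemble of ideal films whose thicknesses
#' follow a Gaussian distribution, truncated at positive thickness: mean
#' thickness plus a surface-roughness SD. Reflectance is the mean spectrum
#' over `n_draws` sampled films (default 400 draws).
#'
#' @param mean_thickness_nm mean thickness in nm, > 0.
#' @param sd_nm surface roughness SD in nm, >= 0.
#' @param n_draws number of sampled films (default 400).
#' @param seed integer seed for the draws, so spectra are reproducible.
#' @param film_index,ambient_index as in [thin_film()].
#' @return object of class `rough_film`.
#' @export
rough_film <- function(mean_thickness_nm, sd_nm, n_draws = 400L, seed = 1L,
                       film_index = 1.56, ambient_index = 1.0) {
  stopifnot(mean_thickness_nm > 0, sd_nm >= 0, n_draws >= 1,
            film_index > ambient_index, ambient_index >= 1)
  structure(list(mean_thickness_nm = mean_thickness_nm, sd_nm = sd_nm,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 film_index = film_index, ambient_index = ambient_index),
            class = "rough_film")
}

#' Objective illumination cone
#'
#' Geometry of the inverted cone of light delivered/collected by a microscope
#' objective. The maximal half-angle follows from the numerical aperture,
#' theta_max = arcsin(NA / ambient_index); NA = 0.5 in air gives 30 degrees.
#'
#' @param numerical_aperture NA of the objective, in (0, 1).
#' @param n_theta number of equally spaced angles on [0, theta_max] used in
#'   cone averaging (default 31).
#' @param ambient_index index of the medium (default 1, air).
#' @return object of class `illumination_cone` with derived `theta_max_deg`.
#' @export
#' @examples
#' illumination_cone(0.5)$theta_max_deg  # 30
illumination_cone <- function(numerical_aperture = 0.5, n_theta = 31L,
                              ambient_index = 1.0) {
  stopifnot(numerical_aperture > 0, numerical_aperture < 1, n_theta >= 1)
  theta_max <- asin(numerical_aperture / ambient_index)
  structure(list(numerical_aperture = numerical_aperture,
                 theta_max_deg = theta_max * 180 / pi,
                 theta_max_rad = theta_max,
                 n_theta = as.integer(n_theta),
                 ambient_index = ambient_index),
            class = "illumination_cone")
}

#' Fresnel amplitude coefficients at a dielectric interface
#'
#' Amplitude reflection and transmission coefficients for s and p
#' polarization at a planar interface between two lossless dielectrics, plus
#' the refracted angle from Snell's law.
#'
#' @param n1,n2 refractive indices of the incidence and transmission media.
#' @param theta_i_rad angle of incidence in radians, in [0, pi/2).
#' @return list with `r_s`, `r_p`, `t_s`, `t_p`, `theta_t_rad`. Power
#'   reflectances are `r_s^2`, `r_p^2`; power transmittances carry the usual
#'   `(n2 cos(theta_t)) / (n1 cos(theta_i))` factor.
#' @export
#' @examples
#' fresnel_interface(1, 1.56, 0)$r_s  # -0.21875
fresnel_interface <- function(n1, n2, theta_i_rad) {
  stopifnot(n1 > 0, n2 > 0, theta_i_rad >= 0, theta_i_rad < pi / 2)
  s <- n1 * sin(theta_i_rad) / n2
  if (s > 1) stop("total internal reflection: no propagating transmitted wave")
  theta_t <- asin(s)
  ci <- cos(theta_i_rad); ct <- cos(theta_t)
  r_s <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  r_p <- (n2 * ci - n1 * ct) / (n2 * ci + n1 * ct)
  t_s <- 2 * n1 * ci / (n1 * ci + n2 * ct)
  t_p <- 2 * n1 * ci / (n2 * ci + n1 * ct)
  list(r_s = r_s, r_p = r_p, t_s = t_s, t_p = t_p, theta_t_rad = theta_t)
}

# Unpolarized single-film reflectance for a T x lambda matrix at one angle of
# incidence. Airy summation per polarization:
#   r = (r1 + r2 e^{i phi}) / (1 + r1 r2 e^{i phi}),  phi = 4 pi n T cos(theta_t) / lambda
# with r1 the ambient->film and r2 the film->ambient amplitude. Vectorized
# because the inverse fit evaluates hundreds of thicknesses over the grid.
film_reflectance_matrix <- function(thickness_nm, wavelength_nm, theta_i_rad,
                                    film_index = 1.56, ambient_index = 1.0) {
  f1 <- fresnel_interface(ambient_index, film_index, theta_i_rad)
  theta_t <- f1$theta_t_rad
  f2 <- fresnel_interface(film_index, ambient_index, theta_t)
  phi <- 4 * pi * film_index * cos(theta_t) *
    outer(thickness_nm, wavelength_nm, function(T, l) T / l)
  e <- exp(1i * phi)
  Rpol <- function(r1, r2) {
    a <- (r1 + r2 * e) / (1 + r1 * r2 * e)
    Re(a * Conj(a))
  }
  (Rpol(f1$r_s, f2$r_s) + Rpol(f1$r_p, f2$r_p)) / 2
}

#' Single thin-film reflectance
#'
#' Unpolarized power reflectance of an ideal film at one wavelength and angle
#' of incidence, from the two-interface (Airy) interference sum. The phase
#' thickness is \eqn{\phi = 4\pi n T \cos\theta_t / \lambda}; s and p power
#' reflectances are averaged.
#'
#' @param film a [thin_film()].
#' @param wavelength_nm wavelength(s) in nm.
#' @param theta_i_rad angle of incidence in radians (default 0).
#' @return reflectance fraction(s) in [0, 1], one per wavelength.
#' @export
#' @examples
#' # quarter-wave maximum: ((n^2-1)/(n^2+1))^2 = 0.1743 for n = 1.56
#' film_reflectance(thin_film(550 / (4 * 1.56)), 550)
film_reflectance <- function(film, wavelength_nm, theta_i_rad = 0) {
  stopifnot(inherits(film, "thin_film"), all(wavelength_nm > 0))
  drop(film_reflectance_matrix(film$thickness_nm, wavelength_nm, theta_i_rad,
                               film$film_index, film$ambient_index))
}

# Cone-averaged reflectance matrix over a thickness vector: for each lambda,
# Rbar = sum_theta R(lambda, theta) * theta / sum_theta theta, the literal
# 2*pi*theta annulus weighting of the source description (weight = "theta").
# weight = "solid_angle" substitutes sin(theta) (off by default so defaults
# reproduce the published model).
cone_reflectance_matrix <- function(thickness_nm, wavelength_nm, cone,
                                    film_index = 1.56, ambient_index = 1.0,
                                    weight = c("theta", "solid_angle")) {
  weight <- match.arg(weight)
  thetas <- seq(0, cone$theta_max_rad, length.out = max(cone$n_theta, 2L))
  w <- switch(weight, theta = thetas, solid_angle = sin(thetas))
  # composite-trapezoid end correction on both the weighted sum and the
  # cumulative area keeps the average stable (~1e-5) when n_theta doubles
  w[c(1, length(w))] <- w[c(1, length(w))] / 2
  if (sum(w) == 0) w[] <- 1  # degenerate cone: plain normal incidence
  acc <- 0
  for (k in seq_along(thetas))
    acc <- acc + w[k] * film_reflectance_matrix(thickness_nm, wavelength_nm,
                                                thetas[k], film_index,
                                                ambient_index)
  acc / sum(w)
}

#' Cone-averaged model reflectance spectrum
#'
#' Forward model of the adwing measurement: single-film reflectance computed
#' at each angle theta from 0 to the objective's maximal illumination angle,
#' weighted by the circular annulus factor 2 pi theta and averaged over the
#' cumulative circular surface area. For a [rough_film()] the cone-averaged
#' spectra of the sampled thickness ensemble are averaged.
#'
#' @param film a [thin_film()] or [rough_film()].
#' @param grid a [spectral_grid()] (default 400--700 nm, 1 nm).
#' @param cone an [illumination_cone()] (default NA 0.5).
#' @param weight `"theta"` (the published annulus weighting, default) or
#'   `"solid_angle"` (sin theta).
#' @return a reflectance [spectrum()] on `grid`.
#' @export
#' @examples
#' s <- cone_averaged_reflectance(thin_film(187))
#' round(wavrw(s))
cone_averaged_reflectance <- function(film, grid = spectral_grid(),
                                      cone = illumination_cone(0.5),
                                      weight = c("theta", "solid_angle")) {
  weight <- match.arg(weight)
  wl <- as.numeric(unclass(grid))
  if (inherits(film, "thin_film")) {
    R <- drop(cone_reflectance_matrix(film$thickness_nm, wl, cone,
                                      film$film_index, film$ambient_index,
                                      weight))
    meta <- list(thickness_nm = film$thickness_nm)
  } else if (inherits(film, "rough_film")) {
    draws <- rtruncnorm_pos(film$n_draws, film$mean_thickness_nm, film$sd_nm,
                            film$seed)
    M <- cone_reflectance_matrix(draws, wl, cone, film$film_index,
                                 film$ambient_index, weight)
    R <- colMeans(M)
    meta <- list(thickness_nm = film$mean_thickness_nm, sd_nm = film$sd_nm)
  } else stop("film must be a thin_film or rough_film")
  spectrum(wl, R, role = "reflectance", meta = meta)
}

# Gaussian draws truncated at > 0 nm, under a local RNG state.
rtruncnorm_pos <- function(n, mean, sd, seed) {
  if (sd == 0) return(rep(mean, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Pigment-filtered composite reflectance
#'
#' Observed reflectance of a pigmented scale modelled as the lamina spectrum
#' attenuated by Beer--Lambert absorption in the overlying pigmented layer:
#' \eqn{R_{obs} = R_{lamina} 10^{-p A(\lambda)}} with `passes = 2` for light
#' crossing the layer before and after reflection. Captures the qualitative
#' masking behaviour: absorbances at or below 0.2 AU dim but do not cancel
#' the structural color, while strong absorbers (>= 2 AU) mask it.
#'
#' @param lamina reflectance [spectrum()].
#' @param pigment_absorbance absorbance [spectrum()] on the same grid, >= 0.
#' @param passes number of traversals of the pigmented layer (default 2).
#' @return a reflectance [spectrum()].
#' @export
composite_scale_reflectance <- function(lamina, pigment_absorbance,
                                        passes = 2) {
  stopifnot(inherits(lamina, "spectrum"),
            inherits(pigment_absorbance, "spectrum"), passes >= 0)
  stopifnot_same_grid(lamina, pigment_absorbance)
  if (any(pigment_absorbance$value < 0)) stop("absorbance must be >= 0")
  spectrum(lamina$wavelength_nm,
           lamina$value * 10^(-passes * pigment_absorbance$value),
           role = "reflectance", meta = lamina$meta)
}
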