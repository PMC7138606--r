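test_that("Fresnel amplitudes match closed forms at special angles", {
  # normal incidence air -> chitin
  f <- fresnel_interface(1, 1.56, 0)
  expect_equal(abs(f$r_s), 0.56 / 2.56, tolerance = 1e-12)
  expect_equal(abs(f$r_p), 0.56 / 2.56, tolerance = 1e-12)
  expect_equal(f$theta_t_rad, 0)
  # index matched: no reflection at any angle
  for (th in c(0, 0.4, 1.2)) {
    g <- fresnel_interface(1, 1, th)
    expect_equal(g$r_s, 0); expect_equal(g$r_p, 0)
  }
  # Brewster angle: p reflection vanishes
  b <- fresnel_interface(1, 1.56, atan(1.56))
  expect_equal(b$r_p, 0, tolerance = 1e-12)
  expect_gt(abs(b$r_s), 0)
  # Snell's law holds
  f2 <- fresnel_interface(1, 1.56, 0.7)
  expect_equal(sin(0.7), 1.56 * sin(f2$theta_t_rad), tolerance = 1e-12)
  # total internal reflection is a domain error
  expect_error(fresnel_interface(1.56, 1, 1.0), "total internal")
})

test_that("single-interface energy balance R + T = 1", {
  for (th in seq(0, 1.4, by = 0.2)) {
    f <- fresnel_interface(1, 1.56, th)
    fac <- 1.56 * cos(f$theta_t_rad) / cos(th)
    expect_equal(f$r_s^2 + fac * f$t_s^2, 1, tolerance = 1e-10)
    expect_equal(f$r_p^2 + fac * f$t_p^2, 1, tolerance = 1e-10)
  }
})

test_that("film reflectance limits, quarter-wave peak, and scaling law", {
  # vanishing film reflects nothing
  expect_lt(film_reflectance(thin_film(1e-6), 550, 0.3), 1e-9)
  # quarter-wave maximum equals ((n^2-1)/(n^2+1))^2
  n <- 1.56
  Rqw <- ((n^2 - 1) / (n^2 + 1))^2
  expect_equal(film_reflectance(thin_film(550 / (4 * n)), 550), Rqw,
               tolerance = 1e-12)
  # brute-force grid maximum over T and lambda matches the closed form
  M <- scalefilm:::film_reflectance_matrix(seq(10, 1000, 1), seq(300, 800, 5), 0)
  expect_equal(max(M), Rqw, tolerance = 1e-6)
  # scale invariance R(lambda, T) = R(c lambda, c T) at normal incidence
  set.seed(7)
  for (i in 1:10) {
    T <- runif(1, 50, 400); l <- runif(1, 400, 700); cc <- runif(1, 0.5, 2)
    expect_equal(film_reflectance(thin_film(T), l),
                 film_reflectance(thin_film(cc * T), cc * l),
                 tolerance = 1e-12)
  }
})

test_that("reflectance stays in [0, 1] over the physical domain", {
  set.seed(11)
  for (i in 1:50) {
    R <- film_reflectance(thin_film(runif(1, 10, 1000)), runif(1, 300, 800),
                          runif(1, 0, 30 * pi / 180))
    expect_gte(R, 0); expect_lte(R, 1)
  }
})

test_that("film model agrees with the transfer-matrix oracle", {
  set.seed(42)
  for (i in 1:20) {
    T <- runif(1, 10, 1000); l <- runif(1, 300, 800); th <- runif(1, 0, 0.5)
    expect_equal(film_reflectance(thin_film(T), l, th),
                 tm_reflectance(T, l, th), tolerance = 1e-8)
  }
})

test_that("cone averaging: geometry, degenerate limits, and no red shift", {
  expect_equal(illumination_cone(0.5)$theta_max_deg, 30, tolerance = 1e-12)
  grid <- spectral_grid(seq(400, 700, 5))
  film <- thin_film(187)
  # NA -> 0 degenerates to normal incidence
  tiny <- cone_averaged_reflectance(film, grid, illumination_cone(1e-4))
  expect_equal(tiny$value, film_reflectance(film, unclass(grid)),
               tolerance = 1e-6)
  # angular discretization is stable when doubled
  a31 <- cone_averaged_reflectance(film, grid, illumination_cone(0.5, 31))
  a62 <- cone_averaged_reflectance(film, grid, illumination_cone(0.5, 62))
  expect_lt(max(abs(a31$value - a62$value)), 1e-4)
  # cone averaging never shifts the dominant peak to longer wavelengths
  for (T in c(120, 187, 230, 260)) {
    wl <- unclass(spectral_grid())
    Rn <- film_reflectance(thin_film(T), wl)
    Rc <- cone_averaged_reflectance(thin_film(T))$value
    expect_lte(wl[which.max(Rc)], wl[which.max(Rn)] + 1)
  }
})

test_that("rough films: degeneracy at sd 0 and smoothing of oscillations", {
  grid <- spectral_grid(seq(400, 700, 5))
  flat <- cone_averaged_reflectance(rough_film(187, 0, n_draws = 50), grid)
  ideal <- cone_averaged_reflectance(thin_film(187), grid)
  expect_equal(flat$value, ideal$value, tolerance = 1e-12)
  rough <- cone_averaged_reflectance(rough_film(187, 31, seed = 2), grid)
  smooth <- cone_averaged_reflectance(rough_film(187, 11, seed = 2), grid)
  expect_lt(diff(range(rough$value)), diff(range(smooth$value)))
  # seeded draws make rough spectra reproducible
  again <- cone_averaged_reflectance(rough_film(187, 31, seed = 2), grid)
  expect_identical(rough$value, again$value)
})

test_that("pigment compositing follows double-pass Beer-Lambert", {
  lam <- cone_averaged_reflectance(thin_film(187))
  zero <- spectrum(lam$wavelength_nm, rep(0, length(lam$value)), "absorbance")
  expect_equal(composite_scale_reflectance(lam, zero)$value, lam$value)
  # uniform 0.2 AU scales by 10^-0.4 and leaves the centroid untouched
  a02 <- spectrum(lam$wavelength_nm, rep(0.2, length(lam$value)), "absorbance")
  comp <- composite_scale_reflectance(lam, a02)
  expect_equal(comp$value, lam$value * 10^(-0.4), tolerance = 1e-12)
  expect_equal(wavrw(comp), wavrw(lam), tolerance = 1e-9)
  # heavy pigment masks the lamina
  a2 <- spectrum(lam$wavelength_nm, rep(2, length(lam$value)), "absorbance")
  expect_lt(max(composite_scale_reflectance(lam, a2)$value), 1e-4)
  # mismatched grids refuse to combine
  other <- spectrum(seq(400, 700, 5), rep(0.1, 61), "absorbance")
  expect_error(composite_scale_reflectance(lam, other), "grid")
})
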