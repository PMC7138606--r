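# Independent oracles, coded from different formulations than the package.

# Transfer-matrix (characteristic matrix) reflectance of one homogeneous
# dielectric layer between identical half-spaces. Independent of the Airy
# two-beam summation used by the package.
tm_reflectance <- function(thickness_nm, wavelength_nm, theta_i_rad,
                           n_film = 1.56, n0 = 1) {
  c0 <- cos(theta_i_rad)
  st <- n0 * sin(theta_i_rad) / n_film
  ct <- sqrt(1 - st^2)
  delta <- 2 * pi * n_film * thickness_nm * ct / wavelength_nm
  one_pol <- function(eta0, eta1) {
    M <- matrix(c(cos(delta), 1i * sin(delta) / eta1,
                  1i * eta1 * sin(delta), cos(delta)), 2, 2, byrow = TRUE)
    BC <- M %*% c(1, eta0)        # substrate admittance = incident medium's
    r <- (eta0 * BC[1] - BC[2]) / (eta0 * BC[1] + BC[2])
    Re(r * Conj(r))
  }
  Rs <- one_pol(n0 * c0, n_film * ct)
  Rp <- one_pol(n0 / c0, n_film / ct)
  (Rs + Rp) / 2
}

# Brute-force Mann-Whitney: U by direct pair counting, two-sided p by
# enumerating every assignment of the pooled values to the two samples.
mw_enumerate <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  U_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- U_of(x, y)
  center <- n * m / 2
  idx <- utils::combn(n + m, n)
  U_all <- apply(idx, 2, function(ii) U_of(pooled[ii], pooled[-ii]))
  list(U = U_obs,
       p_value = mean(abs(U_all - center) >= abs(U_obs - center) - 1e-9))
}

# small synthetic nested dataset builder used across statistics tests
make_nested <- function(means, n_ind = 3, n_scale = 5, n_point = 10,
                        sd_ind = 5, sd_scale = 5, sd_point = 14, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(means), function(g) {
    ind <- rnorm(n_ind, 0, sd_ind)
    do.call(rbind, lapply(seq_len(n_ind), function(i) {
      sc <- rnorm(n_scale, 0, sd_scale)
      do.call(rbind, lapply(seq_len(n_scale), function(s) {
        data.frame(value = means[g] + ind[i] + sc[s] +
                     rnorm(n_point, 0, sd_point),
                   group = paste0("g", g), individual = i, scale = s)
      }))
    }))
  }))
  nested_dataset(rows$value, rows$group, rows$individual, rows$scale)
}
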