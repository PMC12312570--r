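#' Volume of a sessile water droplet modelled as a spheroid
#'
#' The calibration drop resting on the cantilever tip is modelled as a
#' spheroid of revolution about the horizontal cantilever axis:
#' `V = 4/3 pi a b^2`, with `a` the distinct semi-axis along the cantilever
#' and `b` the vertical semi-axis seen in the side-view video (equal to the
#' transverse one by symmetry). The sphere limit `a = b = r` gives
#' `4/3 pi r^3` regardless of orientation convention.
#'
#' @param a horizontal semi-axis along the cantilever, m.
#' @param b vertical semi-axis (side view), m.
#' @return droplet volume, m^3.
#' @examples
#' droplet_volume(0.6e-3, 0.5e-3) # 6.283e-10 m^3
#' @export
droplet_volume <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop_mfs("mfs_invalid_parameter", "semi-axes must be positive")
  }
  4 / 3 * pi * a * b^2
}

#' Cantilever calibration result
#'
#' @param k_p_mean mean spring constant, N/m.
#' @param k_p_sd standard deviation over repeat calibrations, N/m.
#' @param n_obs number of droplet observations.
#' @param rho water density, kg/m^3.
#' @param g gravitational acceleration, m/s^2.
#' @param low_replication flag set when only one observation was available.
#' @return object of class `cantilever_calibration`.
#' @export
cantilever_calibration <- function(k_p_mean, k_p_sd = 0, n_obs = 1L,
                                   rho = 1000, g = 9.81,
                                   low_replication = n_obs < 2) {
  check_positive(k_p_mean, "k_p_mean"); check_nonneg(k_p_sd, "k_p_sd")
  structure(list(k_p_mean = k_p_mean, k_p_sd = k_p_sd,
                 n_obs = as.integer(n_obs), rho = rho, g = g,
                 low_replication = isTRUE(low_replication)),
            class = "cantilever_calibration")
}

#' @export
print.cantilever_calibration <- function(x, ...) {
  cat(sprintf("<cantilever_calibration> k_p = %.3g +/- %.3g nN/um (n = %d)%s\n",
              N_per_m_to_nN_per_um(x$k_p_mean), N_per_m_to_nN_per_um(x$k_p_sd),
              x$n_obs, if (x$low_replication) " [low replication]" else ""))
  invisible(x)
}

#' Estimate the cantilever spring constant from droplet observations
#'
#' Water-droplet calibration: each observed drop of semi-axes `(a, b)` weighs
#' `W = rho g V` with `V` from [droplet_volume()]; Hooke's law gives a
#' per-observation spring constant `k_i = W_i / delta_x_i`. The calibration
#' reports the mean and sample SD over repeats.
#'
#' @param obs data.frame with columns `a`, `b`, `delta_x` (all m), one row per
#'   droplet observation.
#' @param rho water density, kg/m^3.
#' @param g gravitational acceleration, m/s^2.
#' @return a [cantilever_calibration()] (with a low-replication flag when only
#'   one observation is supplied).
#' @examples
#' obs <- data.frame(a = 0.5e-3, b = 0.5e-3, delta_x = 171.3e-6)
#' estimate_spring_constant(obs) # ~0.030 N/m = 30 nN/um
#' @export
estimate_spring_constant <- function(obs, rho = 1000, g = 9.81) {
  obs <- as.data.frame(obs)
  if (nrow(obs) == 0L) {
    stop_mfs("mfs_invalid_input", "need at least one droplet observation")
  }
  if (!all(c("a", "b", "delta_x") %in% names(obs))) {
    stop_mfs("mfs_invalid_input", "obs must have columns a, b, delta_x")
  }
  if (any(obs$delta_x <= 0)) {
    stop_mfs("mfs_invalid_parameter", "deflections must be positive")
  }
  k_i <- rho * g * droplet_volume(obs$a, obs$b) / obs$delta_x
  cal <- cantilever_calibration(
    k_p_mean = mean(k_i),
    k_p_sd = if (length(k_i) > 1) stats::sd(k_i) else 0,
    n_obs = length(k_i), rho = rho, g = g
  )
  if (cal$low_replication) {
    warning("single droplet observation: k_p SD set to 0", call. = FALSE)
  }
  cal$k_i <- k_i
  cal
}

#' Generate synthetic droplet observations from a known spring constant
#'
#' Inverts the calibration model for testing: spherical drops of assorted
#' radii are hung on a cantilever of known `k_p`, deflections follow Hooke's
#' law exactly, and optional relative noise is applied to the measured
#' semi-axes (as image analysis would incur).
#'
#' @param k_p true spring constant, N/m.
#' @param n number of observations.
#' @param radius_range range of drop radii, m.
#' @param axis_noise relative SD of semi-axis measurement noise.
#' @param rho,g medium constants.
#' @param seed integer seed.
#' @return data.frame with columns `a`, `b`, `delta_x`.
#' @export
simulate_droplet_observations <- function(k_p, n = 10, radius_range = c(3e-4, 8e-4),
                                          axis_noise = 0, rho = 1000, g = 9.81,
                                          seed = 1L) {
  check_positive(k_p, "k_p")
  with_seed(seed, {
    r <- seq(radius_range[1], radius_range[2], length.out = n)
    dx <- rho * g * droplet_volume(r, r) / k_p
    a <- r * exp(stats::rnorm(n, 0, axis_noise))
    b <- r * exp(stats::rnorm(n, 0, axis_noise))
    data.frame(a = a, b = b, delta_x = dx)
  })
}
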