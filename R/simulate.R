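#' Stretching experiment configuration
#'
#' Acquisition and actuation parameters of an MFS stretching experiment. The
#' defaults are the operating point used throughout: motor speed 20 um/s with
#' an initial acceleration of 1 mm/s^2, recording at 30 frames/s, and a
#' cantilever spring constant of 20 nN/um (the study's cantilevers spanned
#' 10-40 nN/um). At these settings the acceleration phase lasts 20 ms, i.e.
#' less than one frame; it is modelled by default and can be switched off.
#'
#' @param v motor speed, m/s.
#' @param accel motor acceleration, m/s^2.
#' @param k_p cantilever spring constant, N/m.
#' @param k_p_sd calibration SD of `k_p`, N/m.
#' @param frame_rate frames per second.
#' @param pixel_size metres per pixel for rendered frames.
#' @param noise_sd Gaussian measurement noise added to the reported
#'   deflection, m (0 = noise off).
#' @param seed integer seed; all stochastic draws of one simulation flow from
#'   it.
#' @param include_accel model the trapezoidal acceleration phase.
#' @param max_duration hard stop for the trace, s.
#' @param threshold_jitter relative (log-normal) spread of per-bond yield and
#'   rupture thresholds; gives chains distinct failure loads so rupture is
#'   gradual, as in a ductile material.
#' @param plastic_factor tangent-stiffness factor applied to a bond past its
#'   yield strain.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(v = 20e-6, accel = 1e-3,
                              k_p = 20e-3, k_p_sd = 0,
                              frame_rate = 30, pixel_size = 0.5e-6,
                              noise_sd = 0, seed = 1L,
                              include_accel = TRUE, max_duration = 15,
                              threshold_jitter = 0.1, plastic_factor = 0.5) {
  check_positive(v, "v"); check_positive(k_p, "k_p")
  check_positive(frame_rate, "frame_rate"); check_positive(pixel_size, "pixel_size")
  check_nonneg(noise_sd, "noise_sd"); check_nonneg(k_p_sd, "k_p_sd")
  check_positive(plastic_factor, "plastic_factor")
  check_nonneg(threshold_jitter, "threshold_jitter")
  structure(list(v = v, accel = accel, k_p = k_p, k_p_sd = k_p_sd,
                 frame_rate = frame_rate, pixel_size = pixel_size,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 include_accel = isTRUE(include_accel),
                 max_duration = max_duration,
                 threshold_jitter = threshold_jitter,
                 plastic_factor = plastic_factor),
            class = "experiment_config")
}

#' Motor position profile
#'
#' Trapezoidal kinematics of the straight (motorised) pipette: constant
#' acceleration up to the working speed, then constant speed. With
#' `include_accel = FALSE` the profile is simply `v t`.
#'
#' @param t time, s (vector).
#' @param cfg an [experiment_config()].
#' @return motor position x_s, m.
#' @export
motor_position <- function(t, cfg) {
  if (!cfg$include_accel) return(cfg$v * t)
  t_a <- cfg$v / cfg$accel
  ifelse(t <= t_a, 0.5 * cfg$accel * t^2, cfg$v * t - 0.5 * cfg$v * t_a)
}

## restore RNG state on exit so simulations are insulated from callers
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Precompute the piecewise-linear tension law of every chain.
##
## Within a chain all springs carry the same tension T. A bond extends by
## T / k while elastic and by l e_y + (T - k l e_y) / (pf k) past yield, so
## the chain extension D(T) is continuous, increasing and piecewise linear
## with one knot per bond (at the bond's yield force, sorted ascending).
## We tabulate, per chain, the knot extensions D_j plus segment slopes and
## intercepts, giving an O(m n) vectorised evaluation of T(Delta L) for all
## chains at once. The chain ruptures when its weakest bond reaches e_r,
## i.e. at tension T_rupt = min_i k l (e_y_i + pf (e_r_i - e_y_i)).
chain_law <- function(net, cfg) {
  b <- net$bonds
  if (any(is.na(b$chain))) {
    stop_mfs("mfs_unsupported",
             "simulate_stretch requires an axial-chain network (lateral bonds off)")
  }
  chains <- sort(unique(b$chain))
  n <- as.integer(table(b$chain)[1])
  if (!all(table(b$chain) == n)) {
    stop_mfs("mfs_unsupported", "all chains must have the same number of springs")
  }
  m <- length(chains)
  k <- b$k[1]; l <- b$rest[1]
  if (!all(b$k == k) || !all(b$rest == l)) {
    stop_mfs("mfs_unsupported", "bond stiffness and rest length must be uniform")
  }
  pf <- cfg$plastic_factor
  cell <- net$cell
  jit <- exp(stats::rnorm(nrow(b), 0, cfg$threshold_jitter))
  ey <- cell$yield_strain * jit
  er <- cell$rupture_strain * jit  # same multiplier keeps e_y <= e_r
  ## order bonds by chain (build order already groups them, but be explicit)
  ord <- order(b$chain)
  ey_m <- matrix(ey[ord], nrow = n)  # columns = chains
  er_m <- matrix(er[ord], nrow = n)
  ey_s <- apply(ey_m, 2, sort)       # n x m, ascending per chain
  if (n == 1L) ey_s <- matrix(ey_s, nrow = 1)
  S <- apply(ey_s, 2, cumsum)        # n x m prefix sums
  if (n == 1L) S <- matrix(S, nrow = 1)
  jn <- seq_len(n)
  slope <- ((n - jn) / k + jn / (pf * k)) %o% rep(1, m)
  icept <- (1 - 1 / pf) * l * S
  Tknot <- k * l * ey_s
  Dknot <- Tknot * slope + icept     # knot extensions (continuity: also equals
                                     # previous-segment value)
  T_rupt <- k * l * apply(ey_m + pf * (er_m - ey_m), 2, min)
  list(m = m, n = n, k = k, l = l, pf = pf,
       Dknot = Dknot, slope = slope, icept = icept, T_rupt = T_rupt)
}

## Tension carried by every chain at common extension dL (scalar), and the
## total aggregate force over the alive chains.
chain_tension <- function(law, dL) {
  if (dL <= 0) return(rep(0, law$m))
  j <- colSums(law$Dknot <= dL)               # yielded bonds per chain
  m <- law$m
  sl0 <- law$n / law$k
  pick <- cbind(pmax(j, 1L), seq_len(m))
  slope <- ifelse(j == 0L, sl0, law$slope[pick])
  icept <- ifelse(j == 0L, 0, law$icept[pick])
  (dL - icept) / slope
}

aggregate_force <- function(law, dL, alive) {
  tens <- chain_tension(law, dL)
  tens[!alive] <- 0
  list(F = sum(tens), T = tens)
}

#' Simulate a quasi-static MFS stretching experiment
#'
#' Couples a Hookean cantilever (spring constant `k_p`) to a ductile
#' spring-network aggregate. Per frame the motor position `x_s(t)` follows the
#' trapezoidal profile; the cantilever deflection `x` solves the quasi-static
#' force balance `k_p x = F_agg(x_s - x)` (bisection on `x` in `[0, x_s]`),
#' where the aggregate tension at extension `Delta L = x_s - x` comes from the
#' exact piecewise-linear law of each force chain: bonds are elastic up to
#' their (jittered) yield strain, continue with tangent stiffness
#' `plastic_factor * k_c`, and the chain breaks when its weakest bond reaches
#' its rupture strain. Chain failures within a frame are cascaded (the load
#' redistributes and may break further chains) until equilibrium. The trace
#' ends at full rupture or `max_duration`.
#'
#' Ground truth records the initial-network modulus
#' `E_true = K_eff L0 / (pi R0^2)` and the realised peak engineering stress.
#'
#' @param net an axial-chain [spring_network()] (the default lattice build).
#' @param cfg an [experiment_config()].
#' @param stop_strain optional engineering strain at which the motor is
#'   stopped early (used for pre-stretch protocols).
#' @return list with `trace` (data.frame `t`, `xs`, `x`, `F`, plus `x_clean`;
#'   attribute `ruptured_at` = frame index of full rupture or `NA`) of class
#'   `simulated_trace`, and `truth` (list `E_true`, `sigma_uts_true`, `K_eff`,
#'   `cell`, `R0`, `L0`).
#' @examples
#' net <- build_lattice_aggregate(10e-6, 20e-6, cell_model())
#' sim <- simulate_stretch(net, experiment_config(seed = 7))
#' @export
simulate_stretch <- function(net, cfg = experiment_config(), stop_strain = Inf) {
  stopifnot(inherits(net, "spring_network"), inherits(cfg, "experiment_config"))
  if (is.null(net$geometry)) {
    stop_mfs("mfs_invalid_parameter", "network must carry cylinder geometry (R0, L0)")
  }
  R0 <- net$geometry$R0; L0 <- net$geometry$L0
  with_seed(cfg$seed, {
    law <- chain_law(net, cfg)
    K_eff <- law$m * law$k / law$n
    alive <- rep(TRUE, law$m)
    dt <- 1 / cfg$frame_rate
    n_max <- ceiling(cfg$max_duration / dt)
    t <- xs <- x <- F <- numeric(n_max + 1)
    ruptured_at <- NA_integer_
    seen_force <- FALSE
    last <- n_max + 1
    for (fr in seq_len(n_max + 1)) {
      t[fr] <- (fr - 1) * dt
      xs[fr] <- motor_position(t[fr], cfg)
      repeat {
        x[fr] <- solve_deflection(law, alive, xs[fr], cfg$k_p)
        eq <- aggregate_force(law, xs[fr] - x[fr], alive)
        newly <- alive & (eq$T >= law$T_rupt - 1e-18)
        if (!any(newly)) break
        alive[newly] <- FALSE
      }
      F[fr] <- eq$F
      if (F[fr] > 0) seen_force <- TRUE
      if (!any(alive) && seen_force) { ruptured_at <- fr; last <- fr; break }
      if ((xs[fr] - x[fr]) / L0 >= stop_strain) { last <- fr; break }
    }
    idx <- seq_len(last)
    x_noisy <- x[idx] + if (cfg$noise_sd > 0) stats::rnorm(last, 0, cfg$noise_sd) else 0
    trace <- data.frame(t = t[idx], xs = xs[idx], x = x_noisy,
                        F = F[idx], x_clean = x[idx])
    attr(trace, "ruptured_at") <- ruptured_at
    class(trace) <- c("simulated_trace", "data.frame")
    truth <- list(
      E_true = K_eff * L0 / (pi * R0^2),
      sigma_uts_true = max(F[idx]) / (pi * R0^2),
      K_eff = K_eff, cell = net$cell, R0 = R0, L0 = L0
    )
    list(trace = trace, truth = truth)
  })
}

## Root of g(x) = k_p x - F_agg(xs - x) on [0, xs]; g is increasing in x
## (jumps only upward at chain failures), so bisection is safe.
solve_deflection <- function(law, alive, xs, k_p) {
  if (xs <= 0 || !any(alive)) return(0)
  g <- function(x) k_p * x - aggregate_force(law, xs - x, alive)$F
  lo <- 0; hi <- xs
  if (g(hi) <= 0) return(hi)
  for (it in 1:60) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Simulate a double-stretch (pre-stretch) experiment
#'
#' First stretch up to `eps1_max` engineering strain, return to the initial
#' configuration, wait, then stretch again until rupture. The relaxation
#' during the wait is not modelled mechanistically; it is summarised by a
#' single `softening` factor applied to the cell spring constant for the
#' second stretch (measured values cluster around 0.7).
#'
#' @param net axial-chain [spring_network()].
#' @param cfg an [experiment_config()].
#' @param eps1_max maximum engineering strain of the pre-stretch (0.2-1 in
#'   practice).
#' @param softening multiplicative stiffness factor for stretch 2.
#' @return list with `stretch1` and `stretch2`, each as from
#'   [simulate_stretch()].
#' @export
simulate_double_stretch <- function(net, cfg = experiment_config(),
                                    eps1_max = 0.5, softening = 0.7) {
  check_positive(eps1_max, "eps1_max"); check_positive(softening, "softening")
  s1 <- simulate_stretch(net, cfg, stop_strain = eps1_max)
  soft_cell <- cell_model(r_c = net$cell$r_c, k_c = net$cell$k_c * softening,
                          yield_strain = net$cell$yield_strain,
                          rupture_strain = net$cell$rupture_strain)
  net2 <- net
  net2$cell <- soft_cell
  net2$bonds$k <- net2$bonds$k * softening
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
  s2 <- simulate_stretch(net2, cfg2)
  list(stretch1 = s1, stretch2 = s2)
}
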