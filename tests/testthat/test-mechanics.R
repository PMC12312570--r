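make_rec <- function(x_m, t_s = NULL, k_p = 20e-3, k_p_sd = 0,
                     R0 = 30e-6, R0_sd = 0, L0 = 60e-6, L0_sd = 0,
                     v = 20e-6, xs = NULL) {
  if (is.null(t_s)) t_s <- (seq_along(x_m) - 1) / 30
  cal <- cantilever_calibration(k_p, k_p_sd, 1, low_replication = FALSE)
  geo <- list(R0_mean = R0, R0_sd = R0_sd, L0_mean = L0, L0_sd = L0_sd)
  tr <- data.frame(t = t_s, x = x_m)
  if (!is.null(xs)) tr$xs <- xs
  stretch_recording(tr, cal, geo, v = v)
}

test_that("stress and strain follow the engineering definitions", {
  # free motor limit: no deflection means no stress, eps = v t / L0
  rec <- make_rec(rep(0, 20))
  cv <- stress_strain(rec)
  expect_equal(cv$sigma, rep(0, 20))
  expect_equal(cv$eps, 20e-6 * cv$t / 60e-6)

  # hand arithmetic: k_p = 20 nN/um, x = 5 um at v t = 20 um, R0 = 30 um
  t_star <- 20e-6 / 20e-6  # 1 s
  rec <- make_rec(c(0, 5e-6), t_s = c(0, t_star))
  cv <- stress_strain(rec)
  expect_equal(cv$sigma[2], 20e-3 * 5e-6 / (pi * (30e-6)^2), tolerance = 1e-12)
  expect_equal(cv$sigma[2], 35.4, tolerance = 1e-3)
  expect_equal(cv$eps[2], (20e-6 - 5e-6) / 60e-6)  # 0.25
})

test_that("pipeline stress-strain matches the simulator internals exactly", {
  net <- small_net()
  cfg <- ref_config(seed = 2, noise_sd = 0)
  sim <- simulate_stretch(net, cfg)
  rec <- sim_recording(sim, cfg, noisy = FALSE)
  cv <- stress_strain(rec)
  expect_equal(cv$sigma, sim$trace$F / (pi * sim$truth$R0^2), tolerance = 1e-12)
  expect_equal(cv$eps, (sim$trace$xs - sim$trace$x_clean) / sim$truth$L0,
               tolerance = 1e-12)
  # kinematic identity eps L0 + x = v t holds after the acceleration phase
  t_a <- cfg$v / cfg$accel
  late <- cv$t > t_a
  expect_equal(cv$eps[late] * sim$truth$L0 + sim$trace$x_clean[late],
               cfg$v * cv$t[late] - 0.5 * cfg$v * t_a, tolerance = 1e-12)
})

test_that("scale invariance: scaling k_p scales sigma and E exactly", {
  x <- seq(0, 5e-6, length.out = 30)
  cv1 <- stress_strain(make_rec(x, k_p = 20e-3))
  cv2 <- stress_strain(make_rec(x, k_p = 60e-3))
  expect_equal(cv2$sigma, 3 * cv1$sigma, tolerance = 1e-12)
  f1 <- fit_young_modulus(cv1, window_policy = "fixed")
  f2 <- fit_young_modulus(cv2, window_policy = "fixed")
  expect_equal(f2$E, 3 * f1$E, tolerance = 1e-12)
})

test_that("error propagation matches the closed form and Monte Carlo", {
  # all SDs zero -> all errors zero
  cv <- stress_strain(make_rec(seq(0, 5e-6, length.out = 15)))
  expect_true(all(cv$sigma_err == 0) && all(cv$eps_err == 0))

  # hand arithmetic: 3% on k_p, 4% on R0 -> 8.54% on sigma
  rec <- make_rec(seq(0, 5e-6, length.out = 15), k_p_sd = 0.03 * 20e-3,
                  R0_sd = 0.04 * 30e-6, L0_sd = 0.05 * 60e-6)
  cv <- stress_strain(rec)
  i <- 10
  expect_equal(cv$sigma_err[i] / cv$sigma[i], sqrt(0.03^2 + 0.08^2),
               tolerance = 1e-10)
  expect_equal(cv$eps_err[i] / cv$eps[i], 0.05, tolerance = 1e-10)

  # Monte-Carlo oracle: draw k_p, R0, L0 and propagate the same frame's
  # deflection and motor position through the stress/strain formulas
  set.seed(123)
  n_mc <- 1e4
  k_p <- rnorm(n_mc, 20e-3, 0.03 * 20e-3)
  R0 <- rnorm(n_mc, 30e-6, 0.04 * 30e-6)
  L0 <- rnorm(n_mc, 60e-6, 0.05 * 60e-6)
  x <- seq(0, 5e-6, length.out = 15)[i]
  xs <- 20e-6 * cv$t[i]
  sig_mc <- stats::sd(k_p * x / (pi * R0^2))
  eps_mc <- stats::sd((xs - x) / L0)
  expect_equal(cv$sigma_err[i], sig_mc, tolerance = 0.05)
  expect_equal(cv$eps_err[i], eps_mc, tolerance = 0.05)
})

test_that("modulus fit recovers exact lines and respects the window policy", {
  # exact line sigma = 250 eps
  eps <- seq(0, 0.2, length.out = 40)
  cv <- data.frame(frame_index = seq_along(eps), t = eps, eps = eps,
                   sigma = 250 * eps)
  f <- fit_young_modulus(cv)
  expect_equal(f$E, 250, tolerance = 1e-10)
  expect_equal(f$E_err, 0, tolerance = 1e-8)
  expect_equal(f$fit_window[2], 30)  # ties at R^2 = 1 go to the largest w

  # piecewise curve rolling off at point 15: the scan stops near the kink
  sigma <- ifelse(seq_along(eps) <= 15, 250 * eps,
                  250 * eps[15] + 25 * (eps - eps[15]))
  cv2 <- data.frame(frame_index = seq_along(eps), t = eps, eps = eps,
                    sigma = sigma)
  f2 <- fit_young_modulus(cv2)
  expect_lte(f2$fit_window[2], 16)
  expect_equal(f2$E, 250, tolerance = 1e-6)

  # fixed policy
  f3 <- fit_young_modulus(cv2, window_policy = "fixed", w_fixed = 12)
  expect_equal(f3$fit_window[2], 12)

  expect_error(fit_young_modulus(cv[1:5, ]), class = "mfs_insufficient_data")
})

test_that("fit recovers the network ground-truth modulus from simulation", {
  net <- small_net()
  cfg <- ref_config(seed = 6, noise_sd = 0)
  sim <- simulate_stretch(net, cfg)
  cv <- stress_strain(sim_recording(sim, cfg, noisy = FALSE))
  f <- fit_young_modulus(cv)
  expect_equal(f$E, sim$truth$E_true, tolerance = 0.05)
})

test_that("UTS is the curve maximum and is withheld under slip", {
  eps <- seq(0, 0.5, length.out = 30)
  sigma <- 390 * sin(eps * pi / 0.6)  # monotone rise to a max
  cv <- data.frame(eps = eps, sigma = sigma)
  expect_equal(ultimate_tensile_strength(cv), max(sigma))
  expect_true(is.na(ultimate_tensile_strength(cv, qc_flags = "slip")))
  # simulator consistency
  net <- small_net()
  cfg <- ref_config(seed = 8, noise_sd = 0)
  sim <- simulate_stretch(net, cfg)
  cv2 <- stress_strain(sim_recording(sim, cfg, noisy = FALSE))
  expect_equal(ultimate_tensile_strength(cv2), sim$truth$sigma_uts_true,
               tolerance = 1e-10)
})

test_that("QC flags jumps, onset ruptures and drift; slip keeps E", {
  net <- small_net()
  cfg <- ref_config(seed = 10, noise_sd = 0)
  sim <- simulate_stretch(net, cfg)
  rec <- sim_recording(sim, cfg, noisy = FALSE)
  cv <- stress_strain(rec)
  qc <- qc_validate(rec, cv)
  expect_length(qc$flags, 0)
  expect_true(qc$valid)

  # inject a 20x-median jump into the loading portion
  cv_j <- cv
  i_mid <- round(which.max(cv$sigma) / 2)
  med <- stats::median(abs(diff(cv$sigma[seq_len(which.max(cv$sigma))])))
  cv_j$sigma[i_mid] <- cv_j$sigma[i_mid] + 20 * med
  qc_j <- qc_validate(rec, cv_j)
  expect_true("jump" %in% qc_j$flags)
  expect_false(qc_j$valid)

  # rupture at tiny strain: no_stretch
  cv_r <- cv[1:10, ]
  attr(cv_r, "ruptured_at") <- 3L
  cv_r$eps <- cv_r$eps / 100
  qc_r <- qc_validate(rec, cv_r)
  expect_true("no_stretch" %in% qc_r$flags)
  expect_false(qc_r$valid)

  # vertical drift beyond tolerance
  cv_d <- cv
  attr(cv_d, "vertical_drift_m") <- 5e-6
  qc_d <- qc_validate(rec, cv_d)
  expect_true("vertical_drift" %in% qc_d$flags)

  # slip annotation: still valid for E, UTS withheld
  qc_s <- qc_validate(rec, cv, annotations = c("slip"))
  expect_true(qc_s$valid)
  props <- analyze_recording(rec, annotations = "slip")
  expect_false(is.na(props$E))
  expect_true(is.na(props$sigma_uts))
})

test_that("double-stretch analysis recovers the softening factor", {
  net <- build_lattice_aggregate(20e-6, 40e-6, ref_cell())
  cfg <- ref_config(seed = 12, noise_sd = 30e-9)
  ds <- simulate_double_stretch(net, cfg, eps1_max = 0.5, softening = 0.7)
  rec1 <- sim_recording(ds$stretch1, cfg)
  rec2 <- sim_recording(ds$stretch2, cfg)
  res <- double_stretch_analysis(rec1, rec2)
  expect_equal(res$ratio, 0.7, tolerance = 0.1)
  expect_equal(res$eps1_max, max(stress_strain(rec1)$eps))
  # identical recordings give ratio 1
  res_id <- double_stretch_analysis(rec1, rec1)
  expect_equal(res_id$ratio, 1, tolerance = 1e-12)
})
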