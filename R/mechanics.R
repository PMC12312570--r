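#' Assemble one stretching experiment
#'
#' Bundles everything needed to turn a deflection trace into mechanical
#' properties: the cantilever calibration, the measured aggregate geometry,
#' the deflection trace and the motor speed.
#'
#' @param trace data.frame with columns `t` (s) and `x` (deflection, m), and
#'   optionally `xs` (motor position, m). A [track_tip()] result or
#'   [simulate_stretch()] trace works directly; for a `track_result` the
#'   deflection is `-x_m` (the opening is pulled towards the motor, i.e.
#'   towards negative image x).
#' @param calibration a [cantilever_calibration()].
#' @param geometry a [measure_geometry()] result (or a list with `R0_mean`,
#'   `R0_sd`, `L0_mean`, `L0_sd` in m).
#' @param v motor speed, m/s; used as `xs = v t` when the trace has no `xs`.
#' @param label optional condition / mouse identifier list.
#' @return object of class `stretch_recording`.
#' @export
stretch_recording <- function(trace, calibration, geometry, v = 20e-6,
                              label = list()) {
  if (inherits(trace, "track_result")) {
    vert <- attr(trace, "vertical_drift_m")
    trace <- data.frame(t = trace$t, x = -trace$x_m)
    attr(trace, "vertical_drift_m") <- vert
  }
  stopifnot(all(c("t", "x") %in% names(trace)))
  check_positive(v, "v")
  dt <- diff(trace$t)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * max(dt)) {
    stop_mfs("mfs_invalid_parameter", "trace must be uniformly sampled")
  }
  structure(list(trace = trace, calibration = calibration, geometry = geometry,
                 v = v, label = label),
            class = "stretch_recording")
}

#' Engineering stress-strain curve of a stretching experiment
#'
#' Per frame: force `F = k_p x` from the cantilever deflection, engineering
#' stress `sigma = F / (pi R0^2)` over the initial cross-section, extension
#' `Delta L = x_s - x` (with `x_s = v t` when the motor position was not
#' tracked) and engineering strain `eps = Delta L / L0`. Engineering (not
#' true) stress and strain are used throughout; no incompressibility update
#' of the radius is applied during stretch. Frames with `Delta L` negative
#' beyond tolerance are flagged as compressed via the `"compressed"`
#' attribute, not dropped.
#'
#' Uncertainties are first-order propagations of the calibration SD of `k_p`
#' and the repeat SDs of `R0` and `L0` (see [propagate_errors()]).
#'
#' @param rec a [stretch_recording()].
#' @return data.frame of class `stress_strain_curve` with columns
#'   `frame_index`, `t`, `eps`, `sigma`, `eps_err`, `sigma_err`.
#' @export
stress_strain <- function(rec) {
  stopifnot(inherits(rec, "stretch_recording"))
  cal <- rec$calibration; geo <- rec$geometry
  check_positive(cal$k_p_mean, "k_p_mean")
  check_positive(geo$R0_mean, "R0_mean"); check_positive(geo$L0_mean, "L0_mean")
  tr <- rec$trace
  xs <- if (!is.null(tr$xs)) tr$xs else rec$v * tr$t
  FF <- cal$k_p_mean * tr$x
  sigma <- FF / (pi * geo$R0_mean^2)
  dL <- xs - tr$x
  eps <- dL / geo$L0_mean
  curve <- data.frame(frame_index = seq_len(nrow(tr)), t = tr$t,
                      eps = eps, sigma = sigma)
  curve <- propagate_errors(curve, cal, geo)
  attr(curve, "compressed") <- any(dL < -0.02 * geo$L0_mean)
  attr(curve, "ruptured_at") <- attr(tr, "ruptured_at")
  attr(curve, "vertical_drift_m") <- attr(tr, "vertical_drift_m")
  class(curve) <- c("stress_strain_curve", "data.frame")
  curve
}

#' First-order error propagation for stress and strain
#'
#' Propagates the standard deviations of the cantilever constant and the
#' repeat geometry measurements into per-frame uncertainties:
#' `sigma_err / sigma = sqrt((k_p_sd / k_p)^2 + (2 R0_sd / R0)^2)` and
#' `eps_err / eps = L0_sd / L0`. Deflection measurement noise is not included,
#' matching the convention of propagating only `k_p`, `R0` and `L0`.
#'
#' @param curve data.frame with `eps` and `sigma` columns.
#' @param calibration a [cantilever_calibration()].
#' @param geometry a geometry list with means and SDs.
#' @return `curve` with `eps_err` and `sigma_err` columns filled.
#' @export
propagate_errors <- function(curve, calibration, geometry) {
  rel_sigma <- sqrt((calibration$k_p_sd / calibration$k_p_mean)^2 +
                      (2 * geometry$R0_sd / geometry$R0_mean)^2)
  rel_eps <- geometry$L0_sd / geometry$L0_mean
  curve$sigma_err <- abs(curve$sigma) * rel_sigma
  curve$eps_err <- abs(curve$eps) * rel_eps
  curve
}

#' Fit the Young's modulus from the initial linear regime
#'
#' Ordinary least squares of stress on strain over the first `w` points of
#' the curve, following the practice of fitting a line to the first 10-30
#' data points. The default policy scans `w` in 10..30 and keeps the window
#' maximising the coefficient of determination (ties broken towards the
#' largest window), so the fit stops short of the plastic roll-off; a fixed
#' window can be requested for reproducibility. An intercept is fitted but
#' not reported.
#'
#' @param curve a [stress_strain()] curve.
#' @param window_policy `"r2"` (scan) or `"fixed"`.
#' @param w_fixed window length under the fixed policy.
#' @param w_range candidate windows under the scan policy.
#' @return list with `E` (Pa), `E_err` (standard error of the slope, Pa),
#'   `fit_window = c(1, w)`, and `r_squared`.
#' @export
fit_young_modulus <- function(curve, window_policy = c("r2", "fixed"),
                              w_fixed = 20L, w_range = 10:30) {
  window_policy <- match.arg(window_policy)
  n <- nrow(curve)
  if (n < 10L) {
    stop_mfs("mfs_insufficient_data",
             "need at least 10 stress-strain points, have %d", n)
  }
  ## manual OLS: avoids summary.lm()'s perfect-fit warnings on noise-free
  ## synthetic curves and is cheap inside the window scan
  fit_w <- function(w) {
    x <- curve$eps[seq_len(w)]; y <- curve$sigma[seq_len(w)]
    sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    rss <- max(syy - slope^2 * sxx, 0)
    list(E = slope,
         E_err = sqrt(rss / (w - 2) / sxx),
         r2 = if (syy > 0) 1 - rss / syy else 1,
         w = w)
  }
  if (window_policy == "fixed") {
    w <- min(w_fixed, n)
    best <- fit_w(w)
  } else {
    ws <- w_range[w_range <= n]
    fits <- lapply(ws, fit_w)
    r2 <- vapply(fits, `[[`, numeric(1), "r2")
    ## ties (within numerical slop) go to the largest window
    best <- fits[[max(which(r2 >= max(r2) - 1e-12))]]
  }
  list(E = best$E, E_err = best$E_err,
       fit_window = c(1L, best$w), r_squared = best$r2)
}

#' Ultimate tensile strength
#'
#' Maximum engineering stress sustained before rupture. When the aggregate
#' slipped in or out of a pipette during the experiment (operator annotation
#' `"slip"`), the peak stress is unreliable and the UTS is withheld (`NA`)
#' while the Young's modulus remains reportable.
#'
#' @param curve a [stress_strain()] curve.
#' @param qc_flags character vector of QC flags (see [qc_validate()]).
#' @return UTS in Pa, or `NA_real_` under a slip flag.
#' @export
ultimate_tensile_strength <- function(curve, qc_flags = character()) {
  stopifnot(nrow(curve) >= 1)
  if ("slip" %in% qc_flags) return(NA_real_)
  max(curve$sigma)
}

#' Quality control of a stretching experiment
#'
#' Applies the exclusion rules used in MFS practice: force jumps (suction
#' pressure fluctuations) detected as any stress increment exceeding
#' `jump_factor` times the median absolute increment; rupture at the onset
#' without observable stretching (`no_stretch`: rupture below `eps_min`);
#' vertical drift of the tracked tip beyond `drift_threshold`; and
#' operator-supplied annotations (`"rotation"`, `"slip"`). An experiment is
#' `valid` for modulus reporting when none of jump / rotation / no_stretch /
#' vertical_drift is present; slip only invalidates the UTS.
#'
#' @param rec a [stretch_recording()].
#' @param curve its [stress_strain()] curve.
#' @param jump_factor jump detection multiplier on the median |d sigma|.
#' @param eps_min minimum rupture strain counted as a real stretch.
#' @param drift_threshold vertical drift tolerance, m.
#' @param annotations character vector of operator annotations.
#' @return list with `flags` (character vector) and `valid` (logical).
#' @export
qc_validate <- function(rec, curve, jump_factor = 10, eps_min = 0.02,
                        drift_threshold = 2e-6, annotations = character()) {
  flags <- character()
  ## jumps are suction artefacts in the loading portion; the collapse after
  ## the stress maximum is rupture and must not be flagged
  loading <- seq_len(which.max(curve$sigma))
  ds <- abs(diff(curve$sigma[loading]))
  med <- stats::median(ds)
  if (length(ds) && med > 0 && any(ds > jump_factor * med)) {
    flags <- c(flags, "jump")
  }
  rupt <- attr(curve, "ruptured_at")
  if (!is.null(rupt) && !is.na(rupt)) {
    eps_r <- max(curve$eps[seq_len(min(rupt, nrow(curve)))])
    if (eps_r < eps_min) flags <- c(flags, "no_stretch")
  }
  drift <- attr(curve, "vertical_drift_m")
  if (!is.null(drift) && is.finite(drift) && drift > drift_threshold) {
    flags <- c(flags, "vertical_drift")
  }
  flags <- union(flags, intersect(annotations, c("rotation", "slip")))
  list(flags = flags,
       valid = !any(c("jump", "rotation", "no_stretch", "vertical_drift") %in% flags))
}

#' Full per-experiment mechanical characterisation
#'
#' Runs the stress-strain computation, quality control, modulus fit and UTS
#' extraction in order, returning the per-experiment results row. QC-invalid
#' experiments are returned with `valid = FALSE` and `E = NA` rather than
#' raised.
#'
#' @param rec a [stretch_recording()].
#' @param annotations operator QC annotations.
#' @param ... passed to [fit_young_modulus()] and [qc_validate()].
#' @return list of class `mechanical_properties`: `E`, `E_err`, `fit_window`,
#'   `r_squared`, `sigma_uts`, `qc_flags`, `valid`.
#' @export
analyze_recording <- function(rec, annotations = character(), ...) {
  curve <- stress_strain(rec)
  qc <- qc_validate(rec, curve, annotations = annotations)
  res <- list(E = NA_real_, E_err = NA_real_, fit_window = c(NA, NA),
              r_squared = NA_real_, sigma_uts = NA_real_,
              qc_flags = qc$flags, valid = qc$valid, curve = curve)
  if (qc$valid) {
    fit <- fit_young_modulus(curve, ...)
    res[c("E", "E_err", "fit_window", "r_squared")] <-
      fit[c("E", "E_err", "fit_window", "r_squared")]
    res$sigma_uts <- ultimate_tensile_strength(curve, qc$flags)
  }
  class(res) <- "mechanical_properties"
  res
}

#' @export
print.mechanical_properties <- function(x, ...) {
  cat(sprintf("<mechanical_properties> E = %.1f +/- %.1f Pa, UTS = %s Pa, valid = %s%s\n",
              x$E, x$E_err,
              if (is.na(x$sigma_uts)) "NA" else sprintf("%.1f", x$sigma_uts),
              x$valid,
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Double-stretch (pre-stretch) analysis
#'
#' Fits the Young's modulus independently on the pre-stretch and the second
#' stretch of a double-stretch experiment and reports the stiffness change
#' `E2 / E1` together with the maximum strain reached during the pre-stretch.
#'
#' @param rec1,rec2 [stretch_recording()]s of the two stretches.
#' @param ... passed to [fit_young_modulus()].
#' @return list with `E1`, `E2`, `ratio`, `eps1_max`.
#' @export
double_stretch_analysis <- function(rec1, rec2, ...) {
  c1 <- stress_strain(rec1)
  c2 <- stress_strain(rec2)
  f1 <- fit_young_modulus(c1, ...)
  f2 <- fit_young_modulus(c2, ...)
  list(E1 = f1$E, E2 = f2$E, ratio = f2$E / f1$E, eps1_max = max(c1$eps))
}
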