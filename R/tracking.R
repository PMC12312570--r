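#' Track the force-sensing pipette tip across frames
#'
#' Template tracking of the L-shaped pipette opening: the frame-0 patch inside
#' `roi` is matched in every frame by normalised cross-correlation over a
#' search window centred on the previous position, and the integer peak is
#' refined by parabolic interpolation of the correlation surface in both axes
#' (sub-pixel). The deflection is reported relative to frame 0 along the
#' horizontal (stretch) axis; vertical motion is not subtracted but summarised
#' as a drift metric for quality control.
#'
#' @param stack a [frame_stack()].
#' @param roi integer vector `c(x0, x1, y0, y1)` (px, inclusive) containing
#'   the tip in frame 0; default from [default_tip_roi()].
#' @param search_radius integer `c(rx, ry)`: per-frame search half-widths, px.
#' @param quality_threshold minimum acceptable peak correlation.
#' @param max_bad_fraction tolerated fraction of frames below the threshold
#'   before a tracking failure is raised.
#' @return data.frame of class `track_result` with columns `t`, `tip_x_px`,
#'   `tip_y_px`, `x_m` (horizontal displacement from frame 0, m) and
#'   `quality`; attributes `pixel_size` and `vertical_drift_m` (max |tip_y -
#'   tip_y[1]| in m).
#' @export
track_tip <- function(stack, roi = NULL, search_radius = c(6L, 3L),
                      quality_threshold = 0.5, max_bad_fraction = 0.05) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) < 2) {
    stop_mfs("mfs_invalid_parameter", "need at least 2 frames to track")
  }
  if (is.null(roi)) roi <- default_tip_roi(stack)
  f0 <- stack$frames[[1]]
  H <- nrow(f0); W <- ncol(f0)
  roi <- as.integer(round(roi))
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > W || roi[4] > H || roi[1] >= roi[2] ||
      roi[3] >= roi[4]) {
    stop_mfs("mfs_invalid_parameter", "roi outside image or degenerate")
  }
  tmpl <- f0[roi[3]:roi[4], roi[1]:roi[2]]
  tv <- as.vector(tmpl) - mean(tmpl)
  tn <- sqrt(sum(tv^2))
  if (tn == 0) stop_mfs("mfs_tracking_failure", "featureless template")
  rx <- search_radius[1]; ry <- search_radius[2]
  th <- nrow(tmpl); tw <- ncol(tmpl)

  n <- length(stack$frames)
  pos_x <- pos_y <- qual <- numeric(n)
  ## position = template-centre coordinates (px, continuous)
  cx0 <- (roi[1] + roi[2]) / 2
  cy0 <- (roi[3] + roi[4]) / 2
  off_x <- 0; off_y <- 0  # integer offset of the template in current frame
  for (fr in seq_len(n)) {
    f <- stack$frames[[fr]]
    rx_f <- rx; ry_f <- ry
    repeat {
      oxs <- (off_x - rx_f):(off_x + rx_f)
      oys <- (off_y - ry_f):(off_y + ry_f)
      ## clip offsets that would push the template out of the image
      oxs <- oxs[roi[1] + oxs >= 1 & roi[2] + oxs <= W]
      oys <- oys[roi[3] + oys >= 1 & roi[4] + oys <= H]
      cc <- matrix(-Inf, length(oys), length(oxs))
      for (a in seq_along(oys)) {
        for (b in seq_along(oxs)) {
          patch <- f[roi[3]:roi[4] + oys[a], roi[1]:roi[2] + oxs[b]]
          pv <- as.vector(patch) - mean(patch)
          pn <- sqrt(sum(pv^2))
          cc[a, b] <- if (pn == 0) 0 else sum(pv * tv) / (pn * tn)
        }
      }
      pk <- arrayInd(which.max(cc), dim(cc))
      a <- pk[1]; b <- pk[2]
      ## a peak on the window border (e.g. the snap-back at rupture) means
      ## the true displacement may lie outside: expand and retry
      on_edge <- (b == 1L || b == length(oxs)) && length(oxs) > 1 && rx_f < 64
      if (!on_edge) break
      rx_f <- rx_f * 2L
    }
    dx <- parabolic_offset(cc[a, ], b)
    dy <- parabolic_offset(cc[, b], a)
    off_x <- oxs[b]; off_y <- oys[a]
    pos_x[fr] <- cx0 + off_x + dx
    pos_y[fr] <- cy0 + off_y + dy
    qual[fr] <- max(0, min(1, cc[a, b]))
  }
  bad <- which(qual < quality_threshold)
  if (length(bad) > max_bad_fraction * n) {
    stop_mfs("mfs_tracking_failure",
             "tracking quality below %.2f in %d/%d frames (first bad frame %d)",
             quality_threshold, length(bad), n, bad[1])
  }
  res <- data.frame(
    t = stack$timestamps,
    tip_x_px = pos_x, tip_y_px = pos_y,
    x_m = (pos_x - pos_x[1]) * stack$pixel_size,
    quality = qual
  )
  attr(res, "pixel_size") <- stack$pixel_size
  attr(res, "vertical_drift_m") <- max(abs(pos_y - pos_y[1])) * stack$pixel_size
  class(res) <- c("track_result", "data.frame")
  res
}

## 3-point parabolic sub-pixel refinement along one axis of the correlation
## surface; returns 0 at window borders or for a degenerate (flat) peak.
parabolic_offset <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (!is.finite(denom) || abs(denom) < 1e-12) return(0)
  d <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  max(min(d, 0.5), -0.5)
}

## Continuous dark extent of one intensity profile: positions where the
## profile crosses the threshold, refined by linear interpolation between
## the adjacent pixels.
column_height_subpx <- function(v, th) {
  dark <- which(v < th)
  if (length(dark) == 0L) return(0)
  r1 <- min(dark); r2 <- max(dark)
  y_top <- if (r1 > 1 && v[r1 - 1] > th) {
    (r1 - 1) + (v[r1 - 1] - th) / (v[r1 - 1] - v[r1])
  } else r1 - 0.5
  y_bot <- if (r2 < length(v) && v[r2 + 1] > th) {
    r2 + (th - v[r2]) / (v[r2 + 1] - v[r2])
  } else r2 + 0.5
  y_bot - y_top
}

## Column-wise longest dark run lengths of a binary image.
dark_runs <- function(binary) {
  apply(binary, 2, function(col) {
    r <- rle(col)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  })
}

## Locate the aggregate as the first contiguous block of columns whose dark
## run is much taller than the pipette wall; returns c(first, last) or NULL.
aggregate_block <- function(runs, bar_h) {
  tall <- runs >= max(2.5 * bar_h, bar_h + 4)
  r <- rle(tall)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 3L)
  if (length(cand) == 0L) return(NULL)
  c(starts[cand[1]], ends[cand[1]])
}

#' Measure initial aggregate geometry from the first frame
#'
#' Segments the dark silhouettes by thresholding, identifies the aggregate as
#' the region between the two pipette openings (columns whose dark extent is
#' much taller than a pipette wall), and measures the initial length `L0` as
#' the horizontal span between the openings and the radius `R0` as half the
#' silhouette height. Each quantity is measured `n_repeats` times - `R0` at
#' distinct axial stations of the aggregate and `L0` with jittered detection
#' thresholds - and reported as mean and standard deviation, mirroring
#' repeat-based manual measurement across different positions of the cluster.
#'
#' @param frame0 grayscale image matrix in `[0, 1]` (or a [frame_stack()],
#'   whose first frame is used).
#' @param pixel_size metres per pixel (taken from the stack if one is given).
#' @param n_repeats number of repeat measurements (>= 2).
#' @param V_tot optional total aggregate volume including aspirated parts, m^3.
#' @return list of class `geometry_measurement`: `R0_mean`, `R0_sd`,
#'   `L0_mean`, `L0_sd` (m), `n_repeats`, `V` (cylinder volume, m^3), `V_tot`.
#' @export
measure_geometry <- function(frame0, pixel_size = NULL, n_repeats = 5L,
                             V_tot = NA_real_) {
  if (inherits(frame0, "frame_stack")) {
    if (is.null(pixel_size)) pixel_size <- frame0$pixel_size
    frame0 <- frame0$frames[[1]]
  }
  check_positive(pixel_size, "pixel_size")
  if (n_repeats < 2) stop_mfs("mfs_invalid_parameter", "n_repeats must be >= 2")
  lo <- stats::quantile(frame0, 0.01); hi <- stats::quantile(frame0, 0.99)
  if (hi - lo < 0.1) stop_mfs("mfs_no_aggregate", "image has no dark silhouette")
  th0 <- (lo + hi) / 2

  measure_once <- function(th) {
    runs <- dark_runs(frame0 < th)
    if (all(runs == 0)) return(NULL)
    left_cols <- seq_len(max(3L, floor(0.12 * length(runs))))
    bar_candidates <- runs[left_cols][runs[left_cols] > 0]
    bar_h <- if (length(bar_candidates)) stats::median(bar_candidates) else 4
    blk <- aggregate_block(runs, bar_h)
    if (is.null(blk)) return(NULL)
    list(L0 = (blk[2] - blk[1] + 1) * pixel_size, blk = blk, runs = runs)
  }

  base <- measure_once(th0)
  if (is.null(base)) stop_mfs("mfs_no_aggregate", "no aggregate silhouette found")

  ## L0: re-detections with jittered thresholds
  jit <- seq(0.92, 1.08, length.out = n_repeats)
  L0s <- vapply(jit, function(j) {
    m <- measure_once(th0 * j)
    if (is.null(m)) NA_real_ else m$L0
  }, numeric(1))
  L0s <- L0s[is.finite(L0s)]
  if (length(L0s) == 0L) stop_mfs("mfs_no_aggregate", "aggregate lost at all thresholds")

  ## R0: silhouette half-height at n_repeats axial stations (central 60%),
  ## with sub-pixel edge refinement by linear interpolation of the intensity
  ## profile at the threshold crossing
  blk <- base$blk
  wdt <- blk[2] - blk[1]
  stations <- round(blk[1] + wdt * seq(0.2, 0.8, length.out = n_repeats))
  R0s <- vapply(stations, function(cc) {
    column_height_subpx(frame0[, cc], th0) / 2 * pixel_size
  }, numeric(1))

  out <- list(
    R0_mean = mean(R0s), R0_sd = stats::sd(R0s),
    L0_mean = mean(L0s), L0_sd = if (length(L0s) > 1) stats::sd(L0s) else 0,
    n_repeats = as.integer(n_repeats),
    V = pi * mean(R0s)^2 * mean(L0s),
    V_tot = V_tot
  )
  if (is.finite(V_tot) && V_tot < out$V) {
    stop_mfs("mfs_invalid_parameter", "V_tot must be >= cylinder volume V")
  }
  class(out) <- "geometry_measurement"
  out
}

#' @export
print.geometry_measurement <- function(x, ...) {
  cat(sprintf("<geometry_measurement> R0 = %.2f +/- %.2f um, L0 = %.2f +/- %.2f um, V = %.3g um^3\n",
              m_to_um(x$R0_mean), m_to_um(x$R0_sd),
              m_to_um(x$L0_mean), m_to_um(x$L0_sd), x$V * 1e18))
  invisible(x)
}

#' Default tracking ROI at the L-pipette opening
#'
#' Places a square template window on the right opening of the aggregate
#' (where the L-shaped pipette grips it) in frame 0, using the same silhouette
#' analysis as [measure_geometry()].
#'
#' @param stack a [frame_stack()].
#' @param half_size template half-size, px.
#' @return integer vector `c(x0, x1, y0, y1)`.
#' @export
default_tip_roi <- function(stack, half_size = 10L) {
  f0 <- stack$frames[[1]]
  lo <- stats::quantile(f0, 0.01); hi <- stats::quantile(f0, 0.99)
  runs <- dark_runs(f0 < (lo + hi) / 2)
  left_cols <- seq_len(max(3L, floor(0.12 * length(runs))))
  bar_candidates <- runs[left_cols][runs[left_cols] > 0]
  bar_h <- if (length(bar_candidates)) stats::median(bar_candidates) else 4
  blk <- aggregate_block(runs, bar_h)
  if (is.null(blk)) stop_mfs("mfs_no_aggregate", "cannot locate aggregate for ROI")
  cx <- blk[2]  # right opening
  cy <- round(nrow(f0) / 2)
  c(max(1L, cx - half_size), min(ncol(f0), cx + half_size),
    max(1L, cy - half_size), min(nrow(f0), cy + half_size))
}
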