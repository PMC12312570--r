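#' Frame stack container
#'
#' A list of 2-D grayscale images (matrices in `[0, 1]`, rows = image y from
#' the top, columns = image x) with a common pixel size and per-frame
#' timestamps.
#'
#' @param frames list of numeric matrices of identical dimension.
#' @param pixel_size metres per pixel.
#' @param timestamps frame times, s.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, timestamps) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_mfs("mfs_invalid_parameter", "all frames must share one image shape")
  }
  check_positive(pixel_size, "pixel_size")
  stopifnot(length(timestamps) == length(frames))
  structure(list(frames = frames, pixel_size = pixel_size,
                 timestamps = as.numeric(timestamps)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.3g um/px\n",
              length(x$frames), d[1], d[2], m_to_um(x$pixel_size)))
  invisible(x)
}

## Anti-aliased dark rectangle: blends `value` into img over the continuous
## pixel rectangle [x0, x1] x [y0, y1] (px units, pixel j spans [j-1, j]).
draw_rect <- function(img, x0, x1, y0, y1, value) {
  W <- ncol(img); H <- nrow(img)
  cx0 <- max(1L, floor(x0) + 1L); cx1 <- min(W, ceiling(x1))
  cy0 <- max(1L, floor(y0) + 1L); cy1 <- min(H, ceiling(y1))
  if (cx0 > cx1 || cy0 > cy1) return(img)
  cols <- cx0:cx1; rows <- cy0:cy1
  cov_x <- pmin(cols, x1) - pmax(cols - 1, x0)
  cov_y <- pmin(rows, y1) - pmax(rows - 1, y0)
  cov <- pmax(cov_y, 0) %o% pmax(cov_x, 0)
  img[rows, cols] <- img[rows, cols] * (1 - cov) + value * cov
  img
}

## Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  conv_rows <- function(m) {
    n <- ncol(m)
    out <- matrix(0, nrow(m), n)
    for (d in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n)
      out <- out + w[d + r + 1L] * m[, idx, drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Render microscopy-style frames of a stretching experiment
#'
#' Draws, per trace frame, dark silhouettes on a bright background: the
#' straight pipette entering from the left (its opening recedes with the
#' motor position `x_s`), the L-shaped force-sensing pipette on the right
#' (its opening translates with the deflection `x`), and the aggregate as a
#' textured cylinder spanning the two openings. The drawn cross-section
#' shrinks so that the silhouette area is conserved while the length grows.
#' Silhouette edges are anti-aliased from analytic pixel coverage, then mildly
#' blurred and corrupted with additive Gaussian pixel noise, so pipette
#' positions remain recoverable to sub-pixel accuracy by the tracking module.
#'
#' @param trace a `simulated_trace` (or data.frame with `t`, `xs`, and
#'   `x_clean` or `x`).
#' @param geometry list with initial radius `R0` and length `L0`, m (e.g. the
#'   `truth` element of [simulate_stretch()]).
#' @param cfg an [experiment_config()] (pixel size, seed).
#' @param pipette_halfwidth pipette wall half-thickness, m.
#' @param arm_length horizontal arm length of the L-pipette, m.
#' @param blur_sigma_px Gaussian blur SD, px.
#' @param pixel_noise_sd additive pixel noise SD on the [0, 1] grey scale
#'   (2 grey levels of an 8-bit camera is about 0.008).
#' @param background,foreground grey levels of medium and silhouettes.
#' @return a [frame_stack()]; its `meta` element records the rendered (true)
#'   opening positions in px for validation against tracking.
#' @export
render_frames <- function(trace, geometry, cfg = experiment_config(),
                          pipette_halfwidth = 2e-6, arm_length = 15e-6,
                          blur_sigma_px = 1.0, pixel_noise_sd = 0.008,
                          background = 0.85, foreground = 0.15) {
  stopifnot(nrow(trace) >= 1)
  px <- cfg$pixel_size
  R0 <- geometry$R0; L0 <- geometry$L0
  x_def <- if (!is.null(trace$x_clean)) trace$x_clean else trace$x
  xs <- trace$xs
  margin <- 10e-6
  XL0 <- margin + max(xs)            # left opening at t = 0
  XR0 <- XL0 + L0
  tp <- pipette_halfwidth
  W <- ceiling((XR0 + arm_length + 2 * tp + margin) / px)
  H <- ceiling((2 * R0 + 2 * margin) / px)
  if (W < 8 || H < 8) {
    stop_mfs("mfs_invalid_configuration", "field of view too small")
  }
  yc <- H / 2                         # px
  frames <- vector("list", nrow(trace))
  tip_x_px <- numeric(nrow(trace))
  for (fr in seq_len(nrow(trace))) {
    dL <- max(xs[fr] - x_def[fr], 0)
    L_t <- L0 + dL
    R_t <- R0 * L0 / L_t              # conserve drawn silhouette area
    XL <- (XL0 - xs[fr]) / px         # px coords of openings
    XR <- (XR0 - x_def[fr]) / px
    img <- matrix(background, H, W)
    ## aggregate body
    img <- draw_rect(img, XL, XR, yc - R_t / px, yc + R_t / px, foreground)
    ## straight pipette: bar from the left edge to its opening
    img <- draw_rect(img, 0, XL, yc - tp / px, yc + tp / px, foreground - 0.05)
    ## L-shaped pipette: horizontal arm from its opening, then vertical post
    arm_end <- XR + arm_length / px
    img <- draw_rect(img, XR, arm_end, yc - tp / px, yc + tp / px, foreground - 0.05)
    img <- draw_rect(img, arm_end, arm_end + 2 * tp / px,
                     yc - 0.9 * R0 / px, yc + 0.9 * R0 / px, foreground - 0.05)
    ## axial texture, advected with the material so it stretches with L(t)
    ccols <- seq_len(W)
    inside <- ccols - 0.5 > XL + 1 & ccols - 0.5 < XR - 1
    if (any(inside)) {
      mat_x <- ((ccols[inside] - 0.5) - XL) / (XR - XL) * L0  # material coord, m
      mod <- 0.06 * sin(2 * pi * mat_x / 10e-6)
      rr <- which(abs(seq_len(H) - 0.5 - yc) < (R_t / px - 1.5))
      if (length(rr)) img[rr, ccols[inside]] <-
          img[rr, ccols[inside]] + rep(mod, each = length(rr))
    }
    img <- gaussian_blur(img, blur_sigma_px)
    frames[[fr]] <- img
    tip_x_px[fr] <- XR
  }
  if (pixel_noise_sd > 0) {
    frames <- with_seed(cfg$seed + 7919L, lapply(frames, function(f) {
      f + matrix(stats::rnorm(length(f), 0, pixel_noise_sd), nrow(f))
    }))
  }
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  fs <- frame_stack(frames, px, trace$t)
  fs$meta <- list(tip_x_px = tip_x_px, yc_px = yc,
                  XL0_px = XL0 / px, XR0_px = XR0 / px, R0_px = R0 / px)
  fs
}
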