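#' Default activation-condition group specification
#'
#' Reference condition PMA + ionomycin with pooled modulus mean 248 Pa and SD
#' 234 Pa; adding the calmodulin inhibitor W-7 stiffens aggregates by a
#' same-mouse factor of 2.8 +/- 0.7, while anti-CD3 activation softens them
#' to 0.30 +/- 0.02 of the reference. The `ratio_sd` is interpreted as the
#' across-mice SD of the per-mouse ratio.
#'
#' @return data.frame with columns `group`, `ratio`, `ratio_sd`.
#' @export
default_group_specs <- function() {
  data.frame(
    group = c("PMA+I", "PMA+I+W7", "anti-CD3"),
    ratio = c(1, 2.8, 0.30),
    ratio_sd = c(0, 0.7, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Generate a group-level stiffness dataset
#'
#' Emulates the statistical structure of a multi-mouse aggregate-stiffness
#' study. Each mouse draws a log-normal baseline modulus; the log-normal
#' parameters are tuned so the pooled reference group has the requested mean
#' and SD (the heavy right tail reflects that the observed SD is comparable
#' to the mean). The total log-variance is split between a per-mouse random
#' effect and within-mouse (per-aggregate) scatter, because condition
#' contrasts are sharpest within the same mouse. Condition moduli multiply
#' the mouse baseline by the condition ratio and a per-mouse log-normal ratio
#' noise with relative SD `ratio_sd / ratio`.
#'
#' Null covariates (aggregate volume, aspirated fraction, time post
#' activation) are drawn independently of the modulus, emulating the observed
#' absence of covariate effects.
#'
#' @param group_specs data.frame as [default_group_specs()].
#' @param n_mice mice per group (>= 2).
#' @param aggregates_per_mouse aggregates measured per mouse and condition
#'   (studies ran 5-25 clusters per sample; default 8).
#' @param seed integer seed (fixed seed gives a byte-identical table).
#' @param ref_mean,ref_sd pooled mean and SD of the reference group, Pa.
#' @param mouse_var_share fraction of the total log-variance assigned to the
#'   per-mouse random effect.
#' @param groups optional character vector to restrict to named groups;
#'   unknown names raise an error.
#' @return data.frame with columns `group`, `mouse_id`, `E` (Pa),
#'   `volume_um3`, `v_over_vtot`, `time_post_activation_h`.
#' @export
generate_group_dataset <- function(group_specs = default_group_specs(),
                                   n_mice = 10, aggregates_per_mouse = 8,
                                   seed = 1L, ref_mean = 248, ref_sd = 234,
                                   mouse_var_share = 0.5, groups = NULL) {
  if (n_mice < 2) stop_mfs("mfs_invalid_parameter", "n_mice must be >= 2")
  if (!is.null(groups)) {
    unknown <- setdiff(groups, group_specs$group)
    if (length(unknown)) {
      stop_mfs("mfs_invalid_parameter", "unknown group name(s): %s",
               paste(unknown, collapse = ", "))
    }
    group_specs <- group_specs[group_specs$group %in% groups, , drop = FALSE]
  }
  s_tot2 <- log(1 + (ref_sd / ref_mean)^2)
  s_m <- sqrt(mouse_var_share * s_tot2)
  s_w <- sqrt((1 - mouse_var_share) * s_tot2)
  mu <- log(ref_mean) - s_tot2 / 2
  with_seed(seed, {
    baseline <- exp(mu + s_m * stats::rnorm(n_mice))
    rows <- list()
    for (gi in seq_len(nrow(group_specs))) {
      g <- group_specs$group[gi]
      ratio <- group_specs$ratio[gi]
      rel_sd <- if (ratio > 0) group_specs$ratio_sd[gi] / ratio else 0
      mouse_ratio <- ratio * exp(stats::rnorm(n_mice, 0, rel_sd))
      for (mi in seq_len(n_mice)) {
        n_agg <- aggregates_per_mouse
        E <- baseline[mi] * mouse_ratio[mi] * exp(stats::rnorm(n_agg, 0, s_w))
        rows[[length(rows) + 1L]] <- data.frame(
          group = g,
          mouse_id = sprintf("m%02d", mi),
          E = E,
          volume_um3 = exp(stats::runif(n_agg, log(1e4), log(7e5))),
          v_over_vtot = stats::runif(n_agg, 0.3, 0.9),
          time_post_activation_h = stats::runif(n_agg, 0.5, 12),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
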