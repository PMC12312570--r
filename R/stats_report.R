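#' Welch's two-sample t-test with significance stars
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom, two
#' sided), the standard comparison for group-level Young's moduli. Stars
#' follow the usual coding: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, otherwise `ns`.
#'
#' @param a,b numeric samples (each n >= 2 with nonzero variance).
#' @return list of class `welch_result`: `t_stat`, `df`, `p_value`, `stars`.
#' @examples
#' welch_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)) # t = -1, df = 8, p = 0.347
#' @export
welch_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 ||
      stats::var(a) == 0 || stats::var(b) == 0) {
    stop_mfs("mfs_invalid_input",
             "each sample needs n >= 2 and nonzero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  p <- ht$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p < 0.05) "*" else "ns"
  structure(list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = p, stars = stars),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.3f, df = %.2f, p = %.3g (%s)\n",
              x$t_stat, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Box-plot summary with 1.5 IQR whiskers
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers extend to
#' the most extreme data points within 1.5 times the interquartile range of
#' the quartiles; points beyond the whiskers are listed as outliers.
#'
#' @param values numeric sample (n >= 1).
#' @param type quantile type (default 7, linear interpolation).
#' @return list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_summary <- function(values, type = 7) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Same-mouse paired stiffness ratio
#'
#' Condition contrasts are sharpest within the same mouse. For each mouse
#' present in both groups, the per-mouse mean modulus is computed per group
#' and the ratio numerator-group / denominator-group is formed; the mean and
#' SD over mice are reported.
#'
#' @param table data.frame with columns `group`, `mouse_id`, `E`.
#' @param group_num,group_den group labels of numerator and denominator.
#' @return list with `mean_ratio`, `sd_ratio`, `n_mice`, `ratios`.
#' @export
paired_ratio <- function(table, group_num, group_den) {
  table <- as.data.frame(table)
  for (g in c(group_num, group_den)) {
    if (!g %in% table$group) {
      stop_mfs("mfs_invalid_parameter", "unknown group name: %s", g)
    }
  }
  per_mouse <- function(g) {
    d <- table[table$group == g, ]
    tapply(d$E, d$mouse_id, mean)
  }
  num <- per_mouse(group_num); den <- per_mouse(group_den)
  shared <- intersect(names(num), names(den))
  if (length(shared) < 2) {
    stop_mfs("mfs_pairing_impossible",
             "need >= 2 mice shared between %s and %s", group_num, group_den)
  }
  ratios <- num[shared] / den[shared]
  list(mean_ratio = mean(ratios), sd_ratio = stats::sd(ratios),
       n_mice = length(shared), ratios = ratios)
}

#' Covariate null check for the Young's modulus
#'
#' Least-squares slope of E against a covariate (aggregate volume, aspirated
#' fraction, time post activation) with its 95% confidence interval. The
#' relation is declared `flat` when the interval contains zero - the expected
#' outcome for covariates with no mechanobiological effect.
#'
#' @param table data.frame with an `E` column and the covariate column.
#' @param covariate covariate column name.
#' @param response response column name (default `"E"`).
#' @return list with `slope`, `ci` (length 2), `flat`.
#' @export
covariate_null_check <- function(table, covariate, response = "E") {
  table <- as.data.frame(table)
  if (!covariate %in% names(table)) {
    stop_mfs("mfs_invalid_parameter", "no covariate column `%s`", covariate)
  }
  d <- data.frame(y = table[[response]], x = table[[covariate]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5) stop_mfs("mfs_insufficient_data", "need >= 5 points")
  ## manual OLS slope + t-interval (robust to perfect, zero-residual fits)
  n <- nrow(d)
  sxx <- sum((d$x - mean(d$x))^2)
  syy <- sum((d$y - mean(d$y))^2)
  slope <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sxx
  rss <- max(syy - slope^2 * sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  half <- stats::qt(0.975, n - 2) * se
  ci <- c(slope - half, slope + half)
  list(slope = slope, ci = ci,
       flat = ci[1] <= 0 && ci[2] >= 0)
}

#' Publication-style box plot of group moduli
#'
#' @param table data.frame with `group` and `E` columns.
#' @return a ggplot object (log-scaled modulus axis).
#' @export
utils::globalVariables(c("group", "E"))

plot_group_boxes <- function(table) {
  table <- as.data.frame(table)
  ggplot2::ggplot(table, ggplot2::aes(x = group, y = E)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Young's modulus E (Pa)") +
    ggplot2::theme_classic()
}
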