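test_that("Welch's test matches the closed-form example and symmetry", {
  # equal variances make the Welch df exact: t = -1, df = 8, p = 0.347
  w <- welch_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(w$t_stat, -1, tolerance = 1e-12)
  expect_equal(w$df, 8, tolerance = 1e-12)
  expect_equal(w$p_value, 2 * stats::pt(-1, 8), tolerance = 1e-12)
  expect_equal(w$stars, "ns")
  # identical samples: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_stat, 0)
  expect_equal(w0$p_value, 1)
  # symmetry: swapping samples negates t, preserves p
  a <- rlnorm(20, 5, 0.5); b <- rlnorm(15, 5.5, 0.7)
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$t_stat, -w2$t_stat)
  expect_equal(w1$p_value, w2$p_value)
  expect_error(welch_test(c(1, 1, 1), c(1, 2, 3)), class = "mfs_invalid_input")
  expect_error(welch_test(1, c(1, 2)), class = "mfs_invalid_input")
})

test_that("Welch type-I error is near nominal under the generator null", {
  # per-mouse mean moduli of independent mice are the unit of replication;
  # split 30 null mice into two groups of 15 (full 2000-seed calibration is
  # in the acceptance suite; this is a quick sanity band)
  specs <- data.frame(group = "a", ratio = 1, ratio_sd = 0)
  rej <- mean(sapply(1:400, function(s) {
    d <- generate_group_dataset(specs, n_mice = 30, seed = s)
    m <- tapply(d$E, d$mouse_id, mean)
    welch_test(m[1:15], m[16:30])$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("box summaries implement the 1.5 IQR whisker rule", {
  b <- box_summary(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q3 - b$q1, 49.5)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_lo, 1); expect_equal(b$whisker_hi, 100)
  # constant sample: degenerate box
  b0 <- box_summary(rep(7, 9))
  expect_equal(b0$q1, 7); expect_equal(b0$q3, 7)
  expect_equal(b0$whisker_lo, 7); expect_equal(b0$whisker_hi, 7)
  expect_length(b0$outliers, 0)
  # brute check of the fence rule
  b1 <- box_summary(c(1, 2, 3, 4, 100))
  q <- stats::quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75))
  expect_true(100 > q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(b1$outliers, 100)
  expect_equal(b1$whisker_hi, 4)
  # partition property: outliers and whisker-bounded points cover the sample
  set.seed(5)
  for (rep in 1:10) {
    v <- rlnorm(40, 5, 1)
    b <- box_summary(v)
    inside <- v[v >= b$whisker_lo & v <= b$whisker_hi]
    expect_equal(sort(c(inside, b$outliers)), sort(v))
  }
})

test_that("paired same-mouse ratios recover the generator truth", {
  # identical groups: ratio exactly 1 +/- 0
  d <- generate_group_dataset(n_mice = 6, seed = 3)
  d_ref <- d[d$group == "PMA+I", ]
  d2 <- rbind(d_ref, transform(d_ref, group = "copy"))
  pr <- paired_ratio(d2, "copy", "PMA+I")
  expect_equal(pr$mean_ratio, 1)
  expect_equal(pr$sd_ratio, 0)
  # generator truths 2.8 and 0.30 recovered across seeds
  r_w7 <- sapply(1:10, function(s) {
    paired_ratio(generate_group_dataset(n_mice = 10, seed = s),
                 "PMA+I+W7", "PMA+I")$mean_ratio
  })
  expect_lt(abs(mean(r_w7) - 2.8), 0.7)
  r_cd3 <- sapply(1:10, function(s) {
    paired_ratio(generate_group_dataset(n_mice = 10, seed = s),
                 "anti-CD3", "PMA+I")$mean_ratio
  })
  expect_lt(abs(mean(r_cd3) - 0.30), 0.05)
  expect_error(paired_ratio(d, "nope", "PMA+I"),
               class = "mfs_invalid_parameter")
  # disjoint mice: pairing impossible
  d3 <- d[d$group %in% c("PMA+I", "anti-CD3"), ]
  d3 <- d3[!(d3$group == "anti-CD3" & d3$mouse_id %in% unique(d3$mouse_id[d3$group == "PMA+I"])), ]
  d4 <- rbind(d[d$group == "PMA+I", ],
              transform(d[d$group == "anti-CD3", ], mouse_id = paste0("x", mouse_id)))
  expect_error(paired_ratio(d4, "anti-CD3", "PMA+I"),
               class = "mfs_pairing_impossible")
})

test_that("group generator has the reference distribution and determinism", {
  d1 <- generate_group_dataset(n_mice = 15, seed = 11)
  d2 <- generate_group_dataset(n_mice = 15, seed = 11)
  expect_identical(d1, d2)  # byte-identical under a fixed seed
  # pooled reference mean/SD near 248 / 234 Pa over seeds
  ms <- sapply(1:10, function(s) {
    d <- generate_group_dataset(n_mice = 15, seed = s)
    ref <- d$E[d$group == "PMA+I"]
    c(mean(ref), stats::sd(ref))
  })
  expect_equal(mean(ms[1, ]), 248, tolerance = 0.15)
  expect_equal(mean(ms[2, ]), 234, tolerance = 0.35)
  expect_error(generate_group_dataset(groups = "typo"),
               class = "mfs_invalid_parameter")
})

test_that("null groups are non-significant and effect groups are detected", {
  specs_null <- data.frame(group = c("a", "b"), ratio = c(1, 1),
                           ratio_sd = c(0, 0))
  # ratio 1 everywhere: alpha = 0.01 tests reject in ~1% of seeds
  p_null <- sapply(1:60, function(s) {
    d <- generate_group_dataset(specs_null, n_mice = 10, seed = s)
    welch_test(d$E[d$group == "a"], d$E[d$group == "b"])$p_value
  })
  expect_gte(mean(p_null >= 0.01), 0.95)
  # ratio 2.8, n = 15 mice: power at the 1% level
  p_eff <- sapply(1:30, function(s) {
    d <- generate_group_dataset(n_mice = 15, seed = s)
    welch_test(d$E[d$group == "PMA+I+W7"], d$E[d$group == "PMA+I"])$p_value
  })
  expect_gte(mean(p_eff < 0.01), 0.9)
})

test_that("covariate null checks separate flat from sloped relations", {
  # constant E: slope 0, flat
  d0 <- data.frame(E = rep(100, 10), time_post_activation_h = 1:10)
  r0 <- covariate_null_check(d0, "time_post_activation_h")
  expect_equal(r0$slope, 0, tolerance = 1e-10)
  expect_true(r0$flat)
  # volume-independent generated data: flat in >= 90% of seeds
  flat <- sapply(1:40, function(s) {
    d <- generate_group_dataset(n_mice = 8, seed = s)
    covariate_null_check(d[d$group == "PMA+I", ], "volume_um3")$flat
  })
  expect_gte(mean(flat), 0.9)
  # injected slope 10 Pa/h over 0-12 h with 20 Pa noise, n = 30: detected
  det <- sapply(1:40, function(s) {
    set.seed(s)
    h <- runif(30, 0, 12)
    d <- data.frame(E = 100 + 10 * h + rnorm(30, 0, 20),
                    time_post_activation_h = h)
    !covariate_null_check(d, "time_post_activation_h")$flat
  })
  expect_gte(mean(det), 0.8)
  expect_error(covariate_null_check(d0[1:3, ], "time_post_activation_h"),
               class = "mfs_insufficient_data")
})
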