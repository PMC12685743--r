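test_that("F test uses the larger-over-smaller variance ratio", {
  x <- c(1, 2, 3, 4, 5)
  same <- f_test_equal_variance(x, x)
  expect_equal(same$f_stat, 1)
  expect_equal(same$p_value, 1)
  expect_true(same$equal)

  withr::with_seed(2, {
    a <- rnorm(10); a <- (a - mean(a)) / sd(a) * 2  # variance exactly 4
    b <- rnorm(10); b <- (b - mean(b)) / sd(b)      # variance exactly 1
    ft <- f_test_equal_variance(a, b)
    expect_equal(ft$f_stat, 4)
    expect_equal(ft$p_value, 2 * (1 - pf(4, 9, 9)))
    # alpha = 1 never judges variances equal
    expect_false(f_test_equal_variance(a, b, alpha = 1)$equal)
  })
  expect_error(f_test_equal_variance(c(1, 1), c(2, 2)), "zero variance")
  expect_error(f_test_equal_variance(1, c(1, 2)), "at least 2")
})

test_that("pooled t statistic matches the hand-computed example", {
  cmp <- two_sample_t(c(1, 2, 3), c(4, 5, 6), flavour = "pooled")
  expect_equal(cmp$t_stat, -3 / sqrt(2 / 3))  # s_p = 1, t = -3.6742
  expect_equal(cmp$df, 4)
  expect_equal(cmp$t_p, 2 * pt(-3 / sqrt(2 / 3), 4))

  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$t_p, 1)

  # swapping samples flips the sign, p unchanged
  rev <- two_sample_t(c(4, 5, 6), c(1, 2, 3), flavour = "pooled")
  expect_equal(rev$t_stat, -cmp$t_stat)
  expect_equal(rev$t_p, cmp$t_p)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), "degenerate")
})

test_that("auto flavour pools when the F test accepts and Welches otherwise", {
  withr::with_seed(8, {
    x <- rnorm(15, 0, 1)
    y_same <- rnorm(9, 0, 1)
    y_far <- rnorm(9, 0, 20)
  })
  auto1 <- two_sample_t(x, y_same)
  expect_true(auto1$variances_equal)
  expect_equal(auto1$flavour, "pooled")
  expect_equal(auto1$t_stat, oracle_t_pooled(x, y_same)$t)

  auto2 <- two_sample_t(x, y_far)
  expect_false(auto2$variances_equal)
  expect_equal(auto2$flavour, "welch")
  expect_equal(auto2$t_stat, oracle_t_welch(x, y_far)$t)
})

test_that("t-test p is shift invariant and t scales under common rescaling", {
  withr::with_seed(12, {
    x <- rnorm(12, 1, 2); y <- rnorm(7, 0, 2)
    for (fl in c("pooled", "welch")) {
      base <- two_sample_t(x, y, flavour = fl)
      shifted <- two_sample_t(x + 5, y + 5, flavour = fl)
      expect_equal(shifted$t_p, base$t_p, tolerance = 1e-10)
      scaled <- two_sample_t(3 * x, 3 * y, flavour = fl)
      expect_equal(scaled$t_stat, base$t_stat, tolerance = 1e-10)
      expect_equal(scaled$t_p, base$t_p, tolerance = 1e-10)
    }
  })
})

test_that("compare_periods selects annual values by ecological-year range", {
  ann <- data.frame(region = "NSS", ecological_year = 2000:2023,
                    biomass_t = c(rnorm(15, 0.175, 0.05), rnorm(9, 0.014, 0.005)))
  cmp <- compare_periods(ann, c(2000, 2014), c(2015, 2023))
  expect_equal(cmp$n_a, 15)
  expect_equal(cmp$n_b, 9)
  expect_equal(cmp$sample_a, ann$biomass_t[1:15])
})

test_that("climatology box statistics follow the type-7 quartile rule", {
  # constant series: degenerate box, no outliers
  ser <- data.frame(month = rep(1:12, 3), biomass_t = 5,
                    ecological_year = rep(2001:2003, each = 12))
  box <- climatology_box(ser)
  expect_equal(box$q1, rep(5, 12))
  expect_equal(box$q3, rep(5, 12))
  expect_equal(box$n_outliers, rep(0L, 12))

  # a far point beyond the upper fence is an outlier
  v <- c(1, 2, 3, 4, 100)
  ser2 <- data.frame(month = 6, biomass_t = v, ecological_year = 2001:2005)
  box2 <- climatology_box(ser2)
  j <- box2$month == 6
  expect_equal(box2$q1[j], unname(quantile(v, 0.25, type = 7)))
  expect_equal(box2$q3[j], 4)
  expect_equal(box2$whisker_high[j], 4)
  expect_equal(box2$outliers[j][[1]], 100)
  expect_equal(box2$n[j], 5L)
  # unsampled months are no-data records
  expect_equal(box2$n[box2$month == 1], 0L)
  expect_true(is.na(box2$median[box2$month == 1]))
})

test_that("box statistics match the brute-force oracle on random series", {
  withr::with_seed(77, {
    for (i in 1:300) {
      v <- rlnorm(sample(4:30, 1), 0, 1)
      ser <- data.frame(month = 3, biomass_t = v,
                        ecological_year = seq_along(v))
      box <- climatology_box(ser)
      got <- box[box$month == 3, ]
      want <- oracle_box(v)
      expect_equal(got$q1, want$q1, tolerance = 1e-12)
      expect_equal(got$median, want$median, tolerance = 1e-12)
      expect_equal(got$q3, want$q3, tolerance = 1e-12)
      expect_equal(got$whisker_low, want$whisker_low)
      expect_equal(got$whisker_high, want$whisker_high)
      expect_equal(sort(got$outliers[[1]]), want$outliers)
      # quartiles bracket the median; whiskers sit inside the fences
      expect_lte(got$q1, got$median)
      expect_lte(got$median, got$q3)
    }
  })
})

test_that("whisker recomputation after outlier removal matches the oracle", {
  ser <- function(x) data.frame(month = 1, biomass_t = x,
                                ecological_year = seq_along(x))
  # a sole upper outlier: removing it leaves the whiskers where they were
  v <- c(1, 2, 3, 4, 100)
  g1 <- climatology_box(ser(v))[1, ]
  g2 <- climatology_box(ser(c(1, 2, 3, 4)))[1, ]
  expect_lte(g2$whisker_high, g1$whisker_high)
  expect_gte(g2$whisker_low, g1$whisker_low)
  expect_equal(g2$n_outliers, 0L)

  # on random series, dropping an outlier keeps the implementation in
  # lock-step with the brute-force recompute, and whiskers stay inside the
  # fences and the data range
  withr::with_seed(78, {
    for (i in 1:50) {
      v <- c(rnorm(12), rnorm(2, 0, 8))
      b1 <- oracle_box(v)
      if (length(b1$outliers) == 0) next
      v2 <- v[-match(b1$outliers[1], v)]
      b2 <- oracle_box(v2)
      g <- climatology_box(ser(v2))[1, ]
      expect_identical(g$whisker_low, b2$whisker_low)
      expect_identical(g$whisker_high, b2$whisker_high)
      expect_gte(g$whisker_low, min(v2))
      expect_lte(g$whisker_high, max(v2))
      expect_gte(g$whisker_low, g$q1 - 1.5 * (g$q3 - g$q1) - 1e-12)
      expect_lte(g$whisker_high, g$q3 + 1.5 * (g$q3 - g$q1) + 1e-12)
    }
  })
})
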