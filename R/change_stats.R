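#' Two-sample F test for equality of variances
#'
#' The statistic is the ratio of the larger to the smaller sample variance
#' (so F >= 1) with the corresponding degrees of freedom; the two-sided
#' p-value is twice the upper tail, capped at 1. Variances are judged equal
#' when p >= alpha.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alpha significance level (default 0.05).
#' @return List with `f_stat`, `df1`, `df2`, `p_value`, `equal`, `alpha`.
#' @examples
#' f_test_equal_variance(rnorm(10), rnorm(10))
#' @export
f_test_equal_variance <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  if (vx >= vy) {
    f <- vx / vy; df1 <- length(x) - 1; df2 <- length(y) - 1
  } else {
    f <- vy / vx; df1 <- length(y) - 1; df2 <- length(x) - 1
  }
  p <- min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
  list(f_stat = f, df1 = df1, df2 = df2, p_value = p,
       equal = p >= alpha, alpha = alpha)
}

#' Two-sample t test with F-test-guided flavour selection
#'
#' Tests whether two sets of annual biomass values share a mean. With
#' `flavour = "auto"` a two-sample F test for equal variances is run first:
#' if it does not reject at `alpha` the pooled-variance (Student) t test is
#' used, otherwise Welch's. Both flavours are also callable directly. The
#' p-value is two-sided.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param flavour `"auto"`, `"pooled"` or `"welch"`.
#' @param alpha significance level used by the variance pre-test and reported
#'   in the result.
#' @return An object of class `period_comparison`: list with `sample_a`,
#'   `sample_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `f_stat`, `f_p`,
#'   `variances_equal`, `t_stat`, `t_p`, `df`, `flavour`, `alpha`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6), flavour = "pooled")
#' @export
two_sample_t <- function(x, y, flavour = c("auto", "pooled", "welch"),
                         alpha = 0.05) {
  flavour <- match.arg(flavour)
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    stop("degenerate samples: both variances are zero", call. = FALSE)
  }
  ft <- f_test_equal_variance(x, y, alpha = alpha)
  used <- if (flavour == "auto") {
    if (ft$equal) "pooled" else "welch"
  } else flavour
  tt <- t.test(x, y, var.equal = used == "pooled")
  structure(
    list(sample_a = x, sample_b = y, n_a = length(x), n_b = length(y),
         mean_a = mean(x), mean_b = mean(y),
         f_stat = ft$f_stat, f_p = ft$p_value, variances_equal = ft$equal,
         t_stat = unname(tt$statistic), t_p = tt$p.value,
         df = unname(tt$parameter), flavour = used, alpha = alpha),
    class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("<period_comparison> n = %d vs %d, means %.4g vs %.4g\n",
              x$n_a, x$n_b, x$mean_a, x$mean_b))
  cat(sprintf("  F = %.4g (p = %.4g) -> variances %s -> %s t test\n",
              x$f_stat, x$f_p,
              if (x$variances_equal) "equal" else "unequal", x$flavour))
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g (alpha = %g)\n",
              x$t_stat, x$df, x$t_p, x$alpha))
  invisible(x)
}

#' Compare two periods of annual biomass
#'
#' Convenience wrapper: selects annual mean biomass for two ecological-year
#' ranges from an [annual_means()] table and runs [two_sample_t()].
#'
#' @param annual data frame with columns `ecological_year` and `biomass_t`.
#' @param years_a,years_b length-2 integer ranges `c(first, last)`.
#' @inheritParams two_sample_t
#' @return A `period_comparison`.
#' @export
compare_periods <- function(annual, years_a, years_b,
                            flavour = c("auto", "pooled", "welch"),
                            alpha = 0.05) {
  a <- annual$biomass_t[annual$ecological_year >= years_a[1] &
                          annual$ecological_year <= years_a[2]]
  b <- annual$biomass_t[annual$ecological_year >= years_b[1] &
                          annual$ecological_year <= years_b[2]]
  two_sample_t(a, b, flavour = flavour, alpha = alpha)
}

#' Monthly climatological box statistics
#'
#' For each calendar month, quartiles are computed by linear interpolation
#' (type 7); whiskers extend to the most extreme data points within 1.5 times
#' the interquartile range of the first/third quartile, and values beyond the
#' whiskers are outliers. Months with no data yield a no-data record
#' (`n = 0`, `NA` statistics).
#'
#' @param series a `biomass_series` (or any data frame with `month` and a
#'   value column) — see [regional_series()].
#' @param years optional set of ecological years to restrict to.
#' @param value_col name of the value column (default `"biomass_t"`).
#' @return Data frame of class `climatology_box` with one row per month:
#'   `month`, `n`, `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`; the outlier values themselves are in the list column
#'   `outliers`.
#' @export
climatology_box <- function(series, years = NULL, value_col = "biomass_t") {
  df <- as.data.frame(series)
  if (!is.null(years)) df <- df[df$ecological_year %in% years, ]
  out <- vector("list", 12)
  for (m in 1:12) {
    v <- df[[value_col]][df$month == m]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      out[[m]] <- data.frame(month = m, n = 0L, q1 = NA_real_,
                             median = NA_real_, q3 = NA_real_,
                             whisker_low = NA_real_, whisker_high = NA_real_,
                             n_outliers = 0L)
      out[[m]]$outliers <- list(numeric(0))
      next
    }
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v >= lo_fence & v <= hi_fence
    out[[m]] <- data.frame(month = m, n = length(v), q1 = q[1],
                           median = q[2], q3 = q[3],
                           whisker_low = min(v[inside]),
                           whisker_high = max(v[inside]),
                           n_outliers = sum(!inside))
    out[[m]]$outliers <- list(v[!inside])
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("climatology_box", "data.frame")
  out
}
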