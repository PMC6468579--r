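#' Pearson correlation with exact t-transform p-value
#'
#' Sample Pearson correlation between two profiles (e.g. densitometry
#' intensities of two markers across gradient fractions) with the exact
#' two-sided p-value from the t-transform `t = r sqrt(n-2) / sqrt(1-r^2)`
#' on `n - 2` degrees of freedom. Cross-checked against
#' [stats::cor.test()] in the test suite.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; both non-constant.
#' @return An object of class `correlation_result`: `r`, `n`, `t_stat`,
#'   `df`, `p_two_sided`.
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("profiles must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 paired values are required")
  if (any(!is.finite(c(x, y)))) stop("profiles must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant profile: correlation is undefined")
  r <- cor(x, y)
  pearson_test_from_r(r, n)
}

#' Two-sided p-value of a Pearson correlation from r and n
#'
#' The t-transform used by the standard correlation test, exposed directly
#' so that reported correlations can be checked without the raw profiles.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param n number of paired observations (>= 3).
#' @return A `correlation_result` (see [pearson_with_p()]). For `|r| = 1`
#'   the statistic is infinite and the p-value 0.
#' @export
pearson_test_from_r <- function(r, n) {
  stop_if_not_scalar_number(r, "r")
  if (abs(r) > 1) stop("`r` must be in [-1, 1]")
  stop_if_not_scalar_number(n, "n")
  if (n < 3) stop("`n` must be >= 3")
  df <- as.integer(n) - 2L
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  structure(list(r = r, n = as.integer(n), t_stat = t_stat, df = df,
                 p_two_sided = 2 * pt(-abs(t_stat), df)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, n = %d, t = %.3f, df = %d, p = %.4g\n",
              x$r, x$n, x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Two-sided paired t-test
#'
#' Student's paired t-test on per-unit differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom,
#' computed via [stats::t.test()].
#'
#' @param x,y aligned numeric vectors (`n >= 2`).
#' @return An object of class `paired_test_result`: `t_stat`, `df`,
#'   `p_two_sided`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- x - y
  if (sd(d) == 0)
    stop("degenerate paired test: the differences have zero variance")
  tt <- t.test(x, y, paired = TRUE)
  structure(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value, mean_diff = mean(d), n = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> mean diff = %.4g, t = %.3f, df = %d, p = %.4g, n = %d\n",
              x$mean_diff, x$t_stat, x$df, x$p_two_sided, x$n))
  invisible(x)
}

#' Manders colocalization coefficients
#'
#' Classic Manders split coefficients between two intensity channels:
#' `M1` is the fraction of channel-A intensity (summed over pixels where
#' `A > thr_a`) that lies in pixels where `B > thr_b`; `M2` swaps the
#' roles. With the default zero thresholds these are the original Manders
#' coefficients.
#'
#' @param ch_a,ch_b intensity matrices of identical shape.
#' @param thr_a,thr_b intensity thresholds (default 0).
#' @return An object of class `manders_result`: `m1`, `m2`, `thr_a`,
#'   `thr_b`.
#' @examples
#' a <- matrix(c(10, 20, 30), 1); b <- matrix(c(0, 5, 9), 1)
#' manders(a, b, thr_a = 0, thr_b = 4)$m1  # (20+30)/60 = 0.8333
#' @export
manders <- function(ch_a, ch_b, thr_a = 0, thr_b = 0) {
  if (!identical(dim(ch_a), dim(ch_b)))
    stop("channels must have identical shape")
  stop_if_not_scalar_number(thr_a, "thr_a")
  stop_if_not_scalar_number(thr_b, "thr_b")
  denom_a <- sum(ch_a[ch_a > thr_a])
  denom_b <- sum(ch_b[ch_b > thr_b])
  if (denom_a <= 0 || denom_b <= 0)
    stop("undefined Manders coefficient: a channel has no intensity above threshold")
  m1 <- sum(ch_a[ch_b > thr_b]) / denom_a
  m2 <- sum(ch_b[ch_a > thr_a]) / denom_b
  structure(list(m1 = m1, m2 = m2, thr_a = thr_a, thr_b = thr_b),
            class = "manders_result")
}

#' @export
print.manders_result <- function(x, ...) {
  cat(sprintf("<manders_result> M1 = %.4f, M2 = %.4f (thresholds %g / %g)\n",
              x$m1, x$m2, x$thr_a, x$thr_b))
  invisible(x)
}
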