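#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired measurements (e.g. LCBI per case
#' from two methods). Zero differences are dropped before ranking (standard
#' signed-rank convention); absolute differences receive midranks under
#' ties. For up to 25 non-zero pairs the p-value is exact, computed from the
#' full permutation distribution of the positive-rank sum over all `2^n`
#' equally likely sign assignments (ties handled exactly via the observed
#' midranks); above that a normal approximation with tie correction and
#' continuity correction is used. Two-sided p is
#' `min(1, 2 * min(P(T <= t), P(T >= t)))` and is symmetric under swapping
#' the two methods.
#'
#' @param method1,method2 equal-length numeric vectors of paired values.
#' @return List with `p_value`, `statistic` (positive-rank sum `V`),
#'   `n_nonzero`, and `all_zero` (TRUE when every difference is zero, in
#'   which case `p_value = 1`).
#' @export
paired_wilcoxon <- function(method1, method2) {
  stopifnot(length(method1) == length(method2),
            all(is.finite(method1)), all(is.finite(method2)))
  d <- method1 - method2
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L, all_zero = TRUE))
  rk <- rank(abs(d))                     # midranks under ties
  v <- sum(rk[d > 0])
  if (n <= 25L) {
    # exact distribution of the positive-rank sum: convolve over the doubled
    # midranks (integers), each included with probability 1/2
    r2 <- as.integer(round(2 * rk))
    probs <- c(1)                        # P(2T = 0), support 0..sum(r2)
    for (r in r2) {
      shifted <- c(rep(0, r), probs)
      probs <- c(probs, rep(0, r)) / 2 + shifted / 2
    }
    t2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(t2 + 1L)])
    p_ge <- sum(probs[(t2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
  }
  list(p_value = p, statistic = v, n_nonzero = n, all_zero = FALSE)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two (or more) measurement methods — the form suited
#' to asking whether methods are interchangeable, since a constant offset
#' between methods is penalised. Computed from the two-way ANOVA mean
#' squares (subjects x methods); the confidence interval is the standard
#' F-based interval with a Satterthwaite degrees-of-freedom approximation.
#'
#' @param method1,method2 equal-length numeric vectors, `n >= 3` subjects.
#' @param conf_level confidence level, default 0.95.
#' @return List with `estimate`, `ci_low`, `ci_high`, the mean squares
#'   (`msr` rows/subjects, `msc` columns/methods, `mse` error) and
#'   `degenerate` (TRUE when total variance is zero and the ICC undefined;
#'   `estimate` is then `NA`).
#' @export
icc <- function(method1, method2, conf_level = 0.95) {
  stopifnot(length(method1) == length(method2),
            all(is.finite(method1)), all(is.finite(method2)))
  x <- cbind(method1, method2)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("ICC requires at least 3 paired observations", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total == 0)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                msr = 0, msc = 0, mse = 0, degenerate = TRUE))
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- max(0, ss_err) / ((n - 1) * (k - 1))
  est <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: interval collapses at 1
    return(list(estimate = est, ci_low = 1, ci_high = 1,
                msr = msr, msc = msc, mse = mse, degenerate = FALSE))
  }
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(estimate = est, ci_low = lo, ci_high = hi,
       msr = msr, msc = msc, mse = mse, degenerate = FALSE)
}

#' Bland-Altman limits of agreement
#'
#' Differences `method1 - method2` against their means, with the mean
#' difference and limits of agreement at `mean +/- 2 * SD` of the
#' differences (sample standard deviation, `n - 1` denominator; the factor
#' is 2, not 1.96).
#'
#' @param method1,method2 equal-length numeric vectors, `n >= 2`.
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, and a
#'   `data.frame` `points` (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(method1, method2) {
  stopifnot(length(method1) == length(method2))
  if (length(method1) < 2L)
    stop("Bland-Altman requires at least 2 pairs", call. = FALSE)
  stopifnot(all(is.finite(method1)), all(is.finite(method2)))
  d <- method1 - method2
  m <- (method1 + method2) / 2
  md <- mean(d)
  s <- sd(d)
  list(mean_diff = md, loa_low = md - 2 * s, loa_high = md + 2 * s,
       sd_diff = s, points = data.frame(mean = m, diff = d))
}

#' Bland-Altman plot
#'
#' @param ba result of [bland_altman()].
#' @param main plot title.
#' @param xlab,ylab axis labels.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman",
                              xlab = "Mean of methods",
                              ylab = "Difference (method 1 - method 2)") {
  plot(ba$points$mean, ba$points$diff, pch = 19, main = main,
       xlab = xlab, ylab = ylab,
       ylim = range(ba$points$diff, ba$loa_low, ba$loa_high))
  abline(h = ba$mean_diff, lty = 1)
  abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}

#' Median with first and third quartiles
#'
#' @param values numeric vector, `n >= 1`.
#' @param quantile_type passed to [stats::quantile()] (default 7, linear
#'   interpolation).
#' @return List with `median`, `q1`, `q3`.
#' @export
summarize_values <- function(values, quantile_type = 7) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  q <- quantile(values, c(0.25, 0.5, 0.75), type = quantile_type,
                names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}
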