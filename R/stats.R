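# Paired Student's-t comparison of two classifiers across experiment
# stages, on absolute accuracy differences.

#' Two-tailed Student-t critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical value `t` such that the acceptance interval is
#'   `[-t, +t]`.
#' @examples
#' t_critical(3, 0.05)  # 3.182
#' @export
t_critical <- function(df, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  stats::qt(1 - alpha / 2, df)
}

#' Paired difference t comparison of two classifiers
#'
#' Given the accuracies of two classifiers across the same N
#' experiment stages, computes the absolute paired differences
#' `D_i = |a_i - b_i|`, their mean and sample standard deviation
#' (N - 1 denominator), the statistic `T = sqrt(N) * mean / sd`, and
#' compares it with the two-tailed Student-t critical interval at
#' `N - 1` degrees of freedom. The decision text follows the source
#' convention that a statistic inside the interval indicates no
#' significant difference between the classifiers.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of accuracies
#'   (percent), N >= 2.
#' @param alpha Two-tailed significance level.
#' @return A list of class `ttest_result`: `differences`, `mean`, `sd`,
#'   `t_selection`, `df`, `alpha`, `critical`, `within_interval`,
#'   `decision_text`.
#' @export
paired_difference_test <- function(acc_a, acc_b, alpha = 0.05) {
  if (length(acc_a) != length(acc_b)) stop("length mismatch")
  n <- length(acc_a)
  if (n < 2) stop("need at least two paired experiments")
  d <- abs(acc_a - acc_b)
  mu <- mean(d)
  sigma <- stats::sd(d)
  if (sigma == 0) {
    stop("all paired differences are equal: the statistic is undefined (sd = 0)")
  }
  tt <- sqrt(n) * mu / sigma
  crit <- t_critical(n - 1, alpha)
  within <- tt >= -crit && tt <= crit
  structure(list(
    differences = d, mean = mu, sd = sigma, t_selection = tt,
    df = n - 1L, alpha = alpha, critical = crit,
    within_interval = within,
    decision_text = if (within) {
      "T-Selection lies within the critical interval: no significant difference between the classifiers."
    } else {
      "T-Selection lies outside the critical interval: the classifiers differ significantly."
    }
  ), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "<ttest_result> mean diff %.3f, sd %.3f, T = %.3f, interval [%.3f, %.3f] (df = %d, alpha = %.2f)\n  %s\n",
    x$mean, x$sd, x$t_selection, -x$critical, x$critical, x$df, x$alpha,
    x$decision_text))
  invisible(x)
}
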