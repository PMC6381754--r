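#' Sample size for comparing two proportions
#'
#' Study-design calculator for a two-arm comparison of response proportions
#' (here: the anticipated RCB = 0 rate among predicted responders versus
#' predicted non-responders). Uses the unpooled normal-approximation formula
#' without continuity correction:
#'
#' n per group = ceil\[ (z_{1-alpha/2} + z_{power})^2 *
#'   (p1 (1 - p1) + p2 (1 - p2)) / (p1 - p2)^2 \]
#'
#' @param p1,p2 Anticipated proportions in each group, both in (0, 1) and
#'   distinct.
#' @param alpha Two-sided type I error level (default 0.05).
#' @param power Target power (default 0.80).
#' @return An object of class `sample_size_plan`: list with `p1`, `p2`,
#'   `alpha`, `power`, `n_per_group`, `n_total`.
#' @examples
#' two_proportion_sample_size(0.45, 0.10)  # 22 per group, 44 in total
#' @export
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (p1 == p2) {
    stop("p1 and p2 must differ (zero effect needs infinite n)", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(z^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2)
  out <- list(p1 = p1, p2 = p2, alpha = alpha, power = power,
              n_per_group = as.integer(n), n_total = as.integer(2 * n))
  class(out) <- "sample_size_plan"
  out
}

#' Inflate a sample size for anticipated drop-out
#'
#' Multiplicative inflation `ceil(n_total * (1 + dropout))`: a planned total
#' of 44 with 15% drop-out becomes 51 patients.
#'
#' @param n_total Planned total sample size (positive integer).
#' @param dropout Anticipated drop-out proportion in \[0, 1).
#' @return Inflated total (integer).
#' @examples
#' inflate_for_dropout(44, 0.15)
#' @export
inflate_for_dropout <- function(n_total, dropout) {
  stopifnot(n_total >= 1)
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  as.integer(ceiling(n_total * (1 + dropout)))
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat(sprintf(
    "Two-proportion design (p1 = %.2f vs p2 = %.2f, alpha = %.2f, power = %.2f):\n",
    x$p1, x$p2, x$alpha, x$power))
  cat(sprintf("  %d patients per group, %d in total\n",
              x$n_per_group, x$n_total))
  invisible(x)
}

#' Format a count as "x out of n (p%)"
#'
#' Clinical-report formatting of a proportion, percentage rounded to one
#' decimal. The percentage is always recomputed from the counts.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return List with `k`, `n`, `pct` (numeric, one decimal) and `label`.
#' @examples
#' format_rate(3, 28)  # "3 out of 28 (10.7%)"
#' @export
format_rate <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  pct <- round(100 * k / n, 1)
  list(k = k, n = n, pct = pct,
       label = sprintf("%d out of %d (%.1f%%)", k, n, pct))
}
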