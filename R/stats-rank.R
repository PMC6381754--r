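#' Two-sample rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' Compares two sets of measurements by their ranks, the test used throughout
#' the pipeline to contrast responder (RCB = 0) and non-responder (RCB > 0)
#' methylation values. The Mann-Whitney U statistic counts, over all
#' `length(group_a) * length(group_b)` pairs, how often a value from
#' `group_a` exceeds one from `group_b` (ties count 1/2). The permutation
#' distribution is enumerated exactly when the combined sample size is at
#' most `exact_limit` and there are no ties; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors with at least 2 non-missing values
#'   each.
#' @param exact_limit Largest combined sample size for which the exact
#'   permutation p-value is computed (default 20; discovery cohorts here are
#'   of the order 10 vs 14).
#' @return An object of class `rank_test` (a list) with elements
#'   `u_statistic` (wins of `group_a` over `group_b`), `p_two_sided`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`, and
#'   `degenerate` (`TRUE` when all pooled values are identical, in which case
#'   `p_two_sided` is 1 by convention).
#' @examples
#' rank_sum_test(c(0.1, 0.2, 0.15), c(0.5, 0.6, 0.55))
#' @export
rank_sum_test <- function(group_a, group_b, exact_limit = 20) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("rank_sum_test() needs at least 2 non-missing values per group",
         call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    # zero-variance data: no rank information, p = 1 by convention
    out <- list(u_statistic = n_a * n_b / 2, p_two_sided = 1,
                method = "normal_approx", n_a = n_a, n_b = n_b,
                degenerate = TRUE)
    class(out) <- "rank_test"
    return(out)
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && (n_a + n_b) <= exact_limit
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = TRUE, alternative = "two.sided")
  )
  out <- list(u_statistic = unname(ht$statistic),
              p_two_sided = min(1, ht$p.value),
              method = if (use_exact) "exact" else "normal_approx",
              n_a = n_a, n_b = n_b, degenerate = FALSE)
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %.1f (n = %d vs %d), p = %.4g%s\n",
              x$method, x$u_statistic, x$n_a, x$n_b, x$p_two_sided,
              if (x$degenerate) " [degenerate: constant data]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties, used for methylation-expression
#' coupling. The p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' adequate for the moderate sample sizes the pipeline handles.
#'
#' @param x,y Paired numeric vectors of equal length, at least 3 complete
#'   pairs, neither constant.
#' @return A list with `rho` and `p_value`.
#' @examples
#' spearman_correlation(1:4, c(2, 1, 4, 3))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop("spearman_correlation() needs at least 3 complete pairs",
         call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("Spearman correlation is undefined for a constant input",
         call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ht$estimate), p_value = min(1, ht$p.value))
}
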