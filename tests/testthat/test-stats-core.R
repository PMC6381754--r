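test_that("exact rank-sum p matches full enumeration", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_two_sided, 1 / 3)
  expect_identical(r$method, "exact")

  r <- rank_sum_test(c(0.1, 0.2, 0.15, 0.12), c(0.5, 0.6, 0.55, 0.52))
  expect_equal(r$p_two_sided, 2 / 70)

  set.seed(42)
  for (i in 1:30) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    repeat {
      x <- round(runif(n1 + n2), 6)
      if (!anyDuplicated(x)) break
    }
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    expect_equal(rank_sum_test(a, b)$p_two_sided, enum_rank_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum handles degenerate and tied inputs", {
  # identical multisets: symmetric, U = n^2/2, p = 1
  r <- rank_sum_test(c(0.2, 0.4, 0.6), c(0.4, 0.2, 0.6))
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$u_statistic, 9 / 2)

  r <- rank_sum_test(c(1, 1, 1), c(1, 1))
  expect_true(r$degenerate)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$u_statistic, 3)

  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")

  # switch to normal approximation above the exact limit and with ties
  expect_identical(rank_sum_test(rnorm(15), rnorm(15))$method,
                   "normal_approx")
  expect_identical(rank_sum_test(c(1, 2, 2), c(3, 4, 5))$method,
                   "normal_approx")
})

test_that("spearman correlation matches rank arithmetic", {
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  # hand computation: 1 - 6 * sum(d^2) / (n^3 - n), sum(d^2) = 4
  r <- spearman_correlation(1:4, c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  tt <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(r$p_value, 2 * stats::pt(-tt, df = 2), tolerance = 1e-10)
  expect_error(spearman_correlation(rep(1, 4), 1:4), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "3 complete pairs")
})

test_that("logistic fit reports maximum likelihood and AIC", {
  # intercept-only with balanced labels: closed-form p-hat = 0.5
  f <- logistic_fit(matrix(numeric(0), 4, 0), c(0, 0, 1, 1))
  expect_equal(f$log_likelihood, 4 * log(0.5), tolerance = 1e-8)
  expect_equal(f$aic, 2 - 8 * log(0.5), tolerance = 1e-8)
  expect_true(f$converged)

  # AIC invariant 2k - 2 logLik on a non-trivial fit
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(20, 1, plogis(x[, 1]))
  f <- logistic_fit(x, y)
  expect_equal(f$aic, 2 * 3 - 2 * f$log_likelihood, tolerance = 1e-10)

  # degenerate outcome: all labels one class
  f <- suppressWarnings(logistic_fit(matrix(numeric(0), 4, 0),
                                     c(1, 1, 1, 1)))
  expect_false(f$converged)

  # perfect separation: flagged, AIC still reported
  f <- logistic_fit(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                           dimnames = list(NULL, "g")),
                    c(0, 0, 0, 1, 1, 1))
  expect_false(f$converged)
  expect_true(is.finite(f$aic))

  # constant feature dropped with a warning
  x <- data.frame(g = c(1, 2, 3, 4), flat = 1)
  expect_warning(f <- logistic_fit(x, c(0, 0, 1, 1)), "constant")
  expect_identical(f$dropped, "flat")
  expect_false("flat" %in% names(f$coefficients))
})

test_that("two-proportion sample size reproduces the study design", {
  plan <- two_proportion_sample_size(0.45, 0.10, alpha = 0.05, power = 0.80)
  expect_identical(plan$n_per_group, 22L)
  expect_identical(plan$n_total, 44L)
  expect_identical(inflate_for_dropout(plan$n_total, 0.15), 51L)

  # unpooled normal-approximation formula, evaluated independently
  z <- qnorm(0.975) + qnorm(0.80)
  expect_identical(two_proportion_sample_size(0.60, 0.40)$n_per_group,
                   as.integer(ceiling(z^2 * (0.6 * 0.4 + 0.4 * 0.6) / 0.2^2)))
  expect_identical(two_proportion_sample_size(0.60, 0.40)$n_per_group, 95L)

  expect_identical(inflate_for_dropout(10, 0), 10L)
  expect_identical(inflate_for_dropout(100, 0.15), 115L)
  expect_error(two_proportion_sample_size(0.3, 0.3), "differ")
  expect_error(inflate_for_dropout(10, 1), "dropout")

  # monotonicity: n falls with effect size, rises with power
  n_small <- two_proportion_sample_size(0.50, 0.40)$n_per_group
  n_large <- two_proportion_sample_size(0.70, 0.40)$n_per_group
  expect_lt(n_large, n_small)
  n_hipow <- two_proportion_sample_size(0.50, 0.40, power = 0.95)$n_per_group
  expect_gt(n_hipow, n_small)
})

test_that("ROC machinery agrees with pairwise-win and brute-force oracles", {
  # perfect separation
  r <- roc_with_bootstrap(c(3, 4, 1, 2), c(1, 1, 0, 0), n_boot = 50,
                          seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)

  # identical score distributions: ties count one half
  r <- roc_with_bootstrap(c(1, 2, 1, 2), c(1, 1, 0, 0), n_boot = 50,
                          seed = 1)
  expect_equal(r$auc, 0.5)

  # enumerated: 4 wins + 1 tie/2 + 1 loss over 6 pairs
  expect_equal(auc_pairwise(c(4, 3, 2, 3, 1), c(1, 1, 1, 0, 0)), 4.5 / 6)

  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    labels <- c(1, 1, 0, 0, rbinom(n - 4, 1, 0.5))
    scores <- sample(round(rnorm(n), 2), n)  # rounding induces ties
    auc <- auc_pairwise(scores, labels)
    # AUC = U / (n_pos * n_neg) with U from the rank-sum machinery
    u <- rank_sum_test(scores[labels == 1], scores[labels == 0])$u_statistic
    expect_equal(auc, u / (sum(labels == 1) * sum(labels == 0)))
    r <- roc_with_bootstrap(scores, labels, n_boot = 5, seed = i)
    bo <- brute_youden(scores, labels)
    expect_equal(r$youden_cutoff, bo$cutoff)
    expect_equal(r$youden_j, bo$j)
    expect_equal(r$auc, auc)
  }
})

test_that("bootstrap CI is seed-reproducible and point AUC ignores n_boot", {
  scores <- c(0.1, 0.5, 0.4, 0.9, 0.8, 0.3, 0.7, 0.2)
  labels <- c(0, 1, 0, 1, 1, 0, 1, 0)
  r1 <- roc_with_bootstrap(scores, labels, n_boot = 200, seed = 11)
  r2 <- roc_with_bootstrap(scores, labels, n_boot = 200, seed = 11)
  expect_identical(r1, r2)
  r3 <- roc_with_bootstrap(scores, labels, n_boot = 1000, seed = 99)
  expect_identical(r1$auc, r3$auc)
  expect_true(r1$auc_ci_low <= r1$auc && r1$auc <= r1$auc_ci_high)
  expect_error(roc_with_bootstrap(1:4, c(1, 1, 1, 1), 10, seed = 1),
               "both classes")
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:10) {
    scores <- round(rnorm(20), 1)
    labels <- c(1, 0, rbinom(18, 1, 0.4))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_pairwise(scores, labels), ref, tolerance = 1e-12)
  }
})
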