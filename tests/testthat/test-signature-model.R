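mk_model <- function(genes, coefs, cutoff = NA_real_) {
  m <- list(genes = genes, coefficients = setNames(coefs, genes),
            intercept = 0, aic = NA_real_, null_aic = NA_real_, fit = NULL,
            n_used = NA_integer_, n_dropped = 0L, all_fits = NULL,
            cutoff = cutoff, auc = NA_real_, auc_ci_low = NA_real_,
            auc_ci_high = NA_real_)
  class(m) <- "signature_model"
  m
}

test_that("the score is the exact intercept-free weighted sum", {
  m <- mk_model(c("FERD3L", "TRIP10"), c(5, 5))
  gm <- data.frame(sample_id = c("a", "b", "c"),
                   FERD3L = c(80, 0, 10), TRIP10 = c(90, 0, 20))
  sc <- score_samples(m, gm)
  expect_equal(sc$score, c(850, 0, 150))
  m2 <- mk_model(c("FERD3L", "TRIP10"), c(10, 10))
  expect_equal(score_samples(m2, gm)$score, 2 * sc$score)

  # missing measurements skip the sample and are counted
  gm$FERD3L[2] <- NA
  sc2 <- score_samples(m, gm)
  expect_equal(nrow(sc2), 2)
  expect_equal(attr(sc2, "n_skipped"), 1)
  expect_error(score_samples(m, gm[, c("sample_id", "FERD3L")]), "missing")
})

test_that("cutoff derivation reports Youden rule and count-based rates", {
  # perfect separation fixture
  m <- mk_model("G", 1)
  scored <- data.frame(sample_id = sprintf("s%d", 1:8), G = c(8:5, 4:1),
                       score = c(8:5, 4:1),
                       true_response = c(1, 1, 1, 1, 0, 0, 0, 0))
  class(scored) <- c("scored_samples", "data.frame")
  done <- derive_cutoff_and_performance(m, scored, n_boot = 100, seed = 2)
  expect_equal(done$auc, 1)
  expect_equal(done$rate_above$pct, 100)
  expect_equal(done$rate_below$pct, 0)
  expect_equal(done$cutoff, 4)  # smallest threshold attaining J = 1
  # strict inequality: the sample scoring exactly the cutoff is negative
  rescored <- score_samples(done, scored[, c("sample_id", "G")])
  expect_identical(rescored$predicted_positive, scored$score > 4)

  # rates recompute exactly from confusion counts, in the printed form
  expect_identical(format_rate(3, 28)$pct, 10.7)
  expect_identical(format_rate(3, 28)$label, "3 out of 28 (10.7%)")

  # AUC is the pairwise-wins AUC of the same scores (single source)
  set.seed(9)
  sc <- data.frame(sample_id = sprintf("x%d", 1:20), G = rnorm(20))
  sc$score <- sc$G
  sc$true_response <- rbinom(20, 1, 0.5)
  sc$true_response[1:2] <- c(0, 1)
  done2 <- derive_cutoff_and_performance(mk_model("G", 1), sc,
                                         n_boot = 50, seed = 3)
  expect_equal(done2$auc, auc_pairwise(sc$score, sc$true_response))
  u <- rank_sum_test(sc$score[sc$true_response == 1],
                     sc$score[sc$true_response == 0])$u_statistic
  expect_equal(done2$auc,
               u / (sum(sc$true_response == 1) * sum(sc$true_response == 0)))
})

test_that("common rescaling of methylation leaves predictions unchanged", {
  set.seed(11)
  gm <- data.frame(sample_id = sprintf("s%02d", 1:30),
                   A = runif(30, 10, 90), B = runif(30, 10, 90))
  y <- rbinom(30, 1, plogis((gm$A - gm$B) / 20))
  y[1:2] <- c(0, 1)
  samples <- tiny_samples(gm$sample_id, ifelse(y == 1, "R", "NR"))
  m <- mk_model(c("A", "B"), c(2, -1))
  sc <- score_samples(m, gm, samples)
  m <- derive_cutoff_and_performance(m, sc, n_boot = 20, seed = 5)
  pred1 <- score_samples(m, gm, samples)$predicted_positive

  gm2 <- gm
  gm2$A <- gm$A * 3
  gm2$B <- gm$B * 3
  sc2 <- score_samples(mk_model(c("A", "B"), c(2, -1)), gm2, samples)
  m2 <- derive_cutoff_and_performance(mk_model(c("A", "B"), c(2, -1)), sc2,
                                      n_boot = 20, seed = 5)
  pred2 <- score_samples(m2, gm2, samples)$predicted_positive
  expect_identical(pred1, pred2)
  expect_equal(m2$auc, m$auc)
})

test_that("AIC selection recovers planted genes and respects the null margin", {
  # two predictive genes among five candidates
  truth <- planted_truth(paste0("G", 1:5),
                         direction = c("hyper_in_R", "hyper_in_R",
                                       rep("hyper_in_NR", 3)),
                         delta = c(0.25, 0.25, 0, 0, 0), sd_within = 0.15)
  hits <- 0
  for (s in 1:5) {
    sheet <- methresp:::make_sample_sheet(11, 28, "discovery", seed = 40 + s)
    pyro <- generate_pyro_table(truth, sheet, 4, 3, seed = 80 + s)
    gm <- gene_methylation_wide(lapply(paste0("G", 1:5), function(g) {
      aggregate_gene_methylation(pyro, g)
    }))
    m <- suppressWarnings(select_signature(gm, sheet, paste0("G", 1:5)))
    if (setequal(m$genes, c("G1", "G2"))) hits <- hits + 1
  }
  expect_gte(hits, 4)

  # single candidate: AIC ordering equals the likelihood-ratio direction
  sheet <- methresp:::make_sample_sheet(11, 28, "discovery", seed = 3)
  pyro <- generate_pyro_table(truth, sheet, 4, 3, seed = 4)
  gm <- gene_methylation_wide(list(aggregate_gene_methylation(pyro, "G1")))
  m1 <- select_signature(gm, sheet, "G1", aic_margin = 0)
  # oracle refit with plain glm
  d <- merge(gm, sheet[, c("sample_id", "response")], by = "sample_id")
  f1 <- stats::glm(I(response == "R") ~ G1, data = d, family = binomial())
  f0 <- stats::glm(I(response == "R") ~ 1, data = d, family = binomial())
  expect_identical(length(m1$genes) == 1,
                   stats::AIC(f1) < stats::AIC(f0))
  expect_equal(m1$aic, stats::AIC(f1), tolerance = 1e-8)
})

test_that("pure-noise candidates rarely displace the null model", {
  null_truth <- planted_truth(paste0("G", 1:5),
                              direction = "hyper_in_NR", delta = 0,
                              sd_within = 0.15)
  null_wins <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    sheet <- methresp:::make_sample_sheet(11, 28, "discovery",
                                          seed = 7000 + s)
    pyro <- generate_pyro_table(null_truth, sheet, 4, 3, seed = 8000 + s)
    gm <- gene_methylation_wide(lapply(paste0("G", 1:5), function(g) {
      aggregate_gene_methylation(pyro, g)
    }))
    m <- suppressWarnings(select_signature(gm, sheet, paste0("G", 1:5)))
    if (length(m$genes) == 0) null_wins <- null_wins + 1
  }
  expect_gte(null_wins / n_seeds, 0.80)
})
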