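# A 3-gene hand fixture: GENE_A passes everything (4 concordant promoter
# island CpGs), GENE_B has a sub-threshold effect size, GENE_C sits in open
# sea. Group betas are constructed, not simulated.
make_fixture <- function() {
  manifest <- tiny_manifest(
    probe_id = c(paste0("cgA", 1:4), "cgB1", "cgC1"),
    chrom = "chr1",
    pos = c(100, 200, 300, 400, 5000, 9000),
    gene = c(rep("GENE_A", 4), "GENE_B", "GENE_C"),
    gene_group = c(rep("TSS200", 4), "TSS1500", "Body"),
    island_relation = c(rep("Island", 4), "N_Shore", "OpenSea"))
  samples <- tiny_samples(sprintf("S%02d", 1:10),
                          rep(c("R", "NR"), each = 5))
  r <- c(0.10, 0.12, 0.11, 0.13, 0.09)
  nr <- c(0.50, 0.52, 0.51, 0.53, 0.49)
  beta <- rbind(
    cgA1 = c(r, nr), cgA2 = c(r, nr) + 0.01, cgA3 = c(r, nr) - 0.01,
    cgA4 = c(r, nr) + 0.02,
    cgB1 = c(r, r + 0.10),        # delta 0.10 < 0.20
    cgC1 = c(r, nr))              # strong but open sea
  colnames(beta) <- samples$sample_id
  list(manifest = manifest, samples = samples, beta = beta)
}

test_that("per-probe testing records means, effect sizes and exact p", {
  fx <- make_fixture()
  tests <- test_all_probes(fx$beta, fx$samples)
  expect_equal(nrow(tests), 6)
  a1 <- tests[tests$probe_id == "cgA1", ]
  expect_equal(a1$delta_beta, a1$mean_nr - a1$mean_r)
  expect_equal(a1$delta_beta, 0.40)
  expect_identical(a1$direction, "hyper_in_NR")
  # p equals the stats-core exact test on the same values
  expect_equal(a1$p_value,
               rank_sum_test(fx$beta["cgA1", 1:5],
                             fx$beta["cgA1", 6:10])$p_two_sided)
  expect_equal(a1$p_value, enum_rank_p(fx$beta["cgA1", 1:5],
                                       fx$beta["cgA1", 6:10]))

  # a probe with identical groups is null
  beta2 <- fx$beta
  beta2["cgC1", ] <- rep(c(0.3, 0.4, 0.5, 0.6, 0.7), 2)
  t2 <- test_all_probes(beta2, fx$samples)
  expect_equal(t2$delta_beta[t2$probe_id == "cgC1"], 0)
  expect_equal(t2$p_value[t2$probe_id == "cgC1"], 1)
})

test_that("cascade applies the five filters in order with an audit trail", {
  fx <- make_fixture()
  tests <- test_all_probes(fx$beta, fx$samples)
  cas <- apply_cascade(tests, fx$manifest)
  expect_identical(unname(cas$step_counts),
                   c(6L, 6L, 5L, 4L, 4L, 4L))
  ff <- setNames(cas$records$first_failed_filter, cas$records$probe_id)
  expect_identical(unname(ff["cgB1"]), "delta")
  expect_identical(unname(ff["cgC1"]), "region")
  expect_true(all(ff[paste0("cgA", 1:4)] == "none"))
  expect_identical(cas$candidates$gene, "GENE_A")
  expect_identical(cas$candidates$direction, "hyper_in_NR")
  expect_true(all(diff(cas$step_counts) <= 0))
})

test_that("consecutive-CpG consistency uses same-gene neighbours in a window", {
  manifest <- tiny_manifest(
    probe_id = paste0("cg", 1:5), chrom = "chr2",
    pos = c(100, 300, 500, 700, 5000),
    gene = "G1", gene_group = "TSS200", island_relation = "Island")
  rec <- data.frame(
    probe_id = paste0("cg", 1:5),
    delta_beta = c(0.30, 0.25, 0.18, 0.12, 0.40),
    stringsAsFactors = FALSE)
  cc <- consecutive_consistency("cg1", manifest, rec)
  expect_true(cc$pass)  # neighbours 0.25, 0.18, 0.12 all concordant
  expect_equal(nrow(cc$neighbors), 3)  # cg5 is outside the 1 kb window

  rec$delta_beta <- c(0.30, -0.05, 0.02, -0.2, 0.4)
  expect_false(consecutive_consistency("cg1", manifest, rec)$pass)

  # isolated probe fails by default, passes when configured otherwise
  expect_false(consecutive_consistency("cg5", manifest, rec)$pass)
  relaxed <- cascade_params(fail_if_no_neighbors = FALSE)
  expect_true(consecutive_consistency("cg5", manifest, rec,
                                      relaxed)$pass)
})

test_that("degenerate thresholds pass everything; relaxing never loses probes", {
  fx <- make_fixture()
  tests <- test_all_probes(fx$beta, fx$samples)
  open <- cascade_params(p_alpha = 1, delta_min = 0,
                         island_relations = c("Island", "N_Shore", "S_Shore",
                                              "N_Shelf", "S_Shelf",
                                              "OpenSea"),
                         promoter_groups = c("TSS200", "TSS1500", "5UTR",
                                             "1stExon", "Body", "3UTR"),
                         sd_max = 1, fail_if_no_neighbors = FALSE,
                         min_concordant = 1, concordance_delta = 0)
  cas <- apply_cascade(tests, fx$manifest, open)
  expect_setequal(cas$survivors, tests$probe_id)

  strict <- apply_cascade(tests, fx$manifest)
  no_delta <- apply_cascade(tests, fx$manifest,
                            cascade_params(delta_min = 0))
  expect_true(all(strict$survivors %in% no_delta$survivors))
})

test_that("cascade is invariant to probe and sample order", {
  fx <- make_fixture()
  base <- apply_cascade(test_all_probes(fx$beta, fx$samples), fx$manifest)
  set.seed(1)
  beta_perm <- fx$beta[sample(nrow(fx$beta)), sample(ncol(fx$beta))]
  perm <- apply_cascade(test_all_probes(beta_perm, fx$samples), fx$manifest)
  expect_identical(base$step_counts, perm$step_counts)
  expect_setequal(base$survivors, perm$survivors)
  expect_identical(base$candidates[order(base$candidates$gene), ],
                   perm$candidates[order(perm$candidates$gene), ])
})

test_that("multi-gene probes support every annotated gene", {
  manifest <- tiny_manifest(
    probe_id = c("cg1", "cg2", "cg3"), chrom = "chr3",
    pos = c(100, 200, 300),
    gene = c("LOCX;LEFX", "LOCX;LEFX", "LOCX"),
    gene_group = "TSS200", island_relation = "Island")
  samples <- tiny_samples(sprintf("S%02d", 1:8), rep(c("R", "NR"), each = 4))
  r <- c(0.1, 0.12, 0.11, 0.13)
  nr <- c(0.5, 0.52, 0.51, 0.53)
  beta <- rbind(cg1 = c(r, nr), cg2 = c(r, nr) + 0.01,
                cg3 = c(r, nr) - 0.01)
  colnames(beta) <- samples$sample_id
  cas <- apply_cascade(test_all_probes(beta, samples), manifest)
  expect_setequal(cas$candidates$gene, c("LOCX", "LEFX"))
  expect_equal(cas$candidates$n_probes[cas$candidates$gene == "LOCX"], 3)
  expect_equal(cas$candidates$n_probes[cas$candidates$gene == "LEFX"], 2)
})

test_that("planted synthetic cohorts are recovered end to end", {
  for (s in 1:3) {
    manifest <- generate_manifest(20, 8, islands_fraction = 1, seed = s)
    truth <- planted_truth(sprintf("GENE%03d", 1:3),
                           direction = c("hyper_in_NR", "hyper_in_R",
                                         "hyper_in_NR"),
                           delta = 0.30, n_consecutive_cpgs = 4,
                           sd_within = 0.10)
    coh <- generate_cohort(manifest, 12, 12, truth, seed = 50 + s)
    cas <- apply_cascade(test_all_probes(coh$beta, coh$samples), manifest)
    expect_true(all(truth$gene %in% cas$candidates$gene))
    got <- cas$candidates[match(truth$gene, cas$candidates$gene), ]
    expect_identical(got$direction, truth$direction)
  }
})

test_that("probes exceeding the missingness budget are excluded with a reason", {
  fx <- make_fixture()
  beta <- fx$beta
  beta["cgB1", 1:4] <- NA
  tests <- test_all_probes(beta, fx$samples)
  expect_false("cgB1" %in% tests$probe_id)
  excl <- attr(tests, "excluded")
  expect_identical(excl$probe_id, "cgB1")
  expect_match(excl$reason, "missingness")
})
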