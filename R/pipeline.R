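#' Simulate a full synthetic study
#'
#' Generates, under one seed, everything the pipeline consumes: a probe
#' manifest, discovery and validation cohorts (independent biological draws
#' of the same planted truth), pyrosequencing tables for both cohorts, and a
#' pooled Ct table for the planted genes. The planted genes are the first
#' `n_planted_nr` manifest genes (hypermethylated in non-responders) and the
#' following `n_planted_r` genes (hypermethylated in responders, the
#' FERD3L/TRIP10-like class).
#'
#' @param cfg A [pipeline_config()].
#' @return List with `manifest`, `planted`, `discovery` and `validation`
#'   (each a list `beta` / `samples`), `pyro` (stacked both cohorts),
#'   `samples` (stacked sample sheet), `ct`.
#' @export
simulate_study <- function(cfg = pipeline_config()) {
  s <- cfg$sim
  seed <- cfg$seed
  manifest <- generate_manifest(s$n_genes, s$cpgs_per_gene,
                                s$islands_fraction, seed = seed)
  gene_ids <- unique(manifest$gene)
  planted <- planted_truth(
    gene = gene_ids[seq_len(s$n_planted_nr + s$n_planted_r)],
    direction = rep(c("hyper_in_NR", "hyper_in_R"),
                    c(s$n_planted_nr, s$n_planted_r)),
    delta = s$delta, n_consecutive_cpgs = s$n_consecutive_cpgs,
    sd_within = s$sd_within, expression_coupling = s$expression_coupling)

  discovery <- generate_cohort(manifest, s$n_r_discovery, s$n_nr_discovery,
                               planted, noise_sd = s$noise_sd,
                               seed = seed + 11L, cohort = "discovery")
  validation <- generate_cohort(manifest, s$n_r_validation,
                                s$n_nr_validation, planted,
                                noise_sd = s$noise_sd,
                                seed = seed + 23L, cohort = "validation")
  pyro <- rbind(
    generate_pyro_table(planted, discovery$samples, s$cpgs_per_assay,
                        s$assay_noise_sd, seed = seed + 31L),
    generate_pyro_table(planted, validation$samples, s$cpgs_per_assay,
                        s$assay_noise_sd, seed = seed + 37L))
  samples <- rbind(as.data.frame(discovery$samples),
                   as.data.frame(validation$samples))
  class(samples) <- c("sample_sheet", "data.frame")
  ct <- rbind(
    generate_expression(planted, discovery$samples, seed = seed + 41L),
    generate_expression(planted, validation$samples, seed = seed + 43L))
  list(manifest = manifest, planted = planted, discovery = discovery,
       validation = validation, pyro = pyro, samples = samples, ct = ct)
}

#' Run the full discovery-validation-model pipeline
#'
#' Chains the stages end to end on a simulated study (or on data supplied in
#' `study`): per-probe testing and the five-filter cascade on the discovery
#' cohort, pyrosequencing replication of each candidate gene in both
#' cohorts, AIC signature selection and ROC/Youden cutoff derivation on the
#' pooled cohorts (restricted to genes replicated in the validation cohort,
#' or showing a trend there when `model$allow_trend` is set), and a
#' delta-delta-Ct expression analysis of the first responder-hypermethylated
#' planted gene. All stage outputs and a machine-readable run report are
#' written under `out_dir`; identical config and seed reproduce the report
#' byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output.
#' @param study Optional pre-built study (as from [simulate_study()]); by
#'   default one is simulated from `cfg`.
#' @return List of class `pipeline_run`: `study`, `tests`, `cascade`,
#'   `replication`, `model`, `scored`, `expression`, `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         study = NULL) {
  if (is.null(study)) study <- simulate_study(cfg)
  params <- config_cascade_params(cfg)

  tests <- test_all_probes(study$discovery$beta, study$discovery$samples,
                           cohort = "discovery", params = params)
  cascade <- apply_cascade(tests, study$manifest, params)

  assayable <- intersect(cascade$candidates$gene, unique(study$pyro$gene))
  skipped_candidates <- setdiff(cascade$candidates$gene, assayable)
  replication <- NULL
  for (g in assayable) {
    gm <- aggregate_gene_methylation(study$pyro, g)
    dir <- cascade$candidates$direction[cascade$candidates$gene == g]
    for (coh in c("discovery", "validation")) {
      replication <- rbind(replication,
                           replicate_gene(gm, study$samples, coh, dir,
                                          alpha = cfg$validation$alpha,
                                          trend_max = cfg$validation$trend_max))
    }
  }

  model <- NULL
  scored <- NULL
  sig_candidates <- character(0)
  if (!is.null(replication)) {
    vrep <- replication[replication$cohort == "validation", , drop = FALSE]
    keep <- vrep$replicated | (cfg$model$allow_trend & vrep$trend)
    sig_candidates <- vrep$gene[keep]
  }
  if (length(sig_candidates) >= 1) {
    gm_list <- lapply(sig_candidates, function(g) {
      aggregate_gene_methylation(study$pyro, g)
    })
    wide <- gene_methylation_wide(gm_list)
    model <- select_signature(wide, study$samples, sig_candidates,
                              max_genes = cfg$model$max_genes,
                              aic_margin = cfg$model$aic_margin)
    if (length(model$genes) >= 1) {
      scored <- score_samples(model, wide, study$samples)
      model <- derive_cutoff_and_performance(model, scored,
                                             n_boot = cfg$model$n_boot,
                                             seed = cfg$seed + 53L)
      scored <- score_samples(model, wide, study$samples)
    }
  }

  expression <- NULL
  r_genes <- study$planted$gene[study$planted$direction == "hyper_in_R"]
  if (length(r_genes) >= 1 && !is.null(study$ct)) {
    target <- r_genes[1]
    calibrator <- cfg$expression$calibrator
    if (is.null(calibrator)) calibrator <- study$samples$sample_id[1]
    expr <- delta_delta_ct(study$ct, target, cfg$expression$reference_gene,
                           calibrator)
    grp <- compare_expression_groups(expr, study$samples)
    gm <- aggregate_gene_methylation(study$pyro, target)
    paired <- merge(gm, expr, by = "sample_id")
    cor <- methylation_expression_correlation(paired$pct_methylation,
                                              paired$fold_change)
    expression <- list(target = target, relative_expression = expr,
                       group_comparison = grp, correlation = cor)
  }

  report <- list(
    package = "methresp",
    version = as.character(utils::packageVersion("methresp")),
    seed = cfg$seed,
    step_counts = as.list(cascade$step_counts),
    n_excluded_probes = nrow(attr(tests, "excluded")),
    candidate_genes = cascade$candidates$gene,
    candidates_without_assay = skipped_candidates,
    replication = if (!is.null(replication)) {
      replication[, c("gene", "cohort", "delta_pct", "p_value",
                      "replicated", "trend")]
    },
    signature = if (!is.null(model) && length(model$genes)) {
      list(genes = model$genes,
           coefficients = as.list(round(model$coefficients, 6)),
           cutoff = model$cutoff, auc = model$auc,
           auc_ci = c(model$auc_ci_low, model$auc_ci_high),
           n_boot = cfg$model$n_boot,
           rate_above = if (!is.null(model$rate_above)) model$rate_above$label,
           rate_below = if (!is.null(model$rate_below)) model$rate_below$label)
    },
    expression = if (!is.null(expression)) {
      list(target = expression$target,
           group_p = expression$group_comparison$p_value,
           group_direction = expression$group_comparison$direction,
           methylation_expression_rho = expression$correlation$rho,
           methylation_expression_p = expression$correlation$p_value)
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(study$manifest, file.path(out_dir, "manifest.csv"))
    write_beta_matrix(study$discovery$beta,
                      file.path(out_dir, "beta_discovery.tsv"))
    write_sample_sheet(study$samples, file.path(out_dir, "samples.csv"))
    write_pyro(study$pyro, file.path(out_dir, "pyro.csv"))
    write_ct(study$ct, file.path(out_dir, "ct.csv"))
    utils::write.table(cascade$records,
                       file.path(out_dir, "probe_records.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cascade$candidates,
                       file.path(out_dir, "candidate_genes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(replication)) {
      utils::write.table(replication,
                         file.path(out_dir, "replication.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(scored)) {
      utils::write.table(scored, file.path(out_dir, "scored_samples.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (length(cascade$survivors)) {
      bed <- manifest_to_bed(
        study$manifest[study$manifest$probe_id %in% cascade$survivors, ])
      write_bed(bed, file.path(out_dir, "surviving_cpgs.bed"))
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
  }

  out <- list(study = study, tests = tests, cascade = cascade,
              replication = replication, model = model, scored = scored,
              expression = expression, report = report)
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  print(x$cascade)
  if (!is.null(x$replication)) {
    cat("Replication (validation cohort):\n")
    print(x$replication[x$replication$cohort == "validation",
                        c("gene", "delta_pct", "p_value", "replicated",
                          "trend")])
  }
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
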