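#' Per-sample gene-level methylation from a pyrosequencing table
#'
#' Averages the assay's CpG percentages per sample (unweighted; missing CpGs
#' dropped per sample), giving one percentage methylation value per sample
#' for the gene.
#'
#' @param pyro Data frame with columns `sample_id`, `gene`, `cpg_index`,
#'   `pct_methylation`.
#' @param gene Gene symbol to aggregate.
#' @return Data frame of class `gene_methylation` with `sample_id`, `gene`,
#'   `pct_methylation`.
#' @export
aggregate_gene_methylation <- function(pyro, gene) {
  sub <- pyro[pyro$gene == gene & !is.na(pyro$pct_methylation), ]
  if (nrow(sub) == 0) stop("gene not present in pyro table: ", gene,
                           call. = FALSE)
  if (any(sub$pct_methylation < 0 | sub$pct_methylation > 100)) {
    stop("pct_methylation outside [0, 100] for gene ", gene, call. = FALSE)
  }
  agg <- stats::aggregate(pct_methylation ~ sample_id, data = sub, FUN = mean)
  out <- data.frame(sample_id = agg$sample_id, gene = gene,
                    pct_methylation = agg$pct_methylation,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_methylation", "data.frame")
  out
}

#' Replicate a candidate gene in a cohort
#'
#' Tests whether the candidate's discovery-stage methylation difference
#' reappears in pyrosequencing data: a two-sided rank-sum test of R vs NR
#' percentage methylation, with replication requiring both p < `alpha` and a
#' group difference in the expected direction. A non-significant p below
#' `trend_max` with the expected sign is annotated as a trend (the band in
#' which a p of 0.19 is reported as "a trend towards significance").
#'
#' @param gm A `gene_methylation` from [aggregate_gene_methylation()].
#' @param samples A sample sheet.
#' @param cohort `"discovery"` (technical replication) or `"validation"`
#'   (independent-cohort replication).
#' @param expected_direction `"hyper_in_NR"` or `"hyper_in_R"`, from the
#'   discovery candidate.
#' @param alpha Significance level (default 0.05).
#' @param trend_max Upper p bound of the trend annotation (default 0.20).
#' @return One-row data frame of class `replication_result`: `gene`,
#'   `cohort`, `n_r`, `n_nr`, `mean_r`, `mean_nr`, `delta_pct`
#'   (mean_NR - mean_R), `p_value`, `expected_direction`, `replicated`,
#'   `trend`.
#' @export
replicate_gene <- function(gm, samples, cohort, expected_direction,
                           alpha = 0.05, trend_max = 0.20) {
  stopifnot(cohort %in% c("discovery", "validation"),
            expected_direction %in% c("hyper_in_NR", "hyper_in_R"))
  sel <- samples[samples$cohort == cohort, ]
  d <- merge(gm, sel[, c("sample_id", "response")], by = "sample_id")
  vr <- d$pct_methylation[d$response == "R"]
  vnr <- d$pct_methylation[d$response == "NR"]
  if (length(vr) < 2 || length(vnr) < 2) {
    stop("both response groups need >= 2 samples in the ", cohort,
         " cohort", call. = FALSE)
  }
  ht <- rank_sum_test(vr, vnr)
  delta_pct <- mean(vnr) - mean(vr)
  observed_dir <- if (delta_pct >= 0) "hyper_in_NR" else "hyper_in_R"
  dir_ok <- observed_dir == expected_direction
  out <- data.frame(
    gene = gm$gene[1], cohort = cohort,
    n_r = length(vr), n_nr = length(vnr),
    mean_r = mean(vr), mean_nr = mean(vnr), delta_pct = delta_pct,
    p_value = ht$p_two_sided, expected_direction = expected_direction,
    replicated = ht$p_two_sided < alpha && dir_ok,
    trend = ht$p_two_sided >= alpha && ht$p_two_sided < trend_max && dir_ok,
    stringsAsFactors = FALSE)
  class(out) <- c("replication_result", "data.frame")
  out
}

#' Association of gene methylation with a clinicopathological covariate
#'
#' Checks that a methylation marker is not simply a proxy for a prognostic
#' factor. Dichotomous covariates are compared with the rank-sum test,
#' covariates with three or more levels with the Kruskal-Wallis test.
#' Numeric covariates (age, Ki67) are dichotomized at `cut` (default: their
#' median). Levels with fewer than 2 samples are dropped and reported.
#'
#' @param gm A `gene_methylation`.
#' @param samples A sample sheet containing the covariate column.
#' @param covariate Column name in `samples`.
#' @param cut Dichotomization cut for numeric covariates (default median).
#' @return List with `covariate`, `p_value`, `method` (`"rank_sum"` or
#'   `"kruskal_wallis"`), `levels`, `dropped_levels`.
#' @export
covariate_association <- function(gm, samples, covariate, cut = NULL) {
  if (!covariate %in% names(samples)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  d <- merge(gm, samples[, c("sample_id", covariate)], by = "sample_id")
  v <- d[[covariate]]
  keep <- !is.na(v)
  d <- d[keep, ]
  v <- v[keep]
  if (is.numeric(v)) {
    if (is.null(cut)) cut <- stats::median(v)
    v <- ifelse(v <= cut, paste0("<=", cut), paste0(">", cut))
  }
  tab <- table(v)
  dropped <- names(tab)[tab < 2]
  keep <- !(v %in% dropped)
  d <- d[keep, ]
  v <- factor(v[keep])
  if (nlevels(v) < 2) {
    stop("covariate ", covariate, " has fewer than 2 usable levels",
         call. = FALSE)
  }
  if (nlevels(v) == 2) {
    g <- split(d$pct_methylation, v)
    p <- rank_sum_test(g[[1]], g[[2]])$p_two_sided
    method <- "rank_sum"
  } else {
    p <- stats::kruskal.test(d$pct_methylation, v)$p.value
    method <- "kruskal_wallis"
  }
  list(covariate = covariate, p_value = p, method = method,
       levels = levels(v), dropped_levels = dropped)
}
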