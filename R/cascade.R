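#' Cascade filter parameters
#'
#' Thresholds of the five-filter differential-methylation cascade. Defaults
#' reproduce the published procedure: unadjusted rank-sum p < 0.05, absolute
#' group mean beta difference >= 0.20, promoter island/shore annotation, both
#' intragroup SDs <= 0.20, and a consecutive-CpG consistency rule. The
#' consistency window, neighbour count and concordance effect size are this
#' package's own quantification of "consistent profile in consecutive CpGs".
#'
#' @param p_alpha Step-1 significance level (unadjusted).
#' @param adjust_p Apply Benjamini-Hochberg before step 1 (off by default to
#'   mirror the published unadjusted filter).
#' @param delta_min Step-2 minimum |mean_NR - mean_R| on the beta scale.
#' @param island_relations,promoter_groups Step-3 annotation sets; a probe
#'   passes when its island relation is in `island_relations` and at least
#'   one of its gene-group annotations is in `promoter_groups`.
#' @param sd_max Step-4 maximum intragroup SD, applied to both groups.
#' @param window Step-5 neighbourhood half-width in bp around the probe.
#' @param min_concordant Step-5 concordant-neighbour requirement (all
#'   neighbours when fewer exist).
#' @param concordance_delta Step-5 minimum same-sign |delta beta| for a
#'   neighbour to count as concordant.
#' @param fail_if_no_neighbors Whether an isolated probe (no annotated
#'   neighbour in the window) fails step 5.
#' @param max_missing Maximum fraction of missing beta values tolerated per
#'   probe per group before the probe is excluded from testing.
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A list of class `cascade_params`.
#' @export
cascade_params <- function(p_alpha = 0.05, adjust_p = FALSE, delta_min = 0.20,
                           island_relations = c("Island", "N_Shore", "S_Shore"),
                           promoter_groups = c("TSS1500", "TSS200", "5UTR",
                                               "1stExon"),
                           sd_max = 0.20, window = 1000, min_concordant = 2,
                           concordance_delta = 0.10,
                           fail_if_no_neighbors = TRUE, max_missing = 0.2,
                           exact_limit = 20) {
  stopifnot(p_alpha > 0, p_alpha <= 1, delta_min >= 0, sd_max > 0,
            window > 0, min_concordant >= 1, concordance_delta >= 0,
            max_missing >= 0, max_missing < 1)
  structure(list(p_alpha = p_alpha, adjust_p = adjust_p,
                 delta_min = delta_min, island_relations = island_relations,
                 promoter_groups = promoter_groups, sd_max = sd_max,
                 window = window, min_concordant = min_concordant,
                 concordance_delta = concordance_delta,
                 fail_if_no_neighbors = fail_if_no_neighbors,
                 max_missing = max_missing, exact_limit = exact_limit),
            class = "cascade_params")
}

#' Per-probe group comparison of beta values
#'
#' For every probe, compares responder against non-responder beta values of
#' one cohort with the rank-sum test and records group means, intragroup SDs
#' and the effect size `delta_beta = mean_NR - mean_R` (positive = higher
#' methylation in non-responders).
#'
#' @param beta Numeric probe x sample matrix of beta values in \[0, 1\].
#' @param samples A sample sheet with `sample_id`, `cohort`, `response`.
#' @param cohort Which cohort to test (`"discovery"` or `"validation"`).
#' @param params A [cascade_params()] list (missingness and exact limit).
#' @return Data frame of class `probe_tests` with one row per tested probe:
#'   `probe_id`, `mean_r`, `mean_nr`, `delta_beta`, `sd_r`, `sd_nr`,
#'   `p_value`, `direction`. Probes excluded for missingness are recorded in
#'   `attr(, "excluded")` with a reason.
#' @export
test_all_probes <- function(beta, samples, cohort = "discovery",
                            params = cascade_params()) {
  stopifnot(is.matrix(beta), cohort %in% c("discovery", "validation"))
  sel <- samples[samples$cohort == cohort, ]
  unknown <- setdiff(sel$sample_id, colnames(beta))
  if (length(unknown)) {
    stop("sample(s) missing from beta matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  r_ids <- sel$sample_id[sel$response == "R"]
  nr_ids <- sel$sample_id[sel$response == "NR"]
  if (length(r_ids) < 2 || length(nr_ids) < 2) {
    stop("need at least 2 samples per response group", call. = FALSE)
  }
  br <- beta[, r_ids, drop = FALSE]
  bnr <- beta[, nr_ids, drop = FALSE]
  keep <- rowMeans(is.na(br)) <= params$max_missing &
    rowMeans(is.na(bnr)) <= params$max_missing &
    rowSums(!is.na(br)) >= 2 & rowSums(!is.na(bnr)) >= 2
  excluded <- data.frame(probe_id = rownames(beta)[!keep],
                         reason = rep("missingness above threshold",
                                      sum(!keep)),
                         stringsAsFactors = FALSE)
  br <- br[keep, , drop = FALSE]
  bnr <- bnr[keep, , drop = FALSE]
  n <- nrow(br)
  mean_r <- rowMeans(br, na.rm = TRUE)
  mean_nr <- rowMeans(bnr, na.rm = TRUE)
  sd_r <- apply(br, 1, stats::sd, na.rm = TRUE)
  sd_nr <- apply(bnr, 1, stats::sd, na.rm = TRUE)
  p_value <- vapply(seq_len(n), function(i) {
    rank_sum_test(br[i, ][!is.na(br[i, ])], bnr[i, ][!is.na(bnr[i, ])],
                  exact_limit = params$exact_limit)$p_two_sided
  }, numeric(1))
  out <- data.frame(
    probe_id = rownames(br),
    mean_r = unname(mean_r), mean_nr = unname(mean_nr),
    delta_beta = unname(mean_nr - mean_r),
    sd_r = unname(sd_r), sd_nr = unname(sd_nr),
    p_value = p_value,
    direction = ifelse(mean_nr - mean_r >= 0, "hyper_in_NR", "hyper_in_R"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "n_r") <- length(r_ids)
  attr(out, "n_nr") <- length(nr_ids)
  class(out) <- c("probe_tests", "data.frame")
  out
}

#' Consecutive-CpG consistency check for one probe
#'
#' A differentially methylated CpG is only trusted when neighbouring CpGs of
#' the same gene show the same methylation shift. Neighbours are probes on
#' the same chromosome annotated to (at least one of) the same gene(s) within
#' `params$window` bp; a neighbour is concordant when its `delta_beta` has
#' the same sign as the probe's and `|delta_beta| >= params$concordance_delta`.
#' The probe passes with at least `params$min_concordant` concordant
#' neighbours (all of them when fewer exist); isolated probes fail by default.
#'
#' @param probe_id Probe to check.
#' @param manifest A `probe_manifest`.
#' @param records A `probe_tests` data frame covering the neighbourhood.
#' @param params A [cascade_params()].
#' @return List with `pass` and a `neighbors` data frame
#'   (`probe_id`, `delta_beta`, `concordant`).
#' @export
consecutive_consistency <- function(probe_id, manifest, records,
                                    params = cascade_params()) {
  i <- match(probe_id, manifest$probe_id)
  if (is.na(i)) stop("probe not in manifest: ", probe_id, call. = FALSE)
  rec <- records[match(probe_id, records$probe_id), ]
  if (is.na(rec$probe_id[1])) {
    stop("probe not in test records: ", probe_id, call. = FALSE)
  }
  genes <- strsplit(manifest$gene[i], ";", fixed = TRUE)[[1]]
  cand <- manifest[manifest$chrom == manifest$chrom[i] &
                     abs(manifest$pos - manifest$pos[i]) <= params$window &
                     manifest$probe_id != probe_id, , drop = FALSE]
  if (nrow(cand)) {
    shared <- vapply(strsplit(cand$gene, ";", fixed = TRUE),
                     function(g) any(g %in% genes), logical(1))
    cand <- cand[shared, , drop = FALSE]
  }
  nb <- records[records$probe_id %in% cand$probe_id, , drop = FALSE]
  if (nrow(nb) == 0) {
    return(list(pass = !params$fail_if_no_neighbors,
                neighbors = data.frame(probe_id = character(0),
                                       delta_beta = numeric(0),
                                       concordant = logical(0))))
  }
  concordant <- sign(nb$delta_beta) == sign(rec$delta_beta) &
    abs(nb$delta_beta) >= params$concordance_delta
  needed <- min(params$min_concordant, nrow(nb))
  list(pass = sum(concordant) >= needed,
       neighbors = data.frame(probe_id = nb$probe_id,
                              delta_beta = nb$delta_beta,
                              concordant = concordant,
                              stringsAsFactors = FALSE))
}

#' Apply the five-filter differential-methylation cascade
#'
#' Filters per-probe test records in the published order: (1) p < `p_alpha`;
#' (2) |delta beta| >= `delta_min`; (3) promoter island/shore annotation;
#' (4) intragroup SD <= `sd_max` in both groups; (5) consecutive-CpG
#' consistency. Each probe is tagged with the first filter it failed, and
#' surviving probes are grouped into candidate genes (semicolon-joined
#' annotations contribute to every named gene; a gene's direction is the
#' majority sign of its supporting probes).
#'
#' @param records A `probe_tests` data frame from [test_all_probes()].
#' @param manifest A `probe_manifest` covering all tested probes.
#' @param params A [cascade_params()].
#' @return An object of class `cascade_result`: list with `records` (the
#'   input plus `first_failed_filter`), `step_counts` (named: tested, p,
#'   delta, region, sd, consistency), `survivors` (probe ids), and
#'   `candidates` (data frame gene / direction / n_probes / mean_delta_beta /
#'   supporting_probes).
#' @export
apply_cascade <- function(records, manifest, params = cascade_params()) {
  mi <- match(records$probe_id, manifest$probe_id)
  if (anyNA(mi)) {
    stop("probe(s) missing from manifest: ",
         paste(utils::head(records$probe_id[is.na(mi)], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  fail <- rep(NA_character_, n)

  p <- records$p_value
  if (params$adjust_p) p <- stats::p.adjust(p, method = "BH")
  pass_p <- p < params$p_alpha
  fail[!pass_p] <- "p"

  pass_delta <- abs(records$delta_beta) >= params$delta_min
  fail[is.na(fail) & !pass_delta] <- "delta"

  rel_ok <- manifest$island_relation[mi] %in% params$island_relations
  grp_ok <- vapply(strsplit(manifest$gene_group[mi], ";", fixed = TRUE),
                   function(g) any(g %in% params$promoter_groups), logical(1))
  pass_region <- rel_ok & grp_ok
  fail[is.na(fail) & !pass_region] <- "region"

  pass_sd <- records$sd_r <= params$sd_max & records$sd_nr <= params$sd_max
  fail[is.na(fail) & !pass_sd] <- "sd"

  alive <- is.na(fail)
  for (i in which(alive)) {
    cc <- consecutive_consistency(records$probe_id[i], manifest, records,
                                  params)
    if (!cc$pass) fail[i] <- "consistency"
  }
  records$first_failed_filter <- ifelse(is.na(fail), "none", fail)

  step_counts <- c(
    tested = n,
    p = sum(pass_p),
    delta = sum(pass_p & pass_delta),
    region = sum(pass_p & pass_delta & pass_region),
    sd = sum(pass_p & pass_delta & pass_region & pass_sd),
    consistency = sum(records$first_failed_filter == "none"))

  survivors <- records$probe_id[records$first_failed_filter == "none"]
  candidates <- summarize_candidates(records, manifest, survivors)
  out <- list(records = records, step_counts = step_counts,
              survivors = survivors, candidates = candidates,
              params = params)
  class(out) <- "cascade_result"
  out
}

summarize_candidates <- function(records, manifest, survivors) {
  empty <- data.frame(gene = character(0), direction = character(0),
                      n_probes = integer(0), mean_delta_beta = numeric(0),
                      supporting_probes = character(0),
                      stringsAsFactors = FALSE)
  if (length(survivors) == 0) return(empty)
  sub <- records[records$probe_id %in% survivors, ]
  genes <- manifest$gene[match(sub$probe_id, manifest$probe_id)]
  long <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    data.frame(gene = strsplit(genes[i], ";", fixed = TRUE)[[1]],
               probe_id = sub$probe_id[i], delta_beta = sub$delta_beta[i],
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(long, long$gene), function(d) {
    # direction by majority sign; discordant-minority probes excluded
    maj <- if (sum(d$delta_beta >= 0) >= sum(d$delta_beta < 0)) 1 else -1
    d <- d[sign(d$delta_beta) == maj | d$delta_beta == 0, , drop = FALSE]
    d <- d[order(d$probe_id), , drop = FALSE]  # stable under input order
    data.frame(gene = d$gene[1],
               direction = if (maj > 0) "hyper_in_NR" else "hyper_in_R",
               n_probes = nrow(d),
               mean_delta_beta = mean(d$delta_beta),
               supporting_probes = paste(d$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-abs(out$mean_delta_beta), out$gene), ]
  rownames(out) <- NULL
  out
}

#' @export
print.cascade_result <- function(x, ...) {
  sc <- x$step_counts
  cat("Differential-methylation cascade:\n")
  cat(sprintf("  tested: %d -> p<%.3g: %d -> |db|>=%.2f: %d -> promoter island/shore: %d -> SD<=%.2f: %d -> consistent: %d\n",
              sc["tested"], x$params$p_alpha, sc["p"], x$params$delta_min,
              sc["delta"], sc["region"], x$params$sd_max, sc["sd"],
              sc["consistency"]))
  cat(sprintf("  candidate genes: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("gene", "direction", "n_probes",
                                       "mean_delta_beta")], 10))
  }
  invisible(x)
}
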