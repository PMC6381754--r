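#' Select a gene signature by AIC over candidate subsets
#'
#' Fits a binomial logistic model of response (RCB = 0 vs RCB > 0) on
#' percentage methylation for every candidate-gene subset of size up to
#' `max_genes`, plus the intercept-only null, and keeps the subset with the
#' lowest AIC. To be selected at all, the best subset must undercut the null
#' model's AIC by at least `aic_margin`; otherwise a null-model sentinel
#' (empty gene set) is returned with a warning. The published decision rule
#' has no intercept term, so the returned signature carries only the
#' per-gene slope coefficients; the fitted intercept is retained internally
#' and absorbed into the score cutoff derived later.
#'
#' @param gene_meth Data frame: `sample_id` column plus one numeric column
#'   per candidate gene with percentage methylation (see
#'   [gene_methylation_wide()]).
#' @param samples A sample sheet (all its samples with complete candidate
#'   measurements are used; incomplete samples are dropped and counted).
#' @param candidates Character vector of candidate gene columns.
#' @param max_genes Largest subset size (default 2, a two-gene signature).
#' @param aic_margin How much the best model must beat the null's AIC
#'   (default 4, the conventional "considerably better support" gap; keeps
#'   pure-noise candidate sets from displacing the null by chance).
#' @return An object of class `signature_model`: list with `genes`,
#'   `coefficients`, `intercept`, `aic`, `null_aic`, `fit`, `n_used`,
#'   `n_dropped`, `all_fits` (AIC per evaluated subset); `cutoff`, `auc` and
#'   rates are filled in by [derive_cutoff_and_performance()].
#' @export
select_signature <- function(gene_meth, samples, candidates, max_genes = 2,
                             aic_margin = 4) {
  stopifnot(length(candidates) >= 1, max_genes >= 1)
  missing_cols <- setdiff(candidates, names(gene_meth))
  if (length(missing_cols)) {
    stop("candidate gene(s) missing from gene_meth: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- merge(gene_meth, samples[, c("sample_id", "response")],
             by = "sample_id")
  complete <- stats::complete.cases(d[, candidates, drop = FALSE])
  n_dropped <- sum(!complete)
  d <- d[complete, ]
  y <- as.integer(d$response == "R")
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)

  subsets <- list(character(0))
  for (k in seq_len(min(max_genes, length(candidates)))) {
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  fits <- lapply(subsets, function(gs) {
    logistic_fit(d[, gs, drop = FALSE], y)
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  all_fits <- data.frame(
    genes = vapply(subsets, function(gs) paste(gs, collapse = "+"),
                   character(1)),
    k = lengths(subsets), aic = aics, stringsAsFactors = FALSE)
  null_aic <- aics[1]
  best <- which.min(aics)
  if (best == 1L || aics[best] > null_aic - aic_margin) {
    if (best != 1L) {
      warning("no candidate subset beats the null model by the AIC margin; ",
              "returning the null-model sentinel", call. = FALSE)
    } else {
      warning("intercept-only null model has the lowest AIC; ",
              "returning the null-model sentinel", call. = FALSE)
    }
    best <- 1L
  }
  fit <- fits[[best]]
  out <- list(genes = subsets[[best]],
              coefficients = fit$coefficients,
              intercept = fit$intercept,
              aic = fit$aic, null_aic = null_aic, fit = fit,
              n_used = length(y), n_dropped = n_dropped,
              all_fits = all_fits[order(all_fits$aic), ],
              cutoff = NA_real_, auc = NA_real_,
              auc_ci_low = NA_real_, auc_ci_high = NA_real_,
              rate_above = NULL, rate_below = NULL)
  class(out) <- "signature_model"
  out
}

#' Reshape per-gene methylation into a wide sample-by-gene table
#'
#' Convenience for [select_signature()] and [score_samples()]: stacks a list
#' of `gene_methylation` frames into one data frame with a `sample_id`
#' column and one percentage column per gene.
#'
#' @param gm_list List of `gene_methylation` data frames.
#' @return Wide data frame.
#' @export
gene_methylation_wide <- function(gm_list) {
  stopifnot(length(gm_list) >= 1)
  out <- NULL
  for (gm in gm_list) {
    w <- data.frame(sample_id = gm$sample_id, stringsAsFactors = FALSE)
    w[[gm$gene[1]]] <- gm$pct_methylation
    out <- if (is.null(out)) w else merge(out, w, by = "sample_id",
                                          all = TRUE)
  }
  out
}

#' Score samples with a linear methylation signature
#'
#' Computes the intercept-free linear predictor
#' `score = sum_g coefficient_g * methylation_g(%)` per sample. Samples
#' missing any signature gene are skipped and counted. When the model
#' already carries a cutoff, `predicted_positive = score > cutoff` (strict).
#'
#' @param model A `signature_model`.
#' @param gene_meth Wide data frame (`sample_id` + one column per gene, %).
#' @param samples Optional sample sheet supplying `true_response`.
#' @return Data frame of class `scored_samples`: `sample_id`, one column per
#'   signature gene, `score`, `true_response` (1 = RCB 0, if known),
#'   `predicted_positive` (if the cutoff is set). `attr(, "n_skipped")`
#'   counts samples dropped for missing measurements.
#' @export
score_samples <- function(model, gene_meth, samples = NULL) {
  stopifnot(inherits(model, "signature_model"), length(model$genes) >= 1)
  missing_cols <- setdiff(model$genes, names(gene_meth))
  if (length(missing_cols)) {
    stop("gene(s) missing from input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(gene_meth[, model$genes, drop = FALSE])
  d <- gene_meth[complete, , drop = FALSE]
  m <- as.matrix(d[, model$genes, drop = FALSE])
  out <- data.frame(sample_id = d$sample_id, stringsAsFactors = FALSE)
  for (g in model$genes) out[[g]] <- d[[g]]
  out$score <- as.numeric(m %*% model$coefficients[model$genes])
  if (!is.null(samples)) {
    out$true_response <- as.integer(
      samples$response[match(out$sample_id, samples$sample_id)] == "R")
  }
  if (!is.na(model$cutoff)) out$predicted_positive <- out$score > model$cutoff
  attr(out, "n_skipped") <- sum(!complete)
  class(out) <- c("scored_samples", "data.frame")
  out
}

#' Derive the decision cutoff and report classification performance
#'
#' Completes a signature model: the ROC of score against true response gives
#' the AUC with a bootstrap percentile CI, the Youden-optimal cutoff, and the
#' clinical rates — among score-positive samples (score > cutoff) the
#' fraction with RCB = 0 (`rate_above`), and analogously below
#' (`rate_below`), both reported in the "x out of n (p%)" form with the
#' percentage recomputed from counts.
#'
#' @param model A `signature_model` from [select_signature()].
#' @param scored A `scored_samples` with `true_response`.
#' @param n_boot Bootstrap resamples for the AUC CI (study design: 1000).
#' @param seed Integer seed for the bootstrap.
#' @return The completed `signature_model` (adds `cutoff`, `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `youden_j`, `rate_above`, `rate_below`,
#'   `roc`, `degenerate`).
#' @export
derive_cutoff_and_performance <- function(model, scored, n_boot = 1000,
                                          seed = 1) {
  stopifnot(inherits(model, "signature_model"),
            "true_response" %in% names(scored))
  roc <- roc_with_bootstrap(scored$score, scored$true_response,
                            n_boot = n_boot, seed = seed)
  model$cutoff <- roc$youden_cutoff
  model$auc <- roc$auc
  model$auc_ci_low <- roc$auc_ci_low
  model$auc_ci_high <- roc$auc_ci_high
  model$youden_j <- roc$youden_j
  model$roc <- roc
  pos <- scored$score > model$cutoff
  model$degenerate <- all(pos) || !any(pos)
  model$rate_above <- if (any(pos)) {
    format_rate(sum(scored$true_response[pos] == 1L), sum(pos))
  } else NULL
  model$rate_below <- if (any(!pos)) {
    format_rate(sum(scored$true_response[!pos] == 1L), sum(!pos))
  } else NULL
  model
}

#' @export
print.signature_model <- function(x, ...) {
  if (length(x$genes) == 0) {
    cat("Null-model sentinel (no gene subset beat the intercept-only AIC)\n")
    return(invisible(x))
  }
  cat("Methylation signature:", paste(x$genes, collapse = " + "), "\n")
  cat("  score =",
      paste(sprintf("%.4g x %s(%%)", x$coefficients[x$genes], x$genes),
            collapse = " + "), "\n")
  cat(sprintf("  AIC = %.2f (null %.2f), fitted on n = %d\n",
              x$aic, x$null_aic, x$n_used))
  if (!is.na(x$cutoff)) {
    cat(sprintf("  decision rule: score > %.4g; AUC = %.4f (95%% CI %.3f-%.3f)\n",
                x$cutoff, x$auc, x$auc_ci_low, x$auc_ci_high))
    if (!is.null(x$rate_above)) {
      cat("  RCB = 0 above cutoff:", x$rate_above$label, "\n")
    }
    if (!is.null(x$rate_below)) {
      cat("  RCB = 0 at or below cutoff:", x$rate_below$label, "\n")
    }
  }
  invisible(x)
}
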