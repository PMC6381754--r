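#' Relative expression by the delta-delta-Ct method
#'
#' Classical 2^-ddCt quantification with an endogenous control: triplicate
#' Ct values are averaged on the Ct scale per sample and gene, the target
#' mean is normalized by the reference gene (dCt = Ct_target - Ct_ref), then
#' by the calibrator sample (ddCt = dCt - dCt_calibrator), and the fold
#' change is 2^-ddCt (amplification efficiency fixed at perfect doubling).
#'
#' @param ct Data frame with columns `sample_id`, `gene`, `replicate`, `ct`.
#' @param target Target gene symbol.
#' @param reference Endogenous-control gene symbol (e.g. `"GAPDH"`).
#' @param calibrator Sample id whose fold change defines 1.
#' @return Data frame of class `relative_expression`: `sample_id`,
#'   `mean_ct_target`, `sd_ct_target`, `mean_ct_reference`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`. Samples lacking the reference gene are
#'   skipped and listed in `attr(, "skipped")`.
#' @examples
#' ct <- data.frame(sample_id = rep(c("a", "b"), each = 2),
#'                  gene = rep(c("T", "REF"), 2), replicate = 1L,
#'                  ct = c(25, 20, 27, 20))
#' delta_delta_ct(ct, "T", "REF", calibrator = "a")
#' @export
delta_delta_ct <- function(ct, target, reference, calibrator) {
  stopifnot(all(c("sample_id", "gene", "replicate", "ct") %in% names(ct)))
  tgt <- ct[ct$gene == target & !is.na(ct$ct), ]
  ref <- ct[ct$gene == reference & !is.na(ct$ct), ]
  if (nrow(tgt) == 0) stop("target gene absent from Ct table: ", target,
                           call. = FALSE)
  if (nrow(ref) == 0) stop("reference gene absent from Ct table: ",
                           reference, call. = FALSE)
  mt <- stats::aggregate(ct ~ sample_id, data = tgt, FUN = mean)
  st <- stats::aggregate(ct ~ sample_id, data = tgt, FUN = stats::sd)
  mr <- stats::aggregate(ct ~ sample_id, data = ref, FUN = mean)
  d <- merge(merge(mt, st, by = "sample_id",
                   suffixes = c("_target", "_sd")),
             mr, by = "sample_id", all.x = TRUE)
  names(d) <- c("sample_id", "mean_ct_target", "sd_ct_target",
                "mean_ct_reference")
  skipped <- d$sample_id[is.na(d$mean_ct_reference)]
  if (length(skipped)) d <- d[!is.na(d$mean_ct_reference), ]
  if (!calibrator %in% d$sample_id) {
    stop("calibrator sample not present with both genes: ", calibrator,
         call. = FALSE)
  }
  d$delta_ct <- d$mean_ct_target - d$mean_ct_reference
  cal_dct <- d$delta_ct[d$sample_id == calibrator]
  d$delta_delta_ct <- d$delta_ct - cal_dct
  d$fold_change <- 2^(-d$delta_delta_ct)
  attr(d, "skipped") <- skipped
  attr(d, "target") <- target
  attr(d, "reference") <- reference
  attr(d, "calibrator") <- calibrator
  class(d) <- c("relative_expression", "data.frame")
  d
}

#' Compare relative expression between response groups
#'
#' Two-sided rank-sum test of fold changes in responders versus
#' non-responders, with the direction of the difference (sign of the median
#' NR - median R difference).
#'
#' @param expr A `relative_expression`.
#' @param samples A sample sheet.
#' @return List with `p_value`, `direction` (`"higher_in_NR"`,
#'   `"higher_in_R"` or `"none"`), `median_r`, `median_nr`, `n_r`, `n_nr`.
#' @export
compare_expression_groups <- function(expr, samples) {
  d <- merge(expr, samples[, c("sample_id", "response")], by = "sample_id")
  fr <- d$fold_change[d$response == "R"]
  fnr <- d$fold_change[d$response == "NR"]
  if (length(fr) < 2 || length(fnr) < 2) {
    stop("both response groups need >= 2 samples", call. = FALSE)
  }
  ht <- rank_sum_test(fr, fnr)
  md <- stats::median(fnr) - stats::median(fr)
  list(p_value = ht$p_two_sided,
       direction = if (md > 0) "higher_in_NR"
                   else if (md < 0) "higher_in_R" else "none",
       median_r = stats::median(fr), median_nr = stats::median(fnr),
       n_r = length(fr), n_nr = length(fnr))
}

#' Correlate methylation with expression
#'
#' Spearman rank correlation between per-sample percentage methylation and
#' relative expression (fold change or any monotone transform of it).
#'
#' @param meth Numeric per-sample methylation values.
#' @param expr Paired per-sample expression values.
#' @return List with `rho` and `p_value` (see [spearman_correlation()]).
#' @export
methylation_expression_correlation <- function(meth, expr) {
  spearman_correlation(meth, expr)
}

#' Demethylating-treatment contrast
#'
#' Compares a demethylating-agent-treated arm against control on both
#' endpoints of the silencing hypothesis: percentage methylation (expected
#' to fall under treatment) and expression fold change (expected to rise),
#' each with an independent two-sided rank-sum test. At least 3 replicates
#' per arm per endpoint are required (the triplicate design).
#'
#' @param treated_methylation,control_methylation Replicate methylation
#'   percentages per arm.
#' @param treated_expression,control_expression Replicate fold changes per
#'   arm.
#' @return An object of class `treatment_contrast`: list with
#'   `p_methylation`, `p_expression`, `delta_methylation`
#'   (treated - control mean), `delta_expression`, and the replicate values.
#' @export
treatment_contrast <- function(treated_methylation, control_methylation,
                               treated_expression, control_expression) {
  for (v in list(treated_methylation, control_methylation,
                 treated_expression, control_expression)) {
    if (length(v) < 3) {
      stop("treatment_contrast() requires >= 3 replicates per arm per ",
           "endpoint", call. = FALSE)
    }
  }
  pm <- rank_sum_test(treated_methylation, control_methylation)
  pe <- rank_sum_test(treated_expression, control_expression)
  out <- list(
    p_methylation = pm$p_two_sided,
    p_expression = pe$p_two_sided,
    delta_methylation = mean(treated_methylation) - mean(control_methylation),
    delta_expression = mean(treated_expression) - mean(control_expression),
    treated_methylation = treated_methylation,
    control_methylation = control_methylation,
    treated_expression = treated_expression,
    control_expression = control_expression)
  class(out) <- "treatment_contrast"
  out
}

#' @export
print.treatment_contrast <- function(x, ...) {
  cat(sprintf(
    "Treatment contrast: methylation %+.1f points (p = %.4g); expression fold %+.2f (p = %.4g)\n",
    x$delta_methylation, x$p_methylation,
    x$delta_expression, x$p_expression))
  invisible(x)
}
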