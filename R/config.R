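#' Pipeline configuration
#'
#' Central configuration of every stage. The defaults reproduce the study's
#' stated thresholds: rank-sum p < 0.05 (unadjusted), |delta beta| >= 0.20,
#' promoter island/shore annotation, intragroup SD <= 0.20, 1000 bootstrap
#' iterations, a two-gene signature, and a validation trend band up to
#' p = 0.20 whose members may still enter the signature (`allow_trend`).
#' The `sim` block defines the synthetic study: discovery 10 R vs 14 NR,
#' validation 9 R vs 21 NR, with planted promoter runs of 4 CpGs at
#' delta beta 0.30 and within-group SD 0.10.
#'
#' @param ... Named overrides of the defaults. Unknown keys (at top level or
#'   inside `cascade`, `validation`, `model`, `sim`) are rejected.
#' @return Nested list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, model = list(n_boot = 200))
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    cascade = list(p_alpha = 0.05, adjust_p = FALSE, delta_min = 0.20,
                   sd_max = 0.20, window = 1000, min_concordant = 2,
                   concordance_delta = 0.10, fail_if_no_neighbors = TRUE,
                   max_missing = 0.2, exact_limit = 20),
    validation = list(alpha = 0.05, trend_max = 0.20),
    model = list(max_genes = 2, aic_margin = 4, n_boot = 1000,
                 allow_trend = TRUE),
    expression = list(reference_gene = "GAPDH", calibrator = NULL),
    sim = list(n_genes = 40, cpgs_per_gene = 8, islands_fraction = 1.0,
               n_r_discovery = 10, n_nr_discovery = 14,
               n_r_validation = 9, n_nr_validation = 21,
               n_planted_nr = 4, n_planted_r = 2,
               delta = 0.30, sd_within = 0.10, n_consecutive_cpgs = 4,
               noise_sd = 0.10, cpgs_per_assay = 4, assay_noise_sd = 3,
               expression_coupling = -4)
  )
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides))) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  for (key in names(overrides)) {
    if (is.list(defaults[[key]])) {
      sub <- overrides[[key]]
      bad <- setdiff(names(sub), names(defaults[[key]]))
      if (length(bad)) {
        stop("unknown configuration key(s) in '", key, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      cfg[[key]][names(sub)] <- sub
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_config <- function(cfg) {
  with(cfg$cascade, {
    stopifnot(p_alpha > 0, p_alpha <= 1, delta_min >= 0, delta_min <= 1,
              sd_max > 0, window > 0, min_concordant >= 1,
              concordance_delta >= 0)
  })
  with(cfg$validation, stopifnot(alpha > 0, alpha < 1, trend_max >= alpha,
                                 trend_max <= 1))
  with(cfg$model, stopifnot(max_genes >= 1, n_boot >= 1, aic_margin >= 0))
  with(cfg$sim, {
    stopifnot(n_genes >= 1, cpgs_per_gene >= 1, delta > 0, delta < 1,
              sd_within > 0, noise_sd > 0, expression_coupling < 0,
              n_planted_nr + n_planted_r <= n_genes)
  })
  invisible(cfg)
}

config_cascade_params <- function(cfg) {
  do.call(cascade_params, cfg$cascade)
}
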