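#' Binomial logistic regression fit with AIC
#'
#' Maximum-likelihood logistic fit used by the signature-selection stage.
#' Always includes an intercept; an empty feature set yields the
#' intercept-only null model. Constant features carry no information and are
#' dropped with a warning. Quasi-complete separation (fitted probabilities
#' numerically 0 or 1) leaves the likelihood monotonically increasing, so the
#' fit is flagged `converged = FALSE` and the coefficients are those reached
#' at the iteration cap; the AIC is still reported.
#'
#' @param features Numeric matrix or data frame, samples in rows, features in
#'   columns. May have zero columns.
#' @param labels Binary outcome per sample (1 = responder / RCB = 0).
#' @param max_iter Iteration cap of the IRLS fit.
#' @return An object of class `logistic_fit`: list with `coefficients`
#'   (named, per feature), `intercept`, `log_likelihood`, `aic`, `converged`,
#'   `n`, `dropped` (names of constant features removed).
#' @examples
#' logistic_fit(matrix(numeric(0), nrow = 4, ncol = 0), c(0, 0, 1, 1))
#' @export
logistic_fit <- function(features, labels, max_iter = 25) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  features <- as.data.frame(features)
  if (nrow(features) == 0) features <- data.frame(row.names = seq_along(labels))
  if (nrow(features) != length(labels)) {
    stop("features and labels must have the same number of samples",
         call. = FALSE)
  }
  dropped <- character(0)
  if (ncol(features) > 0) {
    constant <- vapply(features, function(v) length(unique(v)) == 1L,
                       logical(1))
    if (any(constant)) {
      dropped <- names(features)[constant]
      warning("dropping constant feature(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
      features <- features[, !constant, drop = FALSE]
    }
  }
  dat <- cbind(.y = labels, features)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  degenerate_outcome <- length(unique(labels)) == 1L
  out <- list(
    coefficients = co[setdiff(names(co), "(Intercept)")],
    intercept = unname(co["(Intercept)"]),
    log_likelihood = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    converged = fit$converged && !separated && !degenerate_outcome,
    n = length(labels),
    dropped = dropped
  )
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d): logLik = %.4f, AIC = %.3f%s\n",
              x$n, x$log_likelihood, x$aic,
              if (!x$converged) " [not converged / separated]" else ""))
  if (length(x$coefficients)) {
    cat("  intercept:", format(x$intercept, digits = 4), "\n")
    for (nm in names(x$coefficients)) {
      cat(sprintf("  %s: %.4g\n", nm, x$coefficients[[nm]]))
    }
  } else {
    cat("  intercept-only null model\n")
  }
  invisible(x)
}
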