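# broom-style tidiers for fitted objects.

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param conf.int Add confidence interval columns.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (and `conf.low`/`conf.high` if requested).
#' @export
tidy.pgls_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$t_values),
    p.value = unname(x$coef_p_values)
  )
  if (conf.int) {
    ci <- confint(x, level = conf.level)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  }
  out
}

#' One-row summary of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `lambda`, `lambda_boundary`,
#'   `sigma2`, `statistic` (model F), `p.value` (model p), `logLik`, `AICc`,
#'   `df` (parameter count used by the AICc) and `nobs`.
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    lambda = x$lambda,
    lambda_boundary = x$lambda_boundary,
    sigma2 = x$sigma2,
    statistic = x$f_statistic,
    p.value = x$model_p,
    logLik = x$log_likelihood,
    AICc = x$aicc,
    df = x$k,
    nobs = x$n
  )
}

#' Per-taxon fitted values and residuals of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return The model frame with `.fitted`, `.resid` (response scale) and
#'   `.resid_whitened` (decorrelated scale) appended.
#' @export
augment.pgls_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = x$fitted,
    .resid = x$residuals,
    .resid_whitened = x$whitened_residuals
  )
}

#' Per-tree coefficient table of an ensemble of PGLS fits
#'
#' @param x A `pgls_ensemble`.
#' @param ... Unused.
#' @return One row per tree: `tree`, `intercept`, `slope`, `lambda`,
#'   `r.squared`, `p.value`, `logLik`, `AICc`, `nobs`, `converged`.
#' @export
tidy.pgls_ensemble <- function(x, ...) {
  x$regression_band
}

#' One-row summary of an ensemble of PGLS fits
#'
#' @param x A `pgls_ensemble`.
#' @param ... Unused.
#' @return A tibble with the number of trees, fitted trees, best iteration
#'   index and its statistics, and the median model p and R^2 across trees.
#' @export
glance.pgls_ensemble <- function(x, ...) {
  bg <- glance(x$best_fit)
  tibble::tibble(
    n_trees = length(x$fits),
    n_fitted = sum(!is.na(x$regression_band$logLik)),
    best_index = x$best_index,
    best_r.squared = bg$r.squared,
    best_p.value = bg$p.value,
    best_lambda = bg$lambda,
    best_logLik = bg$logLik,
    median_p.value = x$median_model_p,
    median_r.squared = x$median_r_squared
  )
}
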