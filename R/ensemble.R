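# Ensemble regressions: one ML-lambda PGLS per tree, best-iteration
# selection, median summaries and residual distributions across trees.

#' Run a PGLS regression across an ensemble of trees
#'
#' Fits [pgls_ml()] once per tree, in ensemble order. Each tree is pruned to
#' the sampled taxa first, so full supertrees can be passed directly. The
#' best-performing iteration is the fit with maximum log-likelihood (ties
#' broken by lowest tree index; with equal parameter counts across trees the
#' log-likelihood and AICc orders coincide). Per-tree failures are recorded,
#' excluded from the summaries, and reported with a warning; only if every
#' tree fails is an error raised. The computation is deterministic: repeated
#' calls on identical inputs give identical results.
#'
#' @param ensemble A `tree_ensemble` (from [read_newick_ensemble()]), a
#'   `multiPhylo`, a list of trees, or a single `phylo`.
#' @param data Data frame with `taxon`, response and predictor columns.
#' @param response,predictor Bare column names (tidy evaluation).
#' @param method Likelihood flavour passed to [pgls_ml()].
#' @return A `pgls_ensemble` object with elements `fits` (one `pgls_fit` or
#'   `NULL` per tree), `best_index`, `best_fit`, `median_model_p`,
#'   `median_r_squared`, `regression_band` (per-tree coefficient tibble) and
#'   `residual_table` (long tibble: `taxon`, `tree`, `residual`).
#' @export
#' @examples
#' trees <- replicate(3, simulate_tree(15, seed = 7), simplify = FALSE)
#' d <- simulate_traits(trees[[1]], slope = 0.3, seed = 1)
#' res <- run_ensemble(trees, d, response = response, predictor = predictor)
#' glance(res)
run_ensemble <- function(ensemble, data, response, predictor,
                         method = c("ML", "REML")) {
  method <- match.arg(method)
  if (inherits(ensemble, "phylo")) ensemble <- list(ensemble)
  if (length(ensemble) < 1) abort("The tree ensemble is empty.")
  resp <- rlang::enquo(response)
  pred <- rlang::enquo(predictor)

  fits <- vector("list", length(ensemble))
  failures <- character(0)
  for (i in seq_along(ensemble)) {
    fits[[i]] <- tryCatch(
      pgls_ml(data, ensemble[[i]], response = !!resp, predictor = !!pred,
              method = method),
      error = function(e) {
        failures <<- c(failures, sprintf("tree %d: %s", i,
                                         conditionMessage(e)))
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("Every tree in the ensemble failed to fit:\n",
                 paste(utils::head(failures, 5), collapse = "\n")))
  }
  if (length(failures) > 0) {
    warn(sprintf("%d of %d trees failed to fit and were excluded from summaries.",
                 length(failures), length(ensemble)))
  }

  band <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (is.null(f)) {
      return(tibble::tibble(tree = i, intercept = NA_real_, slope = NA_real_,
                            lambda = NA_real_, r.squared = NA_real_,
                            p.value = NA_real_, logLik = NA_real_,
                            AICc = NA_real_, nobs = NA_integer_,
                            converged = FALSE))
    }
    tibble::tibble(tree = i, intercept = unname(f$coefficients[1]),
                   slope = unname(f$coefficients[2]), lambda = f$lambda,
                   r.squared = f$r_squared, p.value = f$model_p,
                   logLik = f$log_likelihood, AICc = f$aicc,
                   nobs = as.integer(f$n), converged = TRUE)
  })

  lls <- band$logLik
  lls[!ok] <- -Inf
  best_index <- which.max(lls)  # ties -> lowest index

  residual_table <- purrr::map_dfr(which(ok), function(i) {
    f <- fits[[i]]
    tibble::tibble(taxon = f$taxa, tree = i, residual = f$residuals)
  })

  structure(
    list(fits = fits,
         best_index = best_index,
         best_fit = fits[[best_index]],
         median_model_p = median(band$p.value, na.rm = TRUE),
         median_r_squared = median(band$r.squared, na.rm = TRUE),
         regression_band = band,
         residual_table = residual_table,
         failures = failures),
    class = "pgls_ensemble"
  )
}

#' @export
print.pgls_ensemble <- function(x, ...) {
  cat(sprintf("PGLS ensemble: %d tree(s), %d fitted\n",
              length(x$fits), sum(x$regression_band$converged)))
  cat(sprintf("  best iteration: tree %d (logLik = %.3f, R^2 = %.3f, p = %.3g)\n",
              x$best_index, x$best_fit$log_likelihood,
              x$best_fit$r_squared, x$best_fit$model_p))
  cat(sprintf("  median across trees: R^2 = %.3f, p = %.3g\n",
              x$median_r_squared, x$median_model_p))
  invisible(x)
}

#' Per-taxon boxplot summaries of ensemble residuals
#'
#' Summarizes each taxon's residuals across trees using the standard
#' statistical-graphics convention: quartiles by linear interpolation
#' between order statistics ([stats::quantile()] type 7), whiskers at the
#' most extreme data points within 1.5 x IQR of the quartiles, and all
#' points beyond the whiskers listed as outliers.
#'
#' @param result A `pgls_ensemble` from [run_ensemble()].
#' @return A tibble with one row per taxon: `taxon`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high` and an `outliers` list-column.
#' @export
residual_boxplots <- function(result) {
  tab <- result$residual_table
  if (nrow(tab) == 0) abort("The residual table is empty.")
  tab %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(boxplot_summary_one(.data$residual), .groups = "drop") %>%
    dplyr::arrange(match(.data$taxon, unique(tab$taxon)))
}

boxplot_summary_one <- function(r) {
  r <- r[is.finite(r)]
  q <- unname(quantile(r, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  in_lo <- r[r >= q[1] - 1.5 * iqr]
  in_hi <- r[r <= q[3] + 1.5 * iqr]
  inside <- r >= q[1] - 1.5 * iqr & r <= q[3] + 1.5 * iqr
  tibble::tibble(
    n = length(r),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(in_lo), whisker_high = max(in_hi),
    outliers = list(r[!inside])
  )
}

#' Rank taxa by median ensemble residual
#'
#' Orders taxa by descending median residual across trees (a taxon whose
#' response exceeds the allometric expectation ranks first). Ties preserve
#' the input taxon order (stable sort).
#'
#' @param result A `pgls_ensemble` from [run_ensemble()].
#' @return A tibble with `taxon`, `median_residual` and `rank`, sorted by
#'   descending median residual.
#' @export
rank_residuals <- function(result) {
  tab <- result$residual_table
  if (nrow(tab) == 0) abort("The residual table is empty.")
  med <- tab %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(median_residual = median(.data$residual), .groups = "drop") %>%
    dplyr::arrange(match(.data$taxon, unique(tab$taxon)))
  ord <- order(-med$median_residual)  # stable radix/shell order for ties
  out <- med[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Write ensemble reports to CSV
#'
#' Writes the per-tree fit table, the long residual table and the boxplot
#' summaries (outliers serialized as semicolon-separated values) to
#' `<prefix>_fits.csv`, `<prefix>_residuals.csv` and `<prefix>_boxplots.csv`.
#'
#' @param result A `pgls_ensemble`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_ensemble_reports <- function(result, dir, prefix = "ensemble") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_fits.csv", "_residuals.csv",
                                           "_boxplots.csv")))
  readr::write_csv(result$regression_band, paths[1])
  readr::write_csv(result$residual_table, paths[2])
  box <- residual_boxplots(result)
  box$outliers <- vapply(box$outliers, function(v) {
    paste(format(v, digits = 15, trim = TRUE), collapse = ";")
  }, character(1))
  readr::write_csv(box, paths[3])
  invisible(paths)
}
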