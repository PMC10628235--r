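# ggplot2 visualisations for fitted objects.

#' Plot a PGLS fit
#'
#' Scatter of the (typically log10-transformed) trait pair with the fitted
#' regression line.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predictor, y = .data$response)) +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2], colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = object$predictor_name, y = object$response_name,
      subtitle = sprintf("lambda = %.3f, R² = %.3f, model p = %.3g",
                         object$lambda, object$r_squared, object$model_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble of PGLS fits
#'
#' Scatter of the trait pair with the full band of per-tree regression lines
#' in grey and the best-performing iteration's line in red.
#'
#' @param object A `pgls_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgls_ensemble <- function(object, ...) {
  band <- dplyr::filter(object$regression_band, .data$converged)
  ggplot2::ggplot(object$best_fit$data,
                  ggplot2::aes(x = .data$predictor, y = .data$response)) +
    ggplot2::geom_abline(data = band,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         colour = "grey70", alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$best_fit$coefficients[1],
                         slope = object$best_fit$coefficients[2],
                         colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = object$best_fit$predictor_name,
      y = object$best_fit$response_name,
      subtitle = sprintf(
        "best iteration: tree %d (R² = %.3f, p = %.3g); median R² = %.3f",
        object$best_index, object$best_fit$r_squared,
        object$best_fit$model_p, object$median_r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of ensemble residuals by taxon
#'
#' One box per taxon summarising its residuals across all trees, with
#' whiskers at 1.5 x IQR and points beyond them drawn as outliers; the zero
#' line (the allometric expectation) is marked in red.
#'
#' @param result A `pgls_ensemble`.
#' @return A ggplot object.
#' @export
plot_residual_boxplots <- function(result) {
  tab <- result$residual_table
  ord <- rank_residuals(result)$taxon
  tab$taxon <- factor(tab$taxon, levels = ord)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$taxon, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "residual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
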