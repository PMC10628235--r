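# Phylogenetic generalized least squares with maximum-likelihood estimation
# of Pagel's lambda. The fit is computed by whitening both sides of the
# regression with the inverse Cholesky factor of the phylogenetic covariance;
# lambda is profiled (coefficients and sigma^2 solved analytically at each
# candidate) and maximized by bounded scalar search on [0, 1].

#' Generalized least squares under an explicit phylogenetic covariance
#'
#' Fits `response ~ predictor` with error covariance proportional to `vcv`
#' (usually from [phylo_vcv()]; lambda is taken from the matrix's `"lambda"`
#' attribute and is *not* re-estimated). Coefficients solve the generalized
#' normal equations, computed as ordinary least squares after whitening both
#' sides by the inverse Cholesky factor of `vcv`. sigma^2 is the ML estimate
#' (whitened residual sum of squares / n); R^2, t-, F- and p-statistics are
#' computed in the whitened space against the whitened intercept-only
#' baseline, so R^2 lies in \[0, 1\] and reduces to the OLS value on a star
#' phylogeny.
#'
#' @param data Data frame with a `taxon` column plus the response and
#'   predictor columns (already log10-transformed where the analysis calls
#'   for it).
#' @param vcv Covariance matrix with taxon dimnames, e.g. from
#'   [phylo_vcv()]. Row order need not match `data`; taxa are aligned by
#'   normalized label.
#' @param response,predictor Bare column names (tidy evaluation).
#' @param method `"ML"` (default) or `"REML"` for the likelihood reported.
#' @param lambda_estimated Internal: whether lambda was estimated upstream
#'   (affects the AICc parameter count).
#' @return A `pgls_fit` object; see [tidy.pgls_fit()], [glance.pgls_fit()],
#'   [augment.pgls_fit()].
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' d <- tibble::tibble(taxon = c("A", "B", "C"), x = 0:2, y = c(1, 0, 2))
#' gls_fit(d, phylo_vcv(tr, 1), response = y, predictor = x)
gls_fit <- function(data, vcv, response, predictor, method = c("ML", "REML"),
                    lambda_estimated = FALSE) {
  method <- match.arg(method)
  sample <- assemble_sample(data, {{ response }}, {{ predictor }})
  V <- align_vcv(vcv, sample$taxon)
  core <- gls_core(sample$x, sample$y, V, method = method)
  make_pgls_fit(core, sample,
                lambda = attr(vcv, "lambda") %||% NA_real_,
                lambda_estimated = lambda_estimated, method = method,
                response_name = sample_names(sample)["response"],
                predictor_name = sample_names(sample)["predictor"])
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Fits `response ~ predictor` on a time-calibrated tree, estimating Pagel's
#' lambda by maximizing the profile log-likelihood over \[0, 1\]
#' (coefficients and sigma^2 are solved analytically at each candidate
#' lambda). The search is deterministic: the best of a coarse 11-point grid
#' seeds a bounded scalar optimization with absolute tolerance 1e-6, and the
#' boundary values 0 and 1 are always evaluated exactly. Boundary optima are
#' returned as-is and flagged (`lambda_boundary`), never perturbed. The tree
#' is pruned to the sampled taxa before fitting, so tip depths (and hence the
#' covariance) match the pruned-tree convention.
#'
#' @inheritParams gls_fit
#' @param tree An [ape::phylo] tree containing all sampled taxa.
#' @return A `pgls_fit` object with `lambda` set to the ML estimate and
#'   lambda counted as an estimated parameter in the AICc.
#' @export
#' @examples
#' tr <- simulate_tree(n_tips = 20, seed = 1)
#' d <- simulate_traits(tr, slope = 0.3, seed = 2)
#' fit <- pgls_ml(d, tr, response = response, predictor = predictor)
#' glance(fit)
pgls_ml <- function(data, tree, response, predictor, method = c("ML", "REML")) {
  method <- match.arg(method)
  sample <- assemble_sample(data, {{ response }}, {{ predictor }})
  tree <- prune_to_taxa(tree, sample$taxon)
  V1 <- phylo_vcv(tree, lambda = 1)
  V1 <- align_vcv(V1, sample$taxon)
  d <- diag(V1)

  profile_ll <- function(lam) {
    V <- V1
    off <- row(V) != col(V)
    V[off] <- lam * V[off]
    out <- tryCatch(gls_core(sample$x, sample$y, V, method = method),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$log_likelihood)) -Inf else
      out$log_likelihood
  }

  grid <- seq(0, 1, by = 0.1)
  grid_ll <- vapply(grid, profile_ll, numeric(1))
  if (all(!is.finite(grid_ll))) {
    abort("Profile likelihood is non-finite at every candidate lambda; the phylogenetic covariance may be singular (zero-length terminal branches?).")
  }
  i <- which.max(grid_ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(profile_ll, lower = lo, upper = hi, maximum = TRUE,
                  tol = 1e-6)
  # Bounded search cannot land exactly on the boundary; compare explicitly.
  cand <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, profile_ll(0), profile_ll(1))
  lambda_hat <- cand[which.max(cand_ll)]

  V <- V1
  off <- row(V) != col(V)
  V[off] <- lambda_hat * V[off]
  core <- gls_core(sample$x, sample$y, V, method = method)
  fit <- make_pgls_fit(core, sample, lambda = lambda_hat,
                       lambda_estimated = TRUE, method = method,
                       response_name = sample_names(sample)["response"],
                       predictor_name = sample_names(sample)["predictor"])
  fit$lambda_boundary <- lambda_hat %in% c(0, 1)
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2 \log L + 2k + 2k(k+1)/(n-k-1)}. Undefined for
#' `n <= k + 1`.
#'
#' @param log_likelihood Model log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-10, 3, 10)
aicc <- function(log_likelihood, k, n) {
  if (any(n <= k + 1)) {
    abort("AICc requires n > k + 1; the small-sample correction is undefined.")
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# ---- internals --------------------------------------------------------------

assemble_sample <- function(data, response, predictor) {
  data <- tibble::as_tibble(data)
  check_columns(data, "taxon")
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ predictor }})
  rname <- rlang::as_name(rlang::enquo(response))
  pname <- rlang::as_name(rlang::enquo(predictor))
  if (anyNA(x) || anyNA(y)) {
    abort("Regression sample contains missing values after assembly.")
  }
  if (length(y) < 3) {
    abort("At least 3 taxa are required for a PGLS fit.")
  }
  if (anyDuplicated(normalize_taxon(data$taxon))) {
    abort("Duplicate taxa in the regression sample.")
  }
  if (stats::var(x) == 0) {
    abort("Predictor is constant; the regression is degenerate.")
  }
  structure(list(taxon = as.character(data$taxon), x = as.numeric(x),
                 y = as.numeric(y)),
            names_map = c(response = rname, predictor = pname))
}

sample_names <- function(sample) attr(sample, "names_map")

align_vcv <- function(vcv, taxa) {
  if (is.null(dimnames(vcv))) {
    if (nrow(vcv) != length(taxa)) {
      abort("Covariance dimension does not match the sample size.")
    }
    return(vcv)
  }
  idx <- match(normalize_taxon(taxa), normalize_taxon(rownames(vcv)))
  if (anyNA(idx)) {
    abort(sprintf("Taxa missing from the covariance matrix: %s.",
                  paste(taxa[is.na(idx)], collapse = ", ")))
  }
  lam <- attr(vcv, "lambda")
  out <- vcv[idx, idx, drop = FALSE]
  attr(out, "lambda") <- lam
  out
}

# Whitened GLS at a fixed covariance. Errors (rather than jittering) when V
# is not positive definite.
gls_core <- function(x, y, V, method = "ML") {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x)
  U <- tryCatch(chol(V), error = function(e) NULL)
  # chol() can return a factor with a near-zero pivot on exactly singular
  # input rather than failing; reject those explicitly.
  if (!is.null(U) && min(diag(U))^2 <= 1e-10 * max(diag(V))) U <- NULL
  if (is.null(U)) {
    lam <- attr(V, "lambda")
    abort(sprintf("Phylogenetic covariance is singular or not positive definite%s; check for zero-length terminal branches or duplicated tip depths.",
                  if (!is.null(lam)) sprintf(" at lambda = %g", lam) else ""))
  }
  whiten <- function(m) backsolve(U, m, transpose = TRUE)
  Xw <- whiten(X)
  yw <- whiten(y)
  qrX <- qr(Xw)
  beta <- qr.coef(qrX, yw)
  fitted_w <- Xw %*% beta
  rw <- as.numeric(yw - fitted_w)
  rss <- sum(rw^2)
  p <- ncol(X)
  logdetV <- 2 * sum(log(diag(U)))

  if (method == "REML") {
    sigma2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) + logdetV +
                    determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  }

  # Conventional (unbiased-sigma2) standard errors for the t table.
  s2_resid <- rss / (n - p)
  covb <- s2_resid * chol2inv(qr.R(qrX))
  se <- sqrt(diag(covb))
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)

  # Intercept-only baseline, also whitened, for R^2 and the model F-test.
  X0w <- whiten(matrix(1, n, 1))
  b0 <- qr.coef(qr(X0w), yw)
  tss <- sum((yw - X0w %*% b0)^2)
  r2 <- 1 - rss / tss
  fstat <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  model_p <- pf(fstat, p - 1, n - p, lower.tail = FALSE)

  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       std_errors = setNames(se, colnames(X)),
       t_values = setNames(tval, colnames(X)),
       coef_p_values = setNames(pval, colnames(X)),
       model_p = model_p, f_statistic = fstat, r_squared = r2,
       sigma2 = sigma2, log_likelihood = as.numeric(ll),
       fitted = as.numeric(X %*% beta),
       residuals = as.numeric(y - X %*% beta),
       whitened_residuals = rw, n = n, p = p)
}

make_pgls_fit <- function(core, sample, lambda, lambda_estimated, method,
                          response_name, predictor_name) {
  k <- core$p + 1 + as.integer(lambda_estimated)  # coefficients + sigma2 (+ lambda)
  # AICc is undefined for n <= k + 1; report NA rather than refuse the fit
  aicc_val <- if (core$n > k + 1) aicc(core$log_likelihood, k, core$n) else
    NA_real_
  structure(
    c(core,
      list(lambda = lambda, lambda_estimated = lambda_estimated,
           lambda_boundary = FALSE, method = method, k = k,
           aicc = aicc_val,
           taxa = sample$taxon,
           data = tibble::tibble(taxon = sample$taxon, predictor = sample$x,
                                 response = sample$y),
           response_name = unname(response_name),
           predictor_name = unname(predictor_name))),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: %s ~ %s  (n = %d, %s)\n",
              x$response_name, x$predictor_name, x$n, x$method))
  lam_note <- if (x$lambda_estimated) " (ML)" else " (fixed)"
  cat(sprintf("  lambda = %.4f%s%s\n", x$lambda, lam_note,
              if (isTRUE(x$lambda_boundary)) " [boundary]" else ""))
  cat(sprintf("  intercept = %.4f, slope = %.4f\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  R^2 = %.3f, model p = %.3g, logLik = %.3f, AICc = %.3f\n",
              x$r_squared, x$model_p, x$log_likelihood, x$aicc))
  invisible(x)
}

#' Confidence intervals for PGLS coefficients
#'
#' t-based intervals using the whitened-space standard errors with
#' `n - p` residual degrees of freedom.
#'
#' @param object A `pgls_fit`.
#' @param parm Coefficients to include (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.pgls_fit <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  se <- object$std_errors
  if (is.null(parm)) parm <- names(cf)
  q <- stats::qt(1 - (1 - level) / 2, df = object$n - object$p)
  out <- cbind(cf[parm] - q * se[parm], cf[parm] + q * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
residuals.pgls_fit <- function(object, ...) {
  setNames(object$residuals, object$taxa)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients
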