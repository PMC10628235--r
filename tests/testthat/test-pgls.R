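test_that("a star phylogeny reduces PGLS to ordinary least squares", {
  st <- star_tree(8, depth = 2)
  set.seed(1)
  d <- tibble::tibble(taxon = st$tip.label, x = rnorm(8), y = rnorm(8))
  fit <- gls_fit(d, phylo_vcv(st, 1), response = y, predictor = x)
  ols <- summary(lm(y ~ x, data = d))
  expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x, data = d))),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, ols$r.squared, tolerance = 1e-8)
  expect_equal(fit$model_p,
               unname(pf(ols$fstatistic[1], ols$fstatistic[2],
                         ols$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-8)
  expect_equal(unname(fit$std_errors), unname(ols$coefficients[, 2]),
               tolerance = 1e-8)
})

test_that("lambda zero on an ultrametric tree equals OLS", {
  tr <- simulate_tree(12, tree_depth = 80, seed = 3)
  set.seed(4)
  d <- tibble::tibble(taxon = tr$tip.label, x = rnorm(12), y = rnorm(12))
  fit <- gls_fit(d, phylo_vcv(tr, 0), response = y, predictor = x)
  expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x, data = d))),
               tolerance = 1e-8)
})

test_that("coefficients match the brute-force normal-equations oracle", {
  # frozen from (X' V^-1 X)^-1 X' V^-1 y on the hand-built 3-taxon covariance
  tr <- three_taxon_tree()
  d <- tibble::tibble(taxon = c("A", "B", "C"), x = c(0, 1, 2), y = c(1, 0, 2))
  fit <- gls_fit(d, phylo_vcv(tr, 1), response = y, predictor = x)
  expect_equal(unname(fit$coefficients), c(1, 0.125), tolerance = 1e-10)
  expect_equal(fit$sigma2, 0.375, tolerance = 1e-10)
  expect_equal(fit$log_likelihood, -3.68145145471046, tolerance = 1e-10)

  # an exactly linear response is fitted perfectly
  d2 <- tibble::tibble(taxon = c("A", "B", "C"), x = c(0, 1, 2), y = c(0, 1, 2))
  fit2 <- gls_fit(d2, phylo_vcv(tr, 1), response = y, predictor = x)
  expect_equal(unname(fit2$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(fit2$residuals, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
})

test_that("whitened residuals are orthogonal to the whitened design", {
  for (rep in 1:5) {
    tr <- simulate_tree(15, tree_depth = 30, seed = 400 + rep)
    d <- simulate_traits(tr, slope = 0.5, sigma2 = 0.01, lambda = 0.8,
                         seed = 500 + rep)
    fit <- gls_fit(d, phylo_vcv(tr, 0.6), response = response,
                   predictor = predictor)
    V <- phylo_vcv(tr, 0.6)[d$taxon, d$taxon]
    X <- cbind(1, d$predictor)
    g <- t(X) %*% solve(V) %*% fit$residuals
    expect_lt(max(abs(g)), 1e-8)
  }
})

test_that("coefficients are affine-equivariant in the predictor", {
  tr <- simulate_tree(20, tree_depth = 10, seed = 9)
  d <- simulate_traits(tr, slope = 0.3, sigma2 = 0.02, seed = 10)
  f1 <- gls_fit(d, phylo_vcv(tr, 1), response = response,
                predictor = predictor)
  d2 <- dplyr::mutate(d, predictor = predictor + 5)
  f2 <- gls_fit(d2, phylo_vcv(tr, 1), response = response,
                predictor = predictor)
  expect_equal(f2$coefficients[["x"]], f1$coefficients[["x"]],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(f2$coefficients[1]),
               unname(f1$coefficients[1]) - 5 * unname(f1$coefficients[2]),
               tolerance = 1e-8)
})

test_that("ML lambda agrees with an independent GLS implementation", {
  tr <- simulate_tree(40, tree_depth = 100, seed = 5)
  d <- simulate_traits(tr, intercept = -1, slope = 0.2, sigma2 = 4e-4,
                       lambda = 0.7, seed = 9)
  fit <- pgls_ml(d, tr, response = response, predictor = predictor)
  df <- as.data.frame(d)
  g <- nlme::gls(response ~ predictor, data = df,
                 correlation = ape::corPagel(0.5, tr, form = ~taxon),
                 method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fit$lambda,
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("the optimizer's lambda is bracketed by a fine profile grid", {
  tr <- simulate_tree(25, tree_depth = 50, seed = 21)
  d <- simulate_traits(tr, slope = 0.2, sigma2 = 1e-3, lambda = 0.6, seed = 22)
  fit <- pgls_ml(d, tr, response = response, predictor = predictor)
  grid <- seq(0, 1, length.out = 1001)
  V1 <- phylo_vcv(prune_to_taxa(tr, d$taxon), 1)
  ll <- vapply(grid, function(lam) {
    f <- gls_fit(d, phylo_vcv(tr, lam), response = response,
                 predictor = predictor)
    f$log_likelihood
  }, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - fit$lambda), 1.5e-3)  # grid spacing
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-10, 3, 10), 30)  # 20 + 6 + 24/6
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "n > k")
})

test_that("the AICc of a fit counts coefficients, sigma2 and estimated lambda", {
  tr <- simulate_tree(15, tree_depth = 10, seed = 31)
  d <- simulate_traits(tr, seed = 32)
  fit_ml <- pgls_ml(d, tr, response = response, predictor = predictor)
  expect_equal(fit_ml$k, 4)
  expect_equal(fit_ml$aicc, aicc(fit_ml$log_likelihood, 4, fit_ml$n))
  fit_fixed <- gls_fit(d, phylo_vcv(tr, 1), response = response,
                       predictor = predictor)
  expect_equal(fit_fixed$k, 3)
})

test_that("degenerate and mismatched inputs raise explicit errors", {
  tr <- three_taxon_tree()
  d_const <- tibble::tibble(taxon = c("A", "B", "C"), x = c(1, 1, 1),
                            y = c(1, 2, 3))
  expect_error(gls_fit(d_const, phylo_vcv(tr, 1), response = y, predictor = x),
               "constant")
  d_na <- tibble::tibble(taxon = c("A", "B", "C"), x = c(1, NA, 3),
                         y = c(1, 2, 3))
  expect_error(gls_fit(d_na, phylo_vcv(tr, 1), response = y, predictor = x),
               "missing")
  d_extra <- tibble::tibble(taxon = c("A", "B", "Z"), x = 1:3, y = 1:3)
  expect_error(gls_fit(d_extra, phylo_vcv(tr, 1), response = y, predictor = x),
               "Z")
  # singular covariance: duplicated tip depths from zero-length terminals
  tr0 <- ape::read.tree(text = "((A:0,B:0):2,C:2);")
  d3 <- tibble::tibble(taxon = c("A", "B", "C"), x = c(0, 1, 2), y = c(1, 0, 2))
  V <- suppressWarnings(phylo_vcv(tr0, 1))
  expect_error(gls_fit(d3, V, response = y, predictor = x), "singular")
})

test_that("boundary lambda estimates are returned as-is and flagged", {
  st <- star_tree(20, depth = 1)
  set.seed(77)
  d <- tibble::tibble(taxon = st$tip.label, x = rnorm(20),
                      y = rnorm(20))
  fit <- pgls_ml(d, st, response = y, predictor = x)
  expect_equal(fit$lambda_boundary, fit$lambda %in% c(0, 1))
  # permuted (signal-free) data on a structured tree pushes lambda to 0
  tr <- simulate_tree(30, tree_depth = 10, seed = 78)
  d2 <- simulate_traits(tr, sigma2 = 0.05, lambda = 0, seed = 79)
  fit2 <- pgls_ml(d2, tr, response = response, predictor = predictor)
  expect_lte(fit2$lambda, 0.3)
})

test_that("REML is available as a non-default likelihood flavour", {
  tr <- simulate_tree(20, tree_depth = 10, seed = 41)
  d <- simulate_traits(tr, seed = 42)
  fit_reml <- pgls_ml(d, tr, response = response, predictor = predictor,
                      method = "REML")
  fit_ml <- pgls_ml(d, tr, response = response, predictor = predictor)
  expect_false(isTRUE(all.equal(fit_reml$log_likelihood,
                                fit_ml$log_likelihood)))
  expect_s3_class(fit_reml, "pgls_fit")
})

test_that("tidiers expose the fit in broom conventions", {
  tr <- simulate_tree(15, tree_depth = 10, seed = 51)
  d <- simulate_traits(tr, seed = 52)
  fit <- pgls_ml(d, tr, response = response, predictor = predictor)
  td <- tidy(fit, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_true(all(c("r.squared", "lambda", "AICc", "nobs") %in% names(gl)))
  expect_gte(gl$r.squared, 0)
  expect_lte(gl$r.squared, 1)
  au <- augment(fit)
  expect_equal(au$.resid, au$response - au$.fitted, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})
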