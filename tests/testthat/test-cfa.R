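test_that("model specifications carry the documented structure", {
  null <- cfa_model_spec("null")
  expect_length(null$factors, 0)
  expect_equal(count_df(null), 15)
  expect_equal(count_df(cfa_model_spec("one_factor")), 9)     # 12 free
  expect_equal(count_df(cfa_model_spec("two_unrelated")), 9)  # 12 free
  expect_equal(count_df(cfa_model_spec("two_related")), 8)    # 13 free
  expect_equal(count_df(21), 0)  # saturated
  two <- cfa_model_spec("two_related")
  expect_equal(two$factors$response_inhibition,
               c("antisaccade", "stroop", "stop_signal"))
  expect_equal(two$factors$distractor_interference,
               c("flanker", "shape_matching", "word_naming"))
})

test_that("implied covariance follows Lambda Phi Lambda' + Theta", {
  spec1 <- cfa_model_spec("one_factor")
  # zero loadings: diagonal of error variances
  th <- c(1, 2, 3, 4, 5, 6)
  expect_equal(implied_covariance(spec1, list(lambda = rep(0, 6),
                                              theta = th)), diag(th),
               ignore_attr = TRUE)
  # two loaded indicators with zero error variance covary at 1
  S <- implied_covariance(spec1, list(lambda = c(1, 1, 0, 0, 0, 0),
                                      theta = c(0, 0, 1, 1, 1, 1)))
  expect_equal(S[1, 2], 1)
  expect_equal(S[1, 1], 1)
  expect_true(isSymmetric(S))
})

test_that("implied covariance matches a Monte-Carlo moment computation", {
  set.seed(42)
  pars <- random_admissible_params()
  spec <- cfa_model_spec("two_related")
  Sig <- implied_covariance(spec, pars)
  n <- 2e5
  f1 <- rnorm(n)
  f2 <- pars$phi * f1 + sqrt(1 - pars$phi^2) * rnorm(n)
  Fm <- cbind(f1, f2)
  L <- matrix(0, 6, 2); L[1:3, 1] <- pars$lambda[1:3]
  L[4:6, 2] <- pars$lambda[4:6]
  X <- Fm %*% t(L) +
    matrix(rnorm(6 * n), n, 6) %*% diag(sqrt(pars$theta))
  expect_equal(max(abs(cov(X) - Sig)), 0, tolerance = 0.02)
})

test_that("a diagonal covariance saturates the null model", {
  S <- diag(c(2, 1, 3, 0.5, 1.5, 2.5))
  f <- fit_ml(S, 100, "null")
  expect_equal(f$chi_square, 0, tolerance = 1e-8)
  expect_equal(unname(f$error_variances), diag(S), tolerance = 1e-6)
})

test_that("fitting a model to its own implied covariance recovers the truth", {
  set.seed(7)
  pars <- random_admissible_params()
  spec <- cfa_model_spec("two_related")
  Sig <- implied_covariance(spec, pars)
  f <- fit_ml(Sig, 190, spec)
  expect_true(f$converged)
  expect_lt(f$discrepancy, 1e-10)
  expect_equal(unname(f$loadings), pars$lambda, tolerance = 1e-4)
  expect_equal(unname(f$error_variances), pars$theta, tolerance = 1e-4)
  expect_equal(f$phi, pars$phi, tolerance = 1e-4)
})

test_that("rejects degenerate covariance input", {
  S <- matrix(1, 6, 6)              # singular
  expect_error(fit_ml(S, 100, "one_factor"), "positive definite")
  S2 <- diag(6); S2[1, 2] <- 0.5    # asymmetric
  expect_error(fit_ml(S2, 100, "one_factor"), "symmetric")
})

test_that("the related-factors model never fits worse than the unrelated one", {
  set.seed(13)
  for (i in 1:5) {
    S <- random_pd_cov()
    f_rel <- fit_ml(S, 150, "two_related")
    f_unrel <- fit_ml(S, 150, "two_unrelated")
    expect_gte(f_unrel$chi_square, f_rel$chi_square - 1e-6)
    expect_gte(f_rel$chi_square, 0)
  }
})

test_that("standardized solution satisfies lambda^2 + theta = 1 on a correlation matrix", {
  set.seed(21)
  pars <- list(lambda = rep(0.6, 6), theta = rep(0.64, 6), phi = 0.5)
  Sig <- implied_covariance(cfa_model_spec("two_related"), pars)
  X <- matrix(rnorm(500 * 6), 500) %*% chol(Sig)
  R <- cor(X)
  f <- fit_ml(R, 500, "two_related")
  expect_equal(unname(f$loadings_std^2 + f$error_variances_std),
               rep(1, 6), tolerance = 1e-6)
})

test_that("fit indices take their perfect-fit values at zero discrepancy", {
  pars <- list(lambda = rep(0.6, 6), theta = rep(0.64, 6), phi = 0.67)
  Sig <- implied_covariance(cfa_model_spec("two_related"), pars)
  fits <- fit_cfa_models(Sig, 190, c("null", "two_related"))
  f <- fits$two_related
  expect_equal(f$RMSEA, 0)
  expect_lt(f$SRMR, 1e-6)
  expect_equal(f$CFI, 1)
  expect_gt(f$NFI, 0.999)
  # AIC convention: chi2 + 2 * (free params + 6 means)
  expect_equal(fits$null$aic_q, 12)
  expect_equal(fits$null$AIC, fits$null$chi_square + 24)
  expect_equal(f$aic_q, 19)
  # covariance-only convention drops the means
  fits2 <- fit_cfa_models(Sig, 190, c("null", "two_related"),
                          include_means = FALSE)
  expect_equal(fits2$two_related$aic_q, 13)
})

test_that("model comparison ranks by AIC and annotates thresholds", {
  pars <- list(lambda = rep(0.55, 6), theta = rep(0.7, 6), phi = 0.67)
  Sig <- implied_covariance(cfa_model_spec("two_related"), pars)
  set.seed(31)
  X <- matrix(rnorm(300 * 6), 300) %*% chol(Sig)
  fits <- fit_cfa_models(cov(X), 300)
  tab <- compare_models(fits)
  expect_equal(tab$model[1], attr(tab, "preferred"))
  expect_true(all(diff(tab$AIC) >= 0))
  # with equal chi-square, fewer parameters win the AIC ranking
  expect_true(all(c("rmsea_label", "srmr_label") %in% names(tab)))
})

test_that("threshold annotations follow the published cut-offs", {
  expect_equal(inhibitr:::rmsea_label(0.049), "good")
  expect_equal(inhibitr:::rmsea_label(0.009), "excellent")
  expect_equal(inhibitr:::rmsea_label(0.07), "acceptable")
  expect_equal(inhibitr:::srmr_label(0.049), "good")
  expect_equal(inhibitr:::srmr_label(0.07), "fair")
  expect_equal(inhibitr:::incremental_label(0.96), "good")
})

test_that("Mardia statistics reduce to univariate moments at p = 1", {
  set.seed(17)
  x <- matrix(rexp(400), ncol = 1)
  m <- mardia(x)
  n <- nrow(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  expect_equal(m$b1p, (m3 / m2^1.5)^2, tolerance = 1e-10)
  expect_equal(m$b2p, m4 / m2^2, tolerance = 1e-10)
})

test_that("Mardia kurtosis approaches p(p+2) under multivariate normality", {
  set.seed(19)
  X <- matrix(rnorm(1e5 * 6), ncol = 6)
  m <- mardia(X)
  expect_equal(m$b2p, 48, tolerance = 0.5 / 48)
  expect_gt(m$kurtosis_p, 0.001)
})

test_that("a distant row gets the largest Mahalanobis distance", {
  set.seed(23)
  X <- matrix(rnorm(50 * 3), ncol = 3)
  X[50, ] <- c(10, -10, 10)
  m <- mardia(X)
  expect_equal(which.max(m$mahalanobis_d2), 50L)
  expect_true(m$flagged[50])
})

test_that("bootstrap refits are deterministic under a seed", {
  set.seed(29)
  pars <- list(lambda = rep(0.6, 6), theta = rep(0.64, 6), phi = 0.67)
  Sig <- implied_covariance(cfa_model_spec("two_related"), pars)
  X <- as.data.frame(matrix(rnorm(120 * 6), 120) %*% chol(Sig))
  names(X) <- inhibition_tasks()
  b1 <- bootstrap_fit(X, "two_related", B = 2, seed = 99)
  b2 <- bootstrap_fit(X, "two_related", B = 2, seed = 99)
  expect_equal(b1$estimates, b2$estimates)
  expect_equal(b1$B, 2)
  expect_true(all(c("estimate", "boot_se", "p_bc") %in%
                    names(b1$estimates)))
})

test_that("a degenerate dataset of identical rows cannot move the bootstrap", {
  X <- as.data.frame(matrix(rep(c(1, 2, 3, 4, 5, 6), each = 30), 30))
  names(X) <- inhibition_tasks()
  # covariance of identical rows is singular: no admissible ML fit exists
  expect_error(bootstrap_fit(X, "two_related", B = 2, seed = 1),
               "positive definite")
})

test_that("observed-information standard errors are computable", {
  set.seed(37)
  pars <- list(lambda = rep(0.6, 6), theta = rep(0.64, 6), phi = 0.67)
  Sig <- implied_covariance(cfa_model_spec("two_related"), pars)
  X <- matrix(rnorm(400 * 6), 400) %*% chol(Sig)
  f <- fit_ml(cov(X), 400, "two_related")
  se <- cfa_analytic_se(f)
  expect_length(se, 13)
  expect_true(all(se > 0))
  expect_lt(se[["phi"]], 0.2)
})
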