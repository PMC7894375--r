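## fit indices, model set fitting, and model comparison.

#' Attach fit indices to a CFA fit
#'
#' Computes the standard index set relative to the null (independence)
#' baseline:
#' * `RMSEA = sqrt(max(chi2 - df, 0) / (df * (N - 1)))`
#' * `SRMR`: square root of the mean squared correlation-metric residual
#'   over the 21 unique covariance cells (means excluded)
#' * `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_0 - df_0, chi2_M - df_M, 0)`
#' * `NFI = (chi2_0 - chi2_M) / chi2_0`
#' * `AIC = chi2 + 2 q`, where by default `q` counts the covariance-
#'   structure parameters plus the six indicator means
#'   (`include_means = FALSE` switches to the covariance-only convention).
#'
#' @param fit a [fit_ml()] result for the substantive model.
#' @param null_fit a [fit_ml()] result for the null model on the same `S`.
#' @param include_means include the 6 indicator means in the AIC parameter
#'   count (default TRUE).
#' @return `fit` with elements `RMSEA`, `SRMR`, `CFI`, `NFI`, `AIC`,
#'   `aic_q` added.
#' @export
fit_indices <- function(fit, null_fit, include_means = TRUE) {
  N <- fit$N
  chi2 <- fit$chi_square; df <- fit$df
  fit$RMSEA <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (N - 1))) else 0

  S <- fit$S; Sigma <- fit$implied
  d <- sqrt(diag(S))
  R <- (S - Sigma) / tcrossprod(d)
  lower <- R[lower.tri(R, diag = TRUE)]
  fit$SRMR <- sqrt(mean(lower^2))

  chi0 <- null_fit$chi_square; df0 <- null_fit$df
  num <- max(chi2 - df, 0)
  den <- max(chi0 - df0, chi2 - df, 0)
  fit$CFI <- if (den > 0) 1 - num / den else 1
  fit$NFI <- if (chi0 > 0) (chi0 - chi2) / chi0 else NA_real_

  fit$aic_q <- fit$q_free_parameters + if (include_means) 6L else 0L
  fit$AIC <- chi2 + 2 * fit$aic_q
  fit
}

#' Fit the candidate model set to a covariance matrix
#'
#' Fits the null model plus the requested substantive models and attaches
#' fit indices (all relative to the same null baseline).
#'
#' @param S 6 x 6 sample covariance matrix.
#' @param N number of observations.
#' @param models character vector of model kinds (the null model is always
#'   fitted as baseline).
#' @param include_means AIC parameter-count convention, see
#'   [fit_indices()].
#' @param n_starts optimization starts per model.
#' @return named list of `cfa_fit` objects (including `null`), class
#'   `cfa_fit_set`.
#' @export
fit_cfa_models <- function(S, N,
                           models = c("null", "one_factor", "two_related",
                                      "two_unrelated"),
                           include_means = TRUE, n_starts = 5) {
  models <- match.arg(models, several.ok = TRUE)
  null_fit <- fit_ml(S, N, cfa_model_spec("null"), n_starts = 1)
  null_fit <- fit_indices(null_fit, null_fit, include_means)
  fits <- list(null = null_fit)
  for (m in setdiff(models, "null")) {
    f <- fit_ml(S, N, cfa_model_spec(m), n_starts = n_starts)
    fits[[m]] <- fit_indices(f, null_fit, include_means)
  }
  structure(fits[intersect(c("null", "two_unrelated", "two_related",
                             "one_factor"), names(fits))],
            class = "cfa_fit_set")
}

rmsea_label <- function(x) {
  if (is.na(x)) NA_character_
  else if (x < 0.01) "excellent"
  else if (x < 0.05) "good"
  else if (x < 0.08) "acceptable"
  else "poor"
}

srmr_label <- function(x) {
  if (is.na(x)) NA_character_
  else if (x < 0.05) "good"
  else if (x < 0.08) "fair"
  else "poor"
}

incremental_label <- function(x) {
  if (is.na(x)) NA_character_ else if (x > 0.95) "good" else "sub-threshold"
}

#' Compare fitted models
#'
#' Ranks fits by AIC (lowest preferred) and annotates each fit index with
#' the conventional verbal thresholds: RMSEA < .01 excellent / < .05 good /
#' < .08 acceptable; SRMR < .05 good / < .08 fair; CFI and NFI > .95 good.
#'
#' @param fits a `cfa_fit_set` or list of indexed `cfa_fit` objects.
#' @return data.frame ordered by AIC with columns `model`, `df`,
#'   `chi_square`, `p_value`, `RMSEA`, `SRMR`, `CFI`, `AIC`, `NFI`,
#'   `converged` and `*_label` annotations; attribute `preferred` names the
#'   lowest-AIC model.
#' @export
compare_models <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, df = f$df, chi_square = f$chi_square,
               p_value = f$p_value %||% NA_real_,
               RMSEA = f$RMSEA %||% NA_real_, SRMR = f$SRMR %||% NA_real_,
               CFI = f$CFI %||% NA_real_, AIC = f$AIC %||% NA_real_,
               NFI = f$NFI %||% NA_real_,
               converged = f$converged,
               rmsea_label = rmsea_label(f$RMSEA %||% NA_real_),
               srmr_label = srmr_label(f$SRMR %||% NA_real_),
               cfi_label = incremental_label(f$CFI %||% NA_real_),
               nfi_label = incremental_label(f$NFI %||% NA_real_))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "preferred") <- out$model[1]
  out
}
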