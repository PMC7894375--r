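## nonparametric bootstrap for CFA parameters (bias-corrected percentile).

#' Nonparametric bootstrap of a CFA fit
#'
#' Resamples subjects (rows of the outcome matrix) with replacement,
#' refits the model on each resample's covariance matrix (starting from
#' the full-sample solution), and reports per-parameter bootstrap standard
#' errors, bias, and bias-corrected (BC percentile) two-sided p-values for
#' the hypothesis that the parameter is zero. Non-converged resamples are
#' counted and excluded. Factor signs of each resample are aligned with the
#' full-sample solution before aggregation.
#'
#' @param outcomes data.frame of per-subject scores (columns = the six
#'   tasks; a `subject_id` column is ignored; incomplete rows dropped).
#' @param spec a [cfa_model_spec()] or model-kind string.
#' @param B number of resamples (default 5000).
#' @param seed integer seed for the resampling.
#' @param n_starts_fallback multi-start count used when the warm-started
#'   refit fails.
#' @return object of class `cfa_bootstrap`: `estimates` data.frame
#'   (parameter, estimate, boot_se, boot_bias, p_bc), plus
#'   `estimates_std` for the standardized loadings (and `phi`), `B`,
#'   `n_used`, `n_nonconverged`, `seed`, `draws` (raw parameter matrix).
#' @export
bootstrap_fit <- function(outcomes, spec, B = 5000, seed = 1L,
                          n_starts_fallback = 5) {
  if (is.character(spec)) spec <- cfa_model_spec(spec)
  X <- as.matrix(outcomes[, spec$indicators, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  stopifnot(n > 6)
  S <- stats::cov(X)
  full <- fit_ml(S, n, spec)

  par_names <- c(if (spec$model_kind != "null")
                   paste0("lambda_", spec$indicators),
                 paste0("theta_", spec$indicators),
                 if (spec$free_phi) "phi")
  extract <- function(f)
    c(if (spec$model_kind != "null") unname(f$loadings),
      unname(f$error_variances),
      if (spec$free_phi) f$phi)
  extract_std <- function(f)
    c(if (spec$model_kind != "null") unname(f$loadings_std),
      if (spec$free_phi) f$phi)
  std_names <- c(if (spec$model_kind != "null")
                   paste0("lambda_std_", spec$indicators),
                 if (spec$free_phi) "phi")

  ## align a resample's factor signs with the full-sample solution
  align_to_full <- function(f) {
    if (spec$model_kind == "null") return(f)
    flips <- 1
    for (j in seq_along(spec$factors)) {
      rows <- match(spec$factors[[j]], spec$indicators)
      if (sum(f$loadings[rows] * full$loadings[rows]) < 0) {
        f$loadings[rows] <- -f$loadings[rows]
        f$loadings_std[rows] <- -f$loadings_std[rows]
        flips <- -flips
      }
    }
    if (spec$free_phi && flips < 0) f$phi <- -f$phi
    f
  }

  set.seed(seed)
  draws <- matrix(NA_real_, B, length(par_names),
                  dimnames = list(NULL, par_names))
  draws_std <- matrix(NA_real_, B, length(std_names),
                      dimnames = list(NULL, std_names))
  n_bad <- 0L
  warm <- list(lambda = unname(full$loadings),
               theta = unname(full$error_variances), phi = full$phi)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Sb <- stats::cov(X[idx, , drop = FALSE])
    fb <- tryCatch(fit_ml(Sb, n, spec, n_starts = 1, start = warm),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged)
      fb <- tryCatch(fit_ml(Sb, n, spec, n_starts = n_starts_fallback),
                     error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      n_bad <- n_bad + 1L
      next
    }
    fb <- align_to_full(fb)
    draws[b, ] <- extract(fb)
    draws_std[b, ] <- extract_std(fb)
  }

  used <- stats::complete.cases(draws)
  est <- extract(full)
  bc_p <- function(theta_hat, th) {
    th <- th[!is.na(th)]
    Bu <- length(th)
    if (Bu < 10 || stats::sd(th) == 0)
      return(if (isTRUE(all.equal(theta_hat, 0))) 1 else NA_real_)
    z0 <- stats::qnorm(clamp(mean(th < theta_hat), 1 / (Bu + 1),
                             Bu / (Bu + 1)))
    p0 <- clamp(mean(th <= 0), 1 / (Bu + 1), Bu / (Bu + 1))
    z <- stats::qnorm(p0) - 2 * z0
    2 * min(stats::pnorm(z), 1 - stats::pnorm(z))
  }
  summarize <- function(est_vec, mat) {
    data.frame(parameter = colnames(mat),
               estimate = est_vec,
               boot_se = apply(mat, 2, stats::sd, na.rm = TRUE),
               boot_bias = colMeans(mat, na.rm = TRUE) - est_vec,
               p_bc = vapply(seq_along(est_vec), function(i)
                 bc_p(est_vec[i], mat[, i]), numeric(1)),
               row.names = NULL)
  }
  structure(list(
    estimates = summarize(est, draws),
    estimates_std = summarize(extract_std(full), draws_std),
    B = B, n_used = sum(used), n_nonconverged = n_bad,
    seed = seed, full_fit = full, draws = draws
  ), class = "cfa_bootstrap")
}

#' @export
print.cfa_bootstrap <- function(x, ...) {
  cat(sprintf("CFA bootstrap: B = %d (%d used, %d non-converged), seed %d\n",
              x$B, x$n_used, x$n_nonconverged, x$seed))
  print(transform(x$estimates,
                  estimate = round(estimate, 4),
                  boot_se = round(boot_se, 4),
                  boot_bias = round(boot_bias, 4),
                  p_bc = signif(p_bc, 3)), row.names = FALSE)
  invisible(x)
}
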