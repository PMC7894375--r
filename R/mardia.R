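## multivariate normality diagnostics.

#' Mardia's multivariate skewness and kurtosis, with Mahalanobis distances
#'
#' For an N x p matrix with rows x_i, let `g_ij = (x_i - xbar)' S^-1
#' (x_j - xbar)` with `S` the ML (1/N) covariance. Then
#' `b1p = mean over (i, j) of g_ij^3` and `b2p = mean over i of g_ii^2`.
#' The skewness statistic `N b1p / 6` is referred to chi-square with
#' `p(p+1)(p+2)/6` df; the kurtosis z-statistic is
#' `(b2p - p(p+2)) / sqrt(8 p (p+2) / N)` (under exact multivariate
#' normality `E[b2p] = p(p+2)`). Per-row squared Mahalanobis distances
#' (rescaled to the unbiased covariance, `d2_i = g_ii (N-1)/N`) are flagged
#' against the chi-square(p) upper quantile.
#'
#' @param X numeric matrix or data.frame of observations (a `subject_id`
#'   column is ignored; incomplete rows dropped).
#' @param alpha flagging level for Mahalanobis distances (default .001).
#' @return object of class `mardia_result`: `b1p`, `b2p`, `skew_chi2`,
#'   `skew_df`, `skew_p`, `kurtosis_z`, `kurtosis_p`, `mahalanobis_d2`,
#'   `flagged`, `n`, `p`.
#' @export
mardia <- function(X, alpha = 0.001) {
  if (is.data.frame(X))
    X <- as.matrix(X[, setdiff(names(X), "subject_id"), drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  stopifnot(n > p + 1)
  Xc <- sweep(X, 2, colMeans(X))
  S_ml <- crossprod(Xc) / n
  ## whiten instead of forming the n x n Gram matrix: with Y = Xc U^-1
  ## (U the Cholesky factor), g_ij = y_i . y_j, so
  ## sum_ij g_ij^3 = sum_abc (sum_i y_ia y_ib y_ic)^2
  Y <- Xc %*% solve(chol(S_ml))
  M3 <- 0
  for (a in seq_len(p)) for (b in seq_len(p)) for (cc in seq_len(p))
    M3 <- M3 + sum(Y[, a] * Y[, b] * Y[, cc])^2
  b1p <- M3 / n^2
  g_ii <- rowSums(Y^2)
  b2p <- mean(g_ii^2)
  skew_df <- p * (p + 1) * (p + 2) / 6
  skew_chi2 <- n * b1p / 6
  kurt_z <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  ## Mahalanobis d2 on the unbiased covariance, conventional for outlier
  ## screening
  d2 <- g_ii * (n - 1) / n
  cut <- stats::qchisq(1 - alpha, df = p)
  structure(list(
    b1p = b1p, b2p = b2p,
    skew_chi2 = skew_chi2, skew_df = skew_df,
    skew_p = stats::pchisq(skew_chi2, skew_df, lower.tail = FALSE),
    kurtosis_z = kurt_z,
    kurtosis_p = 2 * stats::pnorm(abs(kurt_z), lower.tail = FALSE),
    mahalanobis_d2 = d2,
    flagged = d2 > cut,
    n = n, p = p, alpha = alpha
  ), class = "mardia_result")
}

#' @export
print.mardia_result <- function(x, ...) {
  cat(sprintf("Mardia multivariate normality (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  skewness b1p = %.4f, chi2(%d) = %.2f, p = %.3g\n",
              x$b1p, x$skew_df, x$skew_chi2, x$skew_p))
  cat(sprintf("  kurtosis b2p = %.4f (expected %.0f), z = %.2f, p = %.3g\n",
              x$b2p, x$p * (x$p + 2), x$kurtosis_z, x$kurtosis_p))
  cat(sprintf("  %d observation(s) flagged by Mahalanobis d2 at alpha = %g\n",
              sum(x$flagged), x$alpha))
  invisible(x)
}
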