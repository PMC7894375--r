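## cfa engine: maximum-likelihood covariance-structure fitting of the four
## candidate models (null / one factor / two unrelated / two related
## factors) over the six task outcomes.

#' Declarative CFA model specification
#'
#' The four candidate structures over the six task outcomes. Identification
#' fixes factor variances to 1, so loadings and the inter-factor correlation
#' are free. The null (independence) model constrains all covariances to
#' zero with free indicator variances. The two-factor models assign
#' antisaccade, Stroop and stop-signal to a response-inhibition factor and
#' flanker, shape-matching and word-naming to a distractor-interference
#' factor; `two_related` frees exactly one inter-factor correlation.
#'
#' @param model_kind one of `"null"`, `"one_factor"`, `"two_related"`,
#'   `"two_unrelated"`.
#' @return object of class `cfa_model_spec`.
#' @export
cfa_model_spec <- function(model_kind = c("null", "one_factor",
                                          "two_related", "two_unrelated")) {
  model_kind <- match.arg(model_kind)
  ind <- inhibition_tasks()
  factors <- switch(model_kind,
    null = list(),
    one_factor = list(inhibition = ind),
    list(response_inhibition = ind[1:3],
         distractor_interference = ind[4:6]))
  structure(list(model_kind = model_kind,
                 indicators = ind,
                 factors = factors,
                 free_phi = model_kind == "two_related"),
            class = "cfa_model_spec")
}

## number of free covariance-structure parameters
n_free_params <- function(spec) {
  n_lambda <- if (spec$model_kind == "null") 0L else 6L
  n_lambda + 6L + as.integer(spec$free_phi)
}

#' Model degrees of freedom
#'
#' Unique second-order moments (p(p+1)/2 = 21 for six indicators) minus free
#' covariance-structure parameters: 15 (null), 9 (one factor), 9 (two
#' unrelated), 8 (two related).
#'
#' @param spec a [cfa_model_spec()], or an integer number of free
#'   covariance-structure parameters.
#' @return integer degrees of freedom.
#' @export
count_df <- function(spec) {
  q <- if (inherits(spec, "cfa_model_spec")) n_free_params(spec)
       else as.integer(spec)
  21L - q
}

## 6 x k loading matrix from the free-loading vector
lambda_matrix <- function(spec, lambda) {
  k <- length(spec$factors)
  L <- matrix(0, 6L, max(k, 1L),
              dimnames = list(spec$indicators, names(spec$factors)))
  if (k == 0L) return(L[, 0, drop = FALSE])
  for (j in seq_len(k)) {
    rows <- match(spec$factors[[j]], spec$indicators)
    L[rows, j] <- lambda[rows]
  }
  L
}

#' Model-implied covariance matrix
#'
#' `Sigma = Lambda Phi Lambda' + Theta` under unit factor variances, with
#' `Theta` diagonal. With all loadings zero this reduces to `diag(theta)`.
#'
#' @param spec a [cfa_model_spec()].
#' @param params list with `lambda` (6 loadings, ignored for the null
#'   model), `theta` (6 error variances), `phi` (inter-factor correlation,
#'   `two_related` only).
#' @return symmetric 6 x 6 matrix.
#' @export
implied_covariance <- function(spec, params) {
  theta <- params$theta
  stopifnot(length(theta) == 6L)
  if (spec$model_kind == "null") return(diag(theta))
  L <- lambda_matrix(spec, params$lambda)
  k <- ncol(L)
  Phi <- diag(k)
  if (spec$free_phi) {
    Phi[1, 2] <- Phi[2, 1] <- params$phi
  }
  L %*% Phi %*% t(L) + diag(theta)
}

## ---- parameter vector transforms -------------------------------------
## optimization runs on unconstrained scale: loadings raw, error variances
## log, correlation atanh.

pack_par <- function(spec, lambda, theta, phi = NULL) {
  x <- c(if (spec$model_kind != "null") lambda, log(theta))
  if (spec$free_phi) x <- c(x, atanh(clamp(phi, -0.999, 0.999)))
  x
}

unpack_par <- function(spec, x) {
  i <- 0L
  lambda <- rep(0, 6)
  if (spec$model_kind != "null") {
    lambda <- x[1:6]; i <- 6L
  }
  theta <- exp(x[(i + 1):(i + 6)]); i <- i + 6L
  phi <- if (spec$free_phi) tanh(x[[i + 1]]) else NULL
  list(lambda = unname(lambda), theta = unname(theta), phi = phi)
}

## ML discrepancy F = log|Sigma| - log|S| + tr(S Sigma^-1) - p
ml_discrepancy <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logdet - logdetS + tr - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

objective_factory <- function(spec, S) {
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  function(x) {
    p <- unpack_par(spec, x)
    ml_discrepancy(implied_covariance(spec, p), S, logdetS)
  }
}

## natural-scale objective (lambda, theta, phi untransformed); used for
## observed-information standard errors.
objective_natural <- function(spec, S) {
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  function(x) {
    i <- 0L
    lambda <- rep(0, 6)
    if (spec$model_kind != "null") { lambda <- x[1:6]; i <- 6L }
    theta <- x[(i + 1):(i + 6)]; i <- i + 6L
    if (any(theta <= 0)) return(1e10)
    phi <- if (spec$free_phi) x[i + 1] else NULL
    if (!is.null(phi) && abs(phi) >= 1) return(1e10)
    ml_discrepancy(implied_covariance(spec,
      list(lambda = lambda, theta = theta, phi = phi)), S, logdetS)
  }
}

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

## deterministic start values (multi-start jitters, no RNG use)
start_values <- function(spec, S, n_starts) {
  d <- diag(S)
  base_lambda <- sqrt(0.5 * d)
  base_theta <- 0.5 * d
  if (spec$model_kind == "null")
    return(list(pack_par(spec, NULL, d)))  # analytic optimum as start
  lam_mult <- c(1, 0.6, 1.4, 0.85, 1.15, 0.45, 1.7, 0.75, 1.3, 0.95)
  th_mult <- c(1, 1.3, 0.7, 1.15, 0.85, 1.5, 0.6, 1.05, 0.9, 1.2)
  phi_start <- c(0.3, -0.3, 0.6, 0.05, 0.45, -0.6, 0.8, 0.2, -0.1, 0.5)
  lapply(seq_len(n_starts), function(j) {
    jj <- ((j - 1) %% 10) + 1
    pack_par(spec,
             base_lambda * lam_mult[jj],
             base_theta * th_mult[jj],
             if (spec$free_phi) phi_start[jj] else NULL)
  })
}

## align factor signs: each factor block gets a nonnegative loading sum;
## phi flips with an odd number of block flips.
align_signs <- function(spec, est) {
  if (spec$model_kind == "null") return(est)
  flips <- 1
  for (j in seq_along(spec$factors)) {
    rows <- match(spec$factors[[j]], spec$indicators)
    if (sum(est$lambda[rows]) < 0) {
      est$lambda[rows] <- -est$lambda[rows]
      flips <- -flips
    }
  }
  if (spec$free_phi && flips < 0) est$phi <- -est$phi
  est
}

#' Fit a CFA model by maximum likelihood
#'
#' Minimizes the ML discrepancy `F = log|Sigma(theta)| - log|S| +
#' tr(S Sigma(theta)^-1) - p` over the model's free parameters with BFGS on
#' an unconstrained parameterization (log error variances, tanh-scaled
#' factor correlation), using multiple jittered deterministic starts and
#' keeping the best solution. `chi_square = (N - 1) * F` at the minimum.
#'
#' @param S 6 x 6 sample covariance matrix (symmetric positive definite).
#'   If dimnames are present they must contain the six task names, and rows
#'   and columns are reordered to battery order.
#' @param N number of observations behind `S`.
#' @param spec a [cfa_model_spec()] (or a model-kind string).
#' @param n_starts number of optimization starts (at least 5 recommended).
#' @param start optional explicit start: list with `lambda`, `theta`, `phi`
#'   on the natural scale; used as the only start unless `n_starts > 1`.
#' @param grad_tol gradient-norm convergence tolerance (floored at 1e-5,
#'   the noise level of the central-difference gradient near the optimum).
#' @return object of class `cfa_fit`: `spec`, `loadings` (raw),
#'   `loadings_std` (completely standardized), `error_variances`,
#'   `error_variances_std`, `phi`, `discrepancy`, `chi_square`, `df`,
#'   `p_value`, `N`, `q_free_parameters`, `converged`, `heywood_flags`,
#'   `implied`. Fit indices are added by [fit_indices()] /
#'   [fit_cfa_models()].
#' @export
fit_ml <- function(S, N, spec, n_starts = 5, start = NULL,
                   grad_tol = 1e-8) {
  if (is.character(spec)) spec <- cfa_model_spec(spec)
  stopifnot(inherits(spec, "cfa_model_spec"))
  S <- as.matrix(S)
  stopifnot(nrow(S) == 6L, ncol(S) == 6L)
  if (!is.null(rownames(S)) && all(spec$indicators %in% rownames(S)))
    S <- S[spec$indicators, spec$indicators]
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S)))
    stop("S must be symmetric")
  S <- (S + t(S)) / 2
  if (inherits(tryCatch(chol(S), error = function(e) e), "error"))
    stop("S must be positive definite")
  stopifnot(N > 6)

  ## the ML discrepancy is invariant under diagonal rescaling, so optimize
  ## in the correlation metric (scale-free, far better conditioned) and
  ## map the solution back to the covariance scale afterwards
  d <- sqrt(diag(S))
  R <- S / tcrossprod(d)
  fobj <- objective_factory(spec, R)
  starts <- if (!is.null(start)) {
    c(list(pack_par(spec, start$lambda / d, start$theta / d^2, start$phi)),
      if (n_starts > 1) start_values(spec, R, n_starts - 1))
  } else start_values(spec, R, n_starts)

  best <- NULL
  for (x0 in starts) {
    res <- tryCatch(
      stats::optim(x0, fobj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    ## polish
    res2 <- tryCatch(
      stats::optim(res$par, fobj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-15)),
      error = function(e) res)
    if (!is.null(res2) && res2$value <= res$value) res <- res2
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")

  est <- align_signs(spec, unpack_par(spec, best$par))
  g <- num_grad(fobj, pack_par(spec, est$lambda, est$theta, est$phi))
  grad_norm <- sqrt(sum(g^2))
  ## practical floor: the central-difference gradient itself carries noise
  ## of order 1e-6 near a flat minimum, so demanding less is meaningless
  converged <- best$convergence == 0 && grad_norm < max(grad_tol, 1e-5)
  ## back to the covariance scale
  est$lambda <- est$lambda * d
  est$theta <- est$theta * d^2

  Sigma <- implied_covariance(spec, est)
  dS <- diag(Sigma)
  lambda_std <- est$lambda / sqrt(dS)
  theta_std <- est$theta / dS
  heywood <- est$theta < 1e-6 * diag(S) | abs(lambda_std) > 1
  Fval <- best$value
  df <- count_df(spec)
  chi2 <- (N - 1) * Fval
  structure(list(
    spec = spec,
    loadings = stats::setNames(est$lambda, spec$indicators),
    loadings_std = stats::setNames(lambda_std, spec$indicators),
    error_variances = stats::setNames(est$theta, spec$indicators),
    error_variances_std = stats::setNames(theta_std, spec$indicators),
    phi = est$phi,
    discrepancy = Fval,
    chi_square = chi2,
    df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
              else NA_real_,
    N = N,
    q_free_parameters = n_free_params(spec),
    converged = converged,
    grad_norm = grad_norm,
    heywood_flags = stats::setNames(heywood, spec$indicators),
    implied = Sigma,
    S = S
  ), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA model '%s': chi2(%d) = %.3f, p = %s, N = %d%s\n",
              x$spec$model_kind, x$df, x$chi_square,
              ifelse(is.na(x$p_value), "-", sprintf("%.3f", x$p_value)),
              x$N, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$spec$model_kind != "null") {
    cat("standardized loadings:\n")
    print(round(x$loadings_std, 3))
  }
  if (!is.null(x$phi)) cat(sprintf("factor correlation: %.3f\n", x$phi))
  if (!is.null(x$RMSEA))
    cat(sprintf("RMSEA = %.3f, SRMR = %.3f, CFI = %.3f, NFI = %.3f, AIC = %.3f\n",
                x$RMSEA, x$SRMR, x$CFI, x$NFI, x$AIC))
  if (any(x$heywood_flags))
    cat("Heywood flag(s):",
        paste(names(which(x$heywood_flags)), collapse = ", "), "\n")
  invisible(x)
}

#' Observed-information standard errors
#'
#' Normal-theory standard errors from the numerically differentiated
#' Hessian of the ML discrepancy at the solution, on the natural parameter
#' scale: `acov = 2 / (N - 1) * H^-1`.
#'
#' @param fit a converged [fit_ml()] result.
#' @return named vector of standard errors (loadings, error variances, and
#'   `phi` when free).
#' @export
cfa_analytic_se <- function(fit) {
  spec <- fit$spec
  x <- c(if (spec$model_kind != "null") fit$loadings,
         fit$error_variances,
         if (spec$free_phi) fit$phi)
  nms <- c(if (spec$model_kind != "null")
             paste0("lambda_", spec$indicators),
           paste0("theta_", spec$indicators),
           if (spec$free_phi) "phi")
  f <- objective_natural(spec, fit$S)
  H <- stats::optimHess(x, f)
  acov <- 2 / (fit$N - 1) * solve(H)
  stats::setNames(sqrt(pmax(diag(acov), 0)), nms)
}
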