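## psychometrics: split-half reliability, Spearman correlations, influence
## diagnostics.

#' Spearman-Brown correction
#'
#' Projects a half-test correlation to full test length: `2 r / (1 + r)`.
#' Monotone in `r`, and not smaller than `r` for `r` in (0, 1).
#'
#' @param r split-half correlation in `[-1, 1]`.
#' @return corrected reliability (vectorized).
#' @export
spearman_brown <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  2 * r / (1 + r)
}

#' Split-half reliability of a task outcome
#'
#' Splits each subject's trials into odd- and even-indexed halves within
#' each condition (a deterministic, condition-balanced split), scores each
#' half independently with the full scoring rules (trimming included), and
#' correlates the half scores across subjects. The corrected value applies
#' the Spearman-Brown formula. Subjects with a missing score in either half
#' are dropped from the correlation.
#'
#' @param trials raw trial data.frame (may contain other tasks; only `task`
#'   is used).
#' @param task one of [inhibition_tasks()].
#' @param scheme `"RT"` or `"IES"` (passed to [build_outcome_matrix()]).
#' @return list: `task`, `scheme`, `split_half_r`, `spearman_brown_r`,
#'   `n_subjects`, `n_dropped`.
#' @export
split_half_reliability <- function(trials, task, scheme = c("RT", "IES")) {
  scheme <- match.arg(scheme)
  tt <- trials[trials$task == task, , drop = FALSE]
  if (!nrow(tt)) stop("no trials for task ", task)
  dt <- data.table::as.data.table(tt)
  dt[, half := trial_index %% 2L, by = .(subject_id, condition)]
  score_half <- function(h) {
    sub <- as.data.frame(dt[half == h])
    m <- build_outcome_matrix(sub, scheme = scheme)
    m[, c("subject_id", task)]
  }
  s1 <- score_half(1L)
  s0 <- score_half(0L)
  m <- merge(s1, s0, by = "subject_id", suffixes = c("_odd", "_even"))
  ok <- stats::complete.cases(m)
  r <- if (sum(ok) >= 3)
    stats::cor(m[ok, 2], m[ok, 3]) else NA_real_
  list(task = task, scheme = scheme,
       split_half_r = r,
       spearman_brown_r = spearman_brown(r),
       n_subjects = sum(ok), n_dropped = sum(!ok))
}

#' Spearman rank correlation matrix with p-values
#'
#' Rank-based correlations (average ranks for ties) between all outcome
#' columns, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df. Pairwise-complete
#' observations.
#'
#' @param outcomes data.frame of per-subject scores (a `subject_id` column,
#'   if present, is ignored).
#' @return list: `rho` (matrix), `p` (matrix), `n` (pairwise n matrix).
#' @export
spearman_correlation_matrix <- function(outcomes) {
  x <- outcomes[, setdiff(names(outcomes), "subject_id"), drop = FALSE]
  x <- as.matrix(x)
  k <- ncol(x)
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  n <- crossprod(!is.na(x))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = n)
}

#' Influence diagnostics for a bivariate correlation
#'
#' Simple regression of `y` on `x` with intercept; reports leverage,
#' studentized (externally) residuals and Cook's D per observation. An
#' observation is flagged if leverage exceeds `leverage_cut`, the absolute
#' studentized residual exceeds `resid_cut`, or its Cook's D is "much
#' larger" than the rest (largest value more than 3 times the second
#' largest). The correlation is reported with and without flagged points.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped).
#' @param leverage_cut leverage threshold (default .05).
#' @param resid_cut absolute studentized-residual threshold (default 3).
#' @return list: `table` (per-observation diagnostics with `flagged`),
#'   `cor_all`, `cor_without_flagged`, `n_flagged`. Leverages sum to 2
#'   (the regression's parameter count).
#' @export
influence_diagnostics <- function(x, y, leverage_cut = 0.05,
                                  resid_cut = 3.0) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("influence diagnostics require at least 4 complete pairs")
  fit <- stats::lm(y ~ x)
  lev <- unname(stats::hatvalues(fit))
  rs <- unname(stats::rstudent(fit))
  cd <- unname(stats::cooks.distance(fit))
  cd_sorted <- sort(cd, decreasing = TRUE)
  d_much_larger <- cd == cd_sorted[1] & cd_sorted[1] > 3 * cd_sorted[2]
  flagged <- lev > leverage_cut | abs(rs) > resid_cut | d_much_larger
  tab <- data.frame(index = which(ok), leverage = lev,
                    studentized_residual = rs, cooks_d = cd,
                    flagged = flagged)
  cor_all <- stats::cor(x, y)
  cor_wo <- if (any(flagged) && sum(!flagged) >= 3)
    stats::cor(x[!flagged], y[!flagged]) else cor_all
  list(table = tab, cor_all = cor_all, cor_without_flagged = cor_wo,
       n_flagged = sum(flagged))
}
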