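## Small internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic substream seed for a (subject, task) cell
#'
#' A single global seed is expanded into per-(subject, task) substreams so
#' that generated data do not depend on iteration order. The mixing constants
#' are ordinary LCG multipliers; the result always fits in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param subject_id integer subject index (0 for subject-level trait draws).
#' @param task_index integer task index (0 for trait draws).
#' @return an integer seed suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, subject_id, task_index) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) * 48271 +
    as.numeric(subject_id) * 7919 +
    as.numeric(task_index) * 104729
  as.integer(x %% m)
}

#' Bias-adjusted sample skewness
#'
#' The G1 estimator (as reported by most statistics packages).
#' @param x numeric vector; NAs dropped.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 <= 0) return(NA_real_)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Bias-adjusted sample excess kurtosis
#'
#' The G2 estimator (excess kurtosis; 0 under normality).
#' @param x numeric vector; NAs dropped.
#' @return scalar excess kurtosis.
#' @export
sample_excess_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) return(NA_real_)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}
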