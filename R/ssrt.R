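## Race-model SSRT estimation (constant-SSRT method).

#' Estimate stop-signal reaction time under the independent horse-race model
#'
#' For each stop-signal delay d, the probability of responding p_d is
#' estimated from the stop trials at that delay. All go-trial RTs are rank
#' ordered and the delay is subtracted from the n-th RT, where n equals the
#' number of go RTs multiplied by p_d. Delays with p_d of exactly 0 or 1 are
#' excluded (the relevant order statistic is undefined or degenerate); the
#' final SSRT is the mean of the per-delay estimates over the eligible
#' delays.
#'
#' Non-integer ranks are handled by linear interpolation between the two
#' adjacent order statistics (`rank_mode = "interpolate"`, the default);
#' `"floor"`, `"ceiling"` and `"round"` reproduce integer-rank conventions.
#' Ranks are clamped to `[1, N_go]`.
#'
#' @param go_rts numeric vector of go-trial RTs (ms), already trimmed as
#'   desired; must be non-empty.
#' @param stop_ssd numeric vector of stop-signal delays (ms), one per stop
#'   trial.
#' @param stop_responded logical vector, same length: did the subject
#'   respond on that stop trial?
#' @param rank_mode how to resolve non-integer ranks.
#' @return object of class `ssrt_estimate`: list with `ssrt` (ms, `NA` if no
#'   delay is eligible), `flagged` (TRUE when `ssrt` is missing), `n_go`,
#'   and `per_ssd` (data.frame: `ssd_ms`, `n_stop`, `p_respond`,
#'   `eligible`, `ssrt_d`).
#' @export
estimate_ssrt <- function(go_rts, stop_ssd, stop_responded,
                          rank_mode = c("interpolate", "floor",
                                        "ceiling", "round")) {
  rank_mode <- match.arg(rank_mode)
  go_rts <- go_rts[!is.na(go_rts)]
  if (!length(go_rts)) stop("estimate_ssrt requires at least one go RT")
  stopifnot(length(stop_ssd) == length(stop_responded))
  ok <- !is.na(stop_ssd) & !is.na(stop_responded)
  stop_ssd <- stop_ssd[ok]
  stop_responded <- as.logical(stop_responded[ok])

  sorted <- sort(go_rts)
  n_go <- length(sorted)
  rt_at_rank <- function(n) {
    n <- clamp(n, 1, n_go)
    switch(rank_mode,
      interpolate = {
        lo <- floor(n); hi <- ceiling(n)
        if (lo == hi) sorted[lo]
        else (hi - n) * sorted[lo] + (n - lo) * sorted[hi]
      },
      floor = sorted[max(floor(n), 1)],
      ceiling = sorted[ceiling(n)],
      round = sorted[clamp(round(n), 1, n_go)]
    )
  }

  ssds <- sort(unique(stop_ssd))
  per <- data.frame(ssd_ms = ssds, n_stop = NA_integer_,
                    p_respond = NA_real_, eligible = FALSE,
                    ssrt_d = NA_real_)
  for (k in seq_along(ssds)) {
    i <- stop_ssd == ssds[k]
    per$n_stop[k] <- sum(i)
    p <- mean(stop_responded[i])
    per$p_respond[k] <- p
    if (p > 0 && p < 1) {
      per$eligible[k] <- TRUE
      per$ssrt_d[k] <- rt_at_rank(n_go * p) - ssds[k]
    }
  }
  ssrt <- if (any(per$eligible)) mean(per$ssrt_d[per$eligible]) else NA_real_
  structure(list(ssrt = ssrt, flagged = is.na(ssrt), n_go = n_go,
                 per_ssd = per),
            class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat("SSRT estimate:",
      if (is.na(x$ssrt)) "missing (no eligible SSD)"
      else sprintf("%.1f ms", x$ssrt),
      sprintf("(%d go RTs, %d eligible SSDs)\n",
              x$n_go, sum(x$per_ssd$eligible)))
  print(x$per_ssd, row.names = FALSE)
  invisible(x)
}
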