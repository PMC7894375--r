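## scoring: the six outcome measures under the RT and IES schemes.

## task-specific contrasts: interference condition minus control condition
score_contrasts <- function() {
  list(stroop = c("incongruent", "congruent"),
       flanker = c("noise_incompatible", "no_noise"),
       shape_matching = c("distractor", "no_distractor"),
       word_naming = c("distractor", "no_distractor"))
}

#' Per-subject, per-condition summaries
#'
#' Mean correct RT (computed on the trimmed RT pool) and error rate
#' (incorrect / total scored trials, computed on the *untrimmed* table so
#' that error and anticipation trials keep contributing to the error rate).
#'
#' @param trials raw trial data.frame.
#' @param task optional task filter.
#' @param pool optional pre-trimmed RT pool (from [trim_rt_pool()]);
#'   computed from `trials` if missing.
#' @return data.frame: `subject_id`, `task`, `condition`, `mean_rt_correct`,
#'   `error_rate`, `n_trials`.
#' @export
condition_summary <- function(trials, task = NULL, pool = NULL) {
  dt <- data.table::as.data.table(trials)
  if (!is.null(task)) {
    tk <- task
    dt <- dt[dt$task %in% tk]
  }
  if (is.null(pool)) pool <- trim_rt_pool(as.data.frame(dt))$trials
  pdt <- data.table::as.data.table(pool)
  if (!is.null(task)) pdt <- pdt[pdt$task %in% task]
  er <- dt[, .(error_rate = mean(!correct), n_trials = .N),
           by = .(subject_id, task, condition)]
  mrt <- pdt[correct & !is.na(rt_ms),
             .(mean_rt_correct = mean(rt_ms)),
             by = .(subject_id, task, condition)]
  out <- merge(er, mrt, by = c("subject_id", "task", "condition"),
               all.x = TRUE)
  data.table::setcolorder(out, c("subject_id", "task", "condition",
                                 "mean_rt_correct", "error_rate", "n_trials"))
  data.table::setDF(out)
  out[order(out$subject_id, out$task, out$condition), , drop = FALSE]
}

#' Reaction-time difference scores
#'
#' Task-specific contrast of mean correct RTs: Stroop incongruent minus
#' congruent; flanker noise-incompatible minus no-noise; shape-matching and
#' word-naming distractor minus no-distractor. Negative values are allowed.
#'
#' @param summaries data.frame from [condition_summary()].
#' @param task one of `stroop`, `flanker`, `shape_matching`, `word_naming`.
#' @return data.frame: `subject_id`, `score` (ms).
#' @export
rt_difference_score <- function(summaries, task) {
  con <- score_contrasts()[[task]]
  if (is.null(con)) stop("no RT difference contrast defined for task ", task)
  s <- summaries[summaries$task == task, ]
  hi <- s[s$condition == con[1], c("subject_id", "mean_rt_correct")]
  lo <- s[s$condition == con[2], c("subject_id", "mean_rt_correct")]
  m <- merge(hi, lo, by = "subject_id", suffixes = c("_int", "_ctl"))
  data.frame(subject_id = m$subject_id,
             score = m$mean_rt_correct_int - m$mean_rt_correct_ctl)
}

#' Antisaccade error-proportion score
#'
#' The proportion of errors in the antisaccade target trials (the standard
#' outcome for this task under the RT scheme).
#'
#' @param summaries data.frame from [condition_summary()].
#' @return data.frame: `subject_id`, `score` (proportion in `[0, 1]`).
#' @export
antisaccade_error_score <- function(summaries) {
  s <- summaries[summaries$task == "antisaccade" &
                   summaries$condition == "target", ]
  data.frame(subject_id = s$subject_id, score = s$error_rate)
}

#' Inverse efficiency score
#'
#' Mean correct RT divided by the proportion of correct responses,
#' `RT / (1 - ER)`, in ms. Combines speed and accuracy into one measure; an
#' error rate of 1 yields a missing value (flagged by the caller).
#'
#' @param mean_rt_correct mean correct RT (ms).
#' @param error_rate proportion of errors in `[0, 1]`.
#' @return IES in ms (vectorized); `NA` where `error_rate == 1`.
#' @export
inverse_efficiency <- function(mean_rt_correct, error_rate) {
  stopifnot(all(error_rate >= 0 & error_rate <= 1, na.rm = TRUE))
  out <- mean_rt_correct / (1 - error_rate)
  out[!is.na(error_rate) & error_rate == 1] <- NA_real_
  out
}

#' Inverse-efficiency difference scores
#'
#' IES computed per condition, then contrasted with the same task-specific
#' contrasts as [rt_difference_score()]. The antisaccade score is the
#' single-condition IES of the target trials (no contrast).
#'
#' @param summaries data.frame from [condition_summary()].
#' @param task one of `antisaccade`, `stroop`, `flanker`, `shape_matching`,
#'   `word_naming`.
#' @return data.frame: `subject_id`, `score` (ms).
#' @export
ies_difference_score <- function(summaries, task) {
  s <- summaries[summaries$task == task, ]
  s$ies <- inverse_efficiency(s$mean_rt_correct, s$error_rate)
  if (task == "antisaccade") {
    s <- s[s$condition == "target", ]
    return(data.frame(subject_id = s$subject_id, score = s$ies))
  }
  con <- score_contrasts()[[task]]
  if (is.null(con)) stop("no IES contrast defined for task ", task)
  hi <- s[s$condition == con[1], c("subject_id", "ies")]
  lo <- s[s$condition == con[2], c("subject_id", "ies")]
  m <- merge(hi, lo, by = "subject_id", suffixes = c("_int", "_ctl"))
  data.frame(subject_id = m$subject_id, score = m$ies_int - m$ies_ctl)
}

ssrt_scores <- function(trials, pool) {
  stop_raw <- trials[trials$task == "stop_signal" &
                       trials$condition == "stop", , drop = FALSE]
  go_pool <- pool[pool$task == "stop_signal" & pool$condition == "go" &
                    pool$correct & !is.na(pool$rt_ms), , drop = FALSE]
  ids <- sort(unique(trials$subject_id[trials$task == "stop_signal"]))
  res <- data.frame(subject_id = ids, score = NA_real_)
  diags <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    g <- go_pool$rt_ms[go_pool$subject_id == id]
    st <- stop_raw[stop_raw$subject_id == id, ]
    if (!length(g) || !nrow(st)) next
    est <- estimate_ssrt(g, st$ssd_ms, st$responded)
    res$score[k] <- est$ssrt
    d <- est$per_ssd
    d$subject_id <- id
    diags[[k]] <- d
  }
  attr(res, "per_ssd") <- do.call(rbind, diags)
  res
}

#' Build the N x 6 outcome matrix
#'
#' Applies the scheme's scoring rules to every task present in `trials`,
#' then winsorizes each outcome column between subjects (3 SD rule). Under
#' both schemes the stop-signal column is the race-model SSRT: it already
#' accounts for speed and accuracy, so no IES is computed for it. Lower
#' scores indicate better performance in all columns.
#'
#' @param trials raw trial data.frame.
#' @param scheme `"RT"` (difference scores; antisaccade error proportion) or
#'   `"IES"` (inverse-efficiency difference scores; antisaccade single-
#'   condition IES).
#' @param bounds per-task RT bounds for the trimming chain.
#' @param winsorize_k SD multiplier for the trimming steps; `NULL` disables
#'   the between-subject step.
#' @return data.frame with `subject_id` and one column per task, attributes
#'   `scheme`, `trim_report`, and `ssrt_per_ssd` (per-SSD diagnostics).
#'   Subjects with no eligible stop-signal delay get `NA` SSRT.
#' @export
build_outcome_matrix <- function(trials, scheme = c("RT", "IES"),
                                 bounds = default_trim_bounds(),
                                 winsorize_k = 3) {
  scheme <- match.arg(scheme)
  trimmed <- trim_rt_pool(trials, bounds, k = winsorize_k %||% 3)
  pool <- trimmed$trials
  summaries <- condition_summary(trials, pool = pool)
  tasks <- intersect(inhibition_tasks(), unique(trials$task))
  out <- data.frame(subject_id = sort(unique(trials$subject_id)))
  ssrt_diag <- NULL
  for (t in tasks) {
    sc <- if (t == "stop_signal") {
      s <- ssrt_scores(trials, pool)
      ssrt_diag <- attr(s, "per_ssd")
      s
    } else if (t == "antisaccade") {
      if (scheme == "RT") antisaccade_error_score(summaries)
      else ies_difference_score(summaries, t)
    } else {
      if (scheme == "RT") rt_difference_score(summaries, t)
      else ies_difference_score(summaries, t)
    }
    names(sc)[2] <- t
    out <- merge(out, sc, by = "subject_id", all.x = TRUE)
  }
  if (!is.null(winsorize_k)) {
    w <- winsorize_between_subjects(out, k = winsorize_k)
    out <- w$outcomes
    trimmed$report <- rbind(trimmed$report, w$report)
  }
  attr(out, "scheme") <- scheme
  attr(out, "trim_report") <- trimmed$report
  attr(out, "ssrt_per_ssd") <- ssrt_diag
  out
}
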