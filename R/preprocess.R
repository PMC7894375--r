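## preprocessing: the four-step robust trimming protocol for RT data.
## Fixed order: drop invalid -> fixed bounds -> within-subject 3 SD ->
## (score) -> between-subject 3 SD.

#' Default per-task RT winsorizing bounds (ms)
#'
#' Stroop (400, 2000); word-naming (200, 1000); shape-matching, stop-signal
#' and antisaccade (200, 2000); flanker (200, 1500).
#'
#' @return data.frame with columns `task`, `lower`, `upper`.
#' @export
default_trim_bounds <- function() {
  data.frame(
    task = inhibition_tasks(),
    lower = c(200, 400, 200, 200, 200, 200),
    upper = c(2000, 2000, 2000, 1500, 2000, 1000)
  )
}

trim_report_row <- function(task, step, n_affected, n_total) {
  data.frame(task = task, step = step,
             n_affected = n_affected, n_total = n_total,
             fraction = ifelse(n_total > 0, n_affected / n_total, 0))
}

#' Step 1: drop error trials and anticipations from the RT pool
#'
#' Removes from the reaction-time pool every trial that is incorrect, has no
#' recorded RT (successful stops), or has RT below 200 ms. Error counts are
#' not affected: error rates are always computed on the full trial table,
#' which this function leaves to the caller (it returns only the RT pool).
#'
#' @param trials trial data.frame (see [generate_battery()]).
#' @return list with `trials` (the RT pool) and `report` (a trim report
#'   data.frame; fraction of RT-bearing trials removed, per task).
#' @export
drop_invalid_trials <- function(trials) {
  if (nrow(trials) == 0L)
    return(list(trials = trials,
                report = trim_report_row(character(), character(),
                                         integer(), integer())[0, ]))
  has_rt <- !is.na(trials$rt_ms)
  keep <- has_rt & trials$correct & trials$rt_ms >= 200
  rep_list <- lapply(unique(trials$task), function(t) {
    i <- trials$task == t & has_rt
    trim_report_row(t, "drop_invalid", sum(i & !keep), sum(i))
  })
  list(trials = trials[keep, , drop = FALSE],
       report = do.call(rbind, rep_list))
}

#' Step 2: winsorize RTs to fixed per-task bounds
#'
#' Replaces any RT outside the task's fixed lower/upper criterion with the
#' criterion value. Trial order is preserved.
#'
#' @param trials RT-pool data.frame.
#' @param bounds data.frame as from [default_trim_bounds()].
#' @return list with `trials` and `report` (fraction of trials altered).
#' @export
winsorize_to_bounds <- function(trials, bounds = default_trim_bounds()) {
  stopifnot(all(bounds$lower < bounds$upper))
  out <- trials
  rep_list <- list()
  for (k in seq_len(nrow(bounds))) {
    t <- bounds$task[k]
    i <- which(out$task == t & !is.na(out$rt_ms))
    if (!length(i)) next
    old <- out$rt_ms[i]
    new <- clamp(old, bounds$lower[k], bounds$upper[k])
    out$rt_ms[i] <- new
    rep_list[[t]] <- trim_report_row(t, "bounds", sum(new != old), length(i))
  }
  report <- if (length(rep_list)) do.call(rbind, rep_list) else
    trim_report_row(character(), character(), integer(), integer())[0, ]
  list(trials = out, report = report)
}

#' Step 3: within-subject 3 SD winsorizing
#'
#' Within each (subject, task, condition) cell, RTs farther than `k` SD from
#' the cell mean are replaced with the mean +/- `k` SD boundary. Mean and SD
#' are computed once on the untouched cell (single replacement pass). The
#' stop-signal task is exempt: its dependent measure (SSRT) is not driven by
#' extreme RTs. Cells with fewer than 2 trials or zero SD are left unchanged.
#'
#' @param trials RT-pool data.frame.
#' @param k SD multiplier (default 3).
#' @return list with `trials` and `report`.
#' @export
winsorize_within_subject <- function(trials, k = 3) {
  dt <- data.table::as.data.table(trials)
  dt[, `..row` := .I]
  tgt <- dt[task != "stop_signal" & !is.na(rt_ms)]
  if (nrow(tgt)) {
    tgt[, c("..m", "..s") := .(mean(rt_ms), stats::sd(rt_ms)),
        by = .(subject_id, task, condition)]
    tgt[, `..n` := .N, by = .(subject_id, task, condition)]
    tgt[, `..new` := rt_ms]
    ok <- tgt$`..n` >= 2L & !is.na(tgt$`..s`) & tgt$`..s` > 0
    tgt$`..new`[ok] <- clamp(tgt$rt_ms[ok],
                             tgt$`..m`[ok] - k * tgt$`..s`[ok],
                             tgt$`..m`[ok] + k * tgt$`..s`[ok])
    out <- trials
    out$rt_ms[tgt$`..row`] <- tgt$`..new`
    changed <- tgt[, .(n_affected = sum(`..new` != rt_ms), n_total = .N),
                   by = task]
    report <- do.call(rbind, lapply(seq_len(nrow(changed)), function(i)
      trim_report_row(changed$task[i], "within_subject_3sd",
                      changed$n_affected[i], changed$n_total[i])))
  } else {
    out <- trials
    report <- trim_report_row(character(), character(), integer(),
                              integer())[0, ]
  }
  list(trials = out, report = report)
}

#' Step 4: between-subject 3 SD winsorizing of outcome scores
#'
#' Applied to each final outcome variable across subjects: observations
#' farther than `k` SD from the group mean are replaced with the mean +/-
#' `k` SD boundary (moments from the pre-replacement distribution).
#' Constant columns and columns with fewer than 2 non-missing values are
#' returned unchanged.
#'
#' @param outcomes data.frame of per-subject scores; all numeric columns
#'   except `subject_id` are winsorized.
#' @param k SD multiplier (default 3).
#' @return list with `outcomes` and `report`.
#' @export
winsorize_between_subjects <- function(outcomes, k = 3) {
  out <- outcomes
  cols <- setdiff(names(outcomes)[vapply(outcomes, is.numeric, TRUE)],
                  "subject_id")
  rep_list <- list()
  for (cl in cols) {
    x <- out[[cl]]
    i <- which(!is.na(x))
    if (length(i) < 2L) next
    m <- mean(x[i]); s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) {
      rep_list[[cl]] <- trim_report_row(cl, "between_subject_3sd",
                                        0L, length(i))
      next
    }
    new <- clamp(x[i], m - k * s, m + k * s)
    rep_list[[cl]] <- trim_report_row(cl, "between_subject_3sd",
                                      sum(new != x[i]), length(i))
    out[[cl]][i] <- new
  }
  list(outcomes = out, report = do.call(rbind, rep_list))
}

#' Run the trial-level trimming chain (steps 1-3)
#'
#' Convenience wrapper producing the trimmed RT pool used for all mean-RT
#' computations: drop invalid trials, winsorize to fixed bounds, winsorize
#' within subject. Error rates must be computed on the original table.
#'
#' @param trials trial data.frame.
#' @param bounds per-task bounds, see [default_trim_bounds()].
#' @param k within-subject SD multiplier.
#' @return list with `trials` (RT pool) and `report` (stacked trim reports).
#' @export
trim_rt_pool <- function(trials, bounds = default_trim_bounds(), k = 3) {
  s1 <- drop_invalid_trials(trials)
  s2 <- winsorize_to_bounds(s1$trials, bounds)
  s3 <- winsorize_within_subject(s2$trials, k)
  list(trials = s3$trials,
       report = rbind(s1$report, s2$report, s3$report))
}
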