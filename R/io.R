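## trial-table I/O: comma-separated text with a fixed header; empty field
## encodes an absent value (e.g. no RT on a successfully stopped trial).

trial_columns <- function() {
  c("subject_id", "task", "condition", "trial_index", "rt_ms", "correct",
    "ssd_ms", "responded")
}

#' Write a trial table to a delimited text file
#'
#' Comma-separated, header `subject_id, task, condition, trial_index,
#' rt_ms, correct, ssd_ms, responded`; missing values are written as empty
#' fields. [read_trials()] round-trips the result losslessly.
#'
#' @param trials trial data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns() %in% names(trials)))
  utils::write.table(trials[, trial_columns()], path, sep = ",",
                     na = "", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the delimited format written by [write_trials()] and validates it
#' row by row: known task names, condition labels valid for the task, SSD
#' and responded present if and only if the trial is a stop trial, SSD on
#' the 0-500 ms grid, missing RT only on unanswered stop trials. Errors
#' name the offending data rows.
#'
#' @param path input file path.
#' @param conditions named list of valid condition labels per task
#'   (defaults to the canonical labels of [default_trial_plan()]).
#' @return validated trial data.frame.
#' @export
read_trials <- function(path, conditions = NULL) {
  if (is.null(conditions))
    conditions <- lapply(default_trial_plan(), function(p) p$condition)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "integer",
                                       task = "character",
                                       condition = "character",
                                       trial_index = "integer",
                                       rt_ms = "numeric",
                                       correct = "logical",
                                       ssd_ms = "numeric",
                                       responded = "logical"))
  missing_cols <- setdiff(trial_columns(), names(df))
  if (length(missing_cols))
    stop("trial file lacks column(s): ", paste(missing_cols, collapse = ", "))

  fail <- function(rows, what) {
    rows <- utils::head(rows, 10)
    stop("invalid trial file '", path, "': ", what,
         " at data row(s) ", paste(rows, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$task %in% inhibition_tasks())
  if (length(bad)) fail(bad, paste0("unknown task label(s) '",
                                    paste(unique(df$task[bad]), collapse = "', '"), "'"))
  for (t in unique(df$task)) {
    i <- which(df$task == t)
    bad <- i[!df$condition[i] %in% conditions[[t]]]
    if (length(bad))
      fail(bad, paste0("condition label invalid for task '", t, "'"))
  }
  is_stop <- df$task == "stop_signal" & df$condition == "stop"
  bad <- which(is_stop & (is.na(df$ssd_ms) | is.na(df$responded)))
  if (length(bad)) fail(bad, "stop trial lacks ssd_ms or responded")
  bad <- which(is_stop & !df$ssd_ms %in% seq(0, 500, 100))
  if (length(bad)) fail(bad, "ssd_ms outside the 0-500 ms grid")
  bad <- which(!is_stop & (!is.na(df$ssd_ms) | !is.na(df$responded)))
  if (length(bad)) fail(bad, "ssd_ms/responded present on a non-stop trial")
  bad <- which(is.na(df$rt_ms) & !(is_stop & !df$responded))
  if (length(bad)) fail(bad, "rt_ms absent on a trial that was responded to")
  bad <- which(!is.na(df$rt_ms) & df$rt_ms < 0)
  if (length(bad)) fail(bad, "negative rt_ms")
  df
}

#' Write an outcome matrix to a delimited text file
#'
#' `subject_id`, the six score columns, plus a `scheme` tag column.
#'
#' @param outcomes data.frame from [build_outcome_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  out <- outcomes
  out$scheme <- attr(outcomes, "scheme") %||% NA_character_
  utils::write.table(out, path, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
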