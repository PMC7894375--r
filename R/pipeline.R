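## pipeline: orchestrate generate/ingest -> trim -> score -> psychometrics
## -> CFA -> report.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (use `generator`) or `"ingest"` (read trials
#'   from `input_path`); exactly one source must be active.
#' @param generator a [generator_config()] (simulate mode).
#' @param input_path path to a trial file (ingest mode; see
#'   [read_trials()]).
#' @param scheme `"RT"`, `"IES"`, or `"both"`.
#' @param models model kinds to fit (the null baseline is always fitted).
#' @param bootstrap_B bootstrap resamples for the two-related-factor model
#'   (0 disables the bootstrap stage).
#' @param seed integer seed for seed-dependent stages (bootstrap; and the
#'   generator if its config carries no seed).
#' @param output_dir if non-NULL, [render_report()] writes report files
#'   here.
#' @param include_means AIC parameter-count convention (see
#'   [fit_indices()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            generator = NULL, input_path = NULL,
                            scheme = c("both", "RT", "IES"),
                            models = c("null", "one_factor", "two_related",
                                       "two_unrelated"),
                            bootstrap_B = 0, seed = 1L,
                            output_dir = NULL, include_means = TRUE) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if (mode == "simulate" && is.null(generator))
    stop("simulate mode requires a generator config")
  if (mode == "ingest" && is.null(input_path))
    stop("ingest mode requires input_path")
  if (!is.null(generator) && !is.null(input_path))
    stop("exactly one of generator/input_path may be active")
  structure(list(mode = mode, generator = generator,
                 input_path = input_path, scheme = scheme, models = models,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 output_dir = output_dir, include_means = include_means),
            class = "pipeline_config")
}

## Table-1-style condition descriptives across subjects
condition_descriptives <- function(summaries) {
  dt <- data.table::as.data.table(summaries)
  dt$ies <- inverse_efficiency(dt$mean_rt_correct, dt$error_rate)
  stat <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(NA_real_, NA_real_, NA_real_, NA_real_))
    list(mean(x), stats::sd(x), min(x), max(x))
  }
  out <- dt[, c(.(n_subjects = .N),
                stats::setNames(stat(mean_rt_correct),
                                c("rt_mean", "rt_sd", "rt_min", "rt_max")),
                stats::setNames(stat(error_rate),
                                c("er_mean", "er_sd", "er_min", "er_max")),
                stats::setNames(stat(ies),
                                c("ies_mean", "ies_sd", "ies_min",
                                  "ies_max"))),
            by = .(task, condition)]
  data.table::setDF(out)
  out
}

## Table-2-style outcome descriptives (bias-adjusted skew, excess kurtosis)
outcome_descriptives <- function(outcomes) {
  cols <- setdiff(names(outcomes), "subject_id")
  rows <- lapply(cols, function(cl) {
    x <- outcomes[[cl]]
    x <- x[!is.na(x)]
    data.frame(task = cl, n = length(x), mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x),
               skewness = sample_skewness(x),
               excess_kurtosis = sample_excess_kurtosis(x))
  })
  do.call(rbind, rows)
}

run_scheme <- function(trials, scheme, config, summaries) {
  outcomes <- build_outcome_matrix(trials, scheme = scheme)
  X <- as.matrix(outcomes[, inhibition_tasks(), drop = FALSE])
  complete <- stats::complete.cases(X)
  res <- list(scheme = scheme,
              outcomes = outcomes,
              descriptives = outcome_descriptives(outcomes),
              spearman = spearman_correlation_matrix(outcomes),
              reliability = do.call(rbind, lapply(inhibition_tasks(),
                function(t) as.data.frame(
                  split_half_reliability(trials, t, scheme)))),
              mardia = if (sum(complete) > 7)
                mardia(X[complete, , drop = FALSE]),
              n_complete = sum(complete))
  if (sum(complete) > 12) {
    S <- stats::cov(X[complete, , drop = FALSE])
    res$fits <- fit_cfa_models(S, sum(complete), models = config$models,
                               include_means = config$include_means)
    res$fit_table <- compare_models(res$fits)
    if (config$bootstrap_B > 0 && "two_related" %in% config$models)
      res$bootstrap <- bootstrap_fit(outcomes, "two_related",
                                     B = config$bootstrap_B,
                                     seed = config$seed)
  }
  res
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) trial-level data, apply the trimming protocol,
#' score both outcome schemes, estimate reliabilities and Spearman
#' correlations, check multivariate normality, and fit the candidate CFA
#' models. Deterministic under a fixed seed. A failure in one scheme does
#' not abort the other.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`: `trials` info, `trim_report`,
#'   `condition_descriptives`, and one entry per scheme (`RT`, `IES`) with
#'   outcomes, descriptives, reliability, Spearman matrices, Mardia
#'   diagnostics, CFA fits, fit table and optional bootstrap; plus `seed`
#'   and `config` provenance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  trials <- if (config$mode == "simulate") {
    generate_battery(config$generator)
  } else {
    read_trials(config$input_path)
  }
  if (length(unique(trials$subject_id)) < 2L)
    stop("pipeline requires at least 2 subjects")
  trimmed <- trim_rt_pool(trials)
  summaries <- condition_summary(trials, pool = trimmed$trials)
  schemes <- if (config$scheme == "both") c("RT", "IES") else config$scheme
  per_scheme <- list()
  for (s in schemes) {
    per_scheme[[s]] <- tryCatch(
      run_scheme(trials, s, config, summaries),
      error = function(e) {
        warning("scheme ", s, " failed: ", conditionMessage(e))
        list(scheme = s, error = conditionMessage(e))
      })
  }
  report <- structure(list(
    n_subjects = length(unique(trials$subject_id)),
    n_trials = nrow(trials),
    trim_report = trimmed$report,
    condition_descriptives = condition_descriptives(summaries),
    schemes = per_scheme,
    seed = config$seed,
    config = config
  ), class = "pipeline_report")
  if (!is.null(config$output_dir))
    render_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("inhibitory-control pipeline report: %d subjects, %d trials\n",
              x$n_subjects, x$n_trials))
  for (s in names(x$schemes)) {
    sc <- x$schemes[[s]]
    if (!is.null(sc$error)) {
      cat(sprintf("scheme %s: FAILED (%s)\n", s, sc$error))
      next
    }
    cat(sprintf("\nscheme %s (%d complete subjects):\n", s, sc$n_complete))
    if (!is.null(sc$fit_table))
      print(sc$fit_table[, c("model", "df", "chi_square", "RMSEA", "SRMR",
                             "CFI", "AIC", "NFI")], digits = 4,
            row.names = FALSE)
  }
  invisible(x)
}
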