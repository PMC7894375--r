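## report rendering: machine-readable (JSON) and human-readable (delimited
## tables, fit table with threshold annotations).

write_matrix_csv <- function(m, path) {
  utils::write.table(data.frame(variable = rownames(m), m,
                                check.names = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Render a pipeline report to files
#'
#' Writes, per run: trim report, condition and outcome descriptives,
#' reliability table, Spearman correlation matrices (with p-values),
#' Table-style CFA fit tables with verbal threshold annotations, outcome
#' matrices, and a machine-readable `report.json` carrying the same
#' numbers.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = ",",
                       row.names = FALSE, quote = FALSE, na = "")
  wcsv(report$trim_report, "trim_report.csv")
  wcsv(report$condition_descriptives, "condition_descriptives.csv")

  json <- list(n_subjects = report$n_subjects,
               n_trials = report$n_trials,
               seed = report$seed,
               schemes = list())
  for (s in names(report$schemes)) {
    sc <- report$schemes[[s]]
    if (!is.null(sc$error)) next
    tag <- tolower(s)
    wcsv(sc$descriptives, paste0("outcome_descriptives_", tag, ".csv"))
    wcsv(sc$reliability, paste0("reliability_", tag, ".csv"))
    write_matrix_csv(round(sc$spearman$rho, 4),
                     file.path(dir, paste0("spearman_rho_", tag, ".csv")))
    write_matrix_csv(signif(sc$spearman$p, 4),
                     file.path(dir, paste0("spearman_p_", tag, ".csv")))
    write_outcomes(sc$outcomes, file.path(dir, paste0("outcomes_", tag,
                                                      ".csv")))
    entry <- list(descriptives = sc$descriptives,
                  reliability = sc$reliability,
                  mardia = list(b1p = sc$mardia$b1p, b2p = sc$mardia$b2p,
                                skew_p = sc$mardia$skew_p,
                                kurtosis_p = sc$mardia$kurtosis_p,
                                n_flagged = sum(sc$mardia$flagged)))
    if (!is.null(sc$fit_table)) {
      wcsv(sc$fit_table, paste0("fit_table_", tag, ".csv"))
      entry$fit_table <- sc$fit_table
      writeLines(format_fit_table(sc$fit_table, s),
                 file.path(dir, paste0("fit_table_", tag, ".txt")))
    }
    if (!is.null(sc$bootstrap)) {
      wcsv(sc$bootstrap$estimates, paste0("bootstrap_", tag, ".csv"))
      entry$bootstrap <- sc$bootstrap$estimates
    }
    json$schemes[[s]] <- entry
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(dir)
}

## plain-text fit table in the conventional column order, with threshold
## annotations
format_fit_table <- function(ft, scheme) {
  hdr <- sprintf("CFA fit (%s scheme)", scheme)
  lines <- c(hdr, strrep("-", nchar(hdr)),
             sprintf("%-15s %3s %9s %7s %7s %7s %9s %7s  %s",
                     "model", "df", "chi2", "RMSEA", "SRMR", "CFI", "AIC",
                     "NFI", "assessment"))
  for (i in seq_len(nrow(ft))) {
    lines <- c(lines, sprintf(
      "%-15s %3d %9.3f %7.3f %7.3f %7.3f %9.3f %7.3f  RMSEA %s, SRMR %s%s",
      ft$model[i], ft$df[i], ft$chi_square[i], ft$RMSEA[i], ft$SRMR[i],
      ft$CFI[i], ft$AIC[i], ft$NFI[i], ft$rmsea_label[i], ft$srmr_label[i],
      if (ft$converged[i]) "" else " [NOT CONVERGED]"))
  }
  c(lines, "", sprintf("preferred by AIC: %s", attr(ft, "preferred")))
}
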