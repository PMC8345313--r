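# Report formatting and serialization: the stepwise grid, measurement-model
# and bifactor blocks, and Williams comparisons, in publication-table shape.

format_p <- function(p) ifelse(is.na(p), "NA",
                               ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))

#' Format an analysis report for display or export
#'
#' Rounds to the conventional table precision: standardized betas and CIs to
#' 3 decimals, fit indices to 3, p-values to 3 with \code{"<0.001"} below
#' threshold.
#'
#' @param report an \code{analysis_report}.
#' @return list of formatted data.frames (\code{stepwise},
#'   \code{measurement}, \code{bifactor}, \code{comparisons}).
#' @export
format_report <- function(report) {
  sw <- report$stepwise
  stepwise <- data.frame(
    Outcome = sw$outcome, Predictor = sw$predictor, Covariates = sw$step,
    `Standardized beta (SE)` = sprintf("%.3f (%.2f)", sw$beta, sw$se),
    `95% CI` = sprintf("%.3f, %.3f", sw$ci_lower, sw$ci_upper),
    `Uncorrected p` = format_p(sw$p_raw),
    `FDR corrected p` = format_p(sw$p_fdr),
    RMSEA = sprintf("%.3f", sw$rmsea), CFI = sprintf("%.3f", sw$cfi),
    TLI = sprintf("%.3f", sw$tli), SRMR = sprintf("%.3f", sw$srmr),
    Flags = sw$flags, check.names = FALSE, stringsAsFactors = FALSE)
  bf <- report$bifactor_block
  bifactor <- data.frame(
    Factor = bf$factor,
    `Standardized beta (SE)` = sprintf("%.3f (%.2f)", bf$beta, bf$se),
    `95% CI` = sprintf("%.3f, %.3f", bf$ci_lower, bf$ci_upper),
    `Uncorrected p` = format_p(bf$p_raw),
    `FDR corrected p` = format_p(bf$p_fdr),
    Flags = bf$flags, check.names = FALSE, stringsAsFactors = FALSE)
  comparisons <- lapply(report$comparisons, function(cmp) {
    data.frame(Outcome = cmp$outcome,
               t = sprintf("%.2f", cmp$t_value), df = cmp$df,
               `one-sided p` = format_p(cmp$p_one_sided),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  list(stepwise = stepwise,
       measurement = within(report$measurement, {
         rmsea <- sprintf("%.3f", rmsea); cfi <- sprintf("%.3f", cfi)
         tli <- sprintf("%.3f", tli); srmr <- sprintf("%.3f", srmr)
       }),
       bifactor = bifactor, comparisons = comparisons)
}

#' @export
print.analysis_report <- function(x, ...) {
  fr <- format_report(x)
  cat(sprintf("Analysis report (n = %d; FDR family: %s)\n", x$n, x$fdr_family))
  cat("\nMeasurement models:\n")
  print(fr$measurement, row.names = FALSE)
  cat("\nStepwise latent regressions:\n")
  print(fr$stepwise[, 1:7], row.names = FALSE)
  cat("\nBifactor SVD paths:\n")
  print(fr$bifactor, row.names = FALSE)
  for (nm in names(fr$comparisons)) {
    cat("\nWilliams comparisons (", nm, "):\n", sep = "")
    print(fr$comparisons[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' One CSV per table analogue (raw numeric and formatted), plus a JSON
#' results bundle.
#'
#' @param report an \code{analysis_report}.
#' @param dir output directory (created if absent).
#' @param format \code{"csv"} (default) or \code{"md"} for the formatted
#'   tables.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "md")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$stepwise, file.path(dir, "stepwise_raw.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bifactor_block, file.path(dir, "bifactor_raw.csv"),
                   row.names = FALSE)
  fr <- format_report(report)
  if (format == "csv") {
    utils::write.csv(fr$stepwise, file.path(dir, "stepwise_formatted.csv"),
                     row.names = FALSE)
    utils::write.csv(fr$bifactor, file.path(dir, "bifactor_formatted.csv"),
                     row.names = FALSE)
  } else {
    md_table <- function(df) {
      hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
      body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      c(hdr, sep, body)
    }
    writeLines(md_table(fr$stepwise), file.path(dir, "stepwise.md"))
    writeLines(md_table(fr$bifactor), file.path(dir, "bifactor.md"))
  }
  bundle <- list(
    n = report$n, fdr_family = report$fdr_family,
    measurement = report$measurement,
    stepwise = report$stepwise,
    bifactor = report$bifactor_block,
    bifactor_fit = list(rmsea = report$bifactor_indices$rmsea,
                        cfi = report$bifactor_indices$cfi,
                        tli = report$bifactor_indices$tli,
                        srmr = report$bifactor_indices$srmr),
    comparisons = report$comparisons)
  jsonlite::write_json(bundle, file.path(dir, "results_bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(dir)
}
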