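comparisonToList <- function(cmp) {
  out <- list(test = cmp@testName, statistic = cmp@statistic,
              p_value = cmp@pValue,
              groups = cmp@groupSummaries[order(cmp@groupSummaries$group), ])
  if (!is.null(cmp@tukey)) out$tukey <- cmp@tukey
  out
}

#' Assemble a machine- and human-readable session report
#'
#' Builds a deterministic summary bundle from any subset of upstream
#' outputs: per-group AUC summaries (mean +/- SEM), per-category vesicle
#' density summaries, and a table of group tests.  Re-rendering identical
#' inputs produces byte-identical JSON (keys and rows are sorted).
#'
#' @param auc named list of numeric AUC vectors (one per group), or `NULL`.
#' @param densityRecords data.frame from [densityKinetics()], or `NULL`.
#' @param comparisons named list of [GroupComparisonResult-class], or
#'   `NULL`.
#' @param dir optional output directory; writes `report.json` plus
#'   `auc_summary.csv`, `density_summary.csv` and `tests.csv` as
#'   applicable.
#' @return the report list, invisibly when `dir` is given.
#' @export
renderReport <- function(auc = NULL, densityRecords = NULL,
                         comparisons = NULL, dir = NULL) {
  report <- list()
  if (!is.null(auc) && length(auc)) {
    auc <- auc[order(names(auc))]
    report$auc <- data.frame(
      group = names(auc),
      n = vapply(auc, length, integer(1)),
      mean_auc_min = vapply(auc, mean, numeric(1)),
      sem = vapply(auc, sem, numeric(1)), row.names = NULL)
  }
  if (!is.null(densityRecords) && nrow(densityRecords)) {
    agg <- aggregateDensity(densityRecords)
    final <- agg[agg$time_min == max(agg$time_min), ]
    report$density <- final[order(final$category), ]
    rownames(report$density) <- NULL
  }
  if (!is.null(comparisons) && length(comparisons)) {
    comparisons <- comparisons[order(names(comparisons))]
    report$tests <- data.frame(
      comparison = names(comparisons),
      test = vapply(comparisons, function(x) x@testName, character(1)),
      statistic = vapply(comparisons, function(x) x@statistic, numeric(1)),
      p_value = vapply(comparisons, function(x) x@pValue, numeric(1)),
      row.names = NULL)
    report$testDetails <- lapply(comparisons, comparisonToList)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(report$auc))
      write.csv(report$auc, file.path(dir, "auc_summary.csv"),
                row.names = FALSE)
    if (!is.null(report$density))
      write.csv(report$density, file.path(dir, "density_summary.csv"),
                row.names = FALSE)
    if (!is.null(report$tests))
      write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}
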