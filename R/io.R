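#' Write a cohort to CSV
#'
#' One row per patient: `patient_id`, the ten CAFPA columns, the
#' `";"`-joined `labels` column, then any measurement columns.  UTF-8,
#' header row, `.` decimal separator.  Identical cohorts produce
#' byte-identical files.
#'
#' @param cohort Cohort data frame.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_cohort <- function(cohort, file) {
  cohort_cafpas(cohort)   # validates
  utils::write.csv(cohort, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a cohort from CSV
#'
#' @param file Path to a CSV written by [write_cohort()] (or with the same
#'   layout).
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(file) {
  cohort <- utils::read.csv(file, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (!all(c("patient_id", "labels") %in% names(cohort)))
    stop("cohort file must have 'patient_id' and 'labels' columns",
         call. = FALSE)
  cohort_cafpas(cohort)   # validates CAFPA columns and range
  if (any(is.na(cohort$labels) | cohort$labels == ""))
    stop("every patient must carry at least one label", call. = FALSE)
  cohort
}

# Write a numeric table with stable formatting (byte-identical reruns).
write_table_csv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}
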