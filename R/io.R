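#' Write the clinical table as CSV
#' @param clinical a [generate_cohort()] table
#' @param path output file
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a clinical table written by [write_clinical_csv()]
#' @param path CSV file
#' @return a `clinical_table`
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$menopausal_status <- factor(df$menopausal_status, c("pre", "post"))
  df$surgery <- factor(df$surgery, c("BCS", "mastectomy", "PRE"))
  df$endocrine <- factor(df$endocrine,
                         c("none", "tamoxifen", "AI", "AI_goserelin", "unknown"))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a simulation truth ledger as JSON
#' @param truth the `truth` element of a simulated block or spectrum set
#' @param path output file
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
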