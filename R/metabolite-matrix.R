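#' Construct a samples-by-variables metabolite matrix
#'
#' The central data container: a numeric matrix of concentrations with sample
#' metadata (patient, timepoint) and variable metadata (platform, chemical
#' class, limit of detection). Below-LOD cells are stored as an explicit
#' censored state (`censored` logical matrix; the corresponding `values` cell
#' is NA) rather than as numbers, so the QC stage owns the LOD/2 rule.
#' Missing cells are NA with `censored` FALSE.
#'
#' @param values numeric matrix, samples in rows, variables in columns
#' @param sample_meta data.frame with columns `patient_id`, `timepoint_months`
#' @param variable_meta data.frame with columns `name`, `platform`
#'   (MRS/MS/LIPO), `class`, `lod`
#' @param censored logical matrix marking below-LOD cells (default none)
#' @param truth optional simulation ground-truth ledger
#' @return object of class `metabolite_matrix`
#' @export
metabolite_matrix <- function(values, sample_meta, variable_meta,
                              censored = NULL, truth = NULL) {
  values <- as.matrix(values)
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(values), ncol(values))
  }
  sid <- paste0(sample_meta$patient_id, "_t", sample_meta$timepoint_months)
  if (anyDuplicated(sid)) stopf("metabolite_matrix: duplicate (patient, timepoint) rows")
  if (anyDuplicated(variable_meta$name)) stopf("metabolite_matrix: duplicate variable names")
  if (ncol(values) != nrow(variable_meta) || nrow(values) != nrow(sample_meta))
    stopf("metabolite_matrix: dimension mismatch")
  if (any(variable_meta$lod < 0, na.rm = TRUE)) stopf("metabolite_matrix: lod must be >= 0")
  if (any(values < 0, na.rm = TRUE)) stopf("metabolite_matrix: concentrations must be non-negative")
  dimnames(values) <- list(sid, variable_meta$name)
  dimnames(censored) <- dimnames(values)
  structure(list(values = values, censored = censored,
                 sample_meta = cbind(sample_id = sid, sample_meta),
                 variable_meta = variable_meta, truth = truth),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$variable_meta$platform), collapse = "/")))
  cat(sprintf("  patients: %d  timepoints: %s  censored cells: %d  missing cells: %d\n",
              length(unique(x$sample_meta$patient_id)),
              paste(sort(unique(x$sample_meta$timepoint_months)), collapse = "/"),
              sum(x$censored), sum(is.na(x$values) & !x$censored)))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)

#' Subset a metabolite matrix
#'
#' @param x a `metabolite_matrix`
#' @param i sample (row) index
#' @param j variable (column) index
#' @param ... unused
#' @return a `metabolite_matrix`
#' @export
`[.metabolite_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, x$variable_meta$name)
  metabolite_matrix(x$values[i, j, drop = FALSE],
                    x$sample_meta[i, c("patient_id", "timepoint_months"), drop = FALSE],
                    x$variable_meta[j, , drop = FALSE],
                    censored = x$censored[i, j, drop = FALSE],
                    truth = x$truth)
}

#' Write a metabolite matrix as CSV
#'
#' Samples as rows; `patient_id` and `timepoint_months` as leading columns,
#' then one column per variable. Censored cells are written as `<LOD`.
#'
#' @param x a `metabolite_matrix`
#' @param path output file
#' @export
write_metabolite_csv <- function(x, path) {
  vals <- as.data.frame(x$values)
  for (j in seq_along(vals)) vals[[j]] <- as.character(vals[[j]])
  vals[x$censored] <- "<LOD"
  out <- cbind(x$sample_meta[c("patient_id", "timepoint_months")], vals)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a metabolite matrix written by [write_metabolite_csv()]
#'
#' @param path CSV file
#' @param variable_meta optional variable metadata; reconstructed minimally
#'   (unknown platform, NA lod) when absent
#' @return a `metabolite_matrix`
#' @export
read_metabolite_csv <- function(path, variable_meta = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta <- data.frame(patient_id = df$patient_id,
                     timepoint_months = as.numeric(df$timepoint_months))
  raw <- as.matrix(df[setdiff(names(df), c("patient_id", "timepoint_months"))])
  cens <- raw == "<LOD" & !is.na(raw)
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  vals[cens] <- NA_real_
  if (is.null(variable_meta))
    variable_meta <- data.frame(name = colnames(raw), platform = NA_character_,
                                class = NA_character_, lod = NA_real_)
  metabolite_matrix(vals, meta, variable_meta, censored = cens)
}
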