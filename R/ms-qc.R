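#' Mask instrumental outlier spikes
#'
#' Per column, any observed value strictly greater than 100 times the column
#' median (median over non-missing, non-censored entries, so spikes cannot
#' shift their own threshold) is set to missing. A value at exactly 100x the
#' median is retained.
#'
#' @param matrix a [metabolite_matrix()]
#' @param factor multiplier defining an outlier (default 100)
#' @return list with `matrix` (masked) and `report` (a `qc_report`
#'   data.frame: per-variable median, n_spikes_masked)
#' @export
mask_outliers <- function(matrix, factor = 100) {
  vals <- matrix$values
  med <- rep(NA_real_, ncol(vals))
  n_masked <- integer(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    obs <- vals[, j][!is.na(vals[, j])]
    if (!length(obs)) {
      warning(sprintf("mask_outliers: column %s is entirely missing; skipped",
                      colnames(vals)[j]), call. = FALSE)
      next
    }
    med[j] <- stats::median(obs)
    hit <- !is.na(vals[, j]) & vals[, j] > factor * med[j]
    n_masked[j] <- sum(hit)
    vals[hit, j] <- NA_real_
  }
  matrix$values <- vals
  report <- data.frame(name = colnames(vals), median = med,
                       n_spikes_masked = n_masked)
  class(report) <- c("qc_report", "data.frame")
  list(matrix = matrix, report = report)
}

#' Exclude metabolites with excessive missing or below-LOD values
#'
#' Drops every column whose pooled fraction of missing-or-censored entries
#' strictly exceeds the threshold ("more than 30%"); a column at exactly the
#' threshold is kept. Both fractions are reported separately so the pooled
#' rule can be audited against a per-category reading.
#'
#' @param matrix a [metabolite_matrix()] (outliers already masked)
#' @param threshold exclusion threshold on the pooled fraction (default 0.30)
#' @return list with `matrix` (surviving columns, unchanged values) and
#'   `report` (per-variable missing_fraction, below_lod_fraction, excluded)
#' @export
filter_metabolites <- function(matrix, threshold = 0.30) {
  miss_frac <- colMeans(is.na(matrix$values) & !matrix$censored)
  lod_frac <- colMeans(matrix$censored)
  excluded <- (miss_frac + lod_frac) > threshold
  report <- data.frame(name = colnames(matrix$values),
                       missing_fraction = unname(miss_frac),
                       below_lod_fraction = unname(lod_frac),
                       excluded = unname(excluded))
  class(report) <- c("qc_report", "data.frame")
  list(matrix = matrix[, which(!excluded)], report = report)
}

#' Impute below-LOD cells as LOD/2
#'
#' Replaces every censored cell by half the column's limit of detection; no
#' other cell is altered.
#'
#' @param matrix a filtered [metabolite_matrix()]
#' @return the matrix with censored cells imputed and cleared
#' @export
impute_lod <- function(matrix) {
  cens_cols <- which(colSums(matrix$censored) > 0)
  for (j in cens_cols) {
    lod <- matrix$variable_meta$lod[j]
    if (is.na(lod))
      stopf("impute_lod: censored cells in %s but no LOD defined",
            matrix$variable_meta$name[j])
    matrix$values[matrix$censored[, j], j] <- lod / 2
  }
  matrix$censored[] <- FALSE
  matrix
}

#' Coefficients of variation on quality-control replicates
#'
#' 100 * sd / mean per column over replicate QC measurements, with flags at
#' the 15% and 25% review thresholds. The sd is the sample (n-1) standard
#' deviation.
#'
#' @param qc_samples numeric matrix of QC replicates (rows) by metabolites,
#'   or a [metabolite_matrix()]
#' @return data.frame with columns `name`, `cov_pct`, `over_15`, `over_25`
#' @export
compute_cov <- function(qc_samples) {
  vals <- if (inherits(qc_samples, "metabolite_matrix")) qc_samples$values else
    as.matrix(qc_samples)
  if (nrow(vals) < 2L) stopf("compute_cov: need >= 2 QC replicates")
  m <- colMeans(vals, na.rm = TRUE)
  s <- apply(vals, 2, stats::sd, na.rm = TRUE)
  cov <- 100 * s / m
  data.frame(name = colnames(vals) %||% paste0("V", seq_along(cov)),
             cov_pct = unname(cov),
             over_15 = unname(cov > 15), over_25 = unname(cov > 25))
}

#' Impute residual missing values for the multivariate arm
#'
#' After QC, sporadic missing cells (instrument dropouts and masked spikes)
#' remain; projection methods need complete rows. Replaces every missing,
#' non-censored cell by the column median of the observed values. The
#' univariate mixed-model arm does not need this and keeps its NAs.
#'
#' @param matrix a filtered, LOD-imputed [metabolite_matrix()]
#' @return the matrix with missing cells imputed
#' @export
impute_missing <- function(matrix) {
  if (any(matrix$censored)) stopf("impute_missing: run impute_lod first")
  for (j in which(colSums(is.na(matrix$values)) > 0)) {
    v <- matrix$values[, j]
    matrix$values[is.na(v), j] <- stats::median(v, na.rm = TRUE)
  }
  matrix
}

#' Run the full MS quality-control chain
#'
#' Fixed order: outlier masking, then missing/below-LOD exclusion, then LOD/2
#' imputation. Re-running the chain on its own output changes nothing.
#'
#' @param matrix a raw MS [metabolite_matrix()]
#' @param outlier_factor,threshold rule parameters (defaults 100 and 0.30)
#' @return list with `matrix` (cleaned) and `report` (merged per-variable QC
#'   table)
#' @export
ms_qc_pipeline <- function(matrix, outlier_factor = 100, threshold = 0.30) {
  st1 <- mask_outliers(matrix, factor = outlier_factor)
  st2 <- filter_metabolites(st1$matrix, threshold = threshold)
  cleaned <- impute_lod(st2$matrix)
  report <- merge(st1$report, st2$report, by = "name", sort = FALSE)
  report <- report[match(colnames(matrix$values), report$name), ]
  rownames(report) <- NULL
  class(report) <- c("qc_report", "data.frame")
  list(matrix = cleaned, report = report)
}
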