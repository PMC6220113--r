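#' Default Lorentzian peak table for the 30 NMR signals
#'
#' One or more Lorentzian components per metabolite: centre (ppm), half-width
#' at half-maximum (ppm) and the fraction of the metabolite's total area in
#' that component. Centres follow typical serum assignments (alanine doublet
#' with its left line at 1.47 ppm, lipid methyl at 0.8-0.9, lipid methylene
#' at 1.55-1.60, anomeric glucose at 5.23, formate at 8.45, ...), spaced so
#' the default integration windows of [default_region_table()] are resolved.
#'
#' @return data.frame with columns `name`, `ppm_center`, `halfwidth`, `weight`
#' @export
default_peak_table <- function() {
  rows <- list(
    c("lipid1", 0.86, 0.012, 1),
    c("isoleucine", 0.93, 0.0015, 1),
    c("leucine", 0.96, 0.0015, 1),
    c("valine", 1.03, 0.0015, 1),
    c("methylglutarate_2", 1.08, 0.0015, 1),
    c("lactate", 1.31, 0.0015, 0.5), c("lactate", 1.33, 0.0015, 0.5),
    c("alanine", 1.458, 0.0015, 0.5), c("alanine", 1.470, 0.0015, 0.5),
    c("lipid2", 1.575, 0.008, 1),
    c("lysine", 1.72, 0.0020, 1),
    c("acetate", 1.92, 0.0015, 1),
    c("glutamine_glutamate", 2.12, 0.0025, 1),
    c("acetoacetate", 2.27, 0.0015, 1),
    c("hydroxybutyrate_3", 2.31, 0.0015, 1),
    c("glutamate", 2.35, 0.0015, 1),
    c("pyruvate", 2.41, 0.0015, 1),
    c("glutamine", 2.45, 0.0015, 1),
    c("citrate", 2.54, 0.0015, 0.5), c("citrate", 2.66, 0.0015, 0.5),
    c("methionine", 2.60, 0.0015, 1),
    c("unknown_2_83", 2.83, 0.0015, 1),
    c("creatine", 3.03, 0.0015, 1),
    c("creatinine", 3.12, 0.0015, 1),
    c("dimethyl_sulfone", 3.16, 0.0015, 1),
    c("ornithine", 3.21, 0.0020, 1),
    c("proline_betaine", 3.30, 0.0015, 1),
    c("glucose", 3.47, 0.004, 0.8), c("glucose", 5.23, 0.0015, 0.2),
    c("glycine", 3.57, 0.0015, 1),
    c("tyrosine", 6.89, 0.0015, 1),
    c("histidine", 7.08, 0.0015, 1),
    c("phenylalanine", 7.37, 0.0015, 1),
    c("formate", 8.45, 0.0015, 1))
  out <- data.frame(name = vapply(rows, `[`, "", 1),
                    ppm_center = as.numeric(vapply(rows, `[`, "", 2)),
                    halfwidth = as.numeric(vapply(rows, `[`, "", 3)),
                    weight = as.numeric(vapply(rows, `[`, "", 4)))
  stopifnot(setequal(out$name, mrs_panel()))
  out
}

lorentzian <- function(ppm, center, hw, area) {
  (area / pi) * hw / ((ppm - center)^2 + hw^2)
}

#' Simulate frequency-domain 1D serum-like spectra
#'
#' Each spectrum is the sum of Lorentzian peaks whose areas equal the
#' sample's simulated MRS concentrations (split across components by the
#' peak-table weights), a compactly supported water-residual hump inside
#' 4.38-5.08 ppm, a constant baseline offset, white noise, and one global
#' chemical-shift offset per sample. The axis is descending over
#' [-0.5, 10] ppm. The truth ledger records each sample's metabolite areas,
#' total area, shift offset and baseline.
#'
#' @param matrix an MRS [metabolite_matrix()] from [simulate_metabolite_matrix()]
#' @param config the matching [cohort_config()]
#' @param peak_table Lorentzian component table; see [default_peak_table()]
#' @param n_points axis length (default 32768)
#' @param noise_sd white-noise standard deviation (intensity units)
#' @param baseline_max per-sample constant offsets drawn uniformly in
#'   \[0, baseline_max\]
#' @param water_area area of the water residual hump
#' @param shift_max global shift offsets drawn uniformly in ±`shift_max` ppm
#' @return object of class `spectrum_set`: common `ppm` axis, an
#'   intensities matrix (samples x points) and a `truth` list
#' @export
simulate_spectra <- function(matrix, config, peak_table = default_peak_table(),
                             n_points = 32768, noise_sd = 5e-4,
                             baseline_max = 0.02, water_area = 0.5,
                             shift_max = 0.03) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  vars <- matrix$variable_meta$name
  missing_peaks <- setdiff(vars, peak_table$name)
  if (length(missing_peaks))
    stopf("simulate_spectra: no peak-table entry for: %s",
          paste(missing_peaks, collapse = ", "))
  set.seed(derive_seed(config$seed, "spectra"))
  ppm <- seq(10, -0.5, length.out = n_points)
  n <- nrow(matrix$values)
  shifts <- stats::runif(n, -shift_max, shift_max)
  baselines <- stats::runif(n, 0, baseline_max)

  # water residual: cos^2 bump compactly supported inside the excision window
  water_lo <- 4.38; water_hi <- 5.08
  in_w <- ppm > water_lo & ppm < water_hi
  bump <- numeric(n_points)
  bump[in_w] <- cos(pi * (ppm[in_w] - (water_lo + water_hi) / 2) /
                      (water_hi - water_lo))^2
  bump <- bump / abs(trapz_masked(rev(ppm), rev(bump)))

  intens <- base::matrix(0, n, n_points)
  for (s in seq_len(n)) {
    y <- numeric(n_points)
    conc <- matrix$values[s, ]
    for (r in seq_len(nrow(peak_table))) {
      a <- conc[[peak_table$name[r]]] * peak_table$weight[r]
      if (is.na(a) || a == 0) next
      y <- y + lorentzian(ppm, peak_table$ppm_center[r] + shifts[s],
                          peak_table$halfwidth[r], a)
    }
    y <- y + water_area * bump
    if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
    intens[s, ] <- y + baselines[s]
  }
  rownames(intens) <- rownames(matrix$values)
  areas <- matrix$values[, intersect(vars, peak_table$name), drop = FALSE]
  structure(list(ppm = ppm, intensities = intens,
                 sample_meta = matrix$sample_meta,
                 truth = list(areas = areas,
                              total_area = rowSums(areas, na.rm = TRUE),
                              shift = stats::setNames(shifts, rownames(intens)),
                              baseline = stats::setNames(baselines, rownames(intens)),
                              water_area = water_area, noise_sd = noise_sd)),
            class = "spectrum_set")
}

#' Extract one spectrum from a set
#' @param set a `spectrum_set`
#' @param i sample index or sample id
#' @return object of class `spectrum` (list with `ppm`, `intensity`)
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, rownames(set$intensities))
  structure(list(ppm = set$ppm, intensity = set$intensities[i, ],
                 sample_id = rownames(set$intensities)[i]),
            class = "spectrum")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, %d points, %.2f..%.2f ppm\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Write a spectrum set as a two-file CSV pair
#' @param set a `spectrum_set`
#' @param ppm_path CSV for the ppm axis (single column)
#' @param intensity_path CSV for the intensity matrix (one row per sample,
#'   leading `sample_id` column)
#' @export
write_spectra_csv <- function(set, ppm_path, intensity_path) {
  utils::write.csv(data.frame(ppm = set$ppm), ppm_path, row.names = FALSE)
  utils::write.csv(cbind(data.frame(sample_id = rownames(set$intensities)),
                         as.data.frame(set$intensities)),
                   intensity_path, row.names = FALSE)
  invisible(c(ppm_path, intensity_path))
}
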