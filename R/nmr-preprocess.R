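#' Reference a spectrum to the alanine doublet at 1.47 ppm
#'
#' Detects the alanine doublet inside the search window as two local maxima
#' rising at least 5x the window noise level (median absolute deviation of
#' successive differences) above the window median, separated by
#' 0.005-0.03 ppm, and shifts the ppm axis so the left
#' (higher-ppm) line sits exactly at 1.47 ppm. The applied shift is recorded
#' on the returned spectrum.
#'
#' @param spectrum a `spectrum` (list with `ppm`, `intensity`)
#' @param search_window ppm interval searched for the doublet
#' @param target ppm position assigned to the left line (default 1.47)
#' @return the spectrum with shifted axis and an `applied_shift` field
#' @export
reference_to_alanine <- function(spectrum, search_window = c(1.40, 1.55),
                                 target = 1.47) {
  ppm <- spectrum$ppm; y <- spectrum$intensity
  win <- which(ppm >= min(search_window) & ppm <= max(search_window))
  if (length(win) < 5L)
    stopf("reference_to_alanine: spectrum does not cover the search window")
  yw <- y[win]
  # noise level from successive differences, so structured signal (e.g. a
  # broad lipid tail drifting into the window) does not inflate the threshold
  noise_mad <- stats::mad(diff(yw)) / sqrt(2)
  thresh <- stats::median(yw) + 5 * noise_mad
  # local maxima on the window grid
  inner <- seq(2L, length(win) - 1L)
  is_max <- yw[inner] > yw[inner - 1L] & yw[inner] >= yw[inner + 1L] &
    yw[inner] > thresh
  peaks <- win[inner[is_max]]
  if (length(peaks) < 2L)
    stopf("reference_to_alanine: no doublet above noise in the search window")
  # among pairs with doublet-like separation, take the one whose weaker line
  # is tallest: the two lines of a true doublet have comparable height,
  # whereas chance pairs of noise bumps are weak
  cand <- NULL; best <- -Inf
  for (i in seq_along(peaks)) for (j in seq_along(peaks)) {
    if (i >= j) next
    sep <- abs(ppm[peaks[i]] - ppm[peaks[j]])
    if (sep < 0.005 || sep > 0.03) next
    score <- min(y[peaks[i]], y[peaks[j]])
    if (score > best) { best <- score; cand <- c(peaks[i], peaks[j]) }
  }
  if (is.null(cand))
    stopf("reference_to_alanine: no two-peak pattern with doublet separation found")
  left <- cand[which.max(ppm[cand])]  # left = higher ppm by NMR convention
  shift <- target - ppm[left]
  spectrum$ppm <- ppm + shift
  spectrum$applied_shift <- shift
  spectrum
}

#' Baseline-correct a spectrum by zeroing its minimum
#'
#' Subtracts a constant so the lowest intensity becomes exactly zero.
#'
#' @param spectrum a `spectrum`
#' @return the corrected spectrum
#' @export
correct_baseline <- function(spectrum) {
  if (!length(spectrum$intensity)) stopf("correct_baseline: empty spectrum")
  spectrum$intensity <- spectrum$intensity - min(spectrum$intensity)
  spectrum
}

#' Excise the water residual region
#'
#' Flags every point with ppm inside the closed window (default
#' \[4.33, 5.13\]) as excluded; excluded points contribute nothing to any
#' subsequent area (normalization or integration). Points are flagged, not
#' deleted, so the axis is preserved.
#'
#' @param spectrum a `spectrum`
#' @param window closed ppm interval to excise
#' @return the spectrum with a logical `water_mask` field (TRUE = excluded)
#' @export
excise_water <- function(spectrum, window = c(4.33, 5.13)) {
  mask <- spectrum$ppm >= min(window) & spectrum$ppm <= max(window)
  spectrum$water_mask <- mask
  spectrum
}

retained_mask <- function(spectrum) {
  keep <- rep(TRUE, length(spectrum$ppm))
  if (!is.null(spectrum$water_mask)) keep <- keep & !spectrum$water_mask
  keep
}

# trapezoidal area over the retained points of a closed ppm window,
# with linear interpolation at the exact window bounds
window_area <- function(spectrum, lo, hi) {
  ppm <- spectrum$ppm; y <- spectrum$intensity
  keep <- retained_mask(spectrum)
  asc <- order(ppm)
  x <- ppm[asc]; yy <- y[asc]; kk <- keep[asc]
  if (lo < min(x) || hi > max(x))
    stopf("integration window [%g, %g] outside the spectrum axis", lo, hi)
  inside <- x >= lo & x <= hi
  xs <- x[inside]; ys <- yy[inside]; ks <- kk[inside]
  # interpolated bound points (retained unless they fall in the water mask)
  if (!length(xs) || xs[1] > lo) {
    ylo <- stats::approx(x, yy, xout = lo)$y
    klo <- all(kk[max(which(x <= lo))], kk[min(which(x >= lo))])
    xs <- c(lo, xs); ys <- c(ylo, ys); ks <- c(klo, ks)
  }
  if (xs[length(xs)] < hi) {
    yhi <- stats::approx(x, yy, xout = hi)$y
    khi <- all(kk[max(which(x <= hi))], kk[min(which(x >= hi))])
    xs <- c(xs, hi); ys <- c(ys, yhi); ks <- c(ks, khi)
  }
  trapz_masked(xs, ys, ks)
}

#' Normalize a spectrum to unit total area
#'
#' Divides the intensities by the trapezoidal area over the retained
#' (non-water) points between 0.29 and 8.53 ppm, so that area becomes 1.
#'
#' @param spectrum a water-excised `spectrum`
#' @param region closed ppm interval defining "total area"
#' @return the spectrum with a `normalization_factor` field (the area
#'   divided out)
#' @export
normalize_total_area <- function(spectrum, region = c(0.29, 8.53)) {
  area <- window_area(spectrum, min(region), max(region))
  if (!is.finite(area) || area <= 0)
    stopf("normalize_total_area: non-positive area over the normalization region")
  spectrum$intensity <- spectrum$intensity / area
  spectrum$normalization_factor <- area
  spectrum
}

#' Run the full preprocessing chain on one spectrum
#'
#' Referencing to alanine, baseline zeroing, water excision and total-area
#' normalization, in the fixed order of the preprocessing protocol.
#'
#' @param spectrum a raw `spectrum`
#' @param water_window,norm_region interval overrides
#' @return a preprocessed `spectrum`
#' @export
preprocess_spectrum <- function(spectrum, water_window = c(4.33, 5.13),
                                norm_region = c(0.29, 8.53)) {
  s <- reference_to_alanine(spectrum)
  s <- correct_baseline(s)
  s <- excise_water(s, water_window)
  normalize_total_area(s, norm_region)
}

#' Default 30-metabolite integration region table
#'
#' One row per integration window: metabolite name, window bounds, window
#' index and combine mode (`mean` of the window integrals, or the `single`
#' listed window). lipid1 and lipid2 use their defining windows 0.8-0.9 and
#' 1.55-1.60 ppm; the remaining windows bracket the default peak-table
#' centres. The table is configuration: edit or replace it (e.g. via
#' [read_region_table()]) for real spectra.
#'
#' @param halfspan half-width of the default bracket around narrow peaks, ppm
#' @return data.frame with columns `name`, `ppm_lo`, `ppm_hi`,
#'   `window_index`, `combine_mode`
#' @export
default_region_table <- function(halfspan = 0.015) {
  pk <- default_peak_table()
  fixed <- list(lipid1 = c(0.80, 0.90), lipid2 = c(1.55, 1.60),
                lactate = c(1.295, 1.345), alanine = c(1.443, 1.485),
                glucose_1 = c(3.40, 3.55), glucose_2 = c(5.20, 5.26),
                citrate_1 = c(2.525, 2.555), citrate_2 = c(2.645, 2.675))
  rows <- list()
  for (nm in mrs_panel()) {
    key <- names(fixed)[names(fixed) == nm | startsWith(names(fixed), paste0(nm, "_"))]
    if (length(key)) {
      for (i in seq_along(key)) {
        w <- fixed[[key[i]]]
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, ppm_lo = w[1], ppm_hi = w[2], window_index = i,
          combine_mode = if (length(key) > 1L) "mean" else "single")
      }
    } else {
      ctr <- pk$ppm_center[pk$name == nm][1]
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, ppm_lo = ctr - halfspan, ppm_hi = ctr + halfspan,
        window_index = 1L, combine_mode = "single")
    }
  }
  out <- do.call(rbind, rows)
  validate_region_table(out)
  out
}

validate_region_table <- function(regions) {
  stopifnot(all(c("name", "ppm_lo", "ppm_hi", "combine_mode") %in% names(regions)))
  if (any(regions$ppm_lo >= regions$ppm_hi))
    stopf("region table: ppm_lo must be < ppm_hi")
  if (any(regions$ppm_lo < 0.29 | regions$ppm_hi > 8.53))
    stopf("region table: windows must lie within [0.29, 8.53] ppm")
  if (!all(regions$combine_mode %in% c("mean", "single")))
    stopf("region table: combine_mode must be 'mean' or 'single'")
  invisible(regions)
}

#' Read an integration region table from CSV
#' @param path CSV with columns name, ppm_lo, ppm_hi, window_index, combine_mode
#' @return validated region table
#' @export
read_region_table <- function(path) {
  validate_region_table(utils::read.csv(path))
}

#' Integrate metabolite regions of a preprocessed spectrum
#'
#' Trapezoidal integral of each window (water-excised points contribute
#' nothing); for metabolites with several windows and combine mode `mean`,
#' the mean of the window integrals; for mode `single`, the first listed
#' window. Output order follows the region table.
#'
#' @param spectrum a preprocessed `spectrum`
#' @param regions a region table (see [default_region_table()])
#' @return named numeric vector, one value per metabolite
#' @export
integrate_regions <- function(spectrum, regions = default_region_table()) {
  validate_region_table(regions)
  out <- numeric(0)
  for (nm in unique(regions$name)) {
    sub <- regions[regions$name == nm, , drop = FALSE]
    if (identical(sub$combine_mode[1], "single")) sub <- sub[1, , drop = FALSE]
    vals <- mapply(function(lo, hi) window_area(spectrum, lo, hi),
                   sub$ppm_lo, sub$ppm_hi)
    out[nm] <- mean(vals)
  }
  out
}

#' Preprocess and integrate a whole spectrum set
#'
#' @param set a `spectrum_set`
#' @param regions region table for [integrate_regions()]
#' @return list with `matrix` (a `metabolite_matrix`, platform MRS) and
#'   `shifts` (applied referencing shift per sample)
#' @export
quantify_spectra <- function(set, regions = default_region_table()) {
  n <- nrow(set$intensities)
  shifts <- numeric(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- preprocess_spectrum(get_spectrum(set, i))
    shifts[i] <- s$applied_shift
    rows[[i]] <- integrate_regions(s, regions)
  }
  vals <- do.call(rbind, rows)
  rownames(vals) <- rownames(set$intensities)
  nm <- colnames(vals)
  mm <- metabolite_matrix(vals,
    set$sample_meta[c("patient_id", "timepoint_months")],
    data.frame(name = nm, platform = "MRS", class = "mrs_signal",
               lod = NA_real_))
  list(matrix = mm, shifts = stats::setNames(shifts, rownames(vals)))
}
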