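test_that("alanine referencing shifts the left doublet line to 1.47 ppm", {
  # doublet detected at 1.50/1.49: a -0.03 shift is applied
  s <- make_spectrum(alanine_peaks(left = 1.50), noise = 1e-4)
  step <- 10.5 / 8192
  r <- reference_to_alanine(s)
  expect_lt(abs(r$applied_shift - (-0.03)), step)
  # the left line of the doublet now sits at 1.47 (within a grid step)
  peak_ppm <- r$ppm[which.max(r$intensity * (r$ppm > 1.465 & r$ppm < 1.475))]
  expect_lt(abs(peak_ppm - 1.47), step)
  # doublet already in place: shift is numerically zero
  s0 <- make_spectrum(alanine_peaks(left = 1.47), noise = 1e-4)
  r0 <- reference_to_alanine(s0)
  expect_lt(abs(r0$applied_shift), step)
  # flat window: referencing error
  flat <- make_spectrum(list(list(center = 3.0, hw = 0.002, area = 1)), noise = 0)
  expect_error(reference_to_alanine(flat), "doublet|two-peak")
  # spectrum not covering the window at all
  short <- make_spectrum(alanine_peaks(), lo = 2, hi = 9)
  expect_error(reference_to_alanine(short), "cover")
})

test_that("baseline correction zeroes the spectrum minimum", {
  s <- make_spectrum(list(list(center = 3, hw = 0.01, area = 1)), baseline = 0.2)
  expect_equal(min(correct_baseline(s)$intensity), 0)
  # already zero: unchanged
  s0 <- correct_baseline(s)
  expect_equal(correct_baseline(s0)$intensity, s0$intensity)
  # negative minimum: constant added
  s$intensity <- s$intensity - 0.5
  expect_equal(min(correct_baseline(s)$intensity), 0)
})

test_that("water excision masks the closed 4.33-5.13 window", {
  s <- make_spectrum(list(list(center = 3, hw = 0.01, area = 1)),
                     n_points = 1051, lo = 0, hi = 10.5)
  # axis step 0.01 so 4.33, 4.50 and 5.13 are exact grid points
  w <- excise_water(s)
  expect_true(w$water_mask[which.min(abs(w$ppm - 4.50))])
  expect_true(w$water_mask[which.min(abs(w$ppm - 4.33))])   # closed bound
  expect_true(w$water_mask[which.min(abs(w$ppm - 5.13))])
  expect_false(w$water_mask[which.min(abs(w$ppm - 4.32))])  # outside
  expect_false(w$water_mask[which.min(abs(w$ppm - 5.14))])
  # window outside the axis: empty mask, spectrum unchanged
  narrow <- make_spectrum(list(list(center = 2, hw = 0.01, area = 1)),
                          lo = 0, hi = 4)
  wn <- excise_water(narrow)
  expect_equal(sum(wn$water_mask), 0)
  expect_equal(wn$intensity, narrow$intensity)
})

test_that("total-area normalization yields unit area and scale invariance", {
  s <- make_spectrum(list(list(center = 3, hw = 0.005, area = 2),
                          list(center = 7, hw = 0.005, area = 1)))
  n1 <- normalize_total_area(excise_water(correct_baseline(s)))
  area <- longmet:::window_area(n1, 0.29, 8.53)
  expect_equal(area, 1, tolerance = 1e-10)
  # scaling the raw spectrum by 5 changes nothing after normalization
  s5 <- s; s5$intensity <- 5 * s$intensity
  n5 <- normalize_total_area(excise_water(correct_baseline(s5)))
  expect_equal(n5$intensity, n1$intensity, tolerance = 1e-12)
  expect_equal(n5$normalization_factor / n1$normalization_factor, 5,
               tolerance = 1e-10)
  # an all-zero spectrum cannot be normalized
  z <- s; z$intensity[] <- 0
  expect_error(normalize_total_area(excise_water(z)), "non-positive area")
})

test_that("region integration matches rectangle and truncated-Lorentzian closed forms", {
  # unit-height rectangle over a 0.10 ppm window integrates to 0.10
  s <- make_spectrum(list(), n_points = 10001, lo = 0, hi = 10)
  s$intensity <- as.numeric(s$ppm >= 2.95 & s$ppm <= 3.05)
  reg <- data.frame(name = "rect", ppm_lo = 2.95, ppm_hi = 3.05,
                    window_index = 1, combine_mode = "single")
  expect_equal(unname(integrate_regions(s, reg)["rect"]), 0.10, tolerance = 1e-6)

  # unit-area Lorentzian, half-width 0.005, centred in a 0.10 window:
  # closed form (2/pi) * atan(0.05 / 0.005) of the area is captured
  hw <- 0.005
  sl <- make_spectrum(list(list(center = 3.00, hw = hw, area = 1)),
                      n_points = 65536, lo = -0.5, hi = 10)
  regl <- data.frame(name = "lor", ppm_lo = 2.95, ppm_hi = 3.05,
                     window_index = 1, combine_mode = "single")
  got <- unname(integrate_regions(sl, regl)["lor"])
  closed <- (2 / pi) * atan(0.05 / hw)  # = 0.9365: the truncated-tail area
  expect_equal(got, closed, tolerance = 1e-3)

  # two windows with integrals 0.2 and 0.4 and combine mode mean give 0.3
  s2 <- make_spectrum(list(), n_points = 10001, lo = 0, hi = 10)
  s2$intensity <- 2 * (s2$ppm >= 2.0 & s2$ppm <= 2.1) +
                  4 * (s2$ppm >= 5.9 & s2$ppm <= 6.0)
  reg2 <- data.frame(name = "m", ppm_lo = c(2.0, 5.9), ppm_hi = c(2.1, 6.0),
                     window_index = 1:2, combine_mode = "mean")
  expect_equal(unname(integrate_regions(s2, reg2)["m"]), 0.3, tolerance = 1e-6)

  # a window outside the axis errors
  expect_error(integrate_regions(s, data.frame(
    name = "bad", ppm_lo = 0.29, ppm_hi = 8.53, window_index = 1,
    combine_mode = "single")), NA)
  sshort <- make_spectrum(list(), n_points = 100, lo = 2, hi = 4)
  expect_error(longmet:::window_area(sshort, 0.5, 1), "outside")
})

test_that("region table validation enforces bounds and modes", {
  expect_error(validate_region_table(data.frame(
    name = "x", ppm_lo = 2, ppm_hi = 1, window_index = 1,
    combine_mode = "single")), "ppm_lo")
  expect_error(validate_region_table(data.frame(
    name = "x", ppm_lo = 0.1, ppm_hi = 1, window_index = 1,
    combine_mode = "single")), "0.29")
  expect_error(validate_region_table(data.frame(
    name = "x", ppm_lo = 1, ppm_hi = 2, window_index = 1,
    combine_mode = "best")), "combine_mode")
  tbl <- default_region_table()
  expect_setequal(unique(tbl$name), mrs_panel())
  expect_true(all(tbl$ppm_lo[tbl$name == "lipid1"] == 0.80))
  expect_true(all(tbl$ppm_hi[tbl$name == "lipid2"] == 1.60))
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tbl, tmp, row.names = FALSE)
  expect_equal(read_region_table(tmp)$ppm_lo, tbl$ppm_lo)
})

test_that("preprocessing is idempotent after the first pass", {
  s <- make_spectrum(c(alanine_peaks(left = 1.48),
                       list(list(center = 3, hw = 0.005, area = 2))),
                     noise = 1e-5, baseline = 0.01)
  p1 <- preprocess_spectrum(s)
  p2 <- preprocess_spectrum(p1)
  expect_equal(p2$applied_shift, 0, tolerance = 2e-3)
  expect_equal(p2$intensity, p1$intensity, tolerance = 1e-6)
})

test_that("simulated spectra: truth areas are linear in concentration and recoverable", {
  cfg <- cohort_config(seed = 61, n_patients = 50, timepoints = c(0, 6),
                       weight_missing_fraction = 0, sigma_log = 0.4)
  cl <- generate_cohort(cfg)
  mrs <- simulate_metabolite_matrix(cl, cfg, platform = "MRS")
  # doubling one metabolite's concentration doubles its truth area
  mrs2 <- mrs; mrs2$values[, "citrate"] <- 2 * mrs$values[, "citrate"]
  set1 <- simulate_spectra(mrs[1:2, ], cfg, n_points = 4096, noise_sd = 0)
  set2 <- simulate_spectra(mrs2[1:2, ], cfg, n_points = 4096, noise_sd = 0)
  expect_equal(set2$truth$areas[, "citrate"], 2 * set1$truth$areas[, "citrate"])

  # noise-free, baseline-free spectra: retained area matches summed truth areas
  set0 <- simulate_spectra(mrs[1:3, ], cfg, n_points = 32768, noise_sd = 0,
                           baseline_max = 0, water_area = 0)
  for (i in 1:3) {
    sp <- excise_water(get_spectrum(set0, i))
    area <- longmet:::window_area(sp, 0.29, 8.53)
    expect_equal(area, unname(set0$truth$total_area[i]), tolerance = 0.01)
  }

  # quantification linearity across 100 samples: integrated values correlate
  # with truth areas normalized by each sample's total area (r^2 > 0.99)
  set <- simulate_spectra(mrs, cfg, n_points = 8192, noise_sd = 0,
                          baseline_max = 0)
  q <- quantify_spectra(set)
  truth_norm <- set$truth$areas / set$truth$total_area
  r2 <- vapply(mrs_panel(), function(nm)
    cor(q$matrix$values[, nm], truth_norm[, nm])^2, numeric(1))
  expect_gt(median(r2), 0.99)
  expect_gt(min(r2), 0.95)

  # injected global shifts are recovered by referencing within one axis step
  step <- 10.5 / 8192
  expect_lt(max(abs(unname(q$shifts) + unname(set$truth$shift))), step)
})

test_that("spectra with a shifted axis record and undo a +0.03 ppm offset", {
  cfg <- cohort_config(seed = 62, n_patients = 4, timepoints = c(0, 6),
                       weight_missing_fraction = 0)
  mrs <- simulate_metabolite_matrix(generate_cohort(cfg), cfg, platform = "MRS")
  set <- simulate_spectra(mrs[1, ], cfg, n_points = 16384, noise_sd = 1e-5,
                          shift_max = 0.03)
  truth_shift <- unname(set$truth$shift[1])
  r <- reference_to_alanine(get_spectrum(set, 1))
  expect_lt(abs(r$applied_shift + truth_shift), 10.5 / 16384)
})
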