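test_that("cohort generation is deterministic and matches configured group sizes", {
  cfg <- cohort_config(seed = 11)
  cl1 <- generate_cohort(cfg)
  cl2 <- generate_cohort(cfg)
  expect_identical(cl1, cl2)
  expect_equal(sum(cl1$chemo), 35)
  expect_equal(sum(!cl1$chemo), 25)
  expect_equal(nrow(cl1), 60)
  expect_false(anyDuplicated(cl1$patient_id) > 0)
  # weights positive, hdl < tc, evaluable gainer count matches the design
  expect_true(all(cl1$weight_0 > 0))
  expect_true(all(cl1$hdl < cl1$tc))
  gain <- classify_weight_gain(cl1)
  expect_equal(sum(gain == "gainer"), 17)
  expect_equal(sum(gain == "unknown"), 8)
  # another seed gives different draws but identical design counts
  cl3 <- generate_cohort(cohort_config(seed = 12))
  expect_false(identical(cl1$weight_0, cl3$weight_0))
  expect_equal(sum(cl3$chemo), 35)
})

test_that("gainer flag is consistent with the 1.5 kg rule by construction", {
  cl <- generate_cohort(cohort_config(seed = 3))
  delta <- cl$weight_6 - cl$weight_0
  gain <- classify_weight_gain(cl)
  expect_true(all(delta[gain == "gainer"] >= 1.5))
  expect_true(all(delta[gain == "non_gainer"] < 1.5))
  # gainer_fraction 0: nobody gains 1.5 kg
  cl0 <- generate_cohort(cohort_config(seed = 3, gainer_fraction = 0))
  d0 <- cl0$weight_6 - cl0$weight_0
  expect_true(all(d0[!is.na(d0)] < 1.5))
})

test_that("config validation rejects bad designs", {
  expect_error(cohort_config(seed = 1, n_patients = 3), "n_patients")
  expect_error(cohort_config(seed = 1, icc = 1), "icc")
  expect_error(cohort_config(seed = 1, timepoints = c(0, 6, 6)), "timepoints")
  expect_error(cohort_config(seed = 1, timepoints = c(6, 12)), "timepoints")
  expect_error(cohort_config(seed = 1, chemo_fraction = 1.2), "proportion")
  expect_error(cohort_config(), "seed")
  expect_error(
    cohort_config(seed = 1, effect_registry = list(
      effect_spec("kynurenine", "chemo", 9, 0.3))),
    "timepoint")
  expect_error(effect_spec("x", "chemo", 0, 0.3), "non-baseline")
  cfg <- cohort_config(seed = 1, effect_registry = list(
    effect_spec("not_a_metabolite", "chemo", 6, 0.3)))
  cl <- generate_cohort(cfg)
  expect_error(simulate_metabolite_matrix(cl, cfg), "unknown effect variable")
})

test_that("simulated ICC is recovered by a one-way random-effects ANOVA oracle", {
  cfg <- cohort_config(seed = 21, n_patients = 500, icc = 0.5,
                       weight_missing_fraction = 0, effect_registry = list())
  mm <- simulate_metabolite_matrix(generate_cohort(cfg), cfg, platform = "MRS")
  logv <- log(mm$values)
  pid <- mm$sample_meta$patient_id
  k <- 3  # timepoints per patient
  icc_hat <- apply(logv, 2, function(v) {
    pm <- tapply(v, pid, mean)
    msb <- k * var(pm)
    msw <- sum((v - pm[pid])^2) / (length(v) - length(pm))
    s_b <- (msb - msw) / k
    s_b / (s_b + msw)
  })
  expect_equal(mean(icc_hat), 0.5, tolerance = 0.05)
})

test_that("planted log-fold-changes surface as geometric-mean ratios", {
  # 38% kynurenine rise in the chemo group at 6 months, 25% otherwise;
  # measured on a pathology-free block (no censoring/missingness/spikes)
  # so the geometric-mean ratio is an unbiased readout of the planted effect
  cfg <- cohort_config(seed = 31, n_patients = 400, ms_fraction = 1,
                       weight_missing_fraction = 0, lod_quantile = 0,
                       n_low_quality_ms = 0, missing_rate = 0, spike_rate = 0)
  cl <- generate_cohort(cfg)
  mm <- simulate_metabolite_matrix(cl, cfg)
  sm <- mm$sample_meta
  gm_ratio <- function(patients) {
    v0 <- mm$values[match(paste0(patients, "_t0"), rownames(mm$values)), "kynurenine"]
    v6 <- mm$values[match(paste0(patients, "_t6"), rownames(mm$values)), "kynurenine"]
    ok <- !is.na(v0) & !is.na(v6)
    exp(mean(log(v6[ok] / v0[ok])))
  }
  expect_equal(gm_ratio(cl$patient_id[cl$chemo]), 1.38, tolerance = 0.05)
  expect_equal(gm_ratio(cl$patient_id[!cl$chemo]), 1.25, tolerance = 0.05)
})

test_that("zero noise and empty effect registry give constant trajectories", {
  cfg <- cohort_config(seed = 5, n_patients = 10, sigma_log = 0,
                       missing_rate = 0, spike_rate = 0, n_low_quality_ms = 0,
                       lod_quantile = 0, weight_missing_fraction = 0,
                       effect_registry = list())
  mm <- simulate_metabolite_matrix(generate_cohort(cfg), cfg, platform = "MRS")
  v0 <- mm$values[mm$sample_meta$timepoint_months == 0, ]
  v6 <- mm$values[mm$sample_meta$timepoint_months == 6, ]
  v12 <- mm$values[mm$sample_meta$timepoint_months == 12, ]
  expect_equal(v6, v0, ignore_attr = TRUE)
  expect_equal(v12, v0, ignore_attr = TRUE)
})

test_that("lipoprotein panel has the exact 105-name schema and class structure", {
  schema <- lipoprotein_schema()
  expect_length(schema, 105)
  expect_false(any(grepl("^V6", schema)))
  expect_true(all(nchar(schema) == 4))
  cfg <- cohort_config(seed = 41, n_patients = 500, timepoints = c(0, 6),
                       weight_missing_fraction = 0)
  lp <- simulate_lipoprotein_panel(generate_cohort(cfg), cfg)
  expect_identical(colnames(lp$values), schema)
  expect_true(all(lp$values > 0))
  # within-class correlation exceeds between-class correlation
  v0 <- log(lp$values[lp$sample_meta$timepoint_months == 0, ])
  cls <- as.character(lipoprotein_class(schema))
  cm <- cor(v0)
  same <- outer(cls, cls, `==`) & upper.tri(cm) & cls[row(cm)] != "TP"
  diff <- outer(cls, cls, `!=`) & upper.tri(cm) &
    cls[row(cm)] != "TP" & cls[col(cm)] != "TP"
  expect_gt(mean(cm[same]), mean(cm[diff]))
})

test_that("the truth ledger records every pathology it injects", {
  cfg <- cohort_config(seed = 51)
  mm <- simulate_metabolite_matrix(generate_cohort(cfg), cfg)
  tr <- mm$truth
  # censored cells: ledger matches the censored matrix exactly
  cens_idx <- which(mm$censored, arr.ind = TRUE)
  expect_equal(nrow(tr$censored), nrow(cens_idx))
  expect_setequal(paste(tr$censored$sample_id, tr$censored$variable),
                  paste(rownames(mm$values)[cens_idx[, 1]],
                        colnames(mm$values)[cens_idx[, 2]]))
  # spiked cells carry the recorded value and exceed 150x the pre-spike median
  for (i in seq_len(min(20, nrow(tr$spikes)))) {
    sp <- tr$spikes[i, ]
    expect_equal(mm$values[sp$sample_id, sp$variable], sp$value)
    expect_gte(sp$factor, 150); expect_lte(sp$factor, 500)
  }
  # missing cells are NA and not censored
  miss_idx <- cbind(match(tr$missing$sample_id, rownames(mm$values)),
                    match(tr$missing$variable, colnames(mm$values)))
  expect_true(all(is.na(mm$values[miss_idx])))
  expect_true(all(!mm$censored[miss_idx]))
  # designated low-quality columns are recorded
  expect_length(tr$low_quality_columns, 48)
})

test_that("simulated blocks and spectra are byte-identical under the same seed", {
  cfg <- cohort_config(seed = 8, n_patients = 8, weight_missing_fraction = 0)
  cl <- generate_cohort(cfg)
  expect_identical(simulate_metabolite_matrix(cl, cfg),
                   simulate_metabolite_matrix(cl, cfg))
  expect_identical(simulate_lipoprotein_panel(cl, cfg),
                   simulate_lipoprotein_panel(cl, cfg))
  mrs <- simulate_metabolite_matrix(cl, cfg, platform = "MRS")
  s1 <- simulate_spectra(mrs, cfg, n_points = 2048)
  s2 <- simulate_spectra(mrs, cfg, n_points = 2048)
  expect_identical(s1, s2)
})

test_that("a cohort config round-trips through a JSON document", {
  cfg <- cohort_config(seed = 4, n_patients = 12, icc = 0.4,
                       effect_registry = list(
                         effect_spec("kynurenine", "chemo", 6, log(1.38))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  back <- read_cohort_config(f)
  expect_equal(back$icc, 0.4)
  expect_equal(back$seed, 4L)
  expect_length(back$effect_registry, 1)
  expect_equal(back$effect_registry[[1]]$log_fold_change, log(1.38))
  expect_identical(generate_cohort(back), generate_cohort(cfg))
  # a config without a seed is rejected
  doc <- jsonlite::read_json(f)
  doc$seed <- NULL
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), f)
  expect_error(read_cohort_config(f), "seed")
})

test_that("tables and spectra survive a CSV round trip", {
  cfg <- cohort_config(seed = 9, n_patients = 8, weight_missing_fraction = 0)
  cl <- generate_cohort(cfg)
  mm <- simulate_metabolite_matrix(cl, cfg)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "ms.csv")
  write_metabolite_csv(mm, f)
  back <- read_metabolite_csv(f, variable_meta = mm$variable_meta)
  expect_equal(back$values, mm$values, tolerance = 1e-12)
  expect_identical(back$censored, mm$censored)
  fc <- file.path(tmp, "clinical.csv")
  write_clinical_csv(cl, fc)
  clb <- read_clinical_csv(fc)
  expect_equal(clb$weight_6, cl$weight_6)
  expect_equal(as.character(clb$surgery), as.character(cl$surgery))
  ft <- file.path(tmp, "truth.json")
  write_truth_json(mm$truth, ft)
  expect_silent(jsonlite::read_json(ft))
})
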