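test_that("LMM time effect reduces to the mean within-patient log difference", {
  set.seed(13)
  n_pat <- 30
  b <- rnorm(n_pat, 0, 0.5)
  v0 <- exp(2 + b + rnorm(n_pat, 0, 0.3))
  v6 <- v0 * exp(0.4 + rnorm(n_pat, 0, 0.3))
  vals <- matrix(rbind(v0, v6), ncol = 1)  # interleaved per patient: t0 then t6
  mm <- make_matrix(vals, timepoints = c(0, 6))
  colnames(mm$values) <- mm$variable_meta$name <- "m"
  r <- lmm_time_effect(mm, "m", 0, 6)
  expect_equal(r$estimate, mean(log(v6) - log(v0)), tolerance = 1e-8)
  expect_equal(r$n_patients_used, n_pat)
  expect_false(r$degenerate)
})

test_that("LMM handles degenerate, incomplete and invalid inputs", {
  set.seed(14)
  v0 <- exp(rnorm(10))
  vals <- matrix(rbind(v0, v0), ncol = 1)  # identical at both timepoints
  mm <- make_matrix(vals, timepoints = c(0, 6))
  colnames(mm$values) <- mm$variable_meta$name <- "m"
  r <- lmm_time_effect(mm, "m", 0, 6)
  expect_true(r$degenerate)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  # patients with one timepoint are retained, not dropped
  mm2 <- mm
  set.seed(15)
  mm2$values[, 1] <- exp(rnorm(20))
  mm2$values[2, 1] <- NA  # patient 1 has baseline only
  r2 <- lmm_time_effect(mm2, "m", 0, 6)
  expect_equal(r2$n_patients_used, 10)
  # non-positive concentrations refuse the log transform
  mm3 <- mm2; mm3$values[3, 1] <- 0
  expect_error(lmm_time_effect(mm3, "m", 0, 6), "non-positive")
  expect_error(lmm_time_effect(mm2, "nope", 0, 6), "unknown variable")
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  # n = 6, tie-free: exact p equals the 2^6 enumeration oracle
  for (seed in 1:5) {
    set.seed(seed)
    d <- round(rnorm(6, 0.3, 1), 3)
    d <- d[d != 0]; if (length(d) < 6 || anyDuplicated(abs(d))) next
    r <- wilcoxon_signed_rank(d)
    expect_equal(r$p_value, wilcoxon_enum_p(d), tolerance = 1e-12)
  }
  # all differences zero: degenerate with p = 1
  r0 <- wilcoxon_signed_rank(rep(0, 10))
  expect_true(r0$degenerate); expect_equal(r0$p_value, 1)
  # 50 strictly positive differences: overwhelming evidence
  rbig <- wilcoxon_signed_rank(abs(rnorm(50)) + 0.1)
  expect_lt(rbig$p_value, 0.001)
  expect_equal(rbig$n_nonzero, 50)
  expect_error(wilcoxon_signed_rank(c(1, -1, 2, 0)), ">= 5")
})

test_that("two-sample t matches the pooled-variance formula and is label-symmetric", {
  set.seed(21)
  x <- rnorm(12, 1); y <- rnorm(15, 0)
  vals <- c(x, y); g <- rep(c("a", "b"), c(12, 15))
  r <- two_sample_t(vals, g)
  sp2 <- ((11 * var(x) + 14 * var(y)) / 25)
  t_direct <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  expect_equal(r$statistic, t_direct, tolerance = 1e-10)
  expect_equal(r$df, 25)
  # swapping labels negates t, keeps p
  r2 <- two_sample_t(vals, rep(c("b", "a"), c(12, 15)))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  # identical groups: t = 0, p = 1
  r3 <- two_sample_t(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(two_sample_t(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("Fisher exact reproduces the reference-cohort contingency p values", {
  tabs <- reference_contingency_tables()
  expect_equal(fisher_exact_2x2(tabs$menopause_chemo)$p_value, 0.053,
               tolerance = 0.02)
  expect_equal(fisher_exact_2x2(tabs$herceptin_chemo)$p_value, 0.26,
               tolerance = 0.01)
  expect_equal(fisher_exact_2x2(tabs$herceptin_gain)$p_value, 0.54,
               tolerance = 0.01)
  expect_gt(fisher_exact_2x2(tabs$menopause_gain)$p_value, 0.99)
  # the transposed layout gives the same p
  expect_equal(fisher_exact_2x2(t(tabs$herceptin_gain))$p_value,
               fisher_exact_2x2(tabs$herceptin_gain)$p_value)
  # a table at the hypergeometric mode has p = 1
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 2, 3, 4), 2)), "integers")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("Fisher exact agrees with hypergeometric enumeration for N <= 40", {
  set.seed(33)
  for (i in 1:60) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1); r1 <- a
    # random margins with both rows/cols positive
    r1 <- sample(1:(N - 1), 1); c1 <- sample(1:(N - 1), 1)
    x <- max(0, c1 - (N - r1)):min(r1, c1)
    obs <- sample(x, 1)
    tb <- matrix(c(obs, r1 - obs, c1 - obs, N - r1 - c1 + obs), 2)
    if (any(tb < 0)) next
    expect_equal(fisher_exact_2x2(tb)$p_value, fisher_enum_p(tb),
                 tolerance = 1e-10)
  }
})

test_that("BH q values follow the step-up definition within blocks", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
  set.seed(5)
  p <- runif(25)
  m <- length(p)
  ord <- order(p)
  q_oracle <- numeric(m)
  q_oracle[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  expect_equal(fdr_bh(p), pmin(q_oracle, 1))
  # monotone in sorted-p order
  q <- fdr_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # permutation invariance
  perm <- sample(m)
  expect_equal(fdr_bh(p[perm]), q[perm])
  # blockwise independence: a block's q values ignore other blocks
  blocks <- rep(c("A", "B"), c(10, 15))
  qb <- fdr_bh(p, blocks)
  expect_equal(qb[blocks == "A"], fdr_bh(p[blocks == "A"]))
  expect_equal(qb[blocks == "B"], fdr_bh(p[blocks == "B"]))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Friedewald LDL follows the mmol/L formula with its validity bound", {
  expect_equal(friedewald_ldl(5.0, 1.2, 1.1), 3.3)
  expect_equal(friedewald_ldl(5.0, 1.2, 0), 3.8)
  expect_error(friedewald_ldl(5.0, 1.2, 5.0), "4.5")
  expect_error(friedewald_ldl(-1, 1, 1), "non-negative")
  # generated cohorts satisfy the formula by construction
  cl <- generate_cohort(cohort_config(seed = 6))
  expect_equal(friedewald_ldl(cl$tc, cl$hdl, cl$tg),
               cl$tc - cl$hdl - cl$tg / 2.2)
})

test_that("weight-gain classification is boundary-inclusive at +1.5 kg", {
  cl <- data.frame(patient_id = c("a", "b", "c"),
                   weight_0 = c(70, 70, 70),
                   weight_6 = c(71.5, 71.49, NA))
  g <- classify_weight_gain(cl)
  expect_equal(as.character(g), c("gainer", "non_gainer", "unknown"))
  cl$weight_0[1] <- NA
  expect_error(classify_weight_gain(cl), "baseline")
})

test_that("univariate tables carry blockwise q values", {
  cfg <- cohort_config(seed = 71, n_patients = 16, weight_missing_fraction = 0)
  cl <- generate_cohort(cfg)
  lp <- simulate_lipoprotein_panel(cl, cfg)
  tab <- univariate_table(lp[, 1:12], design = "multilevel_time",
                          test = "wilcoxon", t_ref = 0, t_cmp = 6,
                          block = "LIPO")
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_equal(tab$q, fdr_bh(tab$p))
})
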