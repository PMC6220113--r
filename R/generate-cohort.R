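#' Reference-cohort 2x2 contingency tables
#'
#' The cross-tabulations of the reference cohort the generator emulates:
#' menopausal status and Herceptin use against chemotherapy (n = 60) and
#' against 6-month weight gain (n = 52 weight-evaluable patients). These are
#' the design constants behind the generator's default covariate frequencies
#' and serve as worked examples for [fisher_exact_2x2()].
#'
#' @return named list of 2x2 integer matrices with dimnames
#' @examples
#' fisher_exact_2x2(reference_contingency_tables()$menopause_chemo)$p_value
#' @export
reference_contingency_tables <- function() {
  list(
    menopause_chemo = matrix(c(14L, 4L, 21L, 21L), 2, byrow = TRUE,
      dimnames = list(menopause = c("pre", "post"), chemo = c("yes", "no"))),
    herceptin_chemo = matrix(c(3L, 0L, 32L, 25L), 2, byrow = TRUE,
      dimnames = list(herceptin = c("yes", "no"), chemo = c("yes", "no"))),
    menopause_gain = matrix(c(6L, 12L, 11L, 23L), 2, byrow = TRUE,
      dimnames = list(menopause = c("pre", "post"), gain = c("gainer", "non_gainer"))),
    herceptin_gain = matrix(c(0L, 3L, 17L, 32L), 2, byrow = TRUE,
      dimnames = list(herceptin = c("yes", "no"), gain = c("gainer", "non_gainer"))))
}

# Covariate frequencies of the reference cohort, by chemotherapy group
# (chemo n = 35 / no-chemo n = 25). Counts are allocated exactly, scaled by
# round() to the configured group sizes.
.cohort_design <- list(
  menopause_pre = c(chemo = 14 / 35, no_chemo = 4 / 25),
  herceptin     = c(chemo = 3 / 35,  no_chemo = 0 / 25),
  radiation     = c(chemo = 25 / 35, no_chemo = 22 / 25),
  surgery = list(chemo    = c(BCS = 22, mastectomy = 12, PRE = 1),
                 no_chemo = c(BCS = 21, mastectomy = 3, PRE = 1)),
  endocrine = list(chemo    = c(none = 4, tamoxifen = 13, AI = 17, AI_goserelin = 1, unknown = 0),
                   no_chemo = c(none = 16, tamoxifen = 0, AI = 6, AI_goserelin = 1, unknown = 2)),
  age = list(chemo = c(mean = 52.8, sd = 7.5, lo = 38, hi = 69),
             no_chemo = c(mean = 58.9, sd = 5.5, lo = 46, hi = 68)),
  weight = c(mean = 70.8, sd = 10, lo = 48, hi = 98),
  hba1c = c(mean = 5.7, sd = 0.4, lo = 4.5, hi = 6.5),
  gain_delta = c(mean = 3.65, sd = 2.0),      # gainers: truncated >= 1.5 kg
  nogain_delta = c(mean = -0.82, sd = 2.2))   # non-gainers: truncated < 1.5 kg

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

# allocate exact counts of a categorical level within a group
allocate <- function(n, counts) {
  counts <- round(counts / sum(counts) * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.max(counts)] <- counts[which.max(counts)] + 1L
  sample(rep(names(counts), counts))
}

#' Generate a synthetic clinical table
#'
#' Draws one row per patient: treatment allocation (chemotherapy,
#' endocrine therapy, radiation, Herceptin, surgery type), menopausal status,
#' age, weights at 0/6/12 months, HbA1c and standard lipids (TG, HDL, LDL by
#' construction, TC as their Friedewald-consistent sum). Group sizes follow
#' `round(n * fraction)` exactly. Weight-gainer status is assigned first and
#' the 6-month weight change drawn from a truncated normal on the matching
#' side of the 1.5 kg threshold, so the gain label is exactly consistent with
#' a >= 1.5 kg 6-month increase. A configured fraction of patients has no
#' follow-up weights (gain status unknown).
#'
#' @param config a [cohort_config()]
#' @return a `data.frame` of class `clinical_table`, one row per patient, with
#'   attribute `timepoints`
#' @examples
#' cl <- generate_cohort(cohort_config(seed = 7))
#' table(cl$chemo)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("generate_cohort: config must be a cohort_config")
  set.seed(derive_seed(config$seed, "clinical"))
  n <- config$n_patients
  d <- .cohort_design

  n_chemo <- round(n * config$chemo_fraction)
  chemo <- sample(rep(c(TRUE, FALSE), c(n_chemo, n - n_chemo)))
  grp <- ifelse(chemo, "chemo", "no_chemo")

  draw_flag <- function(frac_by_grp) {
    out <- logical(n)
    for (g in c("chemo", "no_chemo")) {
      idx <- which(grp == g)
      k <- round(length(idx) * frac_by_grp[[g]])
      out[sample(idx, k)] <- TRUE
    }
    out
  }
  draw_cat <- function(counts_by_grp) {
    out <- character(n)
    for (g in c("chemo", "no_chemo")) {
      idx <- which(grp == g)
      out[idx] <- allocate(length(idx), counts_by_grp[[g]])
    }
    out
  }

  menopause <- ifelse(draw_flag(d$menopause_pre), "pre", "post")
  herceptin <- draw_flag(d$herceptin)
  radiation <- draw_flag(d$radiation)
  surgery <- draw_cat(d$surgery)
  endocrine <- draw_cat(d$endocrine)

  age <- numeric(n)
  for (g in c("chemo", "no_chemo")) {
    idx <- which(grp == g); a <- d$age[[g]]
    age[idx] <- round(rtruncnorm1(length(idx), a["mean"], a["sd"], a["lo"], a["hi"]), 0)
  }

  w0 <- round(rtruncnorm1(n, d$weight["mean"], d$weight["sd"],
                          d$weight["lo"], d$weight["hi"]), 1)
  n_missing_w <- round(n * config$weight_missing_fraction)
  w_missing <- sample(n, n_missing_w)
  n_eval <- n - n_missing_w
  n_gain <- round(n_eval * config$gainer_fraction)
  gainer <- logical(n); gainer[sample(setdiff(seq_len(n), w_missing), n_gain)] <- TRUE

  delta6 <- ifelse(gainer,
                   rtruncnorm1(n, d$gain_delta["mean"], d$gain_delta["sd"], lo = 1.5),
                   rtruncnorm1(n, d$nogain_delta["mean"], d$nogain_delta["sd"], hi = 1.4999))
  delta6 <- round(delta6, 1)
  # rounding to scale precision must not cross the 1.5 kg threshold
  delta6[gainer] <- pmax(delta6[gainer], 1.5)
  delta6[!gainer] <- pmin(delta6[!gainer], 1.4)
  w6 <- round(w0 + delta6, 1)
  w12 <- round(w6 + stats::rnorm(n, 0, 1.5), 1)
  w6[w_missing] <- NA_real_
  w12[w_missing] <- NA_real_

  hba1c <- round(rtruncnorm1(n, d$hba1c["mean"], d$hba1c["sd"],
                             d$hba1c["lo"], d$hba1c["hi"]), 1)
  tg <- round(exp(rtruncnorm1(n, log(1.1), 0.40, hi = log(4.4))), 2)
  hdl <- round(rtruncnorm1(n, 1.55, 0.35, lo = 0.6), 2)
  ldl <- round(rtruncnorm1(n, 3.5, 0.9, lo = 0.8), 2)
  tc <- round(ldl + hdl + tg / 2.2, 2)

  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age,
    menopausal_status = factor(menopause, c("pre", "post")),
    chemo = chemo,
    endocrine = factor(endocrine, names(d$endocrine$chemo)),
    radiation = radiation,
    herceptin = herceptin,
    surgery = factor(surgery, c("BCS", "mastectomy", "PRE")),
    weight_0 = w0, weight_6 = w6, weight_12 = w12,
    hba1c = hba1c, tc = tc, hdl = hdl, tg = tg,
    stringsAsFactors = FALSE)
  attr(out, "timepoints") <- config$timepoints
  class(out) <- c("clinical_table", "data.frame")
  out
}
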