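# group membership used by effect specs
effect_group_index <- function(clinical, group) {
  switch(group,
    all = rep(TRUE, nrow(clinical)),
    chemo = clinical$chemo,
    no_chemo = !clinical$chemo,
    gainer = !is.na(clinical$weight_6) & clinical$weight_6 - clinical$weight_0 >= 1.5)
}

# shared lognormal longitudinal engine: patient random intercept with the
# configured ICC on the log scale, plus planted group-by-time effects
simulate_log_block <- function(clinical, config, varnames, mu, timepoints,
                               patient_ids, stream, extra_per_sample = NULL) {
  set.seed(derive_seed(config$seed, stream))
  p <- length(varnames)
  n_pat <- length(patient_ids)
  sigma_b <- sqrt(config$icc) * config$sigma_log
  sigma_e <- sqrt(1 - config$icc) * config$sigma_log

  meta <- expand.grid(timepoint_months = timepoints, patient_id = patient_ids,
                      stringsAsFactors = FALSE)[, 2:1]
  n <- nrow(meta)
  b <- matrix(stats::rnorm(n_pat * p, 0, sigma_b), n_pat, p,
              dimnames = list(patient_ids, varnames))
  e <- matrix(stats::rnorm(n * p, 0, sigma_e), n, p)
  logv <- matrix(mu, n, p, byrow = TRUE) + b[meta$patient_id, , drop = FALSE] + e
  if (!is.null(extra_per_sample)) logv <- logv + extra_per_sample(meta)

  applied <- list()
  for (ef in config$effect_registry) {
    j <- match(ef$variable_name, varnames)
    if (is.na(j)) next
    in_group <- effect_group_index(clinical, ef$group)
    sel <- meta$patient_id %in% clinical$patient_id[in_group] &
      meta$timepoint_months == ef$timepoint
    logv[sel, j] <- logv[sel, j] + ef$log_fold_change
    applied[[length(applied) + 1L]] <- data.frame(
      variable = ef$variable_name, group = ef$group,
      timepoint = ef$timepoint, log_fold_change = ef$log_fold_change)
  }
  list(values = exp(logv), meta = meta,
       effects = if (length(applied)) do.call(rbind, applied) else
         data.frame(variable = character(), group = character(),
                    timepoint = numeric(), log_fold_change = numeric()))
}

#' Simulate a metabolite concentration block
#'
#' Concentrations are log-normal with a per-patient random intercept giving
#' the configured intraclass correlation, and group-by-time log-fold-change
#' effects from the config's effect registry. For the MS platform the
#' measurement pathologies of a targeted kit are layered on top: below-LOD
#' censoring (LOD = the configured empirical quantile of each column, with
#' `n_low_quality_ms` designated columns censored at 40% so they fail the
#' downstream 30% rule by construction), MCAR missingness, and instrumental
#' spikes of 150-500 times the column median. Every censored cell, missing
#' cell, spike and applied effect is recorded in the returned truth ledger.
#'
#' MS measurements cover baseline and 6 months for the configured patient
#' subset; MRS covers all patients and timepoints and has no LOD/missingness.
#'
#' @param clinical a [generate_cohort()] table
#' @param config the [cohort_config()] used to generate `clinical`
#' @param platform `"MS"` (188-variable kit) or `"MRS"` (30-signal NMR panel)
#' @return a [metabolite_matrix()] whose `truth` element records `mu`
#'   (log-scale baselines), applied effects, censored/missing/spiked cells,
#'   and the per-column LOD
#' @examples
#' cfg <- cohort_config(seed = 1)
#' mm <- simulate_metabolite_matrix(generate_cohort(cfg), cfg)
#' dim(mm)
#' @export
simulate_metabolite_matrix <- function(clinical, config,
                                       platform = c("MS", "MRS")) {
  platform <- match.arg(platform)
  if (platform == "MS") {
    panel <- ms_panel()
    tps <- intersect(config$timepoints, c(0, 6))
    set.seed(derive_seed(config$seed, "ms-design"))
    n_ms <- round(config$n_patients * config$ms_fraction)
    patients <- sort(sample(clinical$patient_id, n_ms))
    mu <- stats::rnorm(nrow(panel), log(50), 1)
  } else {
    panel <- data.frame(name = mrs_panel(), class = "mrs_signal")
    tps <- config$timepoints
    patients <- clinical$patient_id
    set.seed(derive_seed(config$seed, "mrs-mu"))
    mu <- stats::rnorm(nrow(panel), log(0.01), 0.5)
    # the two broad lipid signals dominate serum CPMG spectra
    mu[panel$name %in% c("lipid1", "lipid2")] <- log(0.15)
    mu[panel$name %in% c("glucose", "lactate")] <- log(0.05)
  }
  bad <- setdiff(vapply(config$effect_registry, `[[`, "", "variable_name"),
                 c(ms_panel()$name, mrs_panel(), lipoprotein_schema()))
  if (length(bad))
    stopf("simulate_metabolite_matrix: unknown effect variable(s): %s",
          paste(bad, collapse = ", "))

  sim <- simulate_log_block(clinical, config, panel$name, mu, tps, patients,
                            paste0("block-", platform))
  vals <- sim$values
  n <- nrow(vals); p <- ncol(vals)
  cens <- matrix(FALSE, n, p)
  lod <- rep(NA_real_, p)
  truth <- list(platform = platform, mu = stats::setNames(mu, panel$name),
                icc = config$icc, sigma_log = config$sigma_log,
                effects = sim$effects)

  if (platform == "MS") {
    set.seed(derive_seed(config$seed, "ms-qc-pathologies"))
    protected <- panel$name %in% sim$effects$variable
    low_q <- sample(which(!protected), min(config$n_low_quality_ms, sum(!protected)))
    q <- rep(config$lod_quantile, p)
    q[low_q] <- 0.40
    for (j in seq_len(p)) {
      k <- round(q[j] * n)
      if (k > 0) {
        ord <- order(vals[, j])
        lod[j] <- vals[ord[k + 1L], j]  # LOD sits just above the k censored cells
        cens[ord[seq_len(k)], j] <- TRUE
      } else {
        lod[j] <- stats::quantile(vals[, j], config$lod_quantile, names = FALSE) / 2
      }
    }
    miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p) & !cens
    spike <- matrix(stats::runif(n * p) < config$spike_rate, n, p) & !cens & !miss
    spike_factor <- matrix(stats::runif(n * p, 150, 500), n, p)
    med <- apply(vals, 2, stats::median)
    spiked_vals <- sweep(spike_factor, 2, med, `*`)
    truth$low_quality_columns <- panel$name[sort(low_q)]
    sid <- paste0(sim$meta$patient_id, "_t", sim$meta$timepoint_months)
    cell_df <- function(mask) data.frame(
      sample_id = sid[row(mask)[mask]], variable = panel$name[col(mask)[mask]])
    truth$censored <- cell_df(cens)
    truth$missing <- cell_df(miss)
    truth$spikes <- cbind(cell_df(spike),
                          factor = spike_factor[spike],
                          original = vals[spike], value = spiked_vals[spike])
    vals[spike] <- spiked_vals[spike]
    vals[miss] <- NA_real_
    vals[cens] <- NA_real_
  }
  truth$lod <- stats::setNames(lod, panel$name)

  metabolite_matrix(vals, sim$meta,
                    data.frame(name = panel$name, platform = platform,
                               class = panel$class, lod = lod),
                    censored = cens, truth = truth)
}

#' Simulate the 105-variable lipoprotein subfraction panel
#'
#' Values are strictly positive and log-normal, with (i) a per-patient random
#' intercept giving the configured longitudinal ICC and (ii) one latent
#' factor per particle class (VLDL, IDL, LDL, HDL; total-plasma variables
#' load on the average of the four) so that variables within a class
#' correlate more strongly than variables across classes. Columns follow
#' [lipoprotein_schema()] exactly; no VLDL-6 code is present.
#'
#' @inheritParams simulate_metabolite_matrix
#' @param class_loading loading of the latent class factor on the log scale
#' @return a [metabolite_matrix()] with platform `"LIPO"`
#' @export
simulate_lipoprotein_panel <- function(clinical, config, class_loading = 0.3) {
  nm <- lipoprotein_schema()
  cls <- lipoprotein_class(nm)
  set.seed(derive_seed(config$seed, "lipo-mu"))
  mu <- stats::rnorm(length(nm), log(30), 0.6)

  loadings <- matrix(0, length(nm), 4,
                     dimnames = list(nm, c("VLDL", "IDL", "LDL", "HDL")))
  for (k in colnames(loadings)) loadings[cls == k, k] <- 1
  loadings[cls == "TP", ] <- 1 / 4
  factor_term <- function(meta) {
    f <- matrix(stats::rnorm(nrow(meta) * 4), nrow(meta), 4)
    class_loading * tcrossprod(f, loadings)
  }
  sim <- simulate_log_block(clinical, config, nm, mu, config$timepoints,
                            clinical$patient_id, "block-LIPO",
                            extra_per_sample = factor_term)
  truth <- list(platform = "LIPO", mu = stats::setNames(mu, nm),
                icc = config$icc, sigma_log = config$sigma_log,
                class_loading = class_loading, effects = sim$effects)
  metabolite_matrix(sim$values, sim$meta,
                    data.frame(name = nm, platform = "LIPO",
                               class = as.character(cls), lod = NA_real_),
                    truth = truth)
}
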