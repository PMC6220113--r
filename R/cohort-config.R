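#' Specification of one planted group-by-time effect
#'
#' An effect spec asks the simulator to multiply one variable's concentration
#' by `exp(log_fold_change)` at one follow-up timepoint, in one patient group.
#' Effects are additive on the natural-log scale, matching the log-transform
#' applied before mixed-model analysis.
#'
#' @param variable_name name of a variable present in the simulated panel
#' @param group one of `"chemo"`, `"no_chemo"`, `"gainer"`, `"all"`
#' @param timepoint month offset of the affected timepoint (non-baseline)
#' @param log_fold_change natural-log fold change applied at `timepoint`
#' @return an object of class `effect_spec`
#' @examples
#' effect_spec("kynurenine", "chemo", 6, log(1.38))
#' @export
effect_spec <- function(variable_name, group, timepoint, log_fold_change) {
  group <- match.arg(group, c("chemo", "no_chemo", "gainer", "all"))
  if (!is.character(variable_name) || length(variable_name) != 1L)
    stopf("variable_name must be a single string")
  if (!is.numeric(timepoint) || length(timepoint) != 1L || timepoint == 0)
    stopf("effect timepoint must be a single non-baseline month offset")
  if (!is.numeric(log_fold_change) || !is.finite(log_fold_change))
    stopf("log_fold_change must be a finite number")
  structure(list(variable_name = variable_name, group = group,
                 timepoint = timepoint, log_fold_change = log_fold_change),
            class = "effect_spec")
}

#' Default planted effects
#'
#' Kynurenine rises by 38% at 6 months in chemotherapy recipients and by 25%
#' in non-recipients; these magnitudes anchor the generator's defaults.
#' @return list of [effect_spec()] objects
#' @export
default_effect_registry <- function() {
  list(effect_spec("kynurenine", "chemo", 6, log(1.38)),
       effect_spec("kynurenine", "no_chemo", 6, log(1.25)))
}

#' A planted multivariate treatment shift for power analysis
#'
#' Builds an effect registry that shifts a spread of targeted-MS metabolites
#' (every ninth kit variable, by default 21 of 188, about 15% of the
#' QC-surviving panel) by a common log fold change in one group at one
#' timepoint. This is the scenario used to check that the multilevel
#' OPLS-DA pipeline attains high cross-validated accuracy and a small
#' permutation p when a coordinated treatment effect truly exists.
#'
#' @param n_vars number of shifted variables
#' @param log_fold_change common natural-log fold change (default log(1.35))
#' @param group,timepoint affected group and timepoint
#' @return list of [effect_spec()] objects
#' @export
multivariate_shift_registry <- function(n_vars = 21,
                                        log_fold_change = log(1.35),
                                        group = "chemo", timepoint = 6) {
  nm <- ms_panel()$name[seq(1, 188, by = 9)][seq_len(n_vars)]
  lapply(nm, effect_spec, group = group, timepoint = timepoint,
         log_fold_change = log_fold_change)
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic cohort: design sizes, longitudinal
#' correlation, measurement pathologies (censoring, missingness, spikes) and
#' the registry of planted effects. Defaults reproduce the reference study
#' design: 60 patients, 35 of whom receive chemotherapy, three visits at
#' 0/6/12 months, 17 weight gainers among 52 patients with an observed
#' 6-month weight, and MS measurements for 53 patients at 0 and 6 months.
#'
#' @param n_patients number of patients (>= 4)
#' @param chemo_fraction proportion receiving chemotherapy
#' @param gainer_fraction proportion of weight-evaluable patients gaining
#'   >= 1.5 kg by 6 months
#' @param weight_missing_fraction proportion of patients with no follow-up
#'   weight (gainer status unknown)
#' @param ms_fraction proportion of patients with targeted-MS measurements
#'   (taken at baseline and 6 months only)
#' @param timepoints strictly increasing month offsets starting at 0
#' @param seed integer seed; mandatory for reproducibility
#' @param icc within-patient intraclass correlation of log concentrations,
#'   in [0, 1)
#' @param sigma_log total between+within sd of natural-log concentrations
#' @param missing_rate MCAR missingness proportion (MS block)
#' @param lod_quantile per-column empirical quantile used as the limit of
#'   detection for well-behaved MS columns
#' @param n_low_quality_ms number of MS columns censored at 40% so they fail
#'   the 30% missing/below-LOD rule by construction (default 48, taking the
#'   raw 188-column kit down to 140 after QC)
#' @param spike_rate proportion of MS entries replaced by instrumental spikes
#'   of 150-500 times the column median
#' @param effect_registry list of [effect_spec()] objects
#' @return an object of class `cohort_config`
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 60,
                          chemo_fraction = 35 / 60,
                          gainer_fraction = 17 / 52,
                          weight_missing_fraction = 8 / 60,
                          ms_fraction = 53 / 60,
                          timepoints = c(0, 6, 12),
                          seed,
                          icc = 0.5,
                          sigma_log = 0.4,
                          missing_rate = 0.02,
                          lod_quantile = 0.05,
                          n_low_quality_ms = 48,
                          spike_rate = 0.005,
                          effect_registry = default_effect_registry()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("cohort_config: an integer `seed` is mandatory")
  if (!is.numeric(n_patients) || n_patients < 4)
    stopf("cohort_config: n_patients must be >= 4")
  for (nm in c("chemo_fraction", "gainer_fraction", "weight_missing_fraction",
               "ms_fraction", "missing_rate", "lod_quantile", "spike_rate")) {
    if (!is_prop(get(nm))) stopf("cohort_config: %s must be a proportion in [0,1]", nm)
  }
  if (!is.numeric(icc) || icc < 0 || icc >= 1)
    stopf("cohort_config: icc must lie in [0, 1)")
  if (length(timepoints) < 2L || timepoints[1] != 0 || any(diff(timepoints) <= 0))
    stopf("cohort_config: timepoints must be strictly increasing and start at 0")
  if (!is.numeric(sigma_log) || sigma_log < 0)
    stopf("cohort_config: sigma_log must be non-negative")
  if (!is.numeric(n_low_quality_ms) || n_low_quality_ms < 0 || n_low_quality_ms > 188)
    stopf("cohort_config: n_low_quality_ms must lie in [0, 188]")
  if (!all(vapply(effect_registry, inherits, logical(1), "effect_spec")))
    stopf("cohort_config: effect_registry must be a list of effect_spec objects")
  for (ef in effect_registry) {
    if (!ef$timepoint %in% timepoints[-1])
      stopf("cohort_config: effect timepoint %s not among configured follow-ups", ef$timepoint)
  }
  structure(list(n_patients = as.integer(n_patients),
                 chemo_fraction = chemo_fraction,
                 gainer_fraction = gainer_fraction,
                 weight_missing_fraction = weight_missing_fraction,
                 ms_fraction = ms_fraction,
                 timepoints = as.numeric(timepoints),
                 seed = as.integer(seed),
                 icc = icc, sigma_log = sigma_log,
                 missing_rate = missing_rate,
                 lod_quantile = lod_quantile,
                 n_low_quality_ms = as.integer(n_low_quality_ms),
                 spike_rate = spike_rate,
                 effect_registry = effect_registry),
            class = "cohort_config")
}

#' Read a cohort configuration from JSON or YAML
#'
#' The document holds the same fields as [cohort_config()]; `seed` is
#' mandatory. Effects are given as objects with keys `variable_name`,
#' `group`, `timepoint`, `log_fold_change`.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` document
#' @return a validated `cohort_config`
#' @export
read_cohort_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(doc$effect_registry)) {
    er <- doc$effect_registry
    if (is.data.frame(er)) er <- split(er, seq_len(nrow(er)))
    doc$effect_registry <- lapply(er, function(e)
      effect_spec(e$variable_name, e$group, e$timepoint, e$log_fold_change))
  }
  do.call(cohort_config, doc)
}
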