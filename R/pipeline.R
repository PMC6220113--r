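#' One comparison of an analysis plan
#'
#' @param block `"MRS"`, `"MS"` or `"LIPO"`
#' @param design `"multilevel_time"` (paired change between `t_ref` and
#'   `t_cmp`), `"weight_gain_baseline"` or `"weight_gain_6mo"` (predict
#'   6-month weight gain from the profile at one timepoint)
#' @param group_filter `"chemo"`, `"no_chemo"` or `"all"`
#' @param t_ref,t_cmp timepoints used by the design
#' @return a `comparison` list
#' @export
comparison <- function(block, design, group_filter = "all",
                       t_ref = 0, t_cmp = 6) {
  block <- match.arg(block, c("MRS", "MS", "LIPO"))
  design <- match.arg(design, c("multilevel_time", "weight_gain_baseline",
                                "weight_gain_6mo"))
  group_filter <- match.arg(group_filter, c("chemo", "no_chemo", "all"))
  structure(list(block = block, design = design, group_filter = group_filter,
                 t_ref = t_ref, t_cmp = t_cmp,
                 label = paste(block, design, group_filter,
                               paste0(t_ref, "-", t_cmp), sep = "_")),
            class = "comparison")
}

#' The default study-shaped analysis plan
#'
#' Ten comparisons mirroring the study's result sections: paired 0-to-6-month
#' change in the MS metabolite and lipoprotein blocks for chemotherapy
#' recipients and non-recipients, paired 0-to-12-month change in the NMR
#' metabolite and lipoprotein blocks for chemotherapy recipients and
#' non-recipients, and weight-gain prediction from the baseline and 6-month
#' MS and lipoprotein profiles.
#'
#' @param cv,perm lists of cross-validation / permutation settings
#'   (`max_orth`, `n_folds`, `n_iter`, `n_perm`)
#' @return object of class `analysis_plan`
#' @export
default_analysis_plan <- function(cv = list(max_orth = 3, n_folds = 10, n_iter = 20),
                                  perm = list(n_perm = 1000)) {
  comparisons <- list(
    comparison("MS", "multilevel_time", "chemo", 0, 6),
    comparison("MS", "multilevel_time", "no_chemo", 0, 6),
    comparison("LIPO", "multilevel_time", "chemo", 0, 6),
    comparison("LIPO", "multilevel_time", "no_chemo", 0, 6),
    comparison("MRS", "multilevel_time", "chemo", 0, 12),
    comparison("MRS", "multilevel_time", "no_chemo", 0, 12),
    comparison("MS", "weight_gain_baseline", "all", 0, NA),
    comparison("LIPO", "weight_gain_baseline", "all", 0, NA),
    comparison("MS", "weight_gain_6mo", "all", 6, NA),
    comparison("LIPO", "weight_gain_6mo", "all", 6, NA))
  structure(list(comparisons = comparisons, cv = cv, perm = perm),
            class = "analysis_plan")
}

#' Validate an analysis plan against the available blocks
#'
#' Checks that every comparison references an existing block and that the
#' timepoints it uses are measured in that block (e.g. the targeted-MS block
#' covers baseline and 6 months only).
#'
#' @param plan an `analysis_plan`
#' @param blocks named list of [metabolite_matrix()] objects
#' @return the plan, invisibly; errors on the first violation
#' @export
validate_plan <- function(plan, blocks) {
  for (cm in plan$comparisons) {
    if (!cm$block %in% names(blocks))
      stopf("plan validation: block %s not available", cm$block)
    have <- unique(blocks[[cm$block]]$sample_meta$timepoint_months)
    need <- if (cm$design == "multilevel_time") c(cm$t_ref, cm$t_cmp) else cm$t_ref
    if (!all(need %in% have))
      stopf("plan validation: %s lacks timepoint(s) %s required by %s",
            cm$block, paste(setdiff(need, have), collapse = ", "), cm$label)
  }
  invisible(plan)
}

run_one_comparison <- function(cm, blocks, clinical, plan, seed) {
  mm <- blocks[[cm$block]]
  gain <- classify_weight_gain(clinical)
  keep <- switch(cm$group_filter,
                 all = clinical$patient_id,
                 chemo = clinical$patient_id[clinical$chemo],
                 no_chemo = clinical$patient_id[!clinical$chemo])
  cv_cfg <- plan$cv; n_perm <- plan$perm$n_perm
  seed_cm <- derive_seed(seed, cm$label)
  mm_mv <- impute_missing(mm)  # multivariate arm needs complete rows

  if (cm$design == "multilevel_time") {
    sub <- mm[mm$sample_meta$patient_id %in% keep, ]
    ds <- build_paired_dataset(mm_mv[mm_mv$sample_meta$patient_id %in% keep, ],
                               cm$t_ref, cm$t_cmp)
    uni <- univariate_table(sub,
                            design = "multilevel_time",
                            test = if (cm$block == "LIPO") "wilcoxon" else "lmm",
                            t_ref = cm$t_ref, t_cmp = cm$t_cmp,
                            group_filter = keep, block = cm$block)
  } else {
    t_use <- cm$t_ref
    labelled <- names(gain)[gain != "unknown"]
    idx <- which(mm_mv$sample_meta$timepoint_months == t_use &
                   mm_mv$sample_meta$patient_id %in% intersect(keep, labelled))
    X <- mm_mv$values[idx, , drop = FALSE]
    ok <- !is.na(rowSums(X))
    pid <- mm_mv$sample_meta$patient_id[idx][ok]
    y <- ifelse(gain[pid] == "gainer", 1, -1)
    ds <- list(X = X[ok, , drop = FALSE], y = as.numeric(y), patient_id = pid)
    glab <- stats::setNames(as.character(gain[labelled]), labelled)
    uni <- univariate_table(mm, design = "group_baseline",
                            test = if (cm$block == "LIPO") "wilcoxon" else "ttest",
                            t_ref = t_use, group_labels = glab, block = cm$block)
  }
  cv <- cross_validate(ds, max_orth = cv_cfg$max_orth, n_folds = cv_cfg$n_folds,
                       n_iter = cv_cfg$n_iter, seed = seed_cm)
  pt <- permutation_test(ds, max_orth = cv_cfg$max_orth,
                         n_folds = cv_cfg$n_folds, n_iter = cv_cfg$n_iter,
                         n_perm = n_perm, seed = seed_cm)
  d <- as_ml_dataset(ds)
  final <- fit_opls_da(d$X, d$y, n_orth = cv$chosen_n_orth)
  vip <- sort(vip_scores(final), decreasing = TRUE)
  list(label = cm$label, comparison = cm,
       n_patients = length(unique(d$patient_id)),
       cv = cv, permutation = pt,
       vip = data.frame(variable = names(vip), vip = unname(vip)),
       univariate = uni)
}

#' Run the full study-shaped analysis on a synthetic cohort
#'
#' Generates the cohort, simulates the measured blocks (optionally pushing
#' the NMR panel through spectrum simulation, preprocessing and region
#' integration rather than using the concentrations directly), applies the
#' targeted-MS QC chain, then runs every comparison of the plan: multilevel
#' or weight-gain OPLS-DA with grouped cross-validation and permutation
#' testing, VIP ranking, and the block's univariate arm with blockwise FDR.
#' Deterministic given the config seed.
#'
#' @param config a [cohort_config()]
#' @param plan an [default_analysis_plan()]-style plan
#' @param use_spectra quantify the NMR block from simulated spectra
#'   (default TRUE); FALSE uses simulated concentrations directly
#' @return object of class `analysis_report`
#' @export
run_full_analysis <- function(config, plan = default_analysis_plan(),
                              use_spectra = TRUE) {
  clinical <- generate_cohort(config)
  mrs_conc <- simulate_metabolite_matrix(clinical, config, platform = "MRS")
  mrs <- if (use_spectra) {
    quantify_spectra(simulate_spectra(mrs_conc, config))$matrix
  } else mrs_conc
  ms_raw <- simulate_metabolite_matrix(clinical, config, platform = "MS")
  qc <- ms_qc_pipeline(ms_raw)
  lipo <- simulate_lipoprotein_panel(clinical, config)
  blocks <- list(MRS = mrs, MS = qc$matrix, LIPO = lipo)
  validate_plan(plan, blocks)
  results <- lapply(plan$comparisons, run_one_comparison,
                    blocks = blocks, clinical = clinical, plan = plan,
                    seed = config$seed)
  names(results) <- vapply(results, `[[`, "", "label")
  structure(list(results = results, qc_report = qc$report,
                 clinical = clinical,
                 provenance = list(seed = config$seed,
                                   config_hash = config_hash(config),
                                   package_version = as.character(utils::packageVersion("longmet")),
                                   r_version = R.version.string)),
            class = "analysis_report")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write an analysis report to disk
#'
#' A master JSON document plus one CSV per table (QC report, and per
#' comparison the CV error curve, VIP ranking and univariate table).
#'
#' @param report an `analysis_report`
#' @param dir output directory (created if needed)
#' @param formats subset of `c("json", "csv_bundle")`
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir, formats = c("json", "csv_bundle")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report_as_list(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("csv_bundle" %in% formats) {
    p <- file.path(dir, "qc_report.csv")
    utils::write.csv(report$qc_report, p, row.names = FALSE)
    paths <- c(paths, p)
    for (res in report$results) {
      base <- file.path(dir, res$label)
      utils::write.csv(res$cv$curve, paste0(base, "_cv_curve.csv"), row.names = FALSE)
      utils::write.csv(res$vip, paste0(base, "_vip.csv"), row.names = FALSE)
      utils::write.csv(res$univariate, paste0(base, "_univariate.csv"), row.names = FALSE)
      paths <- c(paths, paste0(base, c("_cv_curve.csv", "_vip.csv", "_univariate.csv")))
    }
  }
  invisible(paths)
}

# JSON-friendly view of a report: schema_version + per-comparison summaries
report_as_list <- function(report) {
  list(schema_version = "1.0",
       provenance = report$provenance,
       comparisons = lapply(report$results, function(res) {
         list(label = res$label,
              block = res$comparison$block,
              design = res$comparison$design,
              group_filter = res$comparison$group_filter,
              n_patients = res$n_patients,
              chosen_n_orth = res$cv$chosen_n_orth,
              accuracy = res$cv$accuracy,
              sensitivity = res$cv$sensitivity,
              specificity = res$cv$specificity,
              error_curve = res$cv$curve$error,
              permutation_p = res$permutation$p_value,
              permutation_p_label = res$permutation$p_label,
              n_perm = res$permutation$n_perm,
              top_vip = res$vip$variable[seq_len(min(10, nrow(res$vip)))],
              n_significant_q05 = sum(res$univariate$q <= 0.05, na.rm = TRUE))
       }))
}
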