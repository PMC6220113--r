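#' Linear mixed-model time trend for one metabolite
#'
#' Natural-log concentrations are modelled with a fixed categorical timepoint
#' effect and a random per-patient intercept, fitted by REML (nlme). Patients
#' with a single timepoint are retained, which is the point of using a mixed
#' model over a paired test. The p value is the Wald test on the time
#' coefficient. On complete balanced data the estimate equals the mean
#' within-patient log difference. Data with no within-patient variance at all
#' are degenerate for REML and are returned with estimate 0 and p 1, flagged.
#'
#' @param matrix a cleaned, imputed [metabolite_matrix()]
#' @param variable variable name
#' @param t_ref,t_cmp baseline and comparison timepoints; the estimate is the
#'   log change at `t_cmp` relative to `t_ref`
#' @param group_filter optional logical index on patients (e.g. chemotherapy
#'   recipients), as a vector of patient ids to keep
#' @return object of class `lmm_result`: `variable`, `estimate`,
#'   `std_error`, `p_value`, `n_patients_used`, `degenerate`
#' @export
lmm_time_effect <- function(matrix, variable, t_ref = 0, t_cmp = 6,
                            group_filter = NULL) {
  j <- match(variable, matrix$variable_meta$name)
  if (is.na(j)) stopf("lmm_time_effect: unknown variable %s", variable)
  sm <- matrix$sample_meta
  sel <- sm$timepoint_months %in% c(t_ref, t_cmp)
  if (!is.null(group_filter)) sel <- sel & sm$patient_id %in% group_filter
  v <- matrix$values[sel, j]
  df <- data.frame(patient = sm$patient_id[sel],
                   time = factor(sm$timepoint_months[sel], c(t_ref, t_cmp)),
                   value = v)
  df <- df[!is.na(df$value), ]
  if (any(df$value <= 0))
    stopf("lmm_time_effect: non-positive concentrations; impute before log transform")
  if (length(unique(df$patient)) < 6L)
    stopf("lmm_time_effect: fewer than 6 patients with data")
  df$logv <- log(df$value)
  # degenerate: no residual variance after removing patient means
  within_var <- stats::var(df$logv - stats::ave(df$logv, df$patient))
  if (!is.finite(within_var) || within_var < 1e-24) {
    return(structure(list(variable = variable, estimate = 0, std_error = 0,
                          p_value = 1, n_patients_used = length(unique(df$patient)),
                          degenerate = TRUE), class = "lmm_result"))
  }
  fit <- tryCatch(
    nlme::lme(logv ~ time, random = ~ 1 | patient, data = df, method = "REML"),
    error = function(e) stopf("lmm_time_effect: convergence failure for %s (%s)",
                              variable, conditionMessage(e)))
  tt <- summary(fit)$tTable
  structure(list(variable = variable,
                 estimate = unname(tt[2, "Value"]),
                 std_error = unname(tt[2, "Std.Error"]),
                 p_value = unname(tt[2, "p-value"]),
                 n_patients_used = length(unique(df$patient)),
                 degenerate = FALSE),
            class = "lmm_result")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; ties are mid-ranked. The exact null
#' distribution is used for n <= 25 non-zero tie-free differences, the
#' normal approximation with continuity correction above (and whenever ties
#' make the exact distribution unavailable). All-zero input is degenerate and
#' returns p = 1 with a flag.
#'
#' @param paired_diffs numeric vector of within-pair differences
#' @return list with `statistic` (V), `p_value`, `n_nonzero`, `degenerate`
#' @export
wilcoxon_signed_rank <- function(paired_diffs) {
  d <- paired_diffs[!is.na(paired_diffs)]
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, degenerate = TRUE))
  if (length(nz) < 5L)
    stopf("wilcoxon_signed_rank: need >= 5 non-zero differences")
  exact <- length(nz) <= 25L
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(nz), degenerate = FALSE)
}

#' Two-sample t test
#'
#' Two-sided; pooled variance by default (Welch optional).
#'
#' @param values numeric vector
#' @param group_labels two-level grouping of the same length
#' @param welch use the Welch correction instead of pooled variance
#' @return list with `statistic`, `p_value`, `df`, `estimate` (mean difference)
#' @export
two_sample_t <- function(values, group_labels, welch = FALSE) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stopf("two_sample_t: exactly two groups required")
  if (any(table(g[!is.na(values)]) < 2L)) stopf("two_sample_t: need >= 2 values per group")
  tt <- stats::t.test(values ~ g, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       estimate = unname(diff(rev(tt$estimate))))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the point-probability rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. The conditional maximum
#' likelihood odds ratio is reported.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return list with `odds_ratio`, `p_value`
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == 2L)) stopf("fisher_exact_2x2: a 2x2 table is required")
  if (any(tb < 0) || any(tb != round(tb)))
    stopf("fisher_exact_2x2: counts must be non-negative integers")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stopf("fisher_exact_2x2: both margins must be positive")
  ft <- stats::fisher.test(tb)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Benjamini-Hochberg q values within named blocks
#'
#' Step-up FDR correction applied within each block (e.g. MRS, MS and
#' lipoprotein panels separately); q values in one block never depend on p
#' values from another.
#'
#' @param p_values numeric p values in \[0, 1\]
#' @param block_label one block name per p value (default: a single block)
#' @return q values, same order as the input
#' @export
fdr_bh <- function(p_values, block_label = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("fdr_bh: p values must lie in [0, 1]")
  if (is.null(block_label)) block_label <- rep("all", length(p_values))
  q <- rep(NA_real_, length(p_values))
  for (b in unique(block_label)) {
    idx <- which(block_label == b)
    q[idx] <- stats::p.adjust(p_values[idx], method = "BH")
  }
  q
}

#' Friedewald LDL cholesterol
#'
#' ldl = tc - hdl - tg / 2.2 (all mmol/L), valid for tg < 4.5 mmol/L.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol and triglycerides
#' @return LDL cholesterol, mmol/L
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
    stopf("friedewald_ldl: inputs must be non-negative")
  if (any(tg >= 4.5, na.rm = TRUE))
    stopf("friedewald_ldl: formula invalid for tg >= 4.5 mmol/L")
  tc - hdl - tg / 2.2
}

#' Classify 6-month weight gain
#'
#' A patient is a gainer when weight rose by at least 1.5 kg between baseline
#' and 6 months (boundary inclusive); patients without a 6-month weight are
#' `unknown` and excluded from gain-based analyses.
#'
#' @param clinical a [generate_cohort()]-style table with `weight_0`,
#'   `weight_6`
#' @return factor per patient with levels gainer/non_gainer/unknown, named by
#'   patient id
#' @export
classify_weight_gain <- function(clinical) {
  if (any(is.na(clinical$weight_0)))
    stopf("classify_weight_gain: baseline weight missing")
  delta <- clinical$weight_6 - clinical$weight_0
  out <- ifelse(is.na(delta), "unknown",
                ifelse(delta >= 1.5, "gainer", "non_gainer"))
  stats::setNames(factor(out, c("gainer", "non_gainer", "unknown")),
                  clinical$patient_id)
}

#' Univariate screen of a metabolite block
#'
#' Runs the block's designated test per variable (LMM time trend for MS/MRS,
#' Wilcoxon signed-rank on within-patient differences for lipoproteins, or a
#' two-sample t test on log baseline values for group comparisons) and
#' appends blockwise BH q values.
#'
#' @param matrix a cleaned [metabolite_matrix()]
#' @param design `"multilevel_time"` (t_ref vs t_cmp within patients) or
#'   `"group_baseline"` (two-sample comparison at `t_ref`)
#' @param test `"lmm"`, `"wilcoxon"` or `"ttest"`
#' @param t_ref,t_cmp timepoints
#' @param group_filter patient ids to keep (multilevel designs)
#' @param group_labels named +1/-1 or two-level labels per patient
#'   (group designs)
#' @param block block label used for the FDR family
#' @return data.frame `variable, block, test, statistic, p, q`
#' @export
univariate_table <- function(matrix, design = c("multilevel_time", "group_baseline"),
                             test = c("lmm", "wilcoxon", "ttest"),
                             t_ref = 0, t_cmp = 6, group_filter = NULL,
                             group_labels = NULL, block = "block") {
  design <- match.arg(design); test <- match.arg(test)
  vars <- matrix$variable_meta$name
  stat <- p <- rep(NA_real_, length(vars))
  if (design == "multilevel_time") {
    if (test == "lmm") {
      for (i in seq_along(vars)) {
        r <- lmm_time_effect(matrix, vars[i], t_ref, t_cmp, group_filter)
        stat[i] <- r$estimate / max(r$std_error, .Machine$double.eps)
        p[i] <- r$p_value
      }
    } else if (test == "wilcoxon") {
      sm <- matrix$sample_meta
      keep_pat <- if (is.null(group_filter)) unique(sm$patient_id) else group_filter
      a <- matrix$values[match(paste0(keep_pat, "_t", t_ref), rownames(matrix$values)), , drop = FALSE]
      b <- matrix$values[match(paste0(keep_pat, "_t", t_cmp), rownames(matrix$values)), , drop = FALSE]
      for (i in seq_along(vars)) {
        r <- wilcoxon_signed_rank(b[, i] - a[, i])
        stat[i] <- r$statistic; p[i] <- r$p_value
      }
    } else stopf("univariate_table: t test is not a paired-time design test")
  } else {
    if (is.null(group_labels)) stopf("univariate_table: group_labels required")
    sm <- matrix$sample_meta
    idx <- which(sm$timepoint_months == t_ref &
                   sm$patient_id %in% names(group_labels))
    g <- group_labels[sm$patient_id[idx]]
    for (i in seq_along(vars)) {
      v <- matrix$values[idx, i]
      r <- if (test == "ttest") two_sample_t(log(v), g) else {
        wt <- suppressWarnings(stats::wilcox.test(v ~ factor(g)))
        list(statistic = unname(wt$statistic), p_value = wt$p.value)
      }
      stat[i] <- r$statistic; p[i] <- r$p_value
    }
  }
  data.frame(variable = vars, block = block, test = test,
             statistic = stat, p = p, q = fdr_bh(p, rep(block, length(p))))
}
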