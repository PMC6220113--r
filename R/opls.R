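#' Build the multilevel (paired) design from two timepoints
#'
#' For every patient with complete data at both timepoints, the within-patient
#' difference enters twice with mirrored signs: the reference timepoint is
#' represented as the row `x_ref - x_cmp` with label +1 and the comparison
#' timepoint as `x_cmp - x_ref` with label -1. Discriminating the two mirrored
#' classes is the multivariate analogue of the paired t-test: between-patient
#' variation cancels and only intra-patient change remains. Patients missing
#' either timepoint (or with any missing value in the used rows) are excluded
#' and listed.
#'
#' @param matrix a cleaned, imputed [metabolite_matrix()]
#' @param t_ref,t_cmp the two timepoints (month offsets) to contrast
#' @return object of class `paired_dataset`: `X` (2 rows per patient),
#'   `y` (+1/-1), `patient_id` per row, `variables`, `excluded_patients`
#' @export
build_paired_dataset <- function(matrix, t_ref, t_cmp) {
  sm <- matrix$sample_meta
  if (any(matrix$censored)) stopf("build_paired_dataset: censored cells present; run QC first")
  ref_idx <- which(sm$timepoint_months == t_ref)
  cmp_idx <- which(sm$timepoint_months == t_cmp)
  if (!length(ref_idx) || !length(cmp_idx))
    stopf("build_paired_dataset: timepoint not present in the matrix")
  complete_rows <- !is.na(rowSums(matrix$values))
  ref_pat <- sm$patient_id[ref_idx[complete_rows[ref_idx]]]
  cmp_pat <- sm$patient_id[cmp_idx[complete_rows[cmp_idx]]]
  both <- intersect(ref_pat, cmp_pat)
  excluded <- setdiff(unique(sm$patient_id), both)
  if (length(both) < 6L)
    stopf("build_paired_dataset: only %d patients have both timepoints (need >= 6)",
          length(both))
  a <- matrix$values[match(paste0(both, "_t", t_ref), rownames(matrix$values)), , drop = FALSE]
  b <- matrix$values[match(paste0(both, "_t", t_cmp), rownames(matrix$values)), , drop = FALSE]
  d <- a - b
  X <- rbind(d, -d)
  y <- rep(c(1, -1), each = length(both))
  pid <- rep(both, 2)
  ord <- order(match(pid, both), -y)  # per patient: +1 row then its mirror
  structure(list(X = X[ord, , drop = FALSE], y = y[ord], patient_id = pid[ord],
                 variables = colnames(matrix$values),
                 t_ref = t_ref, t_cmp = t_cmp, excluded_patients = excluded),
            class = "paired_dataset")
}

#' Column scaling with a reusable recipe
#'
#' Mean-centres always; optionally divides by the sample standard deviation
#' (autoscaling). Zero-variance columns are centred, given scale 1 and
#' flagged rather than divided.
#'
#' @param X numeric matrix (>= 2 rows)
#' @param unit_variance divide by column sd? (default TRUE)
#' @param recipe an existing recipe to apply instead of fitting a new one
#' @return list with `X` (scaled), `center`, `scale`, `constant` (flag per
#'   column), `unit_variance`
#' @export
scale_columns <- function(X, unit_variance = TRUE, recipe = NULL) {
  if (is.null(recipe)) {
    if (nrow(X) < 2L) stopf("scale_columns: need >= 2 rows to fit a recipe")
    ctr <- colMeans(X)
    s <- apply(X, 2, stats::sd)
    constant <- !is.finite(s) | s == 0
    s[constant] <- 1
    if (!unit_variance) s[] <- 1
    recipe <- list(center = ctr, scale = s, constant = constant,
                   unit_variance = unit_variance)
  }
  Xs <- sweep(sweep(X, 2, recipe$center), 2, recipe$scale, `/`)
  c(list(X = Xs), recipe)
}

# one NIPALS PLS1 component: weights from X'y, scores, x/y loadings
pls1_component <- function(X, y) {
  w <- crossprod(X, y)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stopf("fit_opls_da: X'y is numerically zero; no predictive direction")
  w <- w / nw
  t <- as.vector(X %*% w)
  tt <- sum(t^2)
  p <- as.vector(crossprod(X, t)) / tt
  q <- sum(y * t) / tt
  list(w = as.vector(w), t = t, p = p, q = q)
}

#' Fit an OPLS-DA model
#'
#' NIPALS orthogonal projections to latent structures for a two-class ±1
#' response: `n_orth` times, the y-predictive direction `w` is computed from
#' the current residual, the label-orthogonal part of its loading is split
#' off as an orthogonal component and deflated from X; one predictive
#' component is then fitted on the filtered matrix. Input is scaled with
#' [scale_columns()] (autoscaling by default) and the recipe is stored for
#' prediction.
#'
#' @param X raw data matrix (rows = samples)
#' @param y labels in {+1, -1}
#' @param n_orth number of orthogonal components (>= 0)
#' @param unit_variance autoscale (TRUE) or centre only
#' @return object of class `opls_model`: scaling recipe, predictive
#'   `w`/`p`/`t`/`q`, orthogonal `W_o`/`P_o`/`T_o`, variable names
#' @export
fit_opls_da <- function(X, y, n_orth = 0, unit_variance = TRUE) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stopf("fit_opls_da: y must be coded +1/-1")
  if (length(unique(y)) != 2L) stopf("fit_opls_da: both classes must be present")
  if (n_orth < 0) stopf("fit_opls_da: n_orth must be >= 0")
  sc <- scale_columns(X, unit_variance = unit_variance)
  Xd <- sc$X
  p_vars <- ncol(Xd)
  W_o <- P_o <- matrix(0, p_vars, 0)
  T_o <- matrix(0, nrow(Xd), 0)
  for (a in seq_len(n_orth)) {
    comp <- pls1_component(Xd, y)
    w_o <- comp$p - sum(comp$w * comp$p) * comp$w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-10)
      stopf("fit_opls_da: residual orthogonal rank exhausted at component %d", a)
    w_o <- w_o / n_wo
    t_o <- as.vector(Xd %*% w_o)
    p_o <- as.vector(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  pred <- pls1_component(Xd, y)
  structure(list(center = sc$center, scale = sc$scale, constant = sc$constant,
                 unit_variance = unit_variance,
                 w = pred$w, p = pred$p, t = pred$t, q = pred$q,
                 W_o = W_o, P_o = P_o, T_o = T_o, n_orth = n_orth,
                 variables = colnames(X) %||% paste0("V", seq_len(p_vars))),
            class = "opls_model")
}

#' Predict scores and classes from an OPLS-DA model
#'
#' New rows are scaled with the training recipe, the stored orthogonal
#' components are removed in training order, and the predictive score is the
#' projection on `w`. The class is `sign(score * q)`, with a score of exactly
#' zero assigned to +1.
#'
#' @param object an `opls_model`
#' @param newdata matrix with the training variables (matched by name when
#'   column names are present)
#' @param ... unused
#' @return list with `score` and `class` (+1/-1) per row
#' @export
predict.opls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!setequal(colnames(newdata), object$variables))
      stopf("predict.opls_model: variable set mismatch")
    newdata <- newdata[, object$variables, drop = FALSE]
  } else if (ncol(newdata) != length(object$variables)) {
    stopf("predict.opls_model: expected %d variables, got %d",
          length(object$variables), ncol(newdata))
  }
  Xs <- scale_columns(newdata, recipe = object)$X
  for (a in seq_len(ncol(object$W_o))) {
    t_o <- as.vector(Xs %*% object$W_o[, a])
    Xs <- Xs - tcrossprod(t_o, object$P_o[, a])
  }
  score <- as.vector(Xs %*% object$w)
  cls <- ifelse(score * object$q >= 0, 1, -1)
  list(score = score, class = cls)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d variables, 1 predictive + %d orthogonal component(s)\n",
              length(x$w), x$n_orth))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a) over components with
#' explained label variance. Orthogonal components are label-orthogonal by
#' construction (SSY = 0), so only the predictive component contributes and
#' the score reduces to sqrt(p) * |w_j|; squared VIPs average to exactly 1.
#'
#' @param model a fitted `opls_model`
#' @return named non-negative vector of VIP scores
#' @export
vip_scores <- function(model) {
  v <- sqrt(length(model$w)) * abs(model$w)
  stats::setNames(v, model$variables)
}
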