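# canonical internal form for CV: X, y (+1/-1), patient_id, paired flag
as_ml_dataset <- function(data) {
  if (inherits(data, "paired_dataset"))
    return(list(X = data$X, y = data$y, patient_id = data$patient_id, paired = TRUE))
  if (is.list(data) && all(c("X", "y") %in% names(data))) {
    pid <- data$patient_id %||% paste0("r", seq_len(nrow(data$X)))
    if (anyDuplicated(pid) && !isTRUE(data$paired))
      stopf("unpaired dataset: patient_id must be unique per row")
    return(list(X = as.matrix(data$X), y = data$y, patient_id = pid, paired = FALSE))
  }
  stopf("cross_validate: data must be a paired_dataset or a list(X, y, patient_id)")
}

# fit the whole orthogonal path once: models for n_orth = 0..max_orth share
# one scaling recipe and one deflation sequence
fit_opls_path <- function(X, y, max_orth, unit_variance = TRUE) {
  sc <- scale_columns(as.matrix(X), unit_variance = unit_variance)
  Xd <- sc$X
  p <- ncol(Xd)
  W_o <- P_o <- matrix(0, p, 0)
  pred <- vector("list", max_orth + 1L)
  pred[[1L]] <- pls1_component(Xd, y)
  for (a in seq_len(max_orth)) {
    comp <- pred[[a]]
    w_o <- comp$p - sum(comp$w * comp$p) * comp$w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-10) { pred <- pred[seq_len(a)]; break }
    w_o <- w_o / n_wo
    t_o <- as.vector(Xd %*% w_o)
    p_o <- as.vector(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
    pred[[a + 1L]] <- pls1_component(Xd, y)
  }
  list(recipe = sc, W_o = W_o, P_o = P_o, pred = pred)
}

# test-set scores along the path: one column per n_orth in 0..length(pred)-1
predict_opls_path <- function(path, X_new) {
  Xs <- sweep(sweep(as.matrix(X_new), 2, path$recipe$center), 2,
              path$recipe$scale, `/`)
  k <- length(path$pred)
  out <- matrix(NA_real_, nrow(Xs), k)
  for (a in seq_len(k)) {
    comp <- path$pred[[a]]
    out[, a] <- (Xs %*% comp$w) * comp$q  # sign gives the class
    if (a <= ncol(path$W_o)) {
      t_o <- as.vector(Xs %*% path$W_o[, a])
      Xs <- Xs - tcrossprod(t_o, path$P_o[, a])
    }
  }
  out
}

#' Choose the orthogonal-component count from an error curve
#'
#' Returns the first local minimum of the mean classification-error curve:
#' the smallest index whose error does not exceed either neighbour. Ties are
#' broken toward fewer components; a strictly decreasing curve yields the
#' last index.
#'
#' @param errors mean classification errors for n_orth = 0, 1, 2, ...
#' @return chosen n_orth (0-based position in the curve)
#' @export
select_components <- function(errors) {
  k <- length(errors)
  if (!k) stopf("select_components: empty error curve")
  for (i in seq_len(k)) {
    if ((i == 1L || errors[i] <= errors[i - 1L]) &&
        (i == k  || errors[i] <= errors[i + 1L])) return(i - 1L)
  }
  k - 1L
}

# patient-level fold assignment; for unpaired data folds are stratified by
# class so every training set contains both labels
assign_folds <- function(patients, y_by_patient, n_folds, paired) {
  folds <- integer(length(patients))
  if (paired) {
    folds <- sample(rep_len(seq_len(n_folds), length(patients)))
  } else {
    for (cl in unique(y_by_patient)) {
      idx <- which(y_by_patient == cl)
      folds[idx] <- sample(rep_len(sample(n_folds), length(idx)))
    }
  }
  folds
}

#' Patient-grouped cross-validation of OPLS-DA
#'
#' Folds partition patients, never rows: both mirrored rows of a patient in a
#' multilevel design always share a fold, so no patient contributes to both
#' training and test of any split (asserted on every run). The scaling recipe
#' is refit inside each training fold. Classification error, sensitivity and
#' specificity are computed per iteration (each sample predicted once) for
#' every orthogonal-component count 0..`max_orth`, averaged over the
#' `n_iter` random fold assignments, and the component count is chosen as the
#' first local minimum of the mean error curve.
#'
#' @param data a `paired_dataset`, or a list `(X, y, patient_id)` with one
#'   row per patient and labels in {+1, -1}
#' @param max_orth largest orthogonal-component count searched
#' @param n_folds number of patient folds (default 10)
#' @param n_iter number of repeated fold assignments (default 20)
#' @param seed integer seed for fold assignment
#' @param unit_variance autoscale within training folds (default TRUE)
#' @return object of class `cv_result`: `curve` (per-n_orth mean error,
#'   sensitivity, specificity), `chosen_n_orth`, `accuracy`, `sensitivity`,
#'   `specificity`
#' @export
cross_validate <- function(data, max_orth = 3, n_folds = 10, n_iter = 20,
                           seed = 1, unit_variance = TRUE) {
  d <- as_ml_dataset(data)
  patients <- unique(d$patient_id)
  if (length(patients) < n_folds)
    stopf("cross_validate: %d patients but %d folds requested",
          length(patients), n_folds)
  rows_by_patient <- split(seq_along(d$patient_id), match(d$patient_id, patients))
  y_by_patient <- vapply(rows_by_patient, function(r) d$y[r[1]], numeric(1))
  k <- max_orth + 1L
  set.seed(derive_seed(seed, "cv-folds"))
  # confusion counts per iteration and n_orth
  tp <- tn <- fp <- fn <- matrix(0, n_iter, k)
  for (it in seq_len(n_iter)) {
    folds <- assign_folds(patients, y_by_patient, n_folds, d$paired)
    for (f in seq_len(n_folds)) {
      test_pat <- which(folds == f)
      if (!length(test_pat)) next
      test_rows <- unlist(rows_by_patient[test_pat], use.names = FALSE)
      train_rows <- unlist(rows_by_patient[-test_pat], use.names = FALSE)
      if (length(intersect(d$patient_id[train_rows], d$patient_id[test_rows])))
        stopf("cross_validate: internal error - patient split across train and test")
      path <- fit_opls_path(d$X[train_rows, , drop = FALSE], d$y[train_rows],
                            max_orth, unit_variance)
      sc <- predict_opls_path(path, d$X[test_rows, , drop = FALSE])
      if (ncol(sc) < k) sc <- cbind(sc, sc[, rep(ncol(sc), k - ncol(sc)), drop = FALSE])
      pred <- ifelse(sc >= 0, 1, -1)
      truth <- d$y[test_rows]
      tp[it, ] <- tp[it, ] + colSums(pred == 1 & truth == 1)
      tn[it, ] <- tn[it, ] + colSums(pred == -1 & truth == -1)
      fp[it, ] <- fp[it, ] + colSums(pred == 1 & truth == -1)
      fn[it, ] <- fn[it, ] + colSums(pred == -1 & truth == 1)
    }
  }
  sens_it <- tp / (tp + fn)
  spec_it <- tn / (tn + fp)
  sens <- colMeans(sens_it); spec <- colMeans(spec_it)
  err <- 1 - (sens + spec) / 2
  chosen <- select_components(err)
  curve <- data.frame(n_orth = 0:max_orth, error = err,
                      sensitivity = sens, specificity = spec)
  structure(list(curve = curve, chosen_n_orth = chosen,
                 accuracy = 1 - err[chosen + 1L],
                 sensitivity = sens[chosen + 1L],
                 specificity = spec[chosen + 1L],
                 n_folds = n_folds, n_iter = n_iter, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> chosen n_orth = %d, accuracy = %.3f (sens %.3f / spec %.3f)\n",
              x$chosen_n_orth, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Permutation test of cross-validated accuracy
#'
#' The observed cross-validated accuracy is compared with the accuracies of
#' models trained on label-permuted data. Permutations respect the design:
#' for multilevel data, each patient's mirrored +1/-1 pair keeps or swaps its
#' labels at random (equivalently the difference vector's sign is flipped),
#' preserving the antisymmetric structure; for unpaired data, labels are
#' shuffled across patients. By default component selection is rerun inside
#' every permutation; `fix_n_orth` freezes it instead. The p value is the
#' plain proportion of permuted accuracies greater than or equal to the
#' observed one; an exceedance count of zero is additionally reported as
#' "< 1/n_perm".
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (default 1000)
#' @param fix_n_orth optional fixed orthogonal-component count for the
#'   permuted refits (default NULL: selection rerun per permutation)
#' @return object of class `permutation_result`: `observed_accuracy`,
#'   `permuted_accuracies`, `p_value`, `p_label`
#' @export
permutation_test <- function(data, max_orth = 3, n_folds = 10, n_iter = 20,
                             n_perm = 1000, seed = 1, unit_variance = TRUE,
                             fix_n_orth = NULL) {
  if (n_perm < 1) stopf("permutation_test: n_perm must be >= 1")
  d <- as_ml_dataset(data)
  obs <- cross_validate(data, max_orth = max_orth, n_folds = n_folds,
                        n_iter = n_iter, seed = seed,
                        unit_variance = unit_variance)
  patients <- unique(d$patient_id)
  perm_acc <- numeric(n_perm)
  perm_max <- if (is.null(fix_n_orth)) max_orth else fix_n_orth
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("perm-draw-", b)))
    db <- d
    if (d$paired) {
      flip <- sample(c(1, -1), length(patients), replace = TRUE)
      fl <- flip[match(d$patient_id, patients)]
      db$X <- d$X * fl
      # labels unchanged: flipping the difference sign relabels the pair
    } else {
      yp <- sample(d$y[match(patients, d$patient_id)])
      db$y <- yp[match(d$patient_id, patients)]
    }
    cvb <- cross_validate(db, max_orth = perm_max, n_folds = n_folds,
                          n_iter = n_iter,
                          seed = derive_seed(seed, paste0("perm-cv-", b)),
                          unit_variance = unit_variance)
    perm_acc[b] <- if (is.null(fix_n_orth)) cvb$accuracy else
      1 - cvb$curve$error[fix_n_orth + 1L]
  }
  p <- sum(perm_acc >= obs$accuracy) / n_perm
  structure(list(observed_accuracy = obs$accuracy, observed_cv = obs,
                 permuted_accuracies = perm_acc, p_value = p,
                 p_label = if (p == 0) sprintf("< %g", 1 / n_perm) else
                   format(p, digits = 3),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.3f, p = %s (%d permutations)\n",
              x$observed_accuracy, x$p_label, x$n_perm))
  invisible(x)
}
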