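# shared fixture builders; everything is generated in code under fixed seeds

# paired multilevel dataset with pure-noise differences
make_null_paired <- function(seed, n_pat = 40, p = 50) {
  set.seed(seed)
  d <- matrix(rnorm(n_pat * p), n_pat, p)
  X <- rbind(d, -d)
  colnames(X) <- paste0("V", seq_len(p))
  structure(list(X = X, y = rep(c(1, -1), each = n_pat),
                 patient_id = rep(sprintf("P%03d", seq_len(n_pat)), 2),
                 variables = colnames(X), t_ref = 0, t_cmp = 6,
                 excluded_patients = character(0)),
            class = "paired_dataset")
}

# paired dataset with a planted mean shift of size `delta` on `signal` columns
make_signal_paired <- function(seed, n_pat = 40, p = 50, signal = 5, delta = 1) {
  ds <- make_null_paired(seed, n_pat, p)
  d <- ds$X[seq_len(n_pat), , drop = FALSE]
  d[, seq_len(signal)] <- d[, seq_len(signal)] + delta
  ds$X <- rbind(d, -d)
  ds
}

# synthetic spectrum: sum of Lorentzians on a descending axis
make_spectrum <- function(peaks, n_points = 8192, lo = -0.5, hi = 10,
                          noise = 0, baseline = 0, seed = 1) {
  set.seed(seed)
  ppm <- seq(hi, lo, length.out = n_points)
  y <- rep(baseline, n_points)
  for (pk in peaks) {
    y <- y + (pk$area / pi) * pk$hw / ((ppm - pk$center)^2 + pk$hw^2)
  }
  if (noise > 0) y <- y + rnorm(n_points, 0, noise)
  structure(list(ppm = ppm, intensity = y, sample_id = "S1"),
            class = "spectrum")
}

alanine_peaks <- function(left = 1.470, sep = 0.012, area = 1, hw = 0.0015) {
  list(list(center = left, hw = hw, area = area / 2),
       list(center = left - sep, hw = hw, area = area / 2))
}

# tiny metabolite matrix from raw pieces
make_matrix <- function(values, timepoints, patients = NULL, platform = "MS",
                        lod = NA_real_, censored = NULL) {
  n_pat <- nrow(values) / length(timepoints)
  if (is.null(patients)) patients <- sprintf("P%02d", seq_len(n_pat))
  meta <- expand.grid(timepoint_months = timepoints, patient_id = patients,
                      stringsAsFactors = FALSE)[, 2:1]
  vm <- data.frame(name = colnames(values) %||% paste0("V", seq_len(ncol(values))),
                   platform = platform, class = "x",
                   lod = rep_len(lod, ncol(values)))
  colnames(values) <- vm$name
  metabolite_matrix(values, meta, vm, censored = censored)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher p by exhaustive hypergeometric enumeration (independent
# of stats::fisher.test): sum of P(tables with same margins) whose point
# probability <= that of the observed table
fisher_enum_p <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(tb[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# one-component PLS1 closed form: w = X'y / |X'y|, t = Xw (on pre-scaled X)
pls1_closed_form <- function(Xs, y) {
  w <- crossprod(Xs, y)
  w <- w / sqrt(sum(w^2))
  as.vector(Xs %*% w)
}
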