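#' Derive a reproducible sub-stream seed
#'
#' All randomised operations in the package draw from streams derived from a
#' single user seed plus a short text tag, so that e.g. fold assignment and
#' permutation shuffles are decoupled: changing the number of permutations
#' never alters the folds.
#'
#' @param seed base integer seed
#' @param tag character tag naming the stream
#' @return an integer seed in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483629)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_prop <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Trapezoidal integral over contiguous retained segments
#'
#' Integrates y over x by the trapezoid rule, treating `keep = FALSE` points
#' as absent: no trapezoid spans an excluded point, so excluded regions
#' contribute nothing (rather than being bridged over).
#'
#' @param x ordered abscissa (ascending or descending)
#' @param y ordinates
#' @param keep logical mask of retained points (default all)
#' @return scalar integral (positive for ascending x; |.| used by callers)
#' @keywords internal
trapz_masked <- function(x, y, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(x))
  if (length(x) < 2L) return(0)
  dx <- diff(x)
  mid <- (y[-1] + y[-length(y)]) / 2
  ok <- keep[-1] & keep[-length(keep)]
  sum(dx[ok] * mid[ok])
}
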