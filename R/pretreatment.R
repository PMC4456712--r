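#' Data pretreatment methods
#'
#' Three column-wise transforms compensate the differing scales of the
#' similarity metrics before consensus fusion:
#' \describe{
#'   \item{interval}{interval (range) scaling,
#'     \eqn{(x - \min x) / (\max x - \min x)}, mapping each column onto
#'     `[0, 1]`.}
#'   \item{standardize}{autoscaling, \eqn{(x - \bar x) / s} with the sample
#'     standard deviation (`n - 1` denominator).}
#'   \item{rank}{rank transformation by increasing magnitude, minimum rank 1;
#'     ties receive average (fractional) ranks.}
#' }
#' All three are monotone non-decreasing within a column, so the rank order
#' each metric assigns to the molecules is untouched; pretreatment acts on
#' downstream SRD only through the consensus (average) reference.
#'
#' @param x numeric matrix (columns = metrics) or vector.
#' @param method one of `"none"`, `"interval"`, `"standardize"`, `"rank"`.
#' @return The transformed matrix/vector, same shape as `x`.
#' @seealso [interval_scale()], [standardize()], [rank_transform()]
#' @export
pretreat <- function(x, method = c("none", "interval", "standardize", "rank")) {
  method <- match.arg(method)
  f <- switch(method,
              none = identity,
              interval = interval_scale,
              standardize = standardize,
              rank = rank_transform)
  if (is.matrix(x)) {
    out <- apply(x, 2L, f)
    dimnames(out) <- dimnames(x)
    out
  } else {
    f(x)
  }
}

pretreatment_ids <- function() c("interval", "standardize", "rank")

#' Interval (range) scaling of a column
#'
#' `(x - min) / (max - min)`: the minimum maps to 0 and the maximum to 1. A
#' constant column is degenerate (zero range) and is returned as all zeros
#' with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return Numeric vector in `[0, 1]`.
#' @export
interval_scale <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  r <- range(x)
  if (r[1L] == r[2L]) {
    warning("constant column: interval scaling returns zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Standardization (autoscaling) of a column
#'
#' `(x - mean) / sd` with the sample standard deviation. The output has mean
#' 0 and unit sample variance. A constant column (zero sd) is returned as
#' all zeros with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return Numeric vector with mean 0.
#' @export
standardize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant column: standardization returns zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Rank transformation of a column
#'
#' Ranks by increasing magnitude: the smallest value gets rank 1 and, for a
#' tie-free column of length `m`, the largest gets rank `m`. Ties receive
#' average ranks, so every column's ranks sum to `m(m+1)/2`.
#'
#' @param x numeric vector.
#' @return Numeric vector of (possibly fractional) ranks.
#' @export
rank_transform <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  rank(x, ties.method = "average")
}
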