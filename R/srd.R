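#' Consensus (data fusion) reference column
#'
#' Row-wise arithmetic mean of the metric columns, used as the "golden
#' standard" ranking when no true standard is known. Averaging is the same
#' as SUM fusion here because every row has the same number of columns; the
#' working assumption is that all metrics measure the true (unknown)
#' similarity with error, and errors partially cancel in the mean.
#'
#' @param x numeric matrix, molecules in rows and metrics in columns.
#' @return Numeric vector of row means, length `nrow(x)`.
#' @export
consensus_reference <- function(x) {
  stopifnot(is.matrix(x) || is.data.frame(x))
  rowMeans(as.matrix(x))
}

#' Sum of ranking differences of one ranking against a reference
#'
#' `sum(|rank_i - ref_rank_i|)` over objects: 0 iff the two rankings are
#' identical, and smaller values mean the column ranks the objects more like
#' the reference does.
#'
#' @param column_ranks,reference_ranks numeric rank vectors of equal length
#'   (average ranks permitted for ties).
#' @return A single non-negative number.
#' @examples
#' srd_value(c(3, 2, 1), c(1, 2, 3))  # 4
#' @export
srd_value <- function(column_ranks, reference_ranks) {
  if (length(column_ranks) != length(reference_ranks)) {
    stop("rank vectors must have equal length")
  }
  sum(abs(column_ranks - reference_ranks))
}

#' Maximum attainable SRD for a reference ranking
#'
#' The largest value [srd_value()] can take over all tie-free rankings of
#' `m` objects against the given reference. The maximising assignment pairs
#' the largest candidate ranks with the smallest reference ranks (extremal
#' pairing), so `srd_max = sum(|(m:1) - sort(ref)|)`. For a tie-free
#' reference this reduces to the closed forms `m^2/2` (m even) and
#' `(m^2 - 1)/2` (m odd). The pairing argument also covers tied (average
#' rank) references; tied data columns can never exceed it because a tied
#' rank vector is a convex combination of permutations.
#'
#' @param reference_ranks a rank vector of length `m >= 2`, or a single
#'   integer `m >= 2` meaning a tie-free reference of that size.
#' @return A single positive number.
#' @examples
#' srd_max(3)   # 4
#' srd_max(99)  # 4900
#' @export
srd_max <- function(reference_ranks) {
  if (length(reference_ranks) == 1L) {
    m <- as.integer(reference_ranks)
    if (is.na(m) || m < 2L) stop("need m >= 2")
    reference_ranks <- seq_len(m)
  }
  m <- length(reference_ranks)
  if (m < 2L) stop("need at least 2 objects")
  sum(abs(rev(seq_len(m)) - sort(reference_ranks)))
}

#' Normalise an SRD value to the 0--100 scale
#'
#' `SRDnor = 100 * SRD / SRDmax`, making SRD values comparable across
#' datasets of different size.
#'
#' @param srd raw SRD value(s).
#' @param srd_max maximum attainable SRD for the same reference.
#' @return Numeric in `[0, 100]`.
#' @export
normalize_srd <- function(srd, srd_max) {
  stopifnot(srd_max > 0)
  if (any(srd < 0) || any(srd > srd_max + 1e-9)) {
    stop("srd outside [0, srd_max]: inconsistent ranking computation")
  }
  100 * srd / srd_max
}

# All permutations of 1..m as an m! x m integer matrix.
all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(m - 1L)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    q <- p + (p >= i)
    out[[i]] <- cbind(rep.int(i, nrow(q)), q)
  }
  do.call(rbind, out)
}

#' Null distribution of SRD under random rankings
#'
#' Distribution of the normalised SRD of a uniformly random tie-free ranking
#' of `m` objects against a fixed reference. A method whose SRD falls below
#' the 5% quantile (`XX1`) of this distribution ranks the objects in a way
#' distinguishable from random; between `XX1` and the 95% quantile (`XX19`)
#' it is not.
#'
#' For `m <= 10` the distribution can be enumerated exactly over all `m!`
#' permutations; for larger `m` a seeded Monte Carlo sample is drawn. The
#' raw-scale null mean is `(m^2 - 1)/3` for any `m`. Decisions use the
#' empirical/exact quantiles directly; no normal approximation enters.
#'
#' @param m number of objects (>= 2).
#' @param method `"auto"` (exact up to `m = 8`, else Monte Carlo),
#'   `"exact"`, or `"montecarlo"`.
#' @param n_samples Monte Carlo sample count (>= 10^4).
#' @param seed integer seed for the Monte Carlo draw.
#' @return An object of class `"srd_null"`: list with `m`, `method`,
#'   `srd_max`, `mean_raw`, `quantiles` (named `xx1`, `med`, `xx19`, on the
#'   normalised scale), and either `pmf` (exact: data.frame `srd`,
#'   `srd_nor`, `prob`) or `samples` (Monte Carlo, normalised scale).
#' @examples
#' null_distribution(3, method = "exact")$pmf
#' @export
null_distribution <- function(m, method = c("auto", "exact", "montecarlo"),
                              n_samples = 10000L, seed = NULL) {
  method <- match.arg(method)
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("need m >= 2")
  if (method == "auto") method <- if (m <= 8L) "exact" else "montecarlo"
  smax <- srd_max(m)
  ref <- seq_len(m)
  if (method == "exact") {
    if (m > 10L) {
      stop("exact enumeration is limited to m <= 10; use method = 'montecarlo'")
    }
    perms <- all_permutations(m)
    srds <- rowSums(abs(sweep(perms, 2L, ref)))
    tab <- table(srds)
    pmf <- data.frame(
      srd = as.numeric(names(tab)),
      prob = as.numeric(tab) / length(srds)
    )
    pmf$srd_nor <- normalize_srd(pmf$srd, smax)
    cdf <- cumsum(pmf$prob)
    q <- function(p) pmf$srd_nor[which(cdf >= p - 1e-12)[1L]]
    out <- list(
      m = m, method = "exact", srd_max = smax,
      mean_raw = sum(pmf$srd * pmf$prob),
      pmf = pmf[, c("srd", "srd_nor", "prob")],
      quantiles = c(xx1 = q(0.05), med = q(0.5), xx19 = q(0.95))
    )
  } else {
    n_samples <- as.integer(n_samples)
    if (n_samples < 10000L) stop("montecarlo requires n_samples >= 10^4")
    srds <- with_seed(seed, {
      vapply(seq_len(n_samples),
             function(i) sum(abs(sample.int(m) - ref)), numeric(1))
    })
    vals <- normalize_srd(srds, smax)
    out <- list(
      m = m, method = "montecarlo", srd_max = smax,
      mean_raw = mean(srds),
      samples = vals,
      quantiles = stats::quantile(vals, c(0.05, 0.5, 0.95), type = 1L,
                                  names = FALSE)
    )
    names(out$quantiles) <- c("xx1", "med", "xx19")
  }
  structure(out, class = "srd_null")
}

#' @export
print.srd_null <- function(x, ...) {
  cat(sprintf(
    "<srd_null> m = %d (%s): XX1 = %.2f, Med = %.2f, XX19 = %.2f (SRDnor scale)\n",
    x$m, x$method, x$quantiles[["xx1"]], x$quantiles[["med"]],
    x$quantiles[["xx19"]]
  ))
  invisible(x)
}

#' Flag SRD values against the random-ranking limit
#'
#' A normalised SRD below `XX1` (the 5% quantile of the random-ranking null)
#' lies in the acceptable region: the method is distinguishable from random
#' ranking. Anything at or above `XX1` overlaps the null and is flagged
#' random-like.
#'
#' @param srd_nor numeric vector of normalised SRD values.
#' @param null an [null_distribution()] object for the same `m`.
#' @return Character vector, `"acceptable"` or `"random-like"`.
#' @export
classify_vs_random <- function(srd_nor, null) {
  stopifnot(inherits(null, "srd_null"))
  ifelse(srd_nor < null$quantiles[["xx1"]], "acceptable", "random-like")
}

#' Cross-validated SRD values
#'
#' Bootstrap-like validation of an SRD comparison: leave-one-out when the
#' number of objects is smaller than 14, seven-fold otherwise (each fold
#' recomputes SRD on a 6/7 portion of the rows). Within each retained
#' portion the columns and the reference are re-ranked from their values, so
#' each fold is a full SRD recomputation at reduced `m`. The spread of the
#' fold values measures the uncertainty of each metric's SRD.
#'
#' @param x numeric value matrix (molecules x metrics).
#' @param reference numeric reference values (default: consensus row mean).
#' @param seed integer seed for the fold assignment (7-fold case).
#' @return A `n_folds x n_metrics` matrix of normalised SRD values with
#'   attribute `folds` (the held-out fold index of each row).
#' @export
cross_validate <- function(x, reference = NULL, seed = NULL) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 3L) stop("need at least 3 objects to cross-validate")
  if (is.null(reference)) reference <- consensus_reference(x)
  stopifnot(length(reference) == m)
  if (m < 14L) {
    folds <- seq_len(m)
  } else {
    folds <- with_seed(seed, sample(rep_len(seq_len(7L), m)))
  }
  nf <- max(folds)
  out <- matrix(NA_real_, nf, ncol(x), dimnames = list(NULL, colnames(x)))
  for (f in seq_len(nf)) {
    keep <- folds != f
    ref_r <- rank_transform(reference[keep])
    smax <- srd_max(ref_r)
    col_r <- apply(x[keep, , drop = FALSE], 2L, rank_transform)
    out[f, ] <- normalize_srd(
      colSums(abs(col_r - ref_r)), smax
    )
  }
  attr(out, "folds") <- folds
  out
}

#' Sum of ranking differences comparison of methods
#'
#' Fits the SRD comparison to a value matrix with molecules (objects) in
#' rows and methods (similarity metrics) in columns. After optional
#' column-wise pretreatment, a reference column is added (the consensus row
#' mean unless a golden standard is supplied), every column is ranked by
#' increasing magnitude, and each method's SRD is the sum over objects of
#' the absolute rank differences from the reference ranking. SRD is
#' normalised to 0--100 by its maximum attainable value, validated against
#' the random-ranking null distribution and by cross-validation.
#'
#' SRD depends on each column only through its rank order, so metrics that
#' are strictly monotone functions of one another (Tanimoto, Dice and the
#' Soergel-derived similarity; Manhattan- and Euclidean-derived
#' similarities) receive identical SRD values on every dataset.
#'
#' @param x numeric matrix or data.frame, objects x methods (e.g. a
#'   [similarity_table()]).
#' @param reference optional numeric golden-standard column; default is the
#'   consensus mean of the (pretreated) columns.
#' @param pretreatment one of `"none"`, `"interval"`, `"standardize"`,
#'   `"rank"`, applied column-wise before fusion.
#' @param null optional precomputed [null_distribution()] for `nrow(x)`
#'   (reused across datasets of equal size in batch runs).
#' @param n_null Monte Carlo sample size for the null when it must be
#'   simulated.
#' @param cv logical: run [cross_validate()]?
#' @param seed integer seed for the null simulation and fold assignment.
#' @return An object of class `"srd"`: list with elements `srd`, `srd_nor`
#'   (named per metric), `srd_max`, `m`, `metrics`, `pretreatment`,
#'   `reference_ranks`, `consensus` (logical), `null`, `flags`, `cv`, and
#'   `call`. Methods: [print.srd()], [summary.srd()], [coef.srd()],
#'   [plot.srd()].
#' @examples
#' lib <- generate_library(30, "druglike", nbits = 256, seed = 7)
#' st <- similarity_table(lib[[1]], lib[2:30])
#' fit <- srd(st, seed = 1)
#' coef(fit)
#' @export
srd <- function(x, reference = NULL,
                pretreatment = c("none", "interval", "standardize", "rank"),
                null = NULL, n_null = 10000L, cv = TRUE, seed = NULL) {
  cl <- match.call()
  pretreatment <- match.arg(pretreatment)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  m <- nrow(x)
  if (m < 2L) stop("need at least 2 objects")
  xt <- pretreat(x, pretreatment)
  consensus <- is.null(reference)
  if (consensus) reference <- consensus_reference(xt)
  stopifnot(length(reference) == m)

  ref_ranks <- rank_transform(reference)
  col_ranks <- apply(xt, 2L, rank_transform)
  raw <- colSums(abs(col_ranks - ref_ranks))
  smax <- srd_max(ref_ranks)
  srd_nor <- normalize_srd(raw, smax)

  seeds <- derive_seeds(seed, 2L)
  if (is.null(null)) {
    null <- null_distribution(m, method = "auto", n_samples = n_null,
                              seed = seeds[1L])
  } else {
    stopifnot(inherits(null, "srd_null"))
    if (null$m != m) stop("null distribution was computed for m = ", null$m,
                          ", data have m = ", m)
  }
  flags <- classify_vs_random(srd_nor, null)
  names(flags) <- colnames(x)
  cvm <- if (cv) cross_validate(xt, reference, seed = seeds[2L]) else NULL

  structure(
    list(
      srd = raw, srd_nor = srd_nor, srd_max = smax,
      m = m, metrics = colnames(x), pretreatment = pretreatment,
      reference_ranks = ref_ranks, consensus = consensus,
      null = null, flags = flags, cv = cvm, call = cl
    ),
    class = "srd"
  )
}

#' @export
coef.srd <- function(object, ...) object$srd_nor

#' @export
print.srd <- function(x, digits = 3L, ...) {
  cat("Sum of ranking differences (", x$m, " objects, ",
      length(x$metrics), " methods, pretreatment: ", x$pretreatment,
      ")\n", sep = "")
  cat("Reference:", if (x$consensus) "consensus (column average)"
      else "supplied golden standard", "\n\n")
  ord <- order(x$srd_nor)
  df <- data.frame(
    SRD = x$srd[ord],
    SRDnor = round(x$srd_nor[ord], digits),
    flag = x$flags[ord]
  )
  print(df)
  cat(sprintf("\nRandom-ranking limits (SRDnor): XX1 = %.2f, Med = %.2f, XX19 = %.2f\n",
              x$null$quantiles[["xx1"]], x$null$quantiles[["med"]],
              x$null$quantiles[["xx19"]]))
  invisible(x)
}

#' Summary of an SRD comparison
#'
#' @param object an [srd()] fit.
#' @param ... unused.
#' @return A data.frame (class `"summary.srd"`) with one row per method:
#'   raw SRD, normalised SRD, random-limit flag and, when cross-validation
#'   was run, the median and range of the fold values.
#' @export
summary.srd <- function(object, ...) {
  df <- data.frame(
    metric = object$metrics,
    srd = object$srd,
    srd_nor = object$srd_nor,
    flag = object$flags,
    row.names = NULL
  )
  if (!is.null(object$cv)) {
    df$cv_median <- apply(object$cv, 2L, stats::median)
    df$cv_min <- apply(object$cv, 2L, min)
    df$cv_max <- apply(object$cv, 2L, max)
  }
  df <- df[order(df$srd_nor), ]
  attr(df, "null_quantiles") <- object$null$quantiles
  attr(df, "m") <- object$m
  class(df) <- c("summary.srd", "data.frame")
  df
}

#' @export
print.summary.srd <- function(x, digits = 3L, ...) {
  q <- attr(x, "null_quantiles")
  cat("SRD comparison,", attr(x, "m"), "objects\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("XX1 = %.2f, Med = %.2f, XX19 = %.2f\n",
              q[["xx1"]], q[["med"]], q[["xx19"]]))
  invisible(x)
}

#' Plot an SRD comparison against its random-ranking null
#'
#' Normalised SRD values of the methods are drawn as labelled vertical lines
#' on the 0--100 scale, with the null distribution of random rankings
#' overlaid and its 5%/50%/95% quantiles (XX1/Med/XX19) marked. A method
#' whose line falls left of XX1 ranks the objects distinguishably better
#' than random.
#'
#' @param x an [srd()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.srd <- function(x, ...) {
  null <- x$null
  if (null$method == "exact") {
    xs <- null$pmf$srd_nor
    ys <- null$pmf$prob
  } else {
    h <- graphics::hist(null$samples, breaks = 30L, plot = FALSE)
    xs <- h$mids
    ys <- h$density * mean(diff(h$breaks))
  }
  graphics::plot(xs, ys, type = "h", col = "grey40", xlim = c(0, 100),
                 xlab = "SRDnor", ylab = "random-ranking probability",
                 main = "SRD vs random ranking", ...)
  graphics::abline(v = null$quantiles, lty = 3, col = "grey30")
  graphics::mtext(c("XX1", "Med", "XX19"), at = null$quantiles, side = 3,
                  cex = 0.7, col = "grey30")
  cols <- grDevices::hcl.colors(length(x$srd_nor), "Dark 2")
  graphics::abline(v = x$srd_nor, col = cols, lwd = 2)
  graphics::legend("topleft", legend = sprintf("%s (%.1f)", x$metrics,
                                               x$srd_nor),
                   col = cols, lwd = 2, cex = 0.7, bty = "n")
  invisible(x)
}
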