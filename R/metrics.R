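#' The eight similarity/distance metrics
#'
#' Returns the metric registry: eight coefficients defined on the bit
#' statistics `(a, b, c)` of a fingerprint pair. Manhattan, Euclidean and
#' Soergel are native distances and are converted to similarities with
#' [to_similarity()] when a similarity table is assembled; the rest are
#' native similarities.
#'
#' The dichotomous formulas are:
#' \describe{
#'   \item{manhattan}{distance \eqn{a + b - 2c}}
#'   \item{euclidean}{distance \eqn{\sqrt{a + b - 2c}}}
#'   \item{cosine}{similarity \eqn{c / \sqrt{ab}}}
#'   \item{dice}{similarity \eqn{2c / (a + b)}}
#'   \item{tanimoto}{similarity \eqn{c / (a + b - c)}}
#'   \item{soergel}{distance \eqn{1 - c/(a + b - c)} (complement of Tanimoto)}
#'   \item{substructure}{similarity \eqn{c / a}: the fraction of the query
#'     (reference) molecule's on bits present in the library molecule. This
#'     is a bit-containment surrogate for algorithmic substructure screening
#'     scores, not a graph match.}
#'   \item{superstructure}{similarity \eqn{c / b}: the mirror containment
#'     fraction, likewise a surrogate.}
#' }
#'
#' @return A data.frame with columns `metric` (id) and `kind`
#'   (`"similarity"` or `"distance"`), one row per metric, in canonical
#'   order.
#' @export
similarity_metrics <- function() {
  data.frame(
    metric = c("manhattan", "euclidean", "cosine", "dice",
               "tanimoto", "soergel", "substructure", "superstructure"),
    kind = c("distance", "distance", "similarity", "similarity",
             "similarity", "distance", "similarity", "similarity"),
    stringsAsFactors = FALSE
  )
}

metric_ids <- function() similarity_metrics()$metric

check_metric_ids <- function(metrics) {
  bad <- setdiff(metrics, metric_ids())
  if (length(bad)) stop("unknown metric id(s): ", paste(bad, collapse = ", "))
  metrics
}

# Vectorised native metric values over parallel a, b, c count vectors.
# Degenerate denominators (all-off fingerprints) fall back to 0 similarity
# with a warning: such inputs normally indicate a generator bug.
metric_value_vec <- function(metric, a, b, c) {
  if (any(c > pmin(a, b))) stop("invalid bit statistics: c > min(a, b)")
  warn_zero <- function(which) {
    warning("all-zero fingerprint encountered in ", metric,
            " (", which, "); similarity set to 0", call. = FALSE)
  }
  switch(metric,
    manhattan = a + b - 2 * c,
    euclidean = sqrt(a + b - 2 * c),
    cosine = {
      bad <- a == 0 | b == 0
      if (any(bad)) warn_zero("a or b = 0")
      ifelse(bad, 0, c / sqrt(a * b))
    },
    dice = {
      bad <- (a + b) == 0
      if (any(bad)) warn_zero("a = b = 0")
      ifelse(bad, 0, 2 * c / (a + b))
    },
    tanimoto = {
      bad <- (a + b - c) == 0
      if (any(bad)) warn_zero("a = b = 0")
      ifelse(bad, 0, c / (a + b - c))
    },
    soergel = {
      bad <- (a + b - c) == 0
      if (any(bad)) warn_zero("a = b = 0")
      ifelse(bad, 1, 1 - c / (a + b - c))
    },
    substructure = {
      bad <- a == 0
      if (any(bad)) warn_zero("a = 0")
      ifelse(bad, 0, c / a)
    },
    superstructure = {
      bad <- b == 0
      if (any(bad)) warn_zero("b = 0")
      ifelse(bad, 0, c / b)
    },
    stop("unknown metric id: ", metric)
  )
}

#' Native metric value from bit statistics
#'
#' Evaluates one coefficient on the counts `(a, b, c)`. Native distances
#' (`manhattan`, `euclidean`, `soergel`) return a distance; the others a
#' similarity in `[0, 1]`. See [similarity_metrics()] for the formulas and
#' degenerate-input conventions.
#'
#' For the asymmetric containment metrics, molecule A is the query
#' (reference): `substructure` is `c/a`, `superstructure` is `c/b`; swapping
#' A and B swaps the two metrics into each other. All other metrics are
#' symmetric.
#'
#' @param metric one metric id from [similarity_metrics()].
#' @param stats a [bit_statistics()] object (or list with `a`, `b`, `c`).
#' @return A single numeric value on the metric's native scale.
#' @examples
#' s <- list(a = 4, b = 6, c = 2)
#' metric_value("tanimoto", s)   # 0.25
#' metric_value("manhattan", s)  # 6
#' @export
metric_value <- function(metric, stats) {
  stopifnot(is.character(metric), length(metric) == 1L)
  check_metric_ids(metric)
  stopifnot(all(c("a", "b", "c") %in% names(stats)))
  if (stats$c > min(stats$a, stats$b) || min(stats$a, stats$b, stats$c) < 0) {
    stop("invalid bit statistics")
  }
  metric_value_vec(metric, stats$a, stats$b, stats$c)
}

#' Convert a distance to a similarity
#'
#' `similarity = 1 / (1 + distance)`: a strictly decreasing map of
#' `[0, Inf)` onto `(0, 1]` with distance 0 (identical objects) mapping to
#' similarity 1. Note that converted scales differ between metrics even
#' though the range is shared: Euclidean distances 5--8 become similarities
#' 1/9--1/6 while the corresponding Manhattan distances 25--64 become
#' 1/65--1/26.
#'
#' @param distance numeric vector of non-negative distances.
#' @return Numeric vector of similarities in `(0, 1]`.
#' @examples
#' to_similarity(0)   # 1
#' to_similarity(8)   # 1/9
#' @export
to_similarity <- function(distance) {
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("distances must be finite and non-negative")
  }
  1 / (1 + distance)
}

#' Similarity table of a library against a reference compound
#'
#' Computes, for every molecule in `library`, its similarity to `reference`
#' under each requested metric. Native distances are converted with
#' [to_similarity()], so every cell lies in `[0, 1]` and the table records
#' post-conversion values only (the conversion is applied exactly once).
#'
#' @param reference a [fingerprint()]; the query compound. Must not occur in
#'   `library` (each dataset designates one reference drawn out of it) unless
#'   `allow_reference_in_library = TRUE`.
#' @param library an [fp_library()] (or list of fingerprints) of equal
#'   length to `reference`.
#' @param metrics character vector of metric ids; default all eight.
#' @param allow_reference_in_library permit a library molecule to share the
#'   reference id (test scaffolding only).
#' @return A numeric matrix of class `"similarity_table"`, `m x n` with
#'   rownames = molecule ids and colnames = metric ids, plus attributes
#'   `reference` (id) and `nbits`.
#' @examples
#' lib <- generate_library(10, "druglike", nbits = 256, seed = 1)
#' st <- similarity_table(lib[[1]], lib[2:10])
#' range(st)
#' @export
similarity_table <- function(reference, library,
                             metrics = metric_ids(),
                             allow_reference_in_library = FALSE) {
  stopifnot(inherits(reference, "fingerprint"))
  if (is.list(library) && !inherits(library, "fp_library")) {
    library <- fp_library(library)
  }
  stopifnot(inherits(library, "fp_library"))
  if (library$nbits != reference$nbits) stop("fingerprint length mismatch")
  check_metric_ids(metrics)
  if (!allow_reference_in_library && reference$id %in% ids(library)) {
    stop("reference compound '", reference$id,
         "' occurs in the library; molecules may not be drawn more than once")
  }
  refbits <- integer(library$nbits)
  refbits[reference$on_bits + 1L] <- 1L
  b <- rowSums(library$bits)
  a <- rep.int(length(reference$on_bits), length(b))
  c <- as.vector(library$bits %*% refbits)
  vals <- vapply(metrics, function(mt) {
    v <- metric_value_vec(mt, a, b, c)
    if (similarity_metrics()$kind[match(mt, metric_ids())] == "distance") {
      v <- to_similarity(v)
    }
    v
  }, numeric(length(b)))
  vals <- matrix(vals, nrow = length(b), ncol = length(metrics),
                 dimnames = list(ids(library), metrics))
  structure(vals,
            class = c("similarity_table", "matrix", "array"),
            reference = reference$id, nbits = library$nbits)
}

#' Write a similarity table as TSV
#'
#' First column `id`, one column per metric, header row of metric ids.
#'
#' @param table a [similarity_table()] (or any numeric matrix with
#'   rownames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(table, path) {
  df <- data.frame(id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity table TSV written by [write_similarity_table()]
#' @param path input path.
#' @return A numeric matrix with molecule-id rownames and metric colnames.
#' @export
read_similarity_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
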