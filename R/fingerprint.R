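#' Binary molecular fingerprint
#'
#' A fingerprint is a fixed-length bit vector standing for one molecule: a
#' small set of "on" bit positions drawn from `[0, nbits)`. All similarity
#' coefficients in this package are computed from three counts derived from a
#' pair of fingerprints: `a` (on bits in A), `b` (on bits in B) and `c`
#' (bits on in both).
#'
#' Bit positions are 0-based, matching the FPS text format convention used by
#' [write_fps()] and [read_fps()].
#'
#' @param on_bits integer vector of distinct 0-based on-bit positions.
#' @param nbits fingerprint length in bits (positive integer).
#' @param id molecule identifier (coerced to character).
#' @return An object of class `"fingerprint"`: a list with elements `id`,
#'   `nbits` and `on_bits` (sorted integer vector).
#' @examples
#' fp <- fingerprint(c(0, 5, 9), nbits = 16, id = "mol1")
#' n_on(fp)
#' @export
fingerprint <- function(on_bits, nbits, id = "fp") {
  nbits <- as.integer(nbits)
  stopifnot(length(nbits) == 1L, nbits >= 1L)
  on_bits <- sort(unique(as.integer(on_bits)))
  if (length(on_bits) && (min(on_bits) < 0L || max(on_bits) >= nbits)) {
    stop("on-bit positions must lie in [0, nbits)")
  }
  structure(
    list(id = as.character(id), nbits = nbits, on_bits = on_bits),
    class = "fingerprint"
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf(
    "<fingerprint> %s: %d/%d bits on\n",
    x$id, length(x$on_bits), x$nbits
  ))
  invisible(x)
}

#' Number of on bits in a fingerprint
#' @param fp a [fingerprint()].
#' @return Integer count of on bits.
#' @export
n_on <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  length(fp$on_bits)
}

#' Fingerprint library
#'
#' A library is an ordered collection of equal-length fingerprints with
#' unique ids. Internally the on-bits are held as a dense 0/1 integer matrix
#' (rows = molecules) so that pairwise bit statistics vectorise; individual
#' [fingerprint()] objects can be extracted with `[[` and subsets with `[`.
#'
#' @param fps list of [fingerprint()] objects with equal `nbits` and unique
#'   ids.
#' @return An object of class `"fp_library"`: a list with `bits` (n x nbits
#'   integer matrix with rownames = ids) and `nbits`.
#' @seealso [generate_library()] for the synthetic generator.
#' @export
fp_library <- function(fps) {
  stopifnot(is.list(fps), length(fps) >= 1L)
  lens <- vapply(fps, function(f) f$nbits, integer(1))
  if (length(unique(lens)) != 1L) stop("all fingerprints must share one length")
  ids <- vapply(fps, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop("fingerprint ids must be unique within a library")
  nbits <- lens[[1L]]
  bits <- matrix(0L, nrow = length(fps), ncol = nbits,
                 dimnames = list(ids, NULL))
  for (i in seq_along(fps)) {
    bits[i, fps[[i]]$on_bits + 1L] <- 1L
  }
  structure(list(bits = bits, nbits = nbits), class = "fp_library")
}

# Internal constructor from a prebuilt 0/1 matrix (rownames = ids).
fp_library_from_matrix <- function(bits) {
  stopifnot(is.matrix(bits), !is.null(rownames(bits)))
  storage.mode(bits) <- "integer"
  structure(list(bits = bits, nbits = ncol(bits)), class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  cat(sprintf(
    "<fp_library> %d fingerprints x %d bits (mean on-bits %.1f)\n",
    nrow(x$bits), x$nbits, mean(rowSums(x$bits))
  ))
  invisible(x)
}

#' @export
length.fp_library <- function(x) nrow(x$bits)

#' Molecule ids of a library
#' @param library an [fp_library()].
#' @return Character vector of ids in library order.
#' @export
ids <- function(library) {
  stopifnot(inherits(library, "fp_library"))
  rownames(library$bits)
}

#' @export
`[.fp_library` <- function(x, i) {
  fp_library_from_matrix(x$bits[i, , drop = FALSE])
}

#' @export
`[[.fp_library` <- function(x, i) {
  row <- x$bits[i, , drop = TRUE]
  fingerprint(which(row == 1L) - 1L, nbits = x$nbits,
              id = rownames(x$bits)[if (is.character(i)) match(i, ids(x)) else i])
}

#' Pairwise bit statistics of two fingerprints
#'
#' Computes the three counts that every dichotomous similarity coefficient is
#' built from: `a`, the number of on bits in molecule A; `b`, the number of
#' on bits in molecule B; and `c`, the number of bits on in both.
#'
#' @param fpA,fpB [fingerprint()] objects of equal length.
#' @return A list of class `"bit_statistics"` with integer elements `a`, `b`,
#'   `c`; always `c <= min(a, b)`.
#' @examples
#' A <- fingerprint(0:3, 16, "A")
#' B <- fingerprint(2:7, 16, "B")
#' bit_statistics(A, B)  # a = 4, b = 6, c = 2
#' @export
bit_statistics <- function(fpA, fpB) {
  stopifnot(inherits(fpA, "fingerprint"), inherits(fpB, "fingerprint"))
  if (fpA$nbits != fpB$nbits) {
    stop("fingerprint length mismatch: ", fpA$nbits, " vs ", fpB$nbits)
  }
  structure(
    list(
      a = length(fpA$on_bits),
      b = length(fpB$on_bits),
      c = length(intersect(fpA$on_bits, fpB$on_bits))
    ),
    class = "bit_statistics"
  )
}

#' @export
print.bit_statistics <- function(x, ...) {
  cat(sprintf("<bit_statistics> a = %d, b = %d, c = %d\n", x$a, x$b, x$c))
  invisible(x)
}

hex_digits <- strsplit("0123456789abcdef", "")[[1L]]

# bits: 0/1 integer vector, length divisible by 4; most-significant-nibble
# first, bit 0 is the high bit of the first nibble.
bits_to_hex <- function(bits) {
  stopifnot(length(bits) %% 4L == 0L)
  nib <- matrix(bits, nrow = 4L)
  vals <- 8L * nib[1L, ] + 4L * nib[2L, ] + 2L * nib[3L, ] + nib[4L, ]
  paste(hex_digits[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex) {
  vals <- match(strsplit(tolower(hex), "")[[1L]], hex_digits) - 1L
  if (anyNA(vals)) stop("invalid hex fingerprint string")
  as.integer(rbind(
    vals %/% 8L, (vals %/% 4L) %% 2L, (vals %/% 2L) %% 2L, vals %% 2L
  ))
}

#' Write a fingerprint library in FPS-like text format
#'
#' One `#`-prefixed header block, then one line per molecule:
#' `hex<TAB>id`. Hex encoding is most-significant-nibble first with 0-based
#' bit 0 as the high bit of the first nibble.
#'
#' @param library an [fp_library()]; `nbits` must be divisible by 4.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fps <- function(library, path) {
  stopifnot(inherits(library, "fp_library"))
  if (library$nbits %% 4L != 0L) stop("nbits must be divisible by 4 for hex output")
  hdr <- c("#FPS1", sprintf("#num_bits=%d", library$nbits),
           "#software=srdfp")
  body <- vapply(seq_len(nrow(library$bits)), function(i) {
    paste(bits_to_hex(library$bits[i, ]), rownames(library$bits)[i], sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a fingerprint library from an FPS-like text file
#'
#' @param path file written by [write_fps()] (or any `hex<TAB>id` file with
#'   `#` headers).
#' @return An [fp_library()].
#' @export
read_fps <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no fingerprint records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed FPS record at line ", which(bad)[1L])
  hexes <- vapply(parts, `[[`, character(1), 1L)
  idv <- vapply(parts, `[[`, character(1), 2L)
  nhex <- nchar(hexes)
  if (length(unique(nhex)) != 1L) stop("fingerprints have differing lengths")
  bits <- t(vapply(hexes, hex_to_bits, integer(nhex[1L] * 4L)))
  rownames(bits) <- idv
  fp_library_from_matrix(bits)
}
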