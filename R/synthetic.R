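#' Molecule size classes and bit-density regimes
#'
#' The generator emulates a vendor compound database split into fragment,
#' leadlike and druglike size classes (plus "all", a mixture drawn
#' regardless of size) purely through fingerprint bit density. Two density
#' profiles are provided:
#' \describe{
#'   \item{sparse}{dictionary-style fingerprints (ECFP-like) where roughly
#'     one bit in ten to twenty is on: mean 75 on bits per 1024, for every
#'     class. Sparse fingerprints produce heavily degenerate (repeated)
#'     similarity values because the common-on-bit count `c` can take only
#'     a few values.}
#'   \item{dense}{hashed, "darker" fingerprints whose on-bit count grows
#'     with molecular size: mean 150 (fragment), 250 (leadlike), 350
#'     (druglike) on bits per 1024 bits.}
#' }
#' The class means are emulation choices that couple size to density so
#' size-dependence effects can be exercised; they are not measurements of
#' any real fingerprint. The "all" class mixes the three in proportion
#' 3:24:73, mirroring the relative class sizes of a large purchasable
#' compound database.
#'
#' @return A data.frame with columns `size_class`, `sparse_mean`,
#'   `dense_mean` (mean on-bit counts at 1024 bits; NA for the mixture
#'   class) and `mix_weight`.
#' @export
size_classes <- function() {
  data.frame(
    size_class = c("fragment", "leadlike", "druglike", "all"),
    sparse_mean = c(75, 75, 75, NA),
    dense_mean = c(150, 250, 350, NA),
    mix_weight = c(NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

size_class_ids <- function() c("fragment", "leadlike", "druglike", "all")

# Mixture weights of the "all" class over (fragment, leadlike, druglike),
# proportional to the database class counts (~3:24:73).
all_class_weights <- c(fragment = 3, leadlike = 24, druglike = 73) / 100

# Per-bit on probability for one class/profile at a given length. The mean
# on-bit count scales with length so density (fraction on) is preserved.
class_bit_prob <- function(size_class, density, nbits) {
  mean1024 <- if (density == "sparse") 75
  else switch(size_class, fragment = 150, leadlike = 250, druglike = 350)
  p <- mean1024 / 1024
  if (p >= 1) stop("density parameters exceed fingerprint length")
  p
}

#' Generate a synthetic fingerprint library
#'
#' Draws `n` random binary fingerprints for one size class and density
#' profile. Each molecule's on-bit count is binomial over the fingerprint
#' length with the class's per-bit probability, and on-bit positions are
#' uniform without replacement; bits are therefore independent (no
#' substructure correlation is emulated). For the `"all"` class each
#' molecule's class is first drawn from the 3:24:73 fragment/leadlike/
#' druglike mixture. Output is a pure function of the arguments and `seed`.
#'
#' @param n number of fingerprints (>= 1).
#' @param size_class one of `"fragment"`, `"leadlike"`, `"druglike"`,
#'   `"all"`.
#' @param nbits fingerprint length (>= 64; default 1024).
#' @param density `"dense"` (default; class-dependent on-bit counts) or
#'   `"sparse"` (mean 75 on bits per 1024 for every class).
#' @param seed integer seed.
#' @param id_prefix prefix for the generated molecule ids.
#' @return An [fp_library()] with attributes `size_class` and `density`.
#' @examples
#' lib <- generate_library(5, "fragment", nbits = 128, seed = 1)
#' mean(rowSums(lib$bits))
#' @export
generate_library <- function(n, size_class = size_class_ids(),
                             nbits = 1024L,
                             density = c("dense", "sparse"),
                             seed = NULL, id_prefix = NULL) {
  size_class <- match.arg(size_class)
  density <- match.arg(density)
  n <- as.integer(n)
  nbits <- as.integer(nbits)
  stopifnot(n >= 1L)
  if (nbits < 64L) stop("fingerprint length must be at least 64 bits")
  if (is.null(id_prefix)) {
    id_prefix <- paste0(substr(size_class, 1L, 4L),
                        substr(density, 1L, 1L))
  }
  with_seed(seed, {
    classes <- if (size_class == "all") {
      sample(names(all_class_weights), n, replace = TRUE,
             prob = all_class_weights)
    } else {
      rep.int(size_class, n)
    }
    bits <- matrix(0L, n, nbits)
    for (i in seq_len(n)) {
      p <- class_bit_prob(classes[i], density, nbits)
      k <- stats::rbinom(1L, nbits, p)
      if (k > 0L) bits[i, sample.int(nbits, k)] <- 1L
    }
    rownames(bits) <- sprintf("%s_%05d", id_prefix, seq_len(n))
    lib <- fp_library_from_matrix(bits)
    attr(lib, "size_class") <- size_class
    attr(lib, "density") <- density
    lib
  })
}

check_available <- function(library, k, exclude) {
  avail <- setdiff(ids(library), exclude)
  if (length(avail) < k) {
    stop("only ", length(avail), " unused molecules available, need ", k,
         "; molecules may not be drawn more than once")
  }
  avail
}

#' Randomly draw a dataset from a library
#'
#' Draws `k` distinct molecules uniformly at random from the library,
#' skipping any ids in `exclude`. Passing the accumulated ids of earlier
#' draws as `exclude` guarantees that no molecule is ever drawn more than
#' once across datasets.
#'
#' @param library an [fp_library()].
#' @param k dataset size.
#' @param seed integer seed.
#' @param exclude character vector of already-used molecule ids.
#' @return An [fp_library()] of the `k` picked molecules (use [ids()] to
#'   update the exclusion set).
#' @export
pick_random <- function(library, k, seed = NULL, exclude = character()) {
  stopifnot(inherits(library, "fp_library"))
  avail <- check_available(library, k, exclude)
  sel <- with_seed(seed, sample(avail, k))
  library[sel]
}

#' Diversity-pick a dataset from a library (MaxMin)
#'
#' MaxMin selection: the first molecule is chosen uniformly at random, then
#' each subsequent pick is the candidate whose minimum Tanimoto distance
#' (`1 - Tanimoto`) to the already-picked set is largest (ties broken by
#' library order). Deterministic given `seed`; honours the same
#' no-repeat `exclude` contract as [pick_random()].
#'
#' @inheritParams pick_random
#' @return An [fp_library()] of the `k` picked molecules.
#' @export
pick_diverse <- function(library, k, seed = NULL, exclude = character()) {
  stopifnot(inherits(library, "fp_library"))
  avail <- check_available(library, k, exclude)
  bits <- library$bits[avail, , drop = FALSE]
  b <- rowSums(bits)
  first <- with_seed(seed, sample.int(length(avail), 1L))
  picked <- integer(k)
  picked[1L] <- first
  # running minimum Tanimoto distance of every candidate to the picked set
  mindist <- rep.int(Inf, length(avail))
  for (j in seq_len(k - 1L)) {
    new <- picked[j]
    cvec <- as.vector(bits %*% bits[new, ])
    denom <- b + b[new] - cvec
    tan <- ifelse(denom == 0, 0, cvec / denom)
    mindist <- pmin(mindist, 1 - tan)
    mindist[picked[seq_len(j)]] <- -Inf
    picked[j + 1L] <- which.max(mindist)
  }
  library[avail[picked]]
}

#' Degeneracy fraction of a similarity column
#'
#' Fraction of repeated values: `1 - (number of distinct values) / m`.
#' Sparse fingerprints admit only a few possible common-on-bit counts, so
#' their similarity columns are heavily degenerate (many molecules share
#' the same similarity value), which coarsens the rankings SRD consumes.
#'
#' @param column numeric vector of similarity values (length >= 2).
#' @return A number in `[0, 1]`: 0 when all values are distinct,
#'   `1 - 1/m` when all are equal.
#' @export
degeneracy_fraction <- function(column) {
  stopifnot(is.numeric(column), length(column) >= 2L)
  1 - length(unique(column)) / length(column)
}
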