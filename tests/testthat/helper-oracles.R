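# Independent oracles, deliberately implemented along different routes than
# the package internals.

# All permutations of 1..m by repeated insertion (vs the package's
# prefix-extension recursion).
perms_by_insertion <- function(m) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:m) {
    n <- nrow(out)
    grown <- matrix(0L, n * k, k)
    row <- 0L
    for (i in seq_len(n)) {
      for (pos in seq_len(k)) {
        row <- row + 1L
        grown[row, ] <- append(out[i, ], k, after = pos - 1L)
      }
    }
    out <- grown
  }
  out
}

# Brute-force SRD statistics against a reference rank vector.
enumerate_srd <- function(ref_ranks) {
  m <- length(ref_ranks)
  perms <- perms_by_insertion(m)
  apply(perms, 1L, function(p) sum(abs(p - ref_ranks)))
}

# Set-operation evaluation of the dichotomous formulas from explicit 0-based
# bit-position vectors (not from precomputed counts).
set_metric_oracle <- function(bitsA, bitsB, metric) {
  a <- length(bitsA)
  b <- length(bitsB)
  c <- sum(bitsA %in% bitsB)
  switch(metric,
         manhattan = a + b - 2 * c,
         euclidean = (a + b - 2 * c)^0.5,
         cosine = c / (a * b)^0.5,
         dice = 2 * c / (a + b),
         tanimoto = c / (a + b - c),
         soergel = 1 - c / (a + b - c),
         substructure = c / a,
         superstructure = c / b)
}

# Random bit-statistics triples (a, b, c) with c <= min(a, b), a, b >= 1.
random_bit_stats <- function(n, max_bits = 50L) {
  a <- sample.int(max_bits, n, replace = TRUE)
  b <- sample.int(max_bits, n, replace = TRUE)
  c <- vapply(pmin(a, b), function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
  data.frame(a = a, b = b, c = c)
}

# Type-7 sample quantile from first principles (sort + linear interpolation).
sorted_quantile_oracle <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Closed-form balanced two-way ANOVA decomposition.
balanced_twoway_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- length(y) / (nlevels(A) * nlevels(B))
  g <- mean(y)
  ma <- tapply(y, A, mean)
  mb <- tapply(y, B, mean)
  mab <- tapply(y, interaction(A, B), mean)
  ssa <- n * nlevels(B) * sum((ma - g)^2)
  ssb <- n * nlevels(A) * sum((mb - g)^2)
  ssab <- n * sum((mab[interaction(A, B)] - ma[A] - mb[B] + g)^2) / n
  # residual: within-cell deviations
  sse <- sum((y - mab[interaction(A, B)])^2)
  list(ssa = ssa, ssb = ssb, ssab = ssab, sse = sse,
       sst = sum((y - g)^2))
}
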