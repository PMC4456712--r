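test_that("dichotomous formulas reproduce the worked values", {
  s <- list(a = 7, b = 7, c = 7)
  expect_equal(metric_value("tanimoto", s), 1)

  s <- list(a = 4, b = 6, c = 2)
  expect_equal(metric_value("tanimoto", s), 0.25)
  expect_equal(metric_value("dice", s), 0.4)
  expect_equal(metric_value("manhattan", s), 6)
  expect_equal(metric_value("soergel", s), 0.75)
  # cosine against an independent set-operation evaluation of the same pair
  expect_equal(metric_value("cosine", s),
               set_metric_oracle(0:3, 2:7, "cosine"))
  expect_equal(metric_value("cosine", s), 2 / sqrt(24))

  expect_equal(metric_value("tanimoto", list(a = 3, b = 5, c = 0)), 0)
  expect_error(metric_value("jaccard3", s), "unknown metric")
  expect_error(metric_value("tanimoto", list(a = 1, b = 1, c = 2)),
               "invalid bit statistics")
})

test_that("every metric agrees with the set-operation oracle on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    bitsA <- sample.int(64, sample(1:30, 1)) - 1L
    bitsB <- sample.int(64, sample(1:30, 1)) - 1L
    s <- bit_statistics(fingerprint(bitsA, 64), fingerprint(bitsB, 64, "B"))
    for (mt in similarity_metrics()$metric) {
      expect_equal(metric_value(mt, s), set_metric_oracle(bitsA, bitsB, mt),
                   info = mt)
    }
  }
})

test_that("degenerate all-zero fingerprints fall back to 0 with a warning", {
  z <- list(a = 0, b = 0, c = 0)
  expect_warning(expect_equal(metric_value("cosine", z), 0), "all-zero")
  expect_warning(expect_equal(metric_value("dice", z), 0), "all-zero")
  expect_warning(expect_equal(metric_value("tanimoto", z), 0), "all-zero")
  expect_warning(expect_equal(metric_value("substructure", z), 0), "all-zero")
  expect_warning(expect_equal(metric_value("superstructure",
                                           list(a = 3, b = 0, c = 0)), 0),
                 "all-zero")
})

test_that("distance-to-similarity conversion matches 1/(1+D)", {
  expect_equal(to_similarity(0), 1)
  expect_equal(to_similarity(8), 1 / 9)
  expect_equal(to_similarity(64), 1 / 65)
  d <- seq(0, 50, by = 0.5)
  expect_true(all(diff(to_similarity(d)) < 0))
  expect_error(to_similarity(-0.1), "non-negative")
})

test_that("metrics are symmetric except the containment pair, which swaps", {
  set.seed(5)
  A <- fingerprint(sample.int(128, 20) - 1L, 128, "A")
  B <- fingerprint(sample.int(128, 35) - 1L, 128, "B")
  sAB <- bit_statistics(A, B)
  sBA <- bit_statistics(B, A)
  for (mt in setdiff(similarity_metrics()$metric,
                     c("substructure", "superstructure"))) {
    expect_equal(metric_value(mt, sAB), metric_value(mt, sBA), info = mt)
  }
  expect_equal(metric_value("substructure", sAB),
               metric_value("superstructure", sBA))
  expect_equal(metric_value("superstructure", sAB),
               metric_value("substructure", sBA))
})

test_that("similarity tables have the contracted shape, range and errors", {
  lib <- generate_library(100, "druglike", nbits = 1024, seed = 2)
  ref <- lib[[1]]
  st <- similarity_table(ref, lib[2:100])
  expect_identical(dim(st), c(99L, 8L))
  expect_identical(colnames(st), similarity_metrics()$metric)
  expect_true(all(st >= 0 & st <= 1))
  expect_false(anyNA(st))

  expect_error(similarity_table(ref, lib), "more than once")

  # a copy of the reference in test mode scores 1 under every metric
  twin <- fp_library(list(fingerprint(ref$on_bits, ref$nbits, ref$id)))
  st1 <- similarity_table(ref, twin, allow_reference_in_library = TRUE)
  expect_equal(unname(as.vector(st1)), rep(1, 8))
})

test_that("algebraic identities tie the converted similarity columns together", {
  set.seed(21)
  bs <- random_bit_stats(200)
  tan <- mapply(function(a, b, c) metric_value("tanimoto", list(a=a,b=b,c=c)),
                bs$a, bs$b, bs$c)
  dice <- mapply(function(a, b, c) metric_value("dice", list(a=a,b=b,c=c)),
                 bs$a, bs$b, bs$c)
  soe <- mapply(function(a, b, c) metric_value("soergel", list(a=a,b=b,c=c)),
                bs$a, bs$b, bs$c)
  man <- mapply(function(a, b, c) metric_value("manhattan", list(a=a,b=b,c=c)),
                bs$a, bs$b, bs$c)
  euc <- mapply(function(a, b, c) metric_value("euclidean", list(a=a,b=b,c=c)),
                bs$a, bs$b, bs$c)
  expect_equal(tan, dice / (2 - dice))
  expect_equal(to_similarity(soe), 1 / (2 - tan))
  expect_equal(man, euc^2)  # Manhattan = squared Euclidean on binary data
})

test_that("monotone-equivalent metrics order rows identically", {
  lib <- generate_library(60, "all", nbits = 512, seed = 8)
  st <- similarity_table(lib[[1]], lib[2:60])
  ord_equal <- function(u, v) identical(order(u, seq_along(u)),
                                        order(v, seq_along(v)))
  expect_true(ord_equal(st[, "tanimoto"], st[, "dice"]))
  expect_true(ord_equal(st[, "tanimoto"], st[, "soergel"]))
  expect_true(ord_equal(st[, "manhattan"], st[, "euclidean"]))
})

test_that("similarity tables round-trip through TSV", {
  lib <- generate_library(12, "fragment", nbits = 256, seed = 6)
  st <- similarity_table(lib[[1]], lib[2:12])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_table(st, path)
  back <- read_similarity_table(path)
  expect_equal(unclass(st), back, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(st))
})
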