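test_that("srd_value sums absolute rank differences", {
  expect_equal(srd_value(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(srd_value(c(3, 2, 1), c(1, 2, 3)), 4)
  expect_error(srd_value(1:3, 1:4), "equal length")
  # mean over all m = 3 permutations against the identity is 8/3
  expect_equal(mean(enumerate_srd(1:3)), 8 / 3)
})

test_that("srd_max matches brute-force enumeration and the closed forms", {
  for (m in 3:6) {
    expect_equal(srd_max(m), max(enumerate_srd(seq_len(m))), info = m)
  }
  expect_equal(srd_max(4), 8)
  expect_equal(srd_max(99), (99^2 - 1) / 2)
  expect_equal(srd_max(100), 100^2 / 2)
  expect_error(srd_max(1), "m >= 2")
})

test_that("srd_max bounds every attainable SRD for tied references too", {
  set.seed(31)
  for (i in 1:10) {
    m <- sample(4:6, 1)
    ref <- rank_transform(sample(1:3, m, replace = TRUE))  # tied ranks
    smax <- srd_max(ref)
    expect_equal(smax, max(enumerate_srd(ref)))
    # tied candidate rankings stay within the bound as well
    tied <- rank_transform(sample(1:2, m, replace = TRUE))
    expect_lte(srd_value(tied, ref), smax)
  }
})

test_that("normalisation maps onto [0, 100] and rejects impossible values", {
  expect_equal(normalize_srd(0, 10), 0)
  expect_equal(normalize_srd(10, 10), 100)
  expect_equal(normalize_srd(4, srd_max(3)), 100)
  expect_error(normalize_srd(11, 10), "inconsistent")
})

test_that("exact null distribution matches enumeration cell for cell", {
  n3 <- null_distribution(3, method = "exact")
  expect_equal(n3$pmf$srd, c(0, 2, 4))
  expect_equal(n3$pmf$prob, c(1 / 6, 1 / 3, 1 / 2))
  for (m in c(4, 6)) {
    nd <- null_distribution(m, method = "exact")
    tab <- table(enumerate_srd(seq_len(m)))
    expect_equal(nd$pmf$srd, as.numeric(names(tab)))
    expect_equal(nd$pmf$prob, as.numeric(tab) / factorial(m))
    expect_equal(nd$mean_raw, (m^2 - 1) / 3)
  }
  expect_error(null_distribution(12, method = "exact"), "montecarlo")
})

test_that("Monte Carlo null is seed-reproducible and close to exact", {
  a <- null_distribution(20, method = "montecarlo", seed = 7)
  b <- null_distribution(20, method = "montecarlo", seed = 7)
  expect_identical(a$quantiles, b$quantiles)
  expect_identical(a$samples, b$samples)
  c2 <- null_distribution(20, method = "montecarlo", seed = 8)
  expect_false(identical(a$samples, c2$samples))
  expect_error(null_distribution(20, method = "montecarlo", n_samples = 100),
               "10\\^4")
  # raw-scale mean converges on (m^2 - 1)/3 at m = 99
  n99 <- null_distribution(99, method = "montecarlo", seed = 1,
                           n_samples = 20000)
  expect_equal(n99$mean_raw, (99^2 - 1) / 3, tolerance = 0.01)
  expect_true(n99$quantiles[["xx1"]] <= n99$quantiles[["med"]])
  expect_true(n99$quantiles[["med"]] <= n99$quantiles[["xx19"]])
})

test_that("classification flags SRD below XX1 as distinguishable from random", {
  nd <- null_distribution(8, method = "exact")
  expect_identical(classify_vs_random(0, nd), "acceptable")
  expect_identical(classify_vs_random(nd$quantiles[["med"]], nd),
                   "random-like")
  expect_identical(
    classify_vs_random(c(1, 99), nd), c("acceptable", "random-like")
  )
})

test_that("cross-validation follows the LOO / seven-fold size rule", {
  set.seed(17)
  x10 <- matrix(runif(10 * 4), 10, 4)
  cv10 <- cross_validate(x10)
  expect_identical(nrow(cv10), 10L)
  expect_identical(attr(cv10, "folds"), 1:10)

  x13 <- matrix(runif(13 * 4), 13, 4)
  expect_identical(nrow(cross_validate(x13)), 13L)

  x99 <- matrix(runif(99 * 4), 99, 4)
  cv99 <- cross_validate(x99, seed = 3)
  expect_identical(nrow(cv99), 7L)
  expect_identical(sort(unique(attr(cv99, "folds"))), 1:7)
  expect_identical(cv99, cross_validate(x99, seed = 3))

  # identical metric columns collapse onto the consensus: zero spread
  same <- matrix(rep(runif(20), 3), 20, 3)  # 20 objects -> 7 folds
  cv_same <- cross_validate(same, seed = 2)
  expect_equal(unname(as.vector(cv_same)), rep(0, length(cv_same)))
})

test_that("SRD is a rank statistic: invariant under strictly increasing maps", {
  set.seed(23)
  x <- matrix(runif(30 * 4), 30, 4)
  ref <- runif(30)
  base_fit <- srd(x, reference = ref, cv = FALSE, seed = 1)
  y <- x
  y[, 2] <- exp(3 * y[, 2])          # strictly increasing transform
  y[, 4] <- y[, 4]^3 + 10 * y[, 4]
  fit2 <- srd(y, reference = ref, cv = FALSE, seed = 1)
  expect_equal(base_fit$srd, fit2$srd)
})

test_that("srd_value obeys the triangle-style bound on rank vectors", {
  set.seed(29)
  for (i in 1:20) {
    m <- sample(5:12, 1)
    x <- sample.int(m); y <- sample.int(m); z <- sample.int(m)
    expect_lte(srd_value(x, z), srd_value(x, y) + srd_value(y, z))
  }
})

test_that("the srd object carries coherent components and methods", {
  lib <- generate_library(25, "leadlike", nbits = 256, seed = 12)
  st <- similarity_table(lib[[1]], lib[2:25])
  fit <- srd(st, pretreatment = "interval", seed = 5)
  expect_s3_class(fit, "srd")
  expect_identical(fit$m, 24L)
  expect_named(coef(fit), similarity_metrics()$metric)
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 100))
  expect_equal(fit$srd_nor, normalize_srd(fit$srd, fit$srd_max))
  s <- summary(fit)
  expect_s3_class(s, "summary.srd")
  expect_true(all(c("cv_median", "flag") %in% names(s)))
  expect_false(is.unsorted(s$srd_nor))
  expect_output(print(fit), "Sum of ranking differences")
  # identical rankings in every column give zero SRD throughout
  same <- matrix(rep(runif(15), 4), 15, 4)
  fit0 <- srd(same, cv = FALSE, seed = 2)
  expect_equal(unname(fit0$srd), rep(0, 4))
  # a precomputed null for the wrong m is rejected
  expect_error(srd(st, null = null_distribution(5, "exact")), "m = 5")
})
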