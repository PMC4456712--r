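make_balanced <- function(n_per_cell, a_levels, b_levels, fun, noise_sd = 0) {
  g <- expand.grid(A = a_levels, B = b_levels,
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  g$srd_nor <- fun(g$A, g$B) + stats::rnorm(nrow(g), sd = noise_sd)
  g
}

test_that("a constant response yields zero effect sums of squares", {
  tab <- make_balanced(4, c("a1", "a2"), c("b1", "b2"),
                       function(A, B) 5)
  # zero residual variance makes lm warn about unreliable F tests; only the
  # SS decomposition is under test here
  at <- suppressWarnings(srd_anova(tab, c("A", "B")))
  expect_equal(at$sum_sq, rep(0, 4), tolerance = 1e-12)
})

test_that("a pure factor-A split puts all between-cell SS on A", {
  # cell means (10, 10, 20, 20): A separates 10s from 20s, B does nothing
  tab <- make_balanced(3, c("a1", "a2"), c("b1", "b2"),
                       function(A, B) ifelse(A == "a1", 10, 20))
  at <- suppressWarnings(srd_anova(tab, c("A", "B")))
  ss <- stats::setNames(at$sum_sq, at$effect)
  # hand computation: 12 observations, deviations +/-5 -> SS(A) = 12 * 25
  expect_equal(ss[["A"]], 12 * 25)
  expect_equal(ss[["B"]], 0)
  expect_equal(ss[["A:B"]], 0)
  expect_equal(ss[["Residuals"]], 0)
})

test_that("balanced two-way decomposition matches the closed-form oracle", {
  set.seed(83)
  for (i in 1:5) {
    tab <- make_balanced(5, c("a1", "a2", "a3"), c("b1", "b2"),
                         function(A, B) 3 * (A == "a2") - 2 * (B == "b1"),
                         noise_sd = 1)
    at <- srd_anova(tab, c("A", "B"))
    orc <- balanced_twoway_oracle(tab$srd_nor, tab$A, tab$B)
    ss <- stats::setNames(at$sum_sq, at$effect)
    expect_equal(ss[["A"]], orc$ssa, tolerance = 1e-8)
    expect_equal(ss[["B"]], orc$ssb, tolerance = 1e-8)
    expect_equal(ss[["A:B"]], orc$ssab, tolerance = 1e-8)
    expect_equal(ss[["Residuals"]], orc$sse, tolerance = 1e-8)
    # additivity: effects + residual recover the total SS
    expect_equal(sum(at$sum_sq), orc$sst, tolerance = 1e-8)
    # F statistics against the closed-form mean squares
    dfa <- 2L; dfb <- 1L; dfe <- nrow(tab) - 6L
    expect_equal(at$statistic[at$effect == "A"],
                 (orc$ssa / dfa) / (orc$sse / dfe), tolerance = 1e-6)
    expect_equal(at$statistic[at$effect == "B"],
                 (orc$ssb / dfb) / (orc$sse / dfe), tolerance = 1e-6)
  }
})

test_that("degrees of freedom partition N - 1 and empty cells are named", {
  tab <- make_balanced(2, c("a1", "a2"), c("b1", "b2", "b3"),
                       function(A, B) 1, noise_sd = 1)
  at <- srd_anova(tab, c("A", "B"))
  expect_equal(sum(at$df), nrow(tab) - 1L)
  tab2 <- tab[!(tab$A == "a2" & tab$B == "b3"), ]
  expect_error(srd_anova(tab2, c("A", "B")), "A=a2.*B=b3")
  expect_error(srd_anova(tab, c("A", "missing_factor")), "not in table")
})

test_that("three-way model with capped interaction order fits and partitions", {
  set.seed(85)
  g <- expand.grid(A = c("x", "y"), B = c("u", "v"), C = c("p", "q", "r"),
                   rep = 1:3, stringsAsFactors = FALSE)
  g$srd_nor <- rnorm(nrow(g)) + 2 * (g$A == "x")
  full <- srd_anova(g, c("A", "B", "C"))
  expect_true("A:B:C" %in% full$effect)
  capped <- srd_anova(g, c("A", "B", "C"), max_order = 2)
  expect_false("A:B:C" %in% capped$effect)
  expect_equal(sum(full$df), nrow(g) - 1L)
  expect_equal(sum(capped$df), nrow(g) - 1L)
})

test_that("cell means are simple means with t-based intervals when balanced", {
  set.seed(87)
  tab <- make_balanced(6, c("a1", "a2"), c("b1", "b2"),
                       function(A, B) 10 * (A == "a2"), noise_sd = 2)
  cm <- cell_means(tab, c("A", "B"))
  expect_identical(nrow(cm), 4L)
  for (i in seq_len(4)) {
    v <- tab$srd_nor[tab$A == cm$A[i] & tab$B == cm$B[i]]
    expect_equal(cm$mean[i], mean(v))
    half <- stats::qt(0.975, 5) * stats::sd(v) / sqrt(6)
    expect_equal(cm$ci_high[i] - cm$mean[i], half)
    expect_equal(cm$mean[i] - cm$ci_low[i], half)
  }
  expect_false(any(cm$degenerate))
  # single-observation cells are flagged with undefined intervals
  one <- data.frame(A = c("a1", "a2"), srd_nor = c(1, 2))
  cm1 <- cell_means(one, "A")
  expect_true(all(cm1$degenerate))
  expect_true(all(is.na(cm1$ci_low)))
})
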