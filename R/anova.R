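#' Factorial ANOVA on a batched SRD table
#'
#' Tests which design factors (molecule size class, selection method, data
#' pretreatment, similarity metric) shift the normalised SRD values, with
#' sigma-restricted (sum-to-zero) parameterisation and all interactions up
#' to the requested order. SRD puts every factor on the same 0--100 scale,
#' which is what makes a joint ANOVA across factors meaningful. For the
#' balanced designs produced by [srd_batch()] the sequential sums of
#' squares coincide with the sigma-restricted (Type III) ones. p-values
#' come from the F distribution with no multiple-testing correction;
#' normality of the response is not enforced — the design leans on the
#' large number of runs.
#'
#' @param table long-format data.frame (the `table` element of an
#'   [srd_batch()] result, or compatible).
#' @param factors character vector of factor column names, e.g.
#'   `c("size_class", "selection")` for the two-way analysis or
#'   `c("size_class", "selection", "pretreatment")` for the three-way one.
#' @param response response column name (default `"srd_nor"`).
#' @param max_order highest interaction order to include (default: all
#'   interactions).
#' @return An object of class `"srd_anova"`: a data.frame with one row per
#'   effect plus residuals — `effect`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic` (F), `p_value` — with attributes `formula` and `nobs`.
#' @examples
#' \donttest{
#' b <- srd_batch(runs_per_cell = 2, n_molecules = 20, nbits = 256, seed = 1)
#' srd_anova(b$table, c("size_class", "selection"))
#' }
#' @export
srd_anova <- function(table, factors, response = "srd_nor",
                      max_order = length(factors)) {
  stopifnot(is.data.frame(table), length(factors) >= 1L)
  missing_cols <- setdiff(c(factors, response), names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  df <- table[, c(factors, response)]
  df[factors] <- lapply(df[factors], factor)
  counts <- table(df[factors])
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE, useNames = TRUE)[1L, ]
    lev <- mapply(function(f, i) levels(df[[f]])[i], factors, empty)
    stop("empty design cell: ", paste(factors, lev, sep = "=",
                                      collapse = ", "))
  }
  stopifnot(max_order >= 1L, max_order <= length(factors))
  rhs <- if (max_order == length(factors) || length(factors) == 1L) {
    paste(factors, collapse = " * ")
  } else {
    sprintf("(%s)^%d", paste(factors, collapse = " + "), max_order)
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = df, contrasts = contr)
  at <- stats::anova(fit)
  out <- data.frame(
    effect = rownames(at),
    df = at$Df,
    sum_sq = at$`Sum Sq`,
    mean_sq = at$`Mean Sq`,
    statistic = at$`F value`,
    p_value = at$`Pr(>F)`,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("srd_anova", "data.frame"),
            formula = fml, nobs = nrow(df))
}

#' @export
print.srd_anova <- function(x, digits = 4L, ...) {
  cat("Factorial ANOVA (sigma-restricted), ", attr(x, "nobs"),
      " observations\n", sep = "")
  cat("Model:", deparse(attr(x, "formula")), "\n")
  y <- x
  y$sum_sq <- signif(y$sum_sq, digits)
  y$mean_sq <- signif(y$mean_sq, digits)
  y$statistic <- signif(y$statistic, digits)
  y$p_value <- format.pval(y$p_value, digits = 3L)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Cell means with confidence intervals
#'
#' Mean normalised SRD per factor-level combination with symmetric
#' t-based confidence intervals, the numbers behind the weighted-means
#' interaction plots of the study (for balanced cells the weighted mean is
#' the simple mean). Cells with a single observation get `NA` intervals and
#' are flagged.
#'
#' @inheritParams srd_anova
#' @param conf_level confidence level (default 0.95).
#' @return A data.frame: the factor columns, `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `degenerate` (TRUE when n = 1).
#' @export
cell_means <- function(table, factors, response = "srd_nor",
                       conf_level = 0.95) {
  stopifnot(is.data.frame(table), length(factors) >= 1L,
            conf_level > 0, conf_level < 1)
  missing_cols <- setdiff(c(factors, response), names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  groups <- interaction(table[factors], drop = TRUE, sep = "\r")
  pieces <- lapply(split(table[[response]], groups), function(v) {
    n <- length(v)
    mu <- mean(v)
    s <- if (n > 1L) stats::sd(v) else NA_real_
    half <- if (n > 1L) stats::qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
            else NA_real_
    data.frame(n = n, mean = mu, sd = s,
               ci_low = mu - half, ci_high = mu + half,
               degenerate = n == 1L)
  })
  keys <- do.call(rbind, strsplit(names(pieces), "\r", fixed = TRUE))
  colnames(keys) <- factors
  out <- cbind(as.data.frame(keys, stringsAsFactors = FALSE),
               do.call(rbind, pieces))
  rownames(out) <- NULL
  out[do.call(order, out[factors]), , drop = FALSE]
}
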