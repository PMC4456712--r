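#' Run the SRD procedure on one synthetic dataset
#'
#' One experiment of the batched design: designate a reference compound
#' (drawn uniformly at random from the dataset unless given), compute the
#' similarity table of the remaining molecules against it, pretreat,
#' fuse into the consensus reference and fit [srd()] with random-ranking
#' classification and cross-validation.
#'
#' @param dataset an [fp_library()] with at least 3 molecules.
#' @param reference id of the reference compound, or `NULL` to draw it.
#' @param pretreatment column pretreatment, see [pretreat()].
#' @param metrics metric ids (the consensus is the average of exactly these
#'   columns).
#' @param null optional precomputed [null_distribution()] for
#'   `length(dataset) - 1` objects.
#' @param n_null Monte Carlo null sample size if `null` is missing.
#' @param cv logical: cross-validate?
#' @param seed integer seed (reference draw, null simulation, folds).
#' @return An [srd()] object with extra elements `reference_id` and
#'   `dataset_ids`.
#' @export
run_single <- function(dataset, reference = NULL,
                       pretreatment = c("interval", "standardize", "rank",
                                        "none"),
                       metrics = metric_ids(), null = NULL,
                       n_null = 10000L, cv = TRUE, seed = NULL) {
  stopifnot(inherits(dataset, "fp_library"))
  pretreatment <- match.arg(pretreatment)
  if (length(dataset) < 3L) stop("dataset needs at least 3 molecules")
  seeds <- derive_seeds(seed, 2L)
  if (is.null(reference)) {
    reference <- with_seed(seeds[1L], sample(ids(dataset), 1L))
  }
  if (!reference %in% ids(dataset)) {
    stop("reference id '", reference, "' not in dataset")
  }
  ref_fp <- dataset[[reference]]
  rest <- dataset[setdiff(ids(dataset), reference)]
  st <- similarity_table(ref_fp, rest, metrics)
  fit <- srd(st, pretreatment = pretreatment, null = null, n_null = n_null,
             cv = cv, seed = seeds[2L])
  fit$reference_id <- reference
  fit$dataset_ids <- ids(rest)
  fit
}

#' Batched SRD experiment over the factorial design
#'
#' Reruns the whole comparison: for every cell of the size-class x
#' selection-method design, datasets of `n_molecules` compounds are drawn
#' (without ever reusing a molecule) from a freshly generated class library,
#' one reference compound is designated per dataset, and the SRD of every
#' metric against the consensus is recorded under each pretreatment. The
#' similarity table of a run is computed once and shared by all
#' pretreatments. All randomness derives from `seed`, so a rerun with the
#' same master seed reproduces the table bit for bit, including diversity
#' picks and reference draws.
#'
#' At full scale the design is 4 size classes x 2 selections x 125 runs
#' (1000 runs) of 100-molecule datasets; `runs_per_cell` scales it down
#' with identical structure.
#'
#' @param runs_per_cell SRD runs per size x selection cell (>= 1; the
#'   full-scale study value is 125).
#' @param size_classes,selections factor levels to include.
#' @param pretreatments pretreatment levels (see [pretreat()]).
#' @param n_molecules dataset size (default 100; one molecule becomes the
#'   reference, leaving `n_molecules - 1` ranked objects).
#' @param nbits,density passed to [generate_library()].
#' @param metrics metric ids entering both the table and the consensus.
#' @param n_null Monte Carlo sample size for the shared random-ranking
#'   null.
#' @param pool_factor class-library size as a multiple of
#'   `runs_per_cell * n_molecules` (> 1 so diversity picking has slack).
#' @param seed master integer seed.
#' @return An object of class `"srd_batch"`: list with `table` (long-format
#'   data.frame: `run`, `size_class`, `selection`, `pretreatment`,
#'   `metric`, `srd`, `srd_nor`, `flag`, `reference`), `null` (the shared
#'   [null_distribution()]), and `config`. Methods: `print`, `summary`
#'   (per-metric box-whisker statistics), `plot`.
#' @examples
#' \donttest{
#' b <- srd_batch(runs_per_cell = 2, n_molecules = 20, nbits = 256,
#'                pretreatments = "interval", seed = 1)
#' summary(b)
#' }
#' @export
srd_batch <- function(runs_per_cell = 8L,
                      size_classes = size_class_ids(),
                      selections = c("random", "diverse"),
                      pretreatments = c("interval", "standardize", "rank"),
                      n_molecules = 100L,
                      nbits = 1024L,
                      density = c("dense", "sparse"),
                      metrics = metric_ids(),
                      n_null = 10000L,
                      pool_factor = 2,
                      seed = NULL) {
  cl <- match.call()
  density <- match.arg(density)
  size_classes <- match.arg(size_classes, size_class_ids(),
                            several.ok = TRUE)
  selections <- match.arg(selections, c("random", "diverse"),
                          several.ok = TRUE)
  pretreatments <- match.arg(pretreatments,
                             c("interval", "standardize", "rank", "none"),
                             several.ok = TRUE)
  check_metric_ids(metrics)
  stopifnot(runs_per_cell >= 1L, n_molecules >= 3L, pool_factor > 1)

  cells <- expand.grid(size_class = size_classes, selection = selections,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  total_runs <- n_cells * runs_per_cell
  seeds <- derive_seeds(seed, 1L + n_cells + 2L * total_runs)
  null <- null_distribution(n_molecules - 1L, method = "auto",
                            n_samples = n_null, seed = seeds[1L])

  rows <- vector("list", total_runs * length(pretreatments))
  ri <- 0L
  run_id <- 0L
  for (ci in seq_len(n_cells)) {
    size_class <- cells$size_class[ci]
    selection <- cells$selection[ci]
    pool <- generate_library(
      n = ceiling(pool_factor * runs_per_cell * n_molecules),
      size_class = size_class, nbits = nbits, density = density,
      seed = seeds[1L + ci],
      id_prefix = paste0(substr(size_class, 1L, 4L), "_",
                         substr(selection, 1L, 3L))
    )
    exclude <- character()
    for (r in seq_len(runs_per_cell)) {
      pick_seed <- seeds[1L + n_cells + 2L * run_id + 1L]
      run_seed <- seeds[1L + n_cells + 2L * run_id + 2L]
      ds <- if (selection == "random") {
        pick_random(pool, n_molecules, seed = pick_seed, exclude = exclude)
      } else {
        pick_diverse(pool, n_molecules, seed = pick_seed, exclude = exclude)
      }
      exclude <- c(exclude, ids(ds))
      rseeds <- derive_seeds(run_seed, 2L)
      reference <- with_seed(rseeds[1L], sample(ids(ds), 1L))
      st <- similarity_table(ds[[reference]],
                             ds[setdiff(ids(ds), reference)], metrics)
      for (pt in pretreatments) {
        fit <- srd(st, pretreatment = pt, null = null, cv = FALSE,
                   seed = rseeds[2L])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          run = run_id, size_class = size_class, selection = selection,
          pretreatment = pt, metric = names(fit$srd_nor),
          srd = unname(fit$srd), srd_nor = unname(fit$srd_nor),
          flag = unname(fit$flags), reference = reference,
          stringsAsFactors = FALSE, row.names = NULL
        )
      }
      run_id <- run_id + 1L
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(
      table = table, null = null,
      config = list(
        runs_per_cell = runs_per_cell, size_classes = size_classes,
        selections = selections, pretreatments = pretreatments,
        n_molecules = n_molecules, nbits = nbits, density = density,
        metrics = metrics, n_null = n_null, pool_factor = pool_factor,
        seed = seed
      ),
      call = cl
    ),
    class = "srd_batch"
  )
}

#' @export
print.srd_batch <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<srd_batch> %d runs (%d per cell) x %d metrics x %d pretreatment(s), m = %d\n",
    length(unique(x$table$run)), cfg$runs_per_cell, length(cfg$metrics),
    length(cfg$pretreatments), cfg$n_molecules - 1L
  ))
  cat("Median SRDnor by metric (pretreatment:", cfg$pretreatments[1L], ")\n")
  sub <- x$table[x$table$pretreatment == cfg$pretreatments[1L], ]
  med <- sort(tapply(sub$srd_nor, sub$metric, stats::median))
  print(round(med, 2))
  invisible(x)
}

#' Box-whisker summary of a batched SRD table
#'
#' Per-metric distribution summary of the normalised SRD values with the
#' whisker conventions of the study's plots: the whiskers span the
#' non-outlier range (points within 1.0 x IQR of the quartiles), points
#' between 1.0 and 1.5 coefficients are outliers, and points beyond 1.5 are
#' extremes.
#'
#' @param table long-format SRD table (the `table` element of an
#'   [srd_batch()] result, or compatible).
#' @param pretreatment which pretreatment level to summarise.
#' @return A data.frame, one row per metric (ordered by median):
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`, `n_extremes`.
#' @export
summarize_box_whisker <- function(table, pretreatment = "interval") {
  stopifnot(is.data.frame(table),
            all(c("metric", "srd_nor") %in% names(table)))
  if ("pretreatment" %in% names(table)) {
    table <- table[table$pretreatment == pretreatment, ]
  }
  if (!nrow(table)) stop("no rows for pretreatment '", pretreatment, "'")
  out <- do.call(rbind, lapply(split(table$srd_nor, table$metric), function(v) {
    if (length(v) < 5L) stop("need at least 5 values per metric")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    in_whisker <- v >= q[1L] - iqr & v <= q[3L] + iqr
    extreme <- v < q[1L] - 1.5 * iqr | v > q[3L] + 1.5 * iqr
    data.frame(
      n = length(v), median = q[2L], q1 = q[1L], q3 = q[3L],
      whisker_low = min(v[in_whisker]), whisker_high = max(v[in_whisker]),
      n_outliers = sum(!in_whisker & !extreme), n_extremes = sum(extreme)
    )
  }))
  out <- data.frame(metric = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$median), ]
}

#' @export
summary.srd_batch <- function(object, pretreatment = NULL, ...) {
  if (is.null(pretreatment)) pretreatment <- object$config$pretreatments[1L]
  summarize_box_whisker(object$table, pretreatment)
}

#' Box-whisker plot of a batched SRD comparison
#'
#' One box per metric (ordered by median normalised SRD), whiskers at the
#' 1.0 x IQR non-outlier range, with the shared random-ranking 5% limit
#' (XX1) drawn as a dashed line.
#'
#' @param x an [srd_batch()] result.
#' @param pretreatment pretreatment level to plot (default: first
#'   configured).
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.srd_batch <- function(x, pretreatment = NULL, ...) {
  if (is.null(pretreatment)) pretreatment <- x$config$pretreatments[1L]
  sub <- x$table[x$table$pretreatment == pretreatment, ]
  med <- sort(tapply(sub$srd_nor, sub$metric, stats::median))
  sub$metric <- factor(sub$metric, levels = names(med))
  graphics::boxplot(srd_nor ~ metric, data = sub, range = 1,
                    ylab = "SRDnor", las = 2,
                    main = paste0("SRD over all runs (", pretreatment, ")"),
                    ...)
  graphics::abline(h = x$null$quantiles[["xx1"]], lty = 2, col = "grey40")
  invisible(x)
}

#' Confirmatory rerun with a metric subset
#'
#' Repeats the whole batched comparison on a subset of the metrics, with
#' the consensus reference recomputed from the surviving columns only. The
#' study's use: omit Dice, Soergel and Manhattan — whose rankings duplicate
#' Tanimoto's and Euclidean's — to check that the monotone-equivalent
#' groups were not overweighting the consensus. Dataset generation reuses
#' the original master seed, so the runs see identical molecules.
#'
#' @param batch an [srd_batch()] result.
#' @param omit metric ids to drop (default `c("dice", "soergel",
#'   "manhattan")`).
#' @return A new [srd_batch()] result over the remaining metrics.
#' @export
confirmatory_subset <- function(batch,
                                omit = c("dice", "soergel", "manhattan")) {
  stopifnot(inherits(batch, "srd_batch"))
  check_metric_ids(omit)
  keep <- setdiff(batch$config$metrics, omit)
  if (length(keep) < 2L) stop("fewer than 2 metrics would remain")
  cfg <- batch$config
  srd_batch(
    runs_per_cell = cfg$runs_per_cell, size_classes = cfg$size_classes,
    selections = cfg$selections, pretreatments = cfg$pretreatments,
    n_molecules = cfg$n_molecules, nbits = cfg$nbits,
    density = cfg$density, metrics = keep, n_null = cfg$n_null,
    pool_factor = cfg$pool_factor, seed = cfg$seed
  )
}
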