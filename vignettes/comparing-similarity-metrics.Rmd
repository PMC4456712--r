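---
title: "Comparing fingerprint similarity metrics with sum of ranking differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing fingerprint similarity metrics with sum of ranking differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdfp)
```

## The question

Ranking a compound library by similarity to a query molecule is one of the
most common operations in cheminformatics, and there are many coefficients
to do it with. On binary fingerprints every coefficient reduces to three
counts — `a` on bits in molecule A, `b` on bits in molecule B, and `c` bits
on in both — yet different coefficients can rank the same library
differently. `srdfp` quantifies *how* differently, without appealing to any
activity data: each metric's ranking is compared to the consensus (average)
of all metrics, under the assumption that every metric measures the true,
unknown similarity with its own bias and noise, so the consensus is the
best available stand-in for a golden standard.

Eight coefficients are covered (`similarity_metrics()`): Tanimoto
`c/(a+b-c)`, Dice `2c/(a+b)`, Cosine `c/sqrt(ab)`, the Soergel distance
`1 - c/(a+b-c)`, the Manhattan distance `a+b-2c`, the Euclidean distance
`sqrt(a+b-2c)`, and two containment fractions: substructure `c/a` and
superstructure `c/b`, with the query as molecule A. The containment pair
deserves a caveat: commercial "substructure similarity" screens are defined
algorithmically on molecular graphs, and no published formula reproduces
them. The bit-containment fractions used here keep the intended semantics
(how much of one fingerprint is contained in the other) in a testable form;
they are surrogates, not claimed equivalents.

Native distances are converted with `to_similarity()`, `S = 1/(1+D)`, so
every table cell lies in (0, 1]. Conversion compresses scales unevenly —
Euclidean distances 5–8 become similarities 1/9–1/6, while the
corresponding Manhattan distances 25–64 become 1/65–1/26 — which is one
reason the metric columns need pretreatment before they are averaged.

## The SRD statistic

Given a table with `m` molecules in rows and `n` metric columns, `srd()`:

1. optionally applies a column-wise pretreatment (below);
2. appends the consensus reference column, the row-wise mean (identical to
   SUM fusion because every row has `n` entries);
3. ranks every column, including the reference, by increasing magnitude
   (ties get average ranks);
4. scores each metric by the sum of ranking differences
   `SRD = sum_i |r_i - q_i|`, where `r` is the metric's rank vector and `q`
   the reference's;
5. normalises to `SRDnor = 100 * SRD / SRDmax` so datasets of different
   size are comparable.

`SRDmax` is the largest SRD any tie-free ranking can achieve against the
reference, obtained by the extremal pairing argument (largest candidate
ranks paired with smallest reference ranks); for a tie-free reference it
equals `m^2/2` (even `m`) or `(m^2-1)/2` (odd `m`). The pairing form also
covers tied references, and tied data columns can never exceed it because a
tied (average-rank) vector is a convex combination of permutations. SRD
depends on a column only through its rank order, so metrics that are
strictly monotone transforms of each other — Tanimoto, Dice and the
Soergel-derived similarity; Manhattan- and Euclidean-derived similarities —
receive exactly equal SRD values on every dataset. Observing those
identities is a useful built-in self-check and the package's tests assert
them on every batch run.

Two validation layers accompany the statistic:

* **Randomization test.** `null_distribution()` gives the distribution of
  `SRDnor` for a uniformly random tie-free ranking: exact enumeration of
  all `m!` permutations for `m <= 10` (we default to exact at `m <= 8`),
  otherwise a seeded Monte Carlo sample (at least 10^4 draws). Its 5%, 50%
  and 95% quantiles are the XX1/Med/XX19 limits; a metric with
  `SRDnor < XX1` ranks the molecules distinguishably better than chance.
  All decisions use the empirical or exact quantiles — a fitted normal
  curve is a display device only, and avoiding it matters at small `m`
  where the null is visibly discrete. The raw-scale null mean is
  `(m^2-1)/3`, a handy closed-form cross-check. The null is sampled over
  tie-free permutations even when the data contain ties, matching the
  "random numbers" comparison it implements.
* **Cross-validation.** `cross_validate()` recomputes `SRDnor` on subsets:
  leave-one-out when `m < 14`, otherwise seven folds, each keeping a 6/7
  portion of the rows (fold assignment is seeded and recorded). The spread
  of fold values says whether two metrics' SRD lines are actually
  distinguishable.

## Pretreatment

Three column-wise transforms are supported (`pretreat()`): interval
scaling onto [0, 1], standardization (sample standard deviation, `n-1`
denominator — recorded explicitly so tests are deterministic), and rank
transformation (min rank 1, average ranks on ties). All three are monotone,
so they never change the rank order *within* a column; they act on the SRD
outcome only through the consensus mean, which weighs columns differently
after each transform. That is precisely why pretreatment is a design factor
in the batch experiment rather than a no-op. Standardization is applied per
column (per metric); the per-row alternative reading of the defining
formula is deliberately not claimed and can be emulated by transposing
before the call. Constant columns are degenerate for the first two
transforms and come back as zeros with a warning.

## The synthetic generator

The original experiment drew a thousand 100-molecule datasets from a ~5M
compound vendor database. `generate_library()` replaces that source with a
controlled emulation driven by one idea: what matters to dichotomous
similarity is bit density. Two profiles are provided.

* **sparse** — dictionary-type fingerprints (ECFP-like), mean 75 on bits
  per 1024 (the documented one-in-ten-to-twenty range, 50–100). Sparse
  fingerprints leave `c` only a few attainable values, so similarity
  columns are *degenerate* — many molecules share a value —
  which coarsens rankings; `degeneracy_fraction()` measures this, and the
  sparse-vs-dense contrast in the tests reproduces the motivation for
  switching to a darker, hashed fingerprint.
* **dense** — hashed-fingerprint regime with class-dependent means at 1024
  bits: fragment 150, leadlike 250, druglike 350. Coupling density to the
  fragment/leadlike/druglike size classes is the minimal structure that
  lets size effects exist at all; the specific means are emulation choices
  fixed once, not measurements. The "all" class draws each molecule's
  class from a 3:24:73 mixture, mirroring the relative class sizes of a
  large purchasable-compound database.

Each fingerprint draws its on-bit count from a binomial over the length and
places the bits uniformly. What this deliberately does **not** emulate:
correlated bits from shared substructures, realistic property profiles
(MW, logP, etc.), or any activity signal. Passing batch tests therefore
demonstrates that the machinery reproduces the *structural* findings (the
monotone groupings, the consensus-proximity ordering, the size and
selection effects), not that any real database would give the same numbers.

Dataset selection follows the study design: `pick_random()` draws without
ever reusing a molecule across datasets (an explicit exclusion set), and
`pick_diverse()` implements MaxMin — first pick uniform at random under the
run seed, then repeatedly the candidate with the largest minimum Tanimoto
distance to the picked set, ties broken by library order.

## The batched experiment and ANOVA

`srd_batch()` runs the full factorial design: size class (4) x selection
method (2) x `runs_per_cell` datasets, each of 100 molecules with one
randomly designated reference, under each pretreatment (the similarity
table is computed once per run and shared across pretreatments). The full
study scale is 125 runs per cell (1000 runs); the package default is 8 per
cell (64 runs), which keeps a complete batch under half a minute on one
core while leaving every distributional conclusion intact — the tests and
the acceptance script use this scale, and `runs_per_cell = 125` reproduces
the full design when wanted. A single Monte Carlo null for `m = 99` is
shared by all runs. All randomness descends from one master seed, so a
batch is bit-reproducible, including diversity picks, reference draws and
fold assignments. `confirmatory_subset()` reruns the identical datasets
with Dice, Soergel and Manhattan omitted, recomputing the consensus from
the five survivors, to verify that the monotone-identical groups were not
overweighting the average.

`summarize_box_whisker()` condenses a batch per metric with the plot
conventions used throughout: whiskers at the 1.0 x IQR non-outlier range,
outliers between 1.0 and 1.5 coefficients, extremes beyond 1.5.

`srd_anova()` fits the factorial ANOVA with sigma-restricted (sum-to-zero)
parameterisation on the long-format batch table; for the balanced designs
the batch produces, the sequential sums of squares equal the Type III ones,
and the implementation is cross-checked in the tests against a closed-form
balanced decomposition. p-values use the F distribution with no
multiple-testing correction, matching the per-effect reporting style of
factorial ANOVA software. Normality of `SRDnor` is not enforced; the
analysis leans on the sample size, and with few runs per cell the weaker
effects (notably the pretreatment main effect, which is small by
construction since pretreatments only act through the consensus) should
not be expected to reach significance. `cell_means()` provides the
weighted means and 0.95 t-intervals behind interaction plots;
single-observation cells are flagged rather than silently given intervals.

## Numerical conventions, edge cases, limitations

* Bit positions are 0-based; FPS text serialisation is
  most-significant-nibble-first hex (`write_fps()`/`read_fps()`).
* All-zero fingerprints make several denominators vanish; the affected
  similarities fall back to 0 with a warning, since such inputs usually
  indicate a generator misconfiguration rather than chemistry.
* Ties are always handled by average ranks, in columns and in the
  reference alike; there is no cap on the number of tied objects.
* `normalize_srd()` refuses `SRD > SRDmax` outright — that combination can
  only arise from a ranking bug upstream.
* The exact null is limited to `m <= 10` (factorial growth); beyond that
  the Monte Carlo path is the supported route, and its seed is part of the
  result's provenance.
* The consensus is a single-reference, equal-weight fusion. Group fusion
  (multiple reference structures) and weighted fusion schemes are out of
  scope.
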