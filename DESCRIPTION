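Package: srdfp
Title: Comparing Fingerprint Similarity Metrics with Sum of Ranking Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing binary molecular fingerprint similarity and
    distance coefficients (Tanimoto, Dice, Cosine, Soergel, Manhattan,
    Euclidean, and containment-based substructure/superstructure scores) by
    how closely each metric's ranking of a compound library matches a
    consensus (average, SUM-fusion) ranking. The core statistic is the sum
    of ranking differences (SRD), normalised by its maximum attainable
    value, validated against a permutation null distribution (exact
    enumeration at small sample sizes, Monte Carlo otherwise) and by
    leave-one-out or seven-fold cross-validation. A synthetic fingerprint
    generator emulates sparse and dense bit-density regimes across molecule
    size classes with random or MaxMin diversity-picked dataset selection,
    so the full batched experiment -- many datasets, three data
    pretreatment methods, factorial ANOVA over size, selection and
    pretreatment -- can be rerun without access to a vendor compound
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
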