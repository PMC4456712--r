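# The scaled-down batched experiment is expensive enough to share across
# test files: 8 runs per design cell, 100-molecule datasets, all three
# pretreatments, one fixed seed.
batch_cache <- new.env(parent = emptyenv())

scaled_batch <- function() {
  if (is.null(batch_cache$b)) {
    batch_cache$b <- srd_batch(runs_per_cell = 8L, n_molecules = 100L,
                               seed = 20150520L)
  }
  batch_cache$b
}
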