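# Shared fixtures, generated once per test run and memoised in this
# environment. The "default" dataset is the generator's documented study
# design (2 x 10 Mb genome, 200 planted regions, 10 tumor + 12 normal
# ChIP samples, 37 tumor RNA samples) at a fixed seed; the "small" dataset
# trades size for speed and backs the cheaper unit tests.

.fixtures <- new.env(parent = emptyenv())

small_synth_config <- function(seed = 11L, ...) {
  synth_config(
    seed = seed,
    genome = c(chr1 = 3e6, chr2 = 2e6),
    n_genes = 80L, n_denovo = 25L,
    n_se_clusters = 3L, n_pairs = 6L, n_triplets = 1L,
    n_mm_chip = 6L, n_rep_normal = 2L,
    n_mm_rna = 12L, n_rep_rna = 3L,
    n_bg_peaks = 80L, n_loss_peaks = 10L,
    n_repressed_blocks = 4L, repressed_block_bp = 80e3,
    cpg_spacing_bp = 1500L,
    ...
  )
}

shared_small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    dir <- file.path(tempdir(), "chromactiv_small_ds")
    simulate_dataset(small_synth_config(), dir)
    .fixtures$small <- list(dir = dir,
                            truth = read_truth_manifest(
                              file.path(dir, "truth.json")))
  }
  .fixtures$small
}

shared_default_dataset <- function() {
  if (is.null(.fixtures$default)) {
    dir <- file.path(tempdir(), "chromactiv_default_ds")
    simulate_dataset(synth_config(seed = 1L), dir)
    .fixtures$default <- list(dir = dir,
                              truth = read_truth_manifest(
                                file.path(dir, "truth.json")))
  }
  .fixtures$default
}

shared_default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    ds <- shared_default_dataset()
    out <- file.path(tempdir(), "chromactiv_default_out")
    .fixtures$default_run <- run_pipeline(pipeline_config(ds$dir, out))
    .fixtures$default_out <- out
  }
  .fixtures$default_run
}
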