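gr1 <- function(chrom, start, end)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

test_that("consensus is unanimous peaks at min_frac 1 and empty when split", {
  pk <- gr1("chr1", c(101, 501), c(200, 700))
  cons <- build_consensus(list(pk, pk, pk), min_frac = 1)
  expect_equal(GenomicRanges::start(cons), c(101, 501))
  expect_equal(cons$support, c(1, 1))
  disjoint <- build_consensus(list(gr1("chr1", 1, 100),
                                   gr1("chr1", 201, 300)), min_frac = 0.6)
  expect_length(disjoint, 0)
  expect_error(build_consensus(list()), "empty")
  expect_error(build_consensus(list(pk), min_frac = 0), "min_frac")
})

test_that("consensus equals the per-base voting oracle", {
  set.seed(77)
  for (min_frac in c(0.34, 0.5, 0.75)) {
    peaks <- lapply(1:6, function(i) random_granges(40, len = 1e5,
                                                    max_w = 3000))
    cons <- build_consensus(peaks, min_frac = min_frac)
    votes <- Reduce(`+`, lapply(peaks, mask_from_granges, len = 1e5))
    exp <- granges_from_mask(votes >= ceiling(min_frac * 6))
    expect_equal(GenomicRanges::ranges(cons), GenomicRanges::ranges(exp))
  }
})

test_that("stable baseline is the base-wise AND / union of consensuses", {
  shared <- gr1("chr1", 1, 100)
  cons <- list(a = shared, b = shared, c = shared, d = shared, e = shared)
  base <- stable_baseline(cons)
  expect_equal(GenomicRanges::ranges(base$stably_present),
               GenomicRanges::ranges(shared))
  # present in 4 of 5 populations: unstable, in neither stable set
  cons$e <- gr1("chr1", 501, 600)
  base2 <- stable_baseline(cons)
  expect_length(GenomicRanges::intersect(base2$stably_present,
                                         gr1("chr1", 1, 100)), 0)
  expect_true(all(IRanges::overlapsAny(gr1("chr1", 1, 100),
                                       base2$covered_any)))
  expect_error(stable_baseline(list(a = shared, b = NULL)), "\\bb\\b")
  expect_error(stable_baseline(list(a = shared)), ">= 2")
})

test_that("stable baseline matches boolean oracles on random input", {
  set.seed(88)
  cons <- lapply(1:5, function(i) merge_intervals(
    random_granges(30, len = 5e4, max_w = 2000)))
  names(cons) <- paste0("p", 1:5)
  base <- stable_baseline(cons)
  masks <- lapply(cons, mask_from_granges, len = 5e4)
  and_mask <- Reduce(`&`, masks)
  any_mask <- Reduce(`|`, masks)
  expect_equal(mask_from_granges(base$stably_present, 5e4), and_mask)
  expect_equal(mask_from_granges(base$covered_any, 5e4), any_mask)
})

test_that("differential calls follow the recurrence thresholds exactly", {
  normal <- gr1("chr1", 1001, 2000)
  cons <- list(a = normal, b = normal, c = normal, d = normal, e = normal)
  # tumor identical to the normal consensus: no gain, no loss
  mm_same <- lapply(1:10, function(i) normal)
  dc <- call_differential("H3K27ac", cons, mm_same)
  expect_length(dc$gain, 0)
  expect_length(dc$loss, 0)
  # one tumor-private peak in 9 of 10 samples over stably absent ground
  private <- gr1("chr1", 5001, 6000)
  mm <- c(lapply(1:9, function(i) c(normal, private)), list(normal))
  dc2 <- call_differential("H3K27ac", cons, mm, min_mm_frac = 0.8)
  expect_length(dc2$gain, 1)
  expect_equal(GenomicRanges::start(dc2$gain), 5001)
  expect_equal(dc2$gain$mark, "H3K27ac")
  # peak absent from all tumor samples inside stably present: a loss
  mm_loss <- lapply(1:10, function(i) gr1("chr1", 9001, 9500))
  dc3 <- call_differential("H3K27ac", cons, mm_loss)
  expect_equal(GenomicRanges::ranges(dc3$loss),
               GenomicRanges::ranges(normal))
  expect_error(call_differential("H3K27ac", cons, list()), "tumor")
})

test_that("gains and losses are disjoint and gains shrink as recurrence rises", {
  set.seed(99)
  cons <- lapply(1:5, function(i)
    merge_intervals(random_granges(30, 1e5, 4000)))
  names(cons) <- paste0("p", 1:5)
  mm <- lapply(1:8, function(i) random_granges(40, 1e5, 4000))
  prev <- Inf
  for (f in c(0.3, 0.5, 0.8)) {
    dc <- call_differential("H3K4me1", cons, mm, min_mm_frac = f,
                            min_region_bp = 1)
    expect_length(GenomicRanges::intersect(dc$gain, dc$loss), 0)
    expect_lte(length(dc$gain), prev)
    prev <- length(dc$gain)
  }
})

test_that("noise-free generation gives perfect planted recovery", {
  dir <- file.path(tempdir(), "chromactiv_clean_ds")
  cfg <- small_synth_config(seed = 4L, dropout = 0, spurious_rate = 0,
                            mm_presence = 1)
  simulate_dataset(cfg, dir)
  truth <- read_truth_manifest(file.path(dir, "truth.json"))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  k27 <- sheet[sheet$assay == "H3K27ac", ]
  pk <- lapply(k27$path, read_bed)
  names(pk) <- k27$sample_id
  cons <- lapply(baseline_populations(), function(p)
    build_consensus(pk[k27$population == p]))
  names(cons) <- baseline_populations()
  dc <- call_differential("H3K27ac", cons, pk[k27$population == "MM"])
  dn <- select_de_novo(dc$gain, pk[k27$population != "MM"],
                       k27$population[k27$population != "MM"])
  expect_equal(mean(IRanges::overlapsAny(dn, truth$planted_denovo)), 1)
  expect_equal(mean(IRanges::overlapsAny(truth$planted_denovo, dn)), 1)
})

test_that("annotation reports ATAC fractions, methylation and host genes", {
  regions <- gr1("chr1", c(1001, 9001), c(2000, 9400))
  atac_mm <- list(gr1("chr1", 1101, 1200), gr1("chr1", 50001, 50100))
  genes <- data.frame(gene_id = "g1", gene_name = "G1", chrom = "chr1",
                      start = 900, end = 2500, strand = "+", tss = 900)
  meth <- data.table::data.table(chrom = "chr1",
                                 pos = c(1100L, 1200L, 1300L),
                                 beta = c(0.2, 0.4, 0.6),
                                 coverage = c(30L, 30L, 30L))
  ann <- annotate_differential(regions, atac_mm = atac_mm,
                               atac_normal = list(),
                               meth_mm = list(s1 = meth),
                               meth_normal = list(),
                               genes = genes, de = NULL)
  expect_equal(ann$atac_fraction_mm, c(0.5, 0))
  expect_equal(ann$medmeth_mm[1], 0.4)          # mean of {0.2, 0.4, 0.6}
  expect_true(is.na(ann$medmeth_mm[2]))          # region with zero CpGs
  expect_equal(ann$host_gene, c("g1", NA))
  expect_equal(ann$host_gene_de, c("na", "na"))
})

test_that("planted repressed blocks lose methylation in the tumor", {
  ds <- shared_small_dataset()
  sheet <- read_sample_sheet(file.path(ds$dir, "samples.tsv"))
  wgbs <- sheet[sheet$assay == "WGBS", ]
  meth <- lapply(wgbs$path, read_methylation)
  names(meth) <- wgbs$sample_id
  genes <- read_gene_annotation(file.path(ds$dir, "genes.tsv"))
  ann <- annotate_differential(
    ds$truth$planted_blocks,
    atac_mm = list(), atac_normal = list(),
    meth_mm = meth[wgbs$population == "MM"],
    meth_normal = meth[wgbs$population != "MM"],
    genes = genes)
  expect_gte(mean(ann$medmeth_mm < ann$medmeth_normal, na.rm = TRUE), 0.9)
})
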