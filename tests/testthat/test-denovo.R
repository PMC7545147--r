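gr1 <- function(chrom, start, end)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

test_that("a single shared base with any normal sample disqualifies", {
  gains <- gr1("chr1", c(1000, 5000), c(1999, 5999))
  bmpc <- gr1("chr1", 1999, 2500)  # 1 bp overlap with the first gain
  dn <- select_de_novo(gains, list(bm = bmpc), "bm-PC")
  expect_length(dn, 1)
  expect_equal(GenomicRanges::start(dn), 5000)
  # no normal peaks anywhere: the filter is vacuous
  dn2 <- select_de_novo(gains, list(bm = GenomicRanges::GRanges()), "bm-PC")
  expect_length(dn2, 2)
})

test_that("the bm-PC filter is mandatory unless overridden", {
  gains <- gr1("chr1", 1000, 1999)
  peaks <- list(a = GenomicRanges::GRanges())
  expect_error(select_de_novo(gains, peaks, "GCBC"), "bm-PC")
  expect_warning(dn <- select_de_novo(gains, peaks, "GCBC",
                                      require_bmpc = FALSE), "overridden")
  expect_length(dn, 1)
})

test_that("mm_support records the tumor peak recurrence", {
  gains <- gr1("chr1", 1000, 1999)
  mm <- list(gr1("chr1", 900, 1100), gr1("chr1", 1500, 2500),
             gr1("chr1", 8000, 9000), gr1("chr1", 1000, 1999))
  dn <- select_de_novo(gains, list(bm = GenomicRanges::GRanges()), "bm-PC",
                       mm_peaks = mm)
  expect_equal(dn$mm_support, 0.75)
})

test_that("stitching respects the distance boundary inclusively", {
  genes <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tss = integer(0))
  track <- gr1("chr1", 1, 60000); track$score <- 1
  # ends at 1000; next starts at 13501 -> gap exactly 12500
  pk <- gr1("chr1", c(1, 13501, 40001), c(1000, 14000, 41000))
  st <- suppressWarnings(stitch_superenhancers(pk, list(track), genes))
  expect_equal(length(st), 2)
  expect_equal(st$n_constituents[1], 2)
  pk2 <- gr1("chr1", c(1, 13502), c(1000, 14000))  # gap 12501
  st2 <- suppressWarnings(stitch_superenhancers(pk2, list(track), genes))
  expect_equal(length(st2), 2)
})

test_that("the tangent cutoff flags only the outlier of (1,1,1,1,100)", {
  genes <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tss = integer(0))
  # five stitched regions of equal width, signal 1,1,1,1,100
  starts <- seq(1, by = 1e5, length.out = 5)
  pk <- gr1("chr1", starts, starts + 999)
  track <- pk
  track$score <- c(1, 1, 1, 1, 100) / 1000  # per-base value -> total
  st <- stitch_superenhancers(pk, list(track), genes)
  expect_equal(sum(st$is_super), 1)
  expect_true(st$is_super[which.max(st$signal)])
  # brute-force tangent oracle: the slope-1 line through the support point
  # leaves no scaled point below it; everything above that rank is super
  sig <- sort(st$signal)
  x <- (seq_along(sig) - 1) / (length(sig) - 1)
  y <- (sig - min(sig)) / (max(sig) - min(sig))
  support <- which(vapply(seq_along(sig), function(i)
    all(y - (y[i] + (x - x[i])) >= -1e-12), logical(1)))
  expect_equal(max(support), 4)
  # flat curve: no superenhancers by convention
  track$score <- rep(0.005, 5)
  st_flat <- stitch_superenhancers(pk, list(track), genes)
  expect_equal(sum(st_flat$is_super), 0)
})

test_that("fewer than three stitched regions disables the cutoff", {
  genes <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tss = integer(0))
  pk <- gr1("chr1", c(1, 50000), c(1000, 51000))
  track <- pk; track$score <- c(1, 50)
  expect_warning(st <- stitch_superenhancers(pk, list(track), genes),
                 "fewer than 3")
  expect_false(any(st$is_super))
})

test_that("peaks fully inside the promoter window are excluded", {
  genes <- data.frame(gene_id = "g1", gene_name = "G1", chrom = "chr1",
                      start = 20000, end = 30000, strand = "+",
                      tss = 20000)
  pk <- gr1("chr1", c(19000, 50000, 60000, 70000),
            c(20500, 51000, 61000, 71000))  # first is within tss +/- 2 kb
  track <- gr1("chr1", 1, 1e5); track$score <- 1
  st <- suppressWarnings(stitch_superenhancers(pk, list(track), genes))
  expect_false(any(IRanges::overlapsAny(st, gr1("chr1", 19000, 20500),
                                        type = "equal")))
  expect_equal(sum(st$n_constituents), 3)
})

test_that("superenhancer constituents partition the stitched bases", {
  run <- shared_default_run()
  se <- run$superenhancers
  expect_length(GenomicRanges::findOverlaps(se, drop.self = TRUE,
                                            ignore.strand = TRUE), 0)
})

test_that("atac_gain flags shared-base overlap including boundaries", {
  dn <- gr1("chr1", 1000, 1999)
  dn$region_id <- "dn_0001"
  flagged <- intersect_atac(dn, GenomicRanges::GRanges())
  expect_false(flagged$atac_gain)
  flagged2 <- intersect_atac(dn, gr1("chr1", 1999, 2500))  # one shared base
  expect_true(flagged2$atac_gain)
})

test_that("every reported de novo region passes the independent audit", {
  ds <- shared_default_dataset()
  run <- shared_default_run()
  sheet <- read_sample_sheet(file.path(ds$dir, "samples.tsv"))
  normals <- sheet[sheet$population != "MM" & sheet$assay == "H3K27ac", ]
  peaks <- lapply(normals$path, read_bed)
  expect_equal(audit_de_novo(run$denovo, peaks), 0)
})
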