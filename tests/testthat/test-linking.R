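gr1 <- function(chrom, start, end)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

make_tads <- function(starts, ends, chrom = "chr1") {
  t <- gr1(chrom, starts, ends)
  t$tad_id <- sprintf("tad_%d", seq_along(t))
  t
}

test_that("assign_tad uses the midpoint rule", {
  tads <- make_tads(c(1, 20001), c(10000, 30000))
  expect_equal(assign_tad(gr1("chr1", 2000, 3000), tads), "tad_1")
  # straddles the boundary with the midpoint on the left
  expect_equal(assign_tad(gr1("chr1", 9001, 10800), tads), "tad_1")
  # midpoint in the inter-TAD gap
  expect_true(is.na(assign_tad(gr1("chr1", 10500, 15000), tads)))
})

test_that("assign_tad matches a brute-force containment oracle", {
  set.seed(55)
  starts <- seq(1, by = 12000, length.out = 20)
  tads <- make_tads(starts, starts + 9999)
  regions <- random_granges(200, len = 250000, max_w = 4000)
  got <- assign_tad(regions, tads)
  mid <- GenomicRanges::start(regions) +
    GenomicRanges::width(regions) %/% 2L
  exp <- vapply(mid, function(m) {
    i <- which(GenomicRanges::start(tads) <= m &
                 GenomicRanges::end(tads) >= m)
    if (length(i)) tads$tad_id[i] else NA_character_
  }, character(1))
  expect_equal(got, exp)
})

fake_de <- function(gene_ids, up_ids) {
  data.frame(gene_id = gene_ids,
             fold_change = ifelse(gene_ids %in% up_ids, 4, 1),
             q_value = ifelse(gene_ids %in% up_ids, 1e-4, 0.6),
             row.names = gene_ids)
}

test_that("linking requires up-regulation against every population", {
  tads <- make_tads(c(1, 20001), c(10000, 30000))
  genes <- data.frame(gene_id = c("g1", "g2"), gene_name = c("G1", "G2"),
                      chrom = "chr1", start = c(2000, 21000),
                      end = c(4000, 23000), strand = "+",
                      tss = c(2000, 21000))
  regions <- gr1("chr1", c(6000, 25000), c(7000, 26000))
  regions$region_id <- c("r1", "r2")
  ids <- genes$gene_id
  # g1 up against every population; g2 up in 4 of 5 only
  de_list <- c(lapply(1:4, function(i) fake_de(ids, c("g1", "g2"))),
               list(fake_de(ids, "g1")))
  links <- link_targets(regions, tads, genes, de_list)
  expect_equal(links$gene_id, "g1")
  expect_equal(links$region_id, "r1")
  expect_true(links$same_tad)
  # a TAD with no genes yields no link (counted, not an error)
  empty_tad_region <- gr1("chr1", 25000, 26000)
  empty_tad_region$region_id <- "r3"
  genes_far <- genes[1, ]
  expect_equal(nrow(link_targets(empty_tad_region, tads, genes_far,
                                 de_list)), 0)
})

test_that("TAD-less regions fall back to a distance window that only shrinks", {
  tads <- make_tads(1, 10000)
  genes <- data.frame(gene_id = "g1", gene_name = "G1", chrom = "chr1",
                      start = 2000, end = 4000, strand = "+", tss = 2000)
  region <- gr1("chr1", 50000, 51000)  # outside every TAD
  region$region_id <- "r1"
  de_list <- list(fake_de("g1", "g1"))
  wide <- link_targets(region, tads, genes, de_list,
                       fallback_window = 1e6)
  expect_equal(nrow(wide), 1)
  expect_true(wide$fallback)
  narrow <- link_targets(region, tads, genes, de_list,
                         fallback_window = 1e4)
  expect_equal(nrow(narrow), 0)
})

test_that("coexpression thresholds are strict and chains merge", {
  set.seed(66)
  genes <- data.frame(gene_id = paste0("g", 1:5),
                      gene_name = paste0("G", 1:5), chrom = "chr1",
                      start = seq(1000, by = 10000, length.out = 5),
                      end = seq(3000, by = 10000, length.out = 5),
                      strand = "+",
                      tss = seq(1000, by = 10000, length.out = 5))
  n <- 37
  z <- rnorm(n)
  expr <- rbind(
    g1 = 100 * exp(0.8 * z + 0.3 * rnorm(n)),
    g2 = 100 * exp(0.8 * z + 0.3 * rnorm(n)),
    g3 = 100 * exp(0.8 * z + 0.3 * rnorm(n)),
    g4 = 100 * exp(rnorm(n)),
    g5 = 100 * exp(rnorm(n)))
  colnames(expr) <- paste0("m", 1:n)
  groups <- find_coregulated(paste0("g", 1:5), genes, expr)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$genes, c("g1", "g2", "g3"))  # one triplet
  expect_true(all(groups[[1]]$r > 0.5 & groups[[1]]$p < 0.05))
  # r exactly at the threshold is excluded (strict inequality)
  r12 <- pearson_test(expr["g1", ], expr["g2", ])$r
  at_thr <- find_coregulated(c("g1", "g2"), genes[1:2, ], expr[1:2, ],
                             r_min = r12)
  expect_length(at_thr, 0)
})

test_that("an intervening non-target gene breaks adjacency", {
  genes <- data.frame(gene_id = c("a", "mid", "b"),
                      gene_name = c("A", "MID", "B"), chrom = "chr1",
                      start = c(1000, 11000, 21000),
                      end = c(3000, 13000, 23000), strand = "+",
                      tss = c(1000, 11000, 21000))
  set.seed(67)
  z <- rnorm(20)
  expr <- rbind(a = exp(z), mid = exp(rnorm(20)), b = exp(z))
  colnames(expr) <- paste0("m", 1:20)
  # a and b correlate perfectly but "mid" sits between them
  expect_length(find_coregulated(c("a", "b"), genes, expr), 0)
  # constant vectors are skipped with a message, not an error
  expr2 <- rbind(a = rep(1, 20), b = exp(z))
  colnames(expr2) <- paste0("m", 1:20)
  expect_message(
    out <- find_coregulated(c("a", "b"), genes[c(1, 3), ], expr2),
    "constant")
  expect_length(out, 0)
})

test_that("reported groups satisfy their thresholds when recomputed", {
  run <- shared_default_run()
  ds <- shared_default_dataset()
  expr <- read_expression(file.path(ds$dir, "expression.tsv"))
  sheet <- read_sample_sheet(file.path(ds$dir, "samples.tsv"))
  rna <- sheet[sheet$assay == "RNA", ]
  mm_cols <- rna$sample_id[rna$population == "MM"]
  for (g in run$groups) {
    for (k in seq_len(length(g$genes) - 1)) {
      ct <- pearson_test(expr[g$genes[k], mm_cols],
                         expr[g$genes[k + 1], mm_cols])
      expect_gt(ct$r, 0.5)
      expect_lt(ct$p, 0.05)
    }
  }
})
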