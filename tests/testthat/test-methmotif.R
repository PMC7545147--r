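uniform_pwm <- function(consensus, p = 0.97, id = "toy") {
  prob <- matrix((1 - p) / 3, nrow = 4, ncol = length(consensus),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(consensus)) prob[consensus[k], k] <- p
  list(id = id, prob = prob,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("maximal and minimal sequences scan as expected", {
  pwm <- uniform_pwm(rep("A", 6))
  hits <- scan_pwm(Biostrings::DNAStringSet(c(s1 = "AAAAAA")), pwm)
  plus <- hits[BiocGenerics::strand(hits) == "+"]
  expect_length(plus, 1)
  expect_equal(plus$offset, 0)
  none <- scan_pwm(Biostrings::DNAStringSet(c(s1 = "CCCCCC")), pwm)
  expect_length(none, 0)
  # sequence shorter than the motif: no hits, no error
  short <- scan_pwm(Biostrings::DNAStringSet(c(s1 = "AAA")), pwm)
  expect_length(short, 0)
})

test_that("random scans equal the exhaustive window oracle", {
  set.seed(12)
  for (rep in 1:3) {
    seq_chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                     collapse = "")
    cons <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    pwm <- uniform_pwm(cons, p = 0.55)
    got <- scan_pwm(Biostrings::DNAStringSet(c(s = seq_chr)), pwm,
                    score_frac = 0.7)
    exp <- scan_oracle(seq_chr, pwm$prob, pwm$background, 0.7)
    got_df <- data.frame(offset = got$offset,
                         strand = as.character(BiocGenerics::strand(got)),
                         score = got$score)
    o1 <- order(got_df$offset, got_df$strand)
    o2 <- order(exp$offset, exp$strand)
    expect_equal(got_df$offset[o1], exp$offset[o2])
    expect_equal(got_df$strand[o1], exp$strand[o2])
    expect_equal(got_df$score[o1], exp$score[o2], tolerance = 1e-12)
  }
})

test_that("reverse-complementing sequences mirrors hits across strands", {
  set.seed(13)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
  pwm <- uniform_pwm(c("T", "T", "C", "G", "A", "A"), p = 0.8)
  ss <- Biostrings::DNAStringSet(c(s = seq_chr))
  fwd <- scan_pwm(ss, pwm, score_frac = 0.75)
  rcs <- Biostrings::reverseComplement(ss)
  names(rcs) <- "s"
  rev <- scan_pwm(rcs, pwm, score_frac = 0.75)
  L <- nchar(seq_chr); w <- ncol(pwm$prob)
  # plus hits of the original appear as minus hits at mirrored offsets
  fwd_plus <- fwd[as.character(BiocGenerics::strand(fwd)) == "+"]
  rev_minus <- rev[as.character(BiocGenerics::strand(rev)) == "-"]
  expect_equal(sort(L - w - fwd_plus$offset), sort(rev_minus$offset))
  expect_equal(sort(fwd_plus$score), sort(rev_minus$score),
               tolerance = 1e-12)
})

test_that("genomic sequence names place hits on the genome", {
  pwm <- uniform_pwm(rep("A", 6))
  hits <- scan_pwm(Biostrings::DNAStringSet(
    c("chr3:1001-1050" = "CCCCAAAAAACCCC")), pwm)
  plus <- hits[BiocGenerics::strand(hits) == "+"]
  expect_equal(as.character(GenomicRanges::seqnames(plus)), "chr3")
  expect_equal(GenomicRanges::start(plus), 1005)  # offset 4 from 1001
})

mk_meth <- function(pos, beta, coverage = 30L)
  data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                         beta = beta, coverage = as.integer(coverage))

mk_hits <- function(centers, w = 10L) {
  h <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(centers - w %/% 2L,
                                               width = w))
  h$score <- 1
  h
}

test_that("cpg_differential applies the threshold arithmetic", {
  hits <- mk_hits(1000)
  mm <- list(mk_meth(998, 0.5), mk_meth(998, 0.5))
  nr <- list(mk_meth(998, 0.8), mk_meth(998, 0.8))
  res <- cpg_differential(hits, mm, nr)
  expect_equal(res$cpgs$delta, -0.3, tolerance = 1e-12)
  expect_true(res$cpgs$hypo_in_mm)
  expect_equal(res$fraction, 1)
  # identical betas in both groups: nothing flagged
  res0 <- cpg_differential(hits, nr, nr)
  expect_equal(res0$cpgs$delta, 0)
  expect_equal(res0$fraction, 0)
  # the unsigned variant flags gains of the same magnitude
  res_gain <- cpg_differential(hits, nr, mm, signed = FALSE)
  expect_equal(res_gain$fraction, 1)
})

test_that("cpg_differential respects the coverage filter and sample order", {
  hits <- mk_hits(1000)
  mm <- list(mk_meth(998, 0.2, coverage = 3), mk_meth(998, 0.6))
  nr <- list(mk_meth(998, 0.9))
  res <- cpg_differential(hits, mm, nr)
  expect_equal(res$cpgs$mean_mm, 0.6)  # low-coverage sample dropped
  res_rev <- cpg_differential(hits, rev(mm), nr)
  expect_equal(res_rev$fraction, res$fraction)
  # zero CpGs near hits: warning, empty result
  far <- list(mk_meth(99000, 0.5))
  expect_warning(empty <- cpg_differential(hits, far, far), "no covered")
  expect_true(is.na(empty$fraction))
})

test_that("composite profiles bin offsets correctly", {
  hits <- mk_hits(10000)
  # uniform beta field: flat profile at 0.7
  pos <- seq(8000, 12000, by = 10)
  mm <- list(mk_meth(pos, 0.7))
  nr <- list(mk_meth(pos, 0.7))
  prof <- composite_profile(hits, mm, nr, flank = 2000, bin_bp = 50)
  filled <- !is.na(prof$mean_beta)
  expect_true(any(filled))
  expect_true(all(abs(prof$mean_beta[filled] - 0.7) < 1e-12))
  # a single CpG at offset +30 lands only in bin [0, 50)
  one <- list(mk_meth(10029, 0.4))  # 0-based pos; center base is 10000
  prof2 <- composite_profile(hits, one, list(mk_meth(10029, 0.4)),
                             flank = 2000, bin_bp = 50, min_cpg = 1)
  mm_rows <- prof2[prof2$group == "MM", ]
  expect_equal(mm_rows$bin_start[mm_rows$n_cpg > 0], 0)
})
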