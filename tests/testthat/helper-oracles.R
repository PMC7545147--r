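# Independent brute-force oracles used across the suite. All work on
# 0-based half-open coordinates via explicit boolean base masks, never
# through the interval code they check.

# GRanges (single chrom) -> logical base mask of length len.
mask_from_granges <- function(gr, len) {
  m <- rep(FALSE, len)
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]
    e <- min(GenomicRanges::end(gr)[i], len)
    if (s <= e) m[s:e] <- TRUE
  }
  m
}

# logical mask -> GRanges on 'chrom' (runs of TRUE).
granges_from_mask <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts[keep], ends[keep]))
}

random_granges <- function(n, len = 1e6, max_w = 5000, chrom = "chr1") {
  s <- sample.int(len - max_w, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, width = w))
}

# Textbook Welch statistic from first principles.
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# Step-up BH from its definition, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive per-window PWM scoring on both strands; returns a data.frame
# (offset 0-based, strand, score) of windows meeting the threshold.
scan_oracle <- function(seq_chr, prob, background, score_frac) {
  lo <- log2(prob / background)
  w <- ncol(prob)
  thr <- score_frac * sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_chr, "")[[1]]
  out <- list()
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    for (strand in c("+", "-")) {
      wv <- if (strand == "+") win else rev(unname(comp[win]))
      sc <- sum(vapply(seq_len(w), function(k) lo[wv[k], k], numeric(1)))
      if (!is.na(sc) && sc >= thr)
        out[[length(out) + 1L]] <- data.frame(offset = off, strand = strand,
                                              score = sc)
    }
  }
  if (!length(out)) return(data.frame(offset = integer(0),
                                      strand = character(0),
                                      score = numeric(0)))
  do.call(rbind, out)
}

# Spec rule table for state assignment, written as the literal if-else
# cascade (independent of the vectorized implementation).
state_oracle <- function(k4me3, k27ac, k4me1, k36, k27me3, k9) {
  if (k4me3 && k27me3) return("BivalentProm")
  if (k4me3 && k27ac) return("ActiveProm")
  if (k4me3) return("WeakProm")
  if (k4me1 && k27ac) return("ActiveEnh")
  if (k4me1) return("WeakEnh")
  if (k36) return("Transcription")
  if (k27me3) return("PolycombRepr")
  if (k9) return("Heterochrom")
  "LowSignal"
}
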