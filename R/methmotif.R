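#' Motif scanning and motif-anchored DNA methylation
#'
#' Stage 4. Supplied PWMs are scanned over region sequences with a
#' log-odds threshold relative to the maximum attainable score; CpGs within
#' a flank of the motif hits are compared between tumor and normal WGBS
#' samples; and a composite binned methylation profile is built around
#' motif centers.
#'
#' @name methylation-motifs
NULL

# Log2-odds matrix of a PWM against its background.
.pwm_log_odds <- function(pwm) log2(pwm$prob / pwm$background)

# Score all windows of coded sequence s (integers 1..4, NA for N) against
# a 4 x w log-odds matrix. Returns numeric vector of window scores
# (position 1 = window starting at base 1); NA-containing windows get -Inf.
.score_windows <- function(s, lo) {
  w <- ncol(lo)
  L <- length(s)
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  sc <- numeric(n_win)
  for (k in seq_len(w)) sc <- sc + lo[, k][s[k:(L - w + k)]]
  sc[is.na(sc)] <- -Inf
  sc
}

.code_seq <- function(chars) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(code[chars])
}

#' Scan position weight matrices over region sequences
#'
#' Scores every window on both strands with the log2-odds of the PWM
#' against its background; a window is a hit when its score reaches
#' `score_frac` times the maximum attainable log-odds for that PWM.
#' Ambiguous bases (N) score minus infinity. Overlapping hits on opposite
#' strands are both reported. Sequences named `chrom:start-end` yield hits
#' in genomic coordinates; other names are treated as chromosome labels
#' with the sequence starting at base 1.
#'
#' @param seqs A [Biostrings::DNAStringSet] of region sequences.
#' @param pwm A PWM as returned by [read_meme_pwm()] (one element).
#' @param score_frac Fraction of the maximum attainable score required for
#'   a hit (default 0.8).
#' @return A `GRanges` of motif hits with strand set and metadata
#'   `motif_id`, `score`, `seq_name`, `offset` (0-based within the
#'   sequence).
#' @export
scan_pwm <- function(seqs, pwm, score_frac = 0.8) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  lo <- .pwm_log_odds(pwm)
  w <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_frac * max_score
  nms <- names(seqs)
  genomic <- length(nms) && all(grepl("^\\S+:\\d+-\\d+$", nms))
  anchors <- if (genomic) .regions_from_names(nms) else NULL
  rows <- list()
  for (i in seq_along(seqs)) {
    chars <- strsplit(as.character(seqs[[i]]), "")[[1]]
    L <- length(chars)
    if (L < w) next
    fwd <- .score_windows(.code_seq(chars), lo)
    rc <- as.character(Biostrings::reverseComplement(seqs[[i]]))
    rev <- .score_windows(.code_seq(strsplit(rc, "")[[1]]), lo)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd else rev
      at <- which(sc >= thr)
      if (!length(at)) next
      off0 <- if (strand == "+") at - 1L else L - (at - 1L) - w
      chrom <- if (genomic)
        as.character(GenomicRanges::seqnames(anchors))[i] else nms[i]
      gstart <- if (genomic)
        GenomicRanges::start(anchors)[i] + off0 else off0 + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = gstart, strand = strand,
        score = sc[at], seq_name = nms[i], offset = off0)
    }
  }
  if (!length(rows))
    return(GenomicRanges::GRanges(motif_id = character(0),
                                  score = numeric(0),
                                  seq_name = character(0),
                                  offset = integer(0)))
  df <- do.call(rbind, rows)
  out <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, width = w),
                                strand = df$strand)
  out$motif_id <- pwm$id
  out$score <- df$score
  out$seq_name <- df$seq_name
  out$offset <- df$offset
  sort(out, ignore.strand = TRUE)
}

# Per-CpG mean beta across the samples of one group, restricted to CpGs
# overlapping 'windows'. Returns data.table(chrom, pos, mean_beta, n).
.group_cpg_means <- function(meth_list, windows, min_cov = 5L) {
  pieces <- lapply(meth_list, function(mt) {
    keep <- mt$coverage >= min_cov
    sub <- mt[keep]
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$pos + 1L, width = 1L))
    sub[IRanges::overlapsAny(gr, windows, ignore.strand = TRUE)]
  })
  all <- data.table::rbindlist(pieces)
  if (!nrow(all))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  mean_beta = numeric(0), n = integer(0)))
  all[, list(mean_beta = mean(beta), n = .N), by = c("chrom", "pos")]
}

#' Per-CpG methylation differential around motif hits
#'
#' Considers CpGs within `motif_flank` bp of any motif hit. Per group, a
#' CpG's beta is averaged over the samples covering it with at least
#' `min_cov` reads; the differential is delta = mean(tumor) - mean(normal),
#' and a CpG is hypomethylated in the tumor when delta < -`delta_threshold`
#' (or |delta| > threshold with `signed = FALSE`).
#'
#' @param hits Motif hits ([scan_pwm()]).
#' @param meth_mm,meth_normal Lists of per-sample methylation tables.
#' @param motif_flank Flank around each hit in bp (default 10).
#' @param delta_threshold Methylation-difference threshold (default 0.25).
#' @param min_cov Minimum per-sample CpG coverage (default 5).
#' @param signed If `FALSE`, flag |delta| > threshold instead of the
#'   hypomethylation direction.
#' @return A list: `cpgs` (data.frame with `chrom`, `pos`, `mean_normal`,
#'   `mean_mm`, `delta`, `hypo_in_mm`) and `fraction` (share of analyzed
#'   CpGs flagged).
#' @export
cpg_differential <- function(hits, meth_mm, meth_normal, motif_flank = 10L,
                             delta_threshold = 0.25, min_cov = 5L,
                             signed = TRUE) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      mean_normal = numeric(0), mean_mm = numeric(0),
                      delta = numeric(0), hypo_in_mm = logical(0))
  if (!length(hits)) {
    warning("no motif hits supplied")
    return(list(cpgs = empty, fraction = NA_real_))
  }
  windows <- GenomicRanges::reduce(hits + motif_flank, ignore.strand = TRUE)
  mm <- .group_cpg_means(meth_mm, windows, min_cov)
  nr <- .group_cpg_means(meth_normal, windows, min_cov)
  merged <- merge(nr, mm, by = c("chrom", "pos"),
                  suffixes = c("_normal", "_mm"))
  if (!nrow(merged)) {
    warning("no covered CpGs near any motif hit")
    return(list(cpgs = empty, fraction = NA_real_))
  }
  delta <- merged$mean_beta_mm - merged$mean_beta_normal
  flag <- if (signed) delta < -delta_threshold else
    abs(delta) > delta_threshold
  cpgs <- data.frame(chrom = merged$chrom, pos = merged$pos,
                     mean_normal = merged$mean_beta_normal,
                     mean_mm = merged$mean_beta_mm,
                     delta = delta, hypo_in_mm = flag)
  list(cpgs = cpgs, fraction = mean(flag))
}

#' Composite methylation profile around motif centers
#'
#' Every CpG within `flank` bp of a motif-hit center contributes its
#' group-mean beta to the bin of its offset (bins of `bin_bp` bp; bin
#' starts are offsets relative to the center, the center bin starting at
#' offset 0). Bins receiving fewer than `min_cpg` CpG contributions are
#' reported as NA.
#'
#' @inheritParams cpg_differential
#' @param flank Profile half-width in bp (default 2000).
#' @param bin_bp Bin width in bp (default 50).
#' @param min_cpg Minimum CpG contributions per bin (default 3).
#' @return A `data.frame` with `bin_start` (offset of the bin's left edge
#'   from the motif center), `group` ("normal"/"MM"), `mean_beta`, `n_cpg`.
#' @export
composite_profile <- function(hits, meth_mm, meth_normal, flank = 2000L,
                              bin_bp = 50L, min_cpg = 3L, min_cov = 5L) {
  if (!length(hits)) stop("need >= 1 motif hit")
  centers <- region_midpoints(GenomicRanges::granges(hits))
  wins <- centers + flank
  bin_starts <- seq(-flank, flank - 1L, by = bin_bp)
  one_group <- function(meth_list, label) {
    cm <- .group_cpg_means(meth_list, GenomicRanges::reduce(wins), min_cov)
    stats_df <- data.frame(bin_start = bin_starts,
                           group = label,
                           mean_beta = NA_real_,
                           n_cpg = 0L)
    if (!nrow(cm)) return(stats_df)
    gr <- GenomicRanges::GRanges(cm$chrom,
                                 IRanges::IRanges(cm$pos + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr, wins, ignore.strand = TRUE)
    if (!length(ov)) return(stats_df)
    offs <- (cm$pos[S4Vectors::queryHits(ov)] + 1L) -
      GenomicRanges::start(centers)[S4Vectors::subjectHits(ov)]
    keep <- offs >= -flank & offs < flank
    offs <- offs[keep]
    betas <- cm$mean_beta[S4Vectors::queryHits(ov)][keep]
    bin <- floor(offs / bin_bp) * bin_bp
    agg_mean <- tapply(betas, bin, mean)
    agg_n <- tapply(betas, bin, length)
    at <- match(as.integer(names(agg_mean)), bin_starts)
    ok <- !is.na(at)
    stats_df$mean_beta[at[ok]] <- as.numeric(agg_mean)[ok]
    stats_df$n_cpg[at[ok]] <- as.integer(agg_n)[ok]
    stats_df$mean_beta[stats_df$n_cpg < min_cpg] <- NA_real_
    stats_df
  }
  rbind(one_group(meth_normal, "normal"), one_group(meth_mm, "MM"))
}
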