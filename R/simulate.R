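#' Synthetic multi-omics dataset with planted ground truth
#'
#' Emulates the statistical structure of a tumor-versus-normal multi-layer
#' epigenomics study: background peaks shared by all cell populations with
#' per-sample dropout and spurious calls, tumor-specific de novo activated
#' regions carrying H3K27ac/H3K4me1/ATAC peaks, superenhancer-like clusters
#' of nearby planted regions, TAD-confined target genes up-regulated in the
#' tumor, adjacent coexpressed gene pairs coupled through a latent factor,
#' motif instances with hypomethylated flanking CpGs, and large repressed
#' blocks losing DNA methylation tumor-wide. Every planted event is recorded
#' in a truth manifest used as the oracle by the test-suite.
#'
#' @name synthetic-data
NULL

# Consensus "TTTCGCGAAA": an IRF-family-like 10-mer carrying two CpGs
# (0-based offsets 3 and 5) so motif-anchored methylation is testable.
.default_pwm <- function() {
  consensus <- c("T", "T", "T", "C", "G", "C", "G", "A", "A", "A")
  prob <- matrix(0.02, nrow = 4, ncol = length(consensus),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(consensus)) prob[consensus[k], k] <- 0.94
  list(id = "IRF_like", prob = prob,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the simulated study: a 2 x 10 Mb genome, 300 genes in
#' ~100 kb TADs, 200 planted de novo activated regions (45 of them in 15
#' superenhancer-like clusters of three), 40 planted adjacent coexpressed
#' pairs plus one triplet generated at Pearson r = 0.7, 10 tumor and 2 x 6
#' normal ChIP/ATAC samples, 37 tumor RNA samples, peak dropout 0.1 and
#' spurious-peak rate 0.05, motif-flank CpGs at mean beta 0.85 (normal)
#' versus 0.30 (tumor), and 10 repressed blocks with tumor-wide methylation
#' loss.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param ... Named overrides of any default listed above (see the returned
#'   list for field names).
#' @return A validated config list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = c(chr1 = 10e6, chr2 = 10e6),
    n_genes = 300L,
    tad_mean_bp = 80e3, tad_sd_bp = 15e3, tad_gap_bp = 5e3,
    n_denovo = 200L,
    n_se_clusters = 15L, se_cluster_size = 3L,
    n_pairs = 40L, n_triplets = 1L, pair_r = 0.7,
    n_mm_chip = 10L, n_rep_normal = 2L,
    n_mm_rna = 37L, n_rep_rna = 3L,
    n_mm_wgbs = 3L, n_rep_wgbs = 1L,
    n_bg_peaks = 250L, n_loss_peaks = 25L,
    dropout = 0.1, spurious_rate = 0.05,
    mm_presence = 0.9, mm_min_presence = 0.8,
    n_repressed_blocks = 10L, repressed_block_bp = 150e3,
    expr_base_mean = 100, expr_cv = 0.2, target_fc = 4,
    cpg_spacing_bp = 500L, coverage_mean = 25, low_cov_frac = 0.05,
    beta_background = 0.80,
    beta_motif_normal = 0.85, beta_motif_mm = 0.30,
    beta_block_normal = 0.80, beta_block_mm = 0.50,
    beta_concentration = 50,
    pwm = .default_pwm()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  counts <- c("n_genes", "n_denovo", "n_se_clusters", "n_pairs", "n_triplets",
              "n_mm_chip", "n_rep_normal", "n_mm_rna", "n_rep_rna",
              "n_mm_wgbs", "n_rep_wgbs", "n_bg_peaks", "n_loss_peaks",
              "n_repressed_blocks")
  for (f in counts) if (cfg[[f]] < 0) stop("'", f, "' must be >= 0")
  rates <- c("dropout", "spurious_rate", "mm_presence", "mm_min_presence",
             "low_cov_frac")
  for (f in rates) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop("'", f, "' must lie in [0, 1]")
  if (abs(cfg$pair_r) >= 1) stop("'pair_r' must lie in (-1, 1)")
  structure(cfg, class = "synth_config")
}

# Uniformly draw n intervals of the given widths on the genome, rejecting
# (and redrawing) any that touch 'forbidden'. Returns a GRanges (1-based).
.draw_intervals <- function(n, widths, genome, forbidden = NULL,
                            max_tries = 50L) {
  if (n == 0) return(GenomicRanges::GRanges())
  w <- rep_len(as.integer(unlist(widths)), n)
  chrom_p <- genome / sum(genome)
  res_chr <- character(n); res_start <- integer(n)
  todo <- seq_len(n)
  for (try in seq_len(max_tries)) {
    chr <- sample(names(genome), length(todo), replace = TRUE,
                  prob = chrom_p)
    s <- 1L + as.integer(floor(stats::runif(length(todo)) *
                                 (genome[chr] - w[todo] - 1L)))
    cand <- GenomicRanges::GRanges(factor(chr, levels = names(genome)),
                                   IRanges::IRanges(s, width = w[todo]))
    bad <- if (is.null(forbidden)) rep(FALSE, length(todo)) else
      IRanges::overlapsAny(cand, forbidden, ignore.strand = TRUE)
    res_chr[todo[!bad]] <- chr[!bad]
    res_start[todo[!bad]] <- s[!bad]
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not place ", length(todo), " interval(s) away from ",
         "planted regions; the genome is too small for the requested ",
         "feature load")
  GenomicRanges::GRanges(factor(res_chr, levels = names(genome)),
                         IRanges::IRanges(res_start, width = w))
}

# Jitter interval boundaries by +/- amp bp, keeping width >= 100 and
# coordinates >= 1.
.jitter_intervals <- function(gr, amp = 50L) {
  if (!length(gr)) return(gr)
  s <- pmax(1L, GenomicRanges::start(gr) +
              sample(seq(-amp, amp), length(gr), replace = TRUE))
  e <- GenomicRanges::end(gr) +
    sample(seq(-amp, amp), length(gr), replace = TRUE)
  e <- pmax(e, s + 99L)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(s, e))
}

.rbeta_mean <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Generate the synthetic dataset
#'
#' Writes a complete on-disk dataset under `out_dir` (sample sheet, per-sample
#' peak BEDs for six marks plus ATAC, bedGraph H3K27ac signal for tumor
#' samples, per-sample CpG methylation TSVs, an expression matrix, gene
#' annotation, TADs, a MEME motif file, region FASTA, and `truth.json`) and
#' returns the truth manifest. Generation is fully deterministic given
#' `config$seed`. Planted de novo regions are guaranteed (and re-checked
#' post hoc) never to overlap any normal-sample peak of any assay.
#'
#' @param config A [synth_config()] list.
#' @param out_dir Output directory (created if missing).
#' @return The truth manifest (invisibly the same content as `truth.json`);
#'   see [read_truth_manifest()] for its structure.
#' @export
simulate_dataset <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("peaks", "signal", "methylation"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  genome <- cfg$genome

  ## ---- TADs ------------------------------------------------------------
  tads <- list()
  for (chr in names(genome)) {
    pos <- 1
    while (pos + 5.5e4 < genome[[chr]]) {
      w <- max(5.5e4, round(stats::rnorm(1, cfg$tad_mean_bp, cfg$tad_sd_bp)))
      if (pos + w > genome[[chr]]) break
      tads[[length(tads) + 1L]] <-
        GenomicRanges::GRanges(factor(chr, levels = names(genome)),
                               IRanges::IRanges(pos, pos + w - 1))
      pos <- pos + w + cfg$tad_gap_bp
    }
  }
  tads <- do.call(c, tads)
  tads$tad_id <- sprintf("tad_%d", seq_along(tads))

  ## ---- genes, placed TAD by TAD so within-TAD genes are adjacent -------
  n_per_tad <- sample(0:3, length(tads), replace = TRUE,
                      prob = c(0.10, 0.45, 0.35, 0.10))
  genes <- list(); gi <- 0L
  gene_cursor_end <- numeric(length(tads))  # last used base per TAD
  for (t in seq_along(tads)) {
    cursor <- GenomicRanges::start(tads)[t] + 2000
    placed <- 0L
    while (placed < n_per_tad[t] && gi < cfg$n_genes) {
      w <- round(stats::runif(1, 5e3, 15e3))
      if (cursor + w > GenomicRanges::end(tads)[t] - 22e3) break
      gi <- gi + 1L; placed <- placed + 1L
      genes[[gi]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi),
        gene_name = sprintf("GENE%d", gi),
        chrom = as.character(GenomicRanges::seqnames(tads))[t],
        start = cursor, end = cursor + w - 1,
        strand = sample(c("+", "-"), 1),
        tad = t, stringsAsFactors = FALSE
      )
      cursor <- cursor + w + round(stats::runif(1, 8e3, 12e3))
    }
    gene_cursor_end[t] <- cursor
    n_per_tad[t] <- placed
  }
  genes <- do.call(rbind, genes)
  if (is.null(genes) || nrow(genes) < cfg$n_pairs * 2 + cfg$n_triplets * 3)
    stop("genome too small: could not place enough genes; ",
         "increase genome length or lower planted-feature counts")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  ## ---- assign planted structures to TADs -------------------------------
  tad_n <- tabulate(genes$tad, nbins = length(tads))
  t3 <- which(tad_n >= 3); t2 <- which(tad_n >= 2); t1 <- which(tad_n >= 1)
  triplet_tads <- utils::head(t3, cfg$n_triplets)
  pair_tads <- utils::head(setdiff(t2, triplet_tads), cfg$n_pairs)
  used <- c(triplet_tads, pair_tads)
  cluster_tads <- utils::head(setdiff(which(tad_n == 1), used),
                              cfg$n_se_clusters)
  used <- c(used, cluster_tads)
  n_group_regions <- length(triplet_tads) + length(pair_tads)
  n_cluster_regions <- length(cluster_tads) * cfg$se_cluster_size
  n_single <- cfg$n_denovo - n_group_regions - n_cluster_regions
  if (n_single < 0) stop("'n_denovo' too small for the requested clusters ",
                         "and coexpression groups")
  single_tads <- utils::head(setdiff(t1, used), n_single)
  if (length(triplet_tads) < cfg$n_triplets ||
      length(pair_tads) < cfg$n_pairs ||
      length(cluster_tads) < cfg$n_se_clusters ||
      length(single_tads) < n_single)
    stop("genome too small: need at least ",
         cfg$n_triplets + cfg$n_pairs + cfg$n_se_clusters + n_single,
         " gene-bearing TADs for the requested planted features; ",
         "increase genome length")

  place_regions <- function(t, k) {
    # k regions after the gene block of TAD t, spaced 2-6 kb apart
    lo <- gene_cursor_end[t] + 3000
    hi <- GenomicRanges::end(tads)[t] - 500
    out <- vector("list", k); pos <- lo
    for (i in seq_len(k)) {
      w <- round(stats::runif(1, 800, 1500))
      if (pos + w > hi)
        stop("genome too small: TAD ", tads$tad_id[t],
             " cannot host ", k, " planted region(s); increase tad_mean_bp")
      out[[i]] <- GenomicRanges::GRanges(
        factor(as.character(GenomicRanges::seqnames(tads))[t],
               levels = names(genome)),
        IRanges::IRanges(pos, pos + w - 1))
      pos <- pos + w + round(stats::runif(1, 2e3, 6e3))
    }
    do.call(c, out)
  }

  denovo <- GenomicRanges::GRanges()
  denovo_meta <- list()
  add_regions <- function(t, k, targets, cluster_id) {
    gr <- place_regions(t, k)
    for (i in seq_along(gr))
      denovo_meta[[length(denovo_meta) + 1L]] <<- list(
        targets = targets, cluster = cluster_id, tad = t)
    denovo <<- c(denovo, gr)
  }
  group_genes <- list()
  for (t in triplet_tads) {
    g <- genes$gene_id[genes$tad == t][1:3]
    group_genes[[length(group_genes) + 1L]] <- g
    add_regions(t, 1L, g, NA_integer_)
  }
  for (t in pair_tads) {
    g <- genes$gene_id[genes$tad == t][1:2]
    group_genes[[length(group_genes) + 1L]] <- g
    add_regions(t, 1L, g, NA_integer_)
  }
  for (ci in seq_along(cluster_tads)) {
    t <- cluster_tads[ci]
    g <- genes$gene_id[genes$tad == t][1]
    add_regions(t, cfg$se_cluster_size, g, ci)
  }
  for (t in single_tads) {
    g <- genes$gene_id[genes$tad == t][1]
    add_regions(t, 1L, g, NA_integer_)
  }
  if (length(denovo)) {
    denovo$region_id <- sprintf("denovo_%03d", seq_along(denovo))
    denovo$cluster <- vapply(denovo_meta, function(x)
      as.integer(x$cluster), integer(1))
    denovo$targets <- vapply(denovo_meta, function(x)
      paste(x$targets, collapse = ","), character(1))
  }
  target_gene_ids <- unique(unlist(lapply(denovo_meta, `[[`, "targets")))

  ## ---- background peak architecture ------------------------------------
  forbidden <- if (length(denovo))
    GenomicRanges::reduce(denovo + 2000) else NULL
  tss_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = names(genome)),
    IRanges::IRanges(genes$tss - 999, genes$tss + 1000))
  narrow <- c("H3K27ac", "H3K4me1", "H3K4me3", "ATAC")
  bg_peaks <- list(); loss_idx <- list()
  for (a in c(.HISTONE_MARKS, "ATAC")) {
    wmean <- if (a %in% narrow) 1500 else 8000
    ws <- pmax(300, round(stats::rnorm(cfg$n_bg_peaks, wmean, wmean / 5)))
    bg_peaks[[a]] <- .draw_intervals(cfg$n_bg_peaks, as.list(ws), genome,
                                     forbidden)
    loss_idx[[a]] <- utils::head(sample.int(cfg$n_bg_peaks),
                                 cfg$n_loss_peaks)
  }
  block_mark <- rep(c("H3K27me3", "H3K9me3"),
                    length.out = cfg$n_repressed_blocks)
  blocks <- .draw_intervals(
    cfg$n_repressed_blocks,
    as.list(rep(cfg$repressed_block_bp, max(1, cfg$n_repressed_blocks))),
    genome, forbidden)
  if (length(blocks)) blocks$mark <- block_mark

  ## ---- per-region tumor presence (shared by H3K27ac/H3K4me1/ATAC) ------
  n_mm <- cfg$n_mm_chip
  presence <- matrix(FALSE, nrow = length(denovo), ncol = n_mm)
  if (length(denovo)) {
    need <- ceiling(cfg$mm_min_presence * n_mm)
    for (i in seq_len(length(denovo))) {
      pres <- stats::runif(n_mm) < cfg$mm_presence
      while (sum(pres) < need) pres[sample(which(!pres), 1)] <- TRUE
      presence[i, ] <- pres
    }
  }

  ## ---- sample layout ---------------------------------------------------
  norm_pops <- .BASELINE_POPULATIONS
  chip_samples <- list()
  for (p in norm_pops) for (r in seq_len(cfg$n_rep_normal))
    chip_samples[[length(chip_samples) + 1L]] <-
      list(id = sprintf("%s_%d", p, r), pop = p,
           assays = c(.HISTONE_MARKS, "ATAC"))
  for (r in seq_len(cfg$n_rep_normal))
    chip_samples[[length(chip_samples) + 1L]] <-
      list(id = sprintf("bm-PC_%d", r), pop = "bm-PC", assays = "H3K27ac")
  mm_ids <- sprintf("MM_%02d", seq_len(n_mm))
  for (i in seq_len(n_mm))
    chip_samples[[length(chip_samples) + 1L]] <-
      list(id = mm_ids[i], pop = "MM", assays = c(.HISTONE_MARKS, "ATAC"))

  ## ---- realize and write per-sample peaks ------------------------------
  sheet <- list()
  add_sheet <- function(id, pop, assay, path)
    sheet[[length(sheet) + 1L]] <<- data.frame(
      sample_id = id, population = pop, assay = assay, path = path,
      stringsAsFactors = FALSE)

  realize_peaks <- function(assay, is_mm, mm_index) {
    keep_bg <- stats::runif(cfg$n_bg_peaks) >= cfg$dropout
    is_loss <- seq_len(cfg$n_bg_peaks) %in% loss_idx[[assay]]
    if (is_mm)  # loss peaks nearly vanish in tumor samples
      keep_bg[is_loss] <- stats::runif(sum(is_loss)) < cfg$spurious_rate
    parts <- list(bg_peaks[[assay]][keep_bg])
    if (assay %in% c("H3K4me3", "H3K27ac", "ATAC")) {
      keep_pr <- stats::runif(length(tss_gr)) >= cfg$dropout
      parts <- c(parts, list(tss_gr[keep_pr]))
    }
    if (assay %in% c("H3K27me3", "H3K9me3") && length(blocks)) {
      bl <- blocks[blocks$mark == assay]
      parts <- c(parts, list(GenomicRanges::granges(bl)))
    }
    if (is_mm && assay %in% c("H3K27ac", "H3K4me1", "ATAC") &&
        length(denovo)) {
      pres <- presence[, mm_index]
      parts <- c(parts, list(GenomicRanges::granges(denovo[pres])))
    }
    n_spur <- stats::rbinom(1, cfg$n_bg_peaks, cfg$spurious_rate)
    if (n_spur > 0) {
      ws <- pmax(300, round(stats::rnorm(n_spur, 1200, 250)))
      parts <- c(parts, list(.draw_intervals(n_spur, as.list(ws), genome,
                                             forbidden)))
    }
    gr <- .jitter_intervals(do.call(c, lapply(parts, GenomicRanges::granges)))
    gr <- .unstrand_sort(gr)
    gr$score <- round(stats::runif(length(gr), 5, 50), 1)
    gr
  }

  mm_peak_cache <- list()  # H3K27ac tumor peaks reused for signal tracks
  for (s in chip_samples) {
    is_mm <- s$pop == "MM"
    mm_index <- if (is_mm) match(s$id, mm_ids) else NA_integer_
    for (a in s$assays) {
      gr <- realize_peaks(a, is_mm, mm_index)
      rel <- file.path("peaks", sprintf("%s_%s.bed", s$id, a))
      write_bed(gr, file.path(out_dir, rel))
      add_sheet(s$id, s$pop, a, rel)
      if (is_mm && a == "H3K27ac") mm_peak_cache[[s$id]] <- gr
    }
  }

  ## ---- H3K27ac signal tracks for tumor samples -------------------------
  # Step value classes: superenhancer-cluster constituents >> planted
  # singletons > promoters > background.
  for (id in names(mm_peak_cache)) {
    pk <- GenomicRanges::reduce(mm_peak_cache[[id]])
    val <- pmax(0.5, stats::rnorm(length(pk), 5, 1))
    if (length(denovo)) {
      in_cl <- !is.na(denovo$cluster)
      hit_single <- IRanges::overlapsAny(pk, denovo[!in_cl])
      hit_cluster <- IRanges::overlapsAny(pk, denovo[in_cl])
      val[hit_single] <- pmax(1, stats::rnorm(sum(hit_single), 8, 1))
      val[hit_cluster] <- pmax(5, stats::rnorm(sum(hit_cluster), 30, 3))
    }
    hit_prom <- IRanges::overlapsAny(pk, tss_gr)
    val[hit_prom & !IRanges::overlapsAny(pk, denovo)] <-
      pmax(1, stats::rnorm(sum(hit_prom &
        !IRanges::overlapsAny(pk, denovo)), 10, 2))
    pk$score <- round(val, 3)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
                     start = GenomicRanges::start(pk) - 1L,
                     end = GenomicRanges::end(pk), value = pk$score)
    utils::write.table(df, file.path(out_dir, "signal",
                                     sprintf("%s_H3K27ac.bedGraph", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  ## ---- motifs, region sequences, planted CpGs --------------------------
  pwm <- cfg$pwm
  write_meme_pwm(stats::setNames(list(pwm), pwm$id),
                 file.path(out_dir, "motifs.meme"))
  consensus <- rownames(pwm$prob)[apply(pwm$prob, 2, which.max)]
  motif_w <- ncol(pwm$prob)
  cpg_off <- which(consensus == "C" & c(consensus[-1], "") == "G") - 1L
  seqs <- character(length(denovo)); seq_names <- character(length(denovo))
  motif_start0 <- integer(length(denovo))  # 0-based genomic motif starts
  hypo_pos <- list()
  for (i in seq_along(denovo)) {
    w <- GenomicRanges::width(denovo)[i]
    letters <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    off <- w %/% 2L - motif_w %/% 2L  # 0-based offset of motif in sequence
    letters[(off + 1):(off + motif_w)] <- consensus
    seqs[i] <- paste(letters, collapse = "")
    seq_names[i] <- sprintf("%s:%d-%d",
                            as.character(GenomicRanges::seqnames(denovo))[i],
                            GenomicRanges::start(denovo)[i],
                            GenomicRanges::end(denovo)[i])
    m0 <- (GenomicRanges::start(denovo)[i] - 1L) + off
    motif_start0[i] <- m0
    hypo_pos[[i]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(denovo))[i],
      pos = c(m0 + cpg_off, m0 - 7L))  # in-motif CpGs plus one flank CpG
  }
  if (length(denovo)) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- seq_names
    Biostrings::writeXStringSet(ss, file.path(out_dir, "regions.fa"))
  }
  hypo_pos <- if (length(hypo_pos)) do.call(rbind, hypo_pos) else
    data.frame(chrom = character(0), pos = integer(0))

  ## ---- methylation tables ----------------------------------------------
  n_cpg_chr <- pmax(round(genome / cfg$cpg_spacing_bp), 1L)
  cpg <- do.call(rbind, lapply(names(genome), function(chr) data.frame(
    chrom = chr,
    pos = sort(sample.int(genome[[chr]] - 2L, n_cpg_chr[[chr]])))))
  cpg <- unique(rbind(cpg, hypo_pos))
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  cpg_gr <- GenomicRanges::GRanges(cpg$chrom,
                                   IRanges::IRanges(cpg$pos + 1L, width = 1))
  near_motif <- rep(FALSE, nrow(cpg))
  if (length(denovo)) {
    motif_gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(denovo)),
      IRanges::IRanges(motif_start0 + 1L, width = motif_w))
    near_motif <- IRanges::overlapsAny(cpg_gr, motif_gr + 10L)
  }
  in_block <- if (length(blocks))
    IRanges::overlapsAny(cpg_gr, blocks) else rep(FALSE, nrow(cpg))
  mean_for <- function(group) {
    m <- rep(cfg$beta_background, nrow(cpg))
    m[in_block] <- if (group == "MM") cfg$beta_block_mm else
      cfg$beta_block_normal
    m[near_motif] <- if (group == "MM") cfg$beta_motif_mm else
      cfg$beta_motif_normal
    m
  }
  wn_pops <- rep(norm_pops, each = cfg$n_rep_wgbs)
  wn_ids <- sprintf("%s_W%d", wn_pops,
                    rep(seq_len(cfg$n_rep_wgbs), times = length(norm_pops)))
  wgbs_samples <- c(stats::setNames(wn_pops, wn_ids),
                    stats::setNames(rep("MM", cfg$n_mm_wgbs),
                                    sprintf("MM_W%02d", seq_len(cfg$n_mm_wgbs))))
  for (sid in names(wgbs_samples)) {
    pop <- wgbs_samples[[sid]]
    grp <- if (pop == "MM") "MM" else "normal"
    beta <- .rbeta_mean(nrow(cpg), mean_for(grp), cfg$beta_concentration)
    covr <- stats::rpois(nrow(cpg), cfg$coverage_mean)
    low <- stats::runif(nrow(cpg)) < cfg$low_cov_frac
    covr[low] <- stats::rpois(sum(low), 3)
    mt <- data.table::data.table(chrom = cpg$chrom, pos = cpg$pos,
                                 beta = round(beta, 4), coverage = covr)
    rel <- file.path("methylation", paste0(sid, ".tsv"))
    data.table::fwrite(mt, file.path(out_dir, rel), sep = "\t")
    add_sheet(sid, pop, "WGBS", rel)
  }

  ## ---- expression matrix ------------------------------------------------
  rna_ids <- character(0); rna_pops <- character(0)
  for (p in c(norm_pops, "bm-PC")) {
    ids <- sprintf("%s_R%d", p, seq_len(cfg$n_rep_rna))
    rna_ids <- c(rna_ids, ids); rna_pops <- c(rna_pops, rep(p, length(ids)))
  }
  mm_rna_ids <- sprintf("MM_R%02d", seq_len(cfg$n_mm_rna))
  rna_ids <- c(rna_ids, mm_rna_ids)
  rna_pops <- c(rna_pops, rep("MM", cfg$n_mm_rna))
  mu <- stats::rlnorm(nrow(genes), log(cfg$expr_base_mean), 0.5)
  names(mu) <- genes$gene_id
  sigma <- cfg$expr_cv
  is_target <- genes$gene_id %in% target_gene_ids
  expr <- matrix(0, nrow = nrow(genes), ncol = length(rna_ids),
                 dimnames = list(genes$gene_id, rna_ids))
  mm_cols <- rna_pops == "MM"
  noise <- matrix(stats::rnorm(nrow(genes) * length(rna_ids), 0, 1),
                  nrow = nrow(genes))
  # latent factors couple coexpression-group genes across tumor samples
  if (length(group_genes)) {
    r <- cfg$pair_r
    for (g in group_genes) {
      z <- stats::rnorm(sum(mm_cols))
      rows <- match(g, genes$gene_id)
      for (ri in rows)
        noise[ri, mm_cols] <- sqrt(r) * z + sqrt(1 - r) * noise[ri, mm_cols]
    }
  }
  for (j in seq_along(rna_ids)) {
    base <- mu
    if (mm_cols[j]) base[is_target] <- base[is_target] * cfg$target_fc
    expr[, j] <- base * exp(sigma * noise[, j])
  }
  expr_df <- data.frame(gene_id = rownames(expr), round(expr, 3),
                        check.names = FALSE)
  utils::write.table(expr_df, file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(rna_ids))
    add_sheet(rna_ids[k], rna_pops[k], "RNA", "expression.tsv")

  ## ---- annotation, TADs, sample sheet ----------------------------------
  gene_out <- data.frame(gene_id = genes$gene_id, gene_name = genes$gene_name,
                         chrom = genes$chrom, start = genes$start - 1L,
                         end = genes$end, strand = genes$strand)
  utils::write.table(gene_out, file.path(out_dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(GenomicRanges::granges(tads), file.path(out_dir, "tads.bed"))
  sheet <- do.call(rbind, sheet)
  utils::write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- hard audit: planted regions never overlap normal peaks ----------
  if (length(denovo)) {
    norm_rows <- sheet[sheet$population != "MM" &
                         sheet$assay %in% c(.HISTONE_MARKS, "ATAC"), ]
    for (pth in norm_rows$path) {
      pk <- read_bed(file.path(out_dir, pth))
      if (any(IRanges::overlapsAny(denovo, pk)))
        stop("internal error: planted region overlaps a normal-sample peak")
    }
  }

  ## ---- truth manifest ---------------------------------------------------
  manifest <- list(
    genome = as.list(genome),
    planted_denovo = if (length(denovo)) data.frame(
      chrom = as.character(GenomicRanges::seqnames(denovo)),
      start = GenomicRanges::start(denovo) - 1L,
      end = GenomicRanges::end(denovo),
      region_id = denovo$region_id,
      cluster = denovo$cluster,
      target_genes = denovo$targets
    ) else NULL,
    planted_pairs = lapply(group_genes, function(g)
      list(genes = g, r = cfg$pair_r)),
    planted_hypo_cpgs = if (nrow(hypo_pos)) data.frame(
      chrom = hypo_pos$chrom, pos = hypo_pos$pos,
      beta_normal = cfg$beta_motif_normal, beta_mm = cfg$beta_motif_mm
    ) else NULL,
    planted_blocks = if (length(blocks)) data.frame(
      chrom = as.character(GenomicRanges::seqnames(blocks)),
      start = GenomicRanges::start(blocks) - 1L,
      end = GenomicRanges::end(blocks), mark = blocks$mark
    ) else NULL,
    planted_state_changes = if (length(denovo)) data.frame(
      region_id = denovo$region_id,
      state_normal = "LowSignal", state_mm = "ActiveEnh"
    ) else NULL,
    config = cfg[setdiff(names(cfg), "pwm")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a truth manifest written by [simulate_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return A list with `planted_denovo` (a `GRanges` with `region_id`,
#'   `cluster`, `target_genes`), `planted_pairs` (list of gene-id groups
#'   with generating `r`), `planted_hypo_cpgs`, `planted_blocks` (a
#'   `GRanges` with `mark`), `planted_state_changes`, and the generator
#'   `config` echo.
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  cols <- function(rows, field, cast = as.character)
    cast(unlist(lapply(rows, function(r)
      if (is.null(r[[field]])) NA else r[[field]])))
  out <- list(config = m$config)
  out$planted_pairs <- lapply(m$planted_pairs, function(g)
    list(genes = unlist(g$genes), r = g$r))
  if (length(m$planted_denovo)) {
    d <- m$planted_denovo
    gr <- GenomicRanges::GRanges(
      cols(d, "chrom"),
      IRanges::IRanges(cols(d, "start", as.integer) + 1L,
                       cols(d, "end", as.integer)))
    gr$region_id <- cols(d, "region_id")
    gr$cluster <- cols(d, "cluster", as.integer)
    gr$target_genes <- strsplit(cols(d, "target_genes"), ",")
    out$planted_denovo <- gr
  } else out$planted_denovo <- GenomicRanges::GRanges()
  if (length(m$planted_blocks)) {
    b <- m$planted_blocks
    gr <- GenomicRanges::GRanges(
      cols(b, "chrom"),
      IRanges::IRanges(cols(b, "start", as.integer) + 1L,
                       cols(b, "end", as.integer)))
    gr$mark <- cols(b, "mark")
    out$planted_blocks <- gr
  } else out$planted_blocks <- GenomicRanges::GRanges()
  out$planted_hypo_cpgs <- if (length(m$planted_hypo_cpgs)) data.frame(
    chrom = cols(m$planted_hypo_cpgs, "chrom"),
    pos = cols(m$planted_hypo_cpgs, "pos", as.integer),
    beta_normal = cols(m$planted_hypo_cpgs, "beta_normal", as.numeric),
    beta_mm = cols(m$planted_hypo_cpgs, "beta_mm", as.numeric)) else NULL
  out$planted_state_changes <- if (length(m$planted_state_changes))
    data.frame(
      region_id = cols(m$planted_state_changes, "region_id"),
      state_normal = cols(m$planted_state_changes, "state_normal"),
      state_mm = cols(m$planted_state_changes, "state_mm")) else NULL
  out
}
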