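#' End-to-end pipeline orchestration
#'
#' Runs the stages in order -- differential chromatin, chromatin states,
#' de novo activation and superenhancers, target linking and coregulated
#' groups, motif-anchored methylation -- from one config, writes per-stage
#' tables plus a machine-readable JSON report, and cross-checks the
#' report's counts against the emitted files.
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' `data_dir` must follow the layout written by [simulate_dataset()]
#' (sample sheet `samples.tsv`, `genes.tsv`, `tads.bed`, `motifs.meme`,
#' `regions.fa`, `expression.tsv`, `signal/`, `peaks/`, `methylation/`).
#' Individual paths and every stage threshold can be overridden through
#' `...`; unknown keys are rejected.
#'
#' @param data_dir Input dataset directory.
#' @param out_dir Output directory for stage tables and the report.
#' @param ... Named overrides of paths, thresholds or stage flags (see the
#'   returned list).
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir, ...) {
  cfg <- list(
    sample_sheet = file.path(data_dir, "samples.tsv"),
    genes = file.path(data_dir, "genes.tsv"),
    tads = file.path(data_dir, "tads.bed"),
    motifs = file.path(data_dir, "motifs.meme"),
    region_fasta = file.path(data_dir, "regions.fa"),
    expression = file.path(data_dir, "expression.tsv"),
    signal_dir = file.path(data_dir, "signal"),
    out_dir = out_dir,
    chrom_prefix = NULL,
    min_frac = 0.5, min_mm_frac = 0.66, min_region_bp = 200L,
    stitch_distance = 12500L, tss_exclusion = 2000L,
    fdr = 0.05, fc = 1.5,
    r_min = 0.5, p_max = 0.05,
    score_frac = 0.8, motif_flank = 10L, delta_threshold = 0.25,
    profile_flank = 2000L, bin_bp = 50L, min_cpg = 3L, min_cov = 5L,
    fallback_window = 1e6, min_bp = 1L,
    require_bmpc = TRUE, signed_delta = TRUE,
    run_states = TRUE, run_denovo = TRUE, run_linking = TRUE,
    run_methylation = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$min_frac <= 0 || cfg$min_frac > 1 ||
      cfg$min_mm_frac <= 0 || cfg$min_mm_frac > 1)
    stop("consensus/recurrence fractions must lie in (0, 1]")
  if (cfg$fdr <= 0 || cfg$fdr >= 1 || cfg$fc <= 1)
    stop("'fdr' must be in (0, 1) and 'fc' > 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML must contain `data_dir` and `out_dir`; any other key overrides
#' the corresponding [pipeline_config()] default, and unknown keys are
#' rejected.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$data_dir) || is.null(y$out_dir))
    stop("config must name 'data_dir' and 'out_dir'")
  extra <- y[setdiff(names(y), c("data_dir", "out_dir"))]
  do.call(pipeline_config, c(list(data_dir = y$data_dir,
                                  out_dir = y$out_dir), extra))
}

# Write a GRanges as BED5 plus a companion TSV of its metadata columns.
.write_region_outputs <- function(gr, stem, out_dir) {
  bed <- GenomicRanges::granges(gr)
  bed$score <- rep(0, length(gr))
  if (!is.null(gr$region_id)) bed$name <- gr$region_id
  write_bed(bed, file.path(out_dir, paste0(stem, ".bed")))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  md <- as.data.frame(S4Vectors::mcols(gr))
  for (j in seq_along(md)) if (is.list(md[[j]]))
    md[[j]] <- vapply(md[[j]], paste, character(1), collapse = ",")
  df <- cbind(df, md)
  utils::write.table(df, file.path(out_dir, paste0(stem, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Run the full pipeline
#'
#' Executes every enabled stage in dependency order and writes, under
#' `config$out_dir`: per-mark differential region BED/TSV pairs, the
#' chromatin-state transition matrix, the de novo region table, the
#' superenhancer table, target links, coregulated groups, the motif-CpG
#' differential table, the composite methylation profile, and
#' `report.json`. Identical inputs and config yield identical outputs.
#'
#' @param config A [pipeline_config()] list.
#' @return An object of class `chromactiv_run`: a list with the per-stage
#'   results (`differential`, `states`, `denovo`, `superenhancers`,
#'   `links`, `groups`, `methylation`) and the `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  genes <- read_gene_annotation(cfg$genes)
  tads <- read_tads(cfg$tads, chrom_prefix = cfg$chrom_prefix)
  expr <- read_expression(cfg$expression)
  if (!any(sheet$population == "MM"))
    stop("validation error: the sample sheet contains no MM samples")

  marks <- c(.HISTONE_MARKS, "ATAC")
  peaks <- list()  # peaks[[assay]][[sample_id]]
  for (a in marks) {
    rows <- .sheet_rows(sheet, .CELL_POPULATIONS, a)
    peaks[[a]] <- .read_peak_list(rows, cfg$chrom_prefix)
  }
  pop_of <- function(ids) sheet$population[match(ids, sheet$sample_id)]

  ## ---- stage 1: differential chromatin ---------------------------------
  meth_rows <- .sheet_rows(sheet, .CELL_POPULATIONS, "WGBS")
  meth <- lapply(meth_rows$path, read_methylation)
  names(meth) <- meth_rows$sample_id
  meth_mm <- meth[meth_rows$population == "MM"]
  meth_normal <- meth[meth_rows$population != "MM"]
  rna <- .sheet_rows(sheet, .CELL_POPULATIONS, "RNA")
  rna <- rna[rna$sample_id %in% colnames(expr), ]
  mm_rna <- rna$sample_id[rna$population == "MM"]
  norm_rna <- rna$sample_id[rna$population != "MM"]
  de_pooled <- de_call(expr, norm_rna, mm_rna, fdr = cfg$fdr, fc = cfg$fc)

  differential <- list()
  baselines <- list()
  for (a in marks) {
    ids <- names(peaks[[a]])
    pops <- pop_of(ids)
    cons <- lapply(.BASELINE_POPULATIONS, function(p) {
      sel <- peaks[[a]][pops == p]
      if (!length(sel)) return(NULL)
      build_consensus(sel, min_frac = cfg$min_frac)
    })
    names(cons) <- .BASELINE_POPULATIONS
    mm_pk <- peaks[[a]][pops == "MM"]
    if (!length(mm_pk)) stop("no MM samples for assay ", a)
    dc <- call_differential(a, cons, mm_pk, min_mm_frac = cfg$min_mm_frac,
                            min_region_bp = cfg$min_region_bp)
    atac_ids <- names(peaks[["ATAC"]])
    atac_pops <- pop_of(atac_ids)
    for (dir in c("gain", "loss")) {
      dc[[dir]] <- annotate_differential(
        dc[[dir]],
        atac_mm = peaks[["ATAC"]][atac_pops == "MM"],
        atac_normal = peaks[["ATAC"]][atac_pops != "MM"],
        meth_mm = meth_mm, meth_normal = meth_normal,
        genes = genes, de = de_pooled,
        min_bp = cfg$min_bp, min_cov = cfg$min_cov)
      .write_region_outputs(dc[[dir]],
                            sprintf("differential_%s_%s", a, dir),
                            cfg$out_dir)
    }
    differential[[a]] <- dc[c("gain", "loss")]
    baselines[[a]] <- dc$baseline
  }

  ## ---- stage 2: chromatin states on activation-mark gains --------------
  states <- NULL
  k27_gain <- differential[["H3K27ac"]]$gain
  if (cfg$run_states && length(k27_gain)) {
    full_ids <- Reduce(intersect, lapply(.HISTONE_MARKS, function(m)
      names(peaks[[m]])))
    full_pops <- pop_of(full_ids)
    state_mat <- vapply(full_ids, function(id) {
      mk <- lapply(.HISTONE_MARKS, function(m) peaks[[m]][[id]])
      names(mk) <- .HISTONE_MARKS
      assign_state(mark_presence(k27_gain, mk, min_bp = cfg$min_bp))
    }, character(length(k27_gain)))
    state_mat <- matrix(state_mat, nrow = length(k27_gain),
                        dimnames = list(NULL, full_ids))
    normal_states <- group_state(state_mat[, full_pops != "MM",
                                           drop = FALSE])
    mm_states <- group_state(state_mat[, full_pops == "MM", drop = FALSE])
    tm <- transition_matrix(normal_states, mm_states)
    states <- list(per_sample = state_mat, normal = normal_states,
                   mm = mm_states, transitions = tm)
    utils::write.table(
      data.frame(mm_state = rownames(tm), round(tm, 6),
                 check.names = FALSE),
      file.path(cfg$out_dir, "state_transitions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- stage 3: de novo activation and superenhancers ------------------
  denovo <- NULL; se <- NULL
  if (cfg$run_denovo) {
    k27_ids <- names(peaks[["H3K27ac"]])
    k27_pops <- pop_of(k27_ids)
    normal_k27 <- peaks[["H3K27ac"]][k27_pops != "MM"]
    mm_k27 <- peaks[["H3K27ac"]][k27_pops == "MM"]
    denovo <- select_de_novo(k27_gain, normal_k27,
                             k27_pops[k27_pops != "MM"],
                             mm_peaks = mm_k27,
                             require_bmpc = cfg$require_bmpc)
    mm_cons <- build_consensus(mm_k27, min_frac = cfg$min_frac)
    sig_files <- file.path(cfg$signal_dir,
                           sprintf("%s_H3K27ac.bedGraph", names(mm_k27)))
    sig_files <- sig_files[file.exists(sig_files)]
    if (!length(sig_files)) stop("no H3K27ac signal tracks found under ",
                                 cfg$signal_dir)
    tracks <- lapply(sig_files, read_bedgraph,
                     chrom_prefix = cfg$chrom_prefix)
    se <- stitch_superenhancers(mm_cons, tracks, genes,
                                stitch_distance = cfg$stitch_distance,
                                tss_exclusion = cfg$tss_exclusion)
    denovo <- assign_superenhancer(denovo, se)
    denovo <- intersect_atac(denovo, differential[["ATAC"]]$gain)
    if (audit_de_novo(denovo, normal_k27) > 0)
      stop("audit failure: a de novo region overlaps a normal peak")
    .write_region_outputs(denovo, "denovo_regions", cfg$out_dir)
    se_df <- .write_region_outputs(se, "superenhancers", cfg$out_dir)
  }

  ## ---- stage 4: target linking and coregulated groups ------------------
  links <- NULL; groups <- NULL; target_genes <- character(0)
  if (cfg$run_linking) {
    if (is.null(denovo))
      stop("target linking requires the de novo stage (run_denovo)")
    de_list <- lapply(split(norm_rna, rna$population[match(
      norm_rna, rna$sample_id)]), function(ids)
        de_call(expr, ids, mm_rna, fdr = cfg$fdr, fc = cfg$fc))
    links <- link_targets(denovo, tads, genes, de_list, fdr = cfg$fdr,
                          fc = cfg$fc, fallback_window = cfg$fallback_window)
    target_genes <- unique(links$gene_id)
    utils::write.table(links, file.path(cfg$out_dir, "target_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    groups <- find_coregulated(target_genes, genes,
                               expr[, mm_rna, drop = FALSE],
                               r_min = cfg$r_min, p_max = cfg$p_max)
    gdf <- if (length(groups)) data.frame(
      group_id = sprintf("group_%02d", seq_along(groups)),
      genes = vapply(groups, function(g) paste(g$genes, collapse = ","),
                     character(1)),
      n_genes = vapply(groups, function(g) length(g$genes), integer(1)),
      min_r = vapply(groups, function(g) min(g$r), numeric(1)),
      max_p = vapply(groups, function(g) max(g$p), numeric(1)),
      span_bp = vapply(groups, function(g) g$span_bp, numeric(1))
    ) else data.frame(group_id = character(0), genes = character(0),
                      n_genes = integer(0), min_r = numeric(0),
                      max_p = numeric(0), span_bp = numeric(0))
    utils::write.table(gdf, file.path(cfg$out_dir, "coregulated_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- stage 5: motif-anchored methylation -----------------------------
  methylation <- NULL
  if (cfg$run_methylation) {
    if (is.null(denovo))
      stop("the methylation stage requires the de novo stage (run_denovo)")
    pwms <- read_meme_pwm(cfg$motifs)
    seqs <- read_region_fasta(cfg$region_fasta)
    anchors <- .regions_from_names(names(seqs))
    seqs <- seqs[IRanges::overlapsAny(anchors, denovo,
                                            ignore.strand = TRUE)]
    hits <- do.call(c, unname(lapply(pwms, function(p)
      scan_pwm(seqs, p, score_frac = cfg$score_frac))))
    cd <- cpg_differential(hits, meth_mm, meth_normal,
                           motif_flank = cfg$motif_flank,
                           delta_threshold = cfg$delta_threshold,
                           min_cov = cfg$min_cov,
                           signed = cfg$signed_delta)
    prof <- composite_profile(hits, meth_mm, meth_normal,
                              flank = cfg$profile_flank,
                              bin_bp = cfg$bin_bp, min_cpg = cfg$min_cpg,
                              min_cov = cfg$min_cov)
    methylation <- list(hits = hits, cpgs = cd$cpgs,
                        fraction = cd$fraction, profile = prof)
    utils::write.table(cd$cpgs, file.path(cfg$out_dir, "motif_cpgs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof,
                       file.path(cfg$out_dir, "methylation_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- report -----------------------------------------------------------
  report <- list(
    differential_regions = lapply(differential, function(dc)
      list(gain = length(dc$gain), loss = length(dc$loss))),
    denovo_regions = if (!is.null(denovo)) length(denovo) else NA,
    superenhancers = if (!is.null(se))
      sum(se$is_super & GenomicRanges::countOverlaps(se, denovo) > 0)
      else NA,
    se_constituents = if (!is.null(denovo))
      sum(!is.na(denovo$se_id)) else NA,
    atac_gain_sites = if (!is.null(denovo)) sum(denovo$atac_gain) else NA,
    target_genes = if (!is.null(links)) length(target_genes) else NA,
    coexpression_groups = if (!is.null(groups)) length(groups) else NA,
    hypo_cpg_fraction = if (!is.null(methylation))
      methylation$fraction else NA,
    config = unclass(cfg)
  )
  # cross-file consistency audit
  if (!is.null(denovo)) {
    n_bed <- length(readLines(file.path(cfg$out_dir, "denovo_regions.bed")))
    if (n_bed != report$denovo_regions)
      stop("report/file mismatch for de novo regions")
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  structure(list(differential = differential, states = states,
                 denovo = denovo, superenhancers = se, links = links,
                 groups = groups, methylation = methylation,
                 de_pooled = de_pooled, report = report),
            class = "chromactiv_run")
}

#' @export
print.chromactiv_run <- function(x, ...) {
  r <- x$report
  cat("chromactiv pipeline run\n")
  for (a in names(r$differential_regions))
    cat(sprintf("  %-9s gain %4d  loss %4d\n", a,
                r$differential_regions[[a]]$gain,
                r$differential_regions[[a]]$loss))
  cat(sprintf("  de novo regions:      %s\n", r$denovo_regions))
  cat(sprintf("  superenhancers:       %s (constituents: %s)\n",
              r$superenhancers, r$se_constituents))
  cat(sprintf("  ATAC-gaining sites:   %s\n", r$atac_gain_sites))
  cat(sprintf("  target genes:         %s\n", r$target_genes))
  cat(sprintf("  coexpression groups:  %s\n", r$coexpression_groups))
  cat(sprintf("  hypo CpG fraction:    %s\n",
              format(r$hypo_cpg_fraction, digits = 3)))
  invisible(x)
}
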