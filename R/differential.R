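#' Stable-baseline differential chromatin calling
#'
#' Stage 1 of the pipeline. Per-population consensus peaks are computed by
#' base-wise voting across replicate samples; the stable baseline is the set
#' of bases covered by every normal-population consensus (stably present) or
#' by none (stably absent); tumor gain regions are recurrent tumor peaks
#' restricted to stably absent ground, and loss regions are stably present
#' bases with near-absent tumor support. Annotation attaches per-group ATAC
#' fractions, median methylation, and host-gene differential-expression
#' status to every differential region.
#'
#' @name differential-chromatin
NULL

#' Consensus peaks for one population and mark
#'
#' Base-wise voting: a base is in the consensus when it is covered by peaks
#' in at least `ceiling(min_frac * n)` of the `n` samples; runs of such bases
#' are merged. The per-interval `support` column reports the fraction of
#' samples overlapping each consensus interval by at least one base.
#'
#' @param peaks A non-empty list of `GRanges`, one per sample.
#' @param min_frac Minimum supporting sample fraction in (0, 1].
#' @return A `GRanges` with a `support` metadata column.
#' @export
build_consensus <- function(peaks, min_frac = 0.5) {
  if (!length(peaks)) stop("empty sample list")
  if (min_frac <= 0 || min_frac > 1) stop("'min_frac' must be in (0, 1]")
  k <- ceiling(min_frac * length(peaks))
  cons <- .vote_bases(peaks, k)
  if (length(cons)) {
    hits <- vapply(peaks, function(p)
      IRanges::overlapsAny(cons, p, ignore.strand = TRUE),
      logical(length(cons)))
    hits <- matrix(hits, nrow = length(cons))
    cons$support <- rowMeans(hits)
  }
  cons
}

#' Stable chromatin baseline across normal populations
#'
#' Intersects the per-population consensus sets: `stably_present` is the set
#' of bases covered by every population's consensus, and the complement of
#' `covered_any` (bases covered by no population) is the stably absent
#' ground. Bases covered by some but not all populations are unstable and
#' belong to neither set.
#'
#' @param consensus_list Named list of consensus `GRanges`, one per normal
#'   population; at least two populations are required, and `NULL` entries
#'   (missing populations) are an error.
#' @return A list with `stably_present` and `covered_any` (`GRanges`);
#'   stably absent bases are those outside `covered_any`.
#' @export
stable_baseline <- function(consensus_list) {
  missing <- names(consensus_list)[vapply(consensus_list, is.null,
                                          logical(1))]
  if (length(missing))
    stop("missing consensus for population(s): ",
         paste(missing, collapse = ", "))
  if (length(consensus_list) < 2)
    stop("need consensus sets for >= 2 normal populations")
  grs <- lapply(consensus_list, function(g)
    GenomicRanges::reduce(.unstrand_sort(GenomicRanges::granges(g))))
  present <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), grs)
  covered <- GenomicRanges::reduce(do.call(c, unname(grs)))
  list(stably_present = present, covered_any = covered)
}

#' Call gain and loss regions for one mark
#'
#' Gain regions are bases supported by peaks in at least
#' `ceiling(min_mm_frac * n)` tumor samples, restricted to stably absent
#' ground (no overlap with any normal population's consensus). Loss regions
#' are stably present bases supported by at most
#' `floor((1 - min_mm_frac) * n)` tumor samples (near-absence tolerates
#' spurious peaks). Both are filtered to a minimum region length.
#'
#' @param mark Mark label (recorded on the output).
#' @param normal_consensus Named list of per-population consensus `GRanges`
#'   (the baseline normal populations).
#' @param mm_peaks Non-empty list of tumor sample peak `GRanges`.
#' @param min_mm_frac Minimum tumor recurrence fraction (default 0.66).
#' @param min_region_bp Minimum region length in bp (default 200).
#' @return A list with `gain` and `loss` `GRanges` (each carrying `mark` and
#'   `direction` metadata) and the `baseline` used.
#' @export
call_differential <- function(mark, normal_consensus, mm_peaks,
                              min_mm_frac = 0.66, min_region_bp = 200L) {
  if (!length(mm_peaks)) stop("no tumor samples supplied for mark ", mark)
  base <- stable_baseline(normal_consensus)
  n_mm <- length(mm_peaks)

  k_gain <- ceiling(min_mm_frac * n_mm)
  mm_recurrent <- .vote_bases(mm_peaks, k_gain)
  gain <- GenomicRanges::setdiff(mm_recurrent, base$covered_any,
                                 ignore.strand = TRUE)
  gain <- gain[GenomicRanges::width(gain) >= min_region_bp]

  k_loss <- floor((1 - min_mm_frac) * n_mm)  # max tolerated tumor support
  mm_above <- .vote_bases(mm_peaks, k_loss + 1L)
  loss <- GenomicRanges::setdiff(base$stably_present, mm_above,
                                 ignore.strand = TRUE)
  loss <- loss[GenomicRanges::width(loss) >= min_region_bp]

  decorate <- function(gr, dir) {
    if (length(gr)) {
      gr$mark <- mark
      gr$direction <- dir
    }
    gr
  }
  list(gain = decorate(gain, "gain"), loss = decorate(loss, "loss"),
       baseline = base)
}

# Median over samples of the per-sample mean beta across the CpGs inside
# each region. meth_list: list of data.tables (chrom, pos 0-based, beta,
# coverage). Returns numeric vector, NA where no covered CpG in any sample.
.region_median_meth <- function(regions, meth_list, min_cov = 5L) {
  if (!length(regions)) return(numeric(0))
  per_sample <- vapply(meth_list, function(mt) {
    keep <- mt$coverage >= min_cov
    if (!any(keep)) return(rep(NA_real_, length(regions)))
    gr <- GenomicRanges::GRanges(mt$chrom[keep],
                                 IRanges::IRanges(mt$pos[keep] + 1L,
                                                  width = 1L))
    ov <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
    out <- rep(NA_real_, length(regions))
    if (length(ov)) {
      means <- tapply(mt$beta[keep][S4Vectors::subjectHits(ov)],
                      S4Vectors::queryHits(ov), mean)
      out[as.integer(names(means))] <- as.numeric(means)
    }
    out
  }, numeric(length(regions)))
  per_sample <- matrix(per_sample, nrow = length(regions))
  apply(per_sample, 1, function(x)
    if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
}

#' Annotate differential regions
#'
#' Adds, per region: the fraction of tumor and normal samples harboring at
#' least `min_bp` bases of ATAC peak overlap; the median (over samples) of
#' per-sample mean CpG beta inside the region, for tumor and normal WGBS
#' samples; the host gene whose body contains the region midpoint (or none,
#' i.e. intergenic); and the host gene's differential-expression status
#' (`up`, `down`, `ns`, or `na` when intergenic or unmeasured).
#'
#' @param regions A `GRanges` of differential regions.
#' @param atac_mm,atac_normal Lists of per-sample ATAC peak `GRanges`.
#' @param meth_mm,meth_normal Lists of per-sample methylation tables
#'   ([read_methylation()]).
#' @param genes Gene annotation ([read_gene_annotation()]).
#' @param de A [de_call()] result (tumor over normal), or `NULL`.
#' @param min_bp Minimum ATAC overlap for "harboring" (default 1).
#' @param min_cov Minimum CpG coverage per sample (default 5).
#' @return `regions` with metadata columns `atac_fraction_mm`,
#'   `atac_fraction_normal`, `medmeth_mm`, `medmeth_normal`, `host_gene`,
#'   `host_gene_de`.
#' @export
annotate_differential <- function(regions, atac_mm, atac_normal,
                                  meth_mm, meth_normal, genes, de = NULL,
                                  min_bp = 1L, min_cov = 5L) {
  stopifnot(methods::is(regions, "GRanges"))
  frac_with_peak <- function(peak_list) {
    if (!length(peak_list)) return(rep(NA_real_, length(regions)))
    hits <- vapply(peak_list, function(p)
      count_overlaps(regions, p, min_bp = min_bp)$hit,
      logical(length(regions)))
    rowMeans(matrix(hits, nrow = length(regions)))
  }
  regions$atac_fraction_mm <- frac_with_peak(atac_mm)
  regions$atac_fraction_normal <- frac_with_peak(atac_normal)
  regions$medmeth_mm <- .region_median_meth(regions, meth_mm, min_cov)
  regions$medmeth_normal <- .region_median_meth(regions, meth_normal,
                                                min_cov)
  mids <- region_midpoints(regions)
  bodies <- .genes_as_granges(genes)
  ov <- GenomicRanges::findOverlaps(mids, bodies, ignore.strand = TRUE,
                                    select = "first")
  regions$host_gene <- ifelse(is.na(ov), NA_character_, genes$gene_id[ov])
  status <- rep("na", length(regions))
  if (!is.null(de)) {
    idx <- match(regions$host_gene, de$gene_id)
    measured <- !is.na(idx)
    status[measured] <- ifelse(
      de$is_de[idx[measured]] & de$fold_change[idx[measured]] > 1, "up",
      ifelse(de$is_de[idx[measured]], "down", "ns"))
  }
  regions$host_gene_de <- status
  regions
}
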