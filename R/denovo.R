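#' De novo activated regions and superenhancers
#'
#' Stage 2. Gain regions for the activation mark are filtered to zero-base
#' overlap against every individual normal sample's peaks -- including the
#' tumor's normal cell-of-origin counterpart (bm-PC), a mandatory filter --
#' yielding de novo activated regions. Tumor consensus peaks away from
#' promoters are stitched into superenhancer candidates and ranked by
#' aggregate signal with a tangent-slope cutoff on the scaled rank curve.
#'
#' @name denovo-activation
NULL

#' Select de novo activated regions
#'
#' Retains tumor gain regions with zero bases of overlap against the union
#' of every individual normal sample's peaks for the activation mark. The
#' normal panel must include bm-PC samples (the cell-of-origin filter);
#' their absence is an error unless explicitly overridden, which logs a
#' warning.
#'
#' @param mm_gains A `GRanges` of tumor gain regions for the activation
#'   mark (from [call_differential()]).
#' @param normal_peaks Named list of per-sample peak `GRanges` for all
#'   normal samples; names are sample ids.
#' @param normal_populations Character vector parallel to `normal_peaks`
#'   giving each sample's population (used to enforce the bm-PC filter).
#' @param mm_peaks Optional list of tumor sample peak `GRanges`; when given,
#'   per-region tumor support fractions are recorded as `mm_support`.
#' @param require_bmpc Set to `FALSE` to override the mandatory bm-PC
#'   filter (a warning is emitted).
#' @return The retained subset of `mm_gains` with a `region_id` and, when
#'   `mm_peaks` is given, an `mm_support` metadata column.
#' @export
select_de_novo <- function(mm_gains, normal_peaks, normal_populations,
                           mm_peaks = NULL, require_bmpc = TRUE) {
  stopifnot(methods::is(mm_gains, "GRanges"))
  if (length(normal_peaks) != length(normal_populations))
    stop("'normal_populations' must parallel 'normal_peaks'")
  if (!any(normal_populations == "bm-PC")) {
    if (require_bmpc)
      stop("no bm-PC samples in the normal panel: the cell-of-origin ",
           "filter is mandatory (set require_bmpc = FALSE to override)")
    warning("bm-PC filter overridden: no cell-of-origin samples present")
  }
  keep <- rep(TRUE, length(mm_gains))
  for (p in normal_peaks)
    keep <- keep & !IRanges::overlapsAny(mm_gains, p,
                                               ignore.strand = TRUE)
  out <- mm_gains[keep]
  if (length(out)) out$region_id <- sprintf("dn_%04d", seq_along(out))
  if (!is.null(mm_peaks) && length(out)) {
    hits <- vapply(mm_peaks, function(p)
      IRanges::overlapsAny(out, p, ignore.strand = TRUE),
      logical(length(out)))
    out$mm_support <- rowMeans(matrix(hits, nrow = length(out)))
  }
  out
}

#' Audit de novo regions against every normal peak file
#'
#' Independent second pass over the raw normal peak sets re-checking the
#' zero-overlap contract; returns the number of violating regions (0 for a
#' clean set).
#'
#' @param denovo A `GRanges` of de novo regions.
#' @param normal_peaks List of per-sample normal peak `GRanges`.
#' @return Integer count of regions overlapping any normal peak.
#' @export
audit_de_novo <- function(denovo, normal_peaks) {
  bad <- rep(FALSE, length(denovo))
  for (p in normal_peaks)
    bad <- bad | IRanges::overlapsAny(denovo, p, ignore.strand = TRUE)
  sum(bad)
}

# Tangent-slope cutoff on the scaled rank curve: signals sorted ascending,
# both axes scaled to [0, 1]; the cutoff is the support point of the
# slope-1 tangent line (the rank minimizing y - x, i.e. where the curve's
# tangent slope passes 1), and everything ranked above it is called super.
# A flat curve (all signals equal) yields no superenhancers by convention.
.super_cutoff <- function(signal_sorted) {
  n <- length(signal_sorted)
  if (n < 3) return(rep(FALSE, n))
  rng <- max(signal_sorted) - min(signal_sorted)
  if (rng == 0) return(rep(FALSE, n))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (signal_sorted - min(signal_sorted)) / rng
  i <- which.min(y - x)
  seq_len(n) > i
}

#' Stitch and rank superenhancers
#'
#' Peaks lying fully within `tss_exclusion` bp of a TSS are removed, the
#' remainder are stitched when separated by at most `stitch_distance` bp,
#' each stitched region is scored by the mean across tumor samples of its
#' total signal, and regions are ranked ascending by score. A stitched
#' region is a superenhancer when it ranks above the support point of the
#' slope-1 tangent to the scaled rank curve (both axes scaled to
#' \[0, 1\]; the point where the curve's tangent slope passes 1). Fewer
#' than three stitched regions leave the cutoff undefined:
#' all are flagged non-super with a warning.
#'
#' @param peaks Tumor consensus peaks for the activation mark (`GRanges`).
#' @param signal_tracks List of per-tumor-sample signal `GRanges`
#'   (bedGraph-style, with `score`).
#' @param genes Gene annotation ([read_gene_annotation()]); supplies TSS
#'   positions.
#' @param stitch_distance Maximum gap for stitching (default 12500).
#' @param tss_exclusion Half-width of the promoter exclusion window
#'   (default 2000).
#' @return A `GRanges` of stitched regions with metadata `se_id`,
#'   `n_constituents`, `signal`, `rank` (1 = lowest signal) and `is_super`.
#' @export
stitch_superenhancers <- function(peaks, signal_tracks, genes,
                                  stitch_distance = 12500L,
                                  tss_exclusion = 2000L) {
  stopifnot(methods::is(peaks, "GRanges"))
  if (!length(signal_tracks)) stop("need >= 1 tumor signal track")
  pk <- GenomicRanges::reduce(.unstrand_sort(GenomicRanges::granges(peaks)))
  tss_win <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(1L, genes$tss - tss_exclusion),
                                  genes$tss + tss_exclusion))
  inside <- IRanges::overlapsAny(pk, tss_win, type = "within",
                                 ignore.strand = TRUE)
  pk <- pk[!inside]
  stitched <- merge_intervals(pk, gap = stitch_distance)
  if (!length(stitched)) return(stitched)
  stitched$n_constituents <- GenomicRanges::countOverlaps(
    stitched, pk, ignore.strand = TRUE)
  sig <- vapply(signal_tracks, function(tr)
    quantify_signal(tr, stitched)$total, numeric(length(stitched)))
  stitched$signal <- rowMeans(matrix(sig, nrow = length(stitched)))
  ord <- order(stitched$signal)
  rank <- integer(length(stitched))
  rank[ord] <- seq_along(ord)
  stitched$rank <- rank
  if (length(stitched) < 3) {
    warning("fewer than 3 stitched regions: superenhancer cutoff undefined")
    stitched$is_super <- FALSE
  } else {
    flag_sorted <- .super_cutoff(stitched$signal[ord])
    is_super <- logical(length(stitched))
    is_super[ord] <- flag_sorted
    stitched$is_super <- is_super
  }
  stitched$se_id <- sprintf("se_%04d", seq_along(stitched))
  stitched
}

#' Flag de novo regions that also gain accessibility
#'
#' Sets `atac_gain` TRUE for every de novo region sharing at least one base
#' with an ATAC gain region.
#'
#' @param denovo A `GRanges` of de novo regions.
#' @param atac_gains A `GRanges` of ATAC gain regions (possibly empty).
#' @return `denovo` with a logical `atac_gain` metadata column.
#' @export
intersect_atac <- function(denovo, atac_gains) {
  stopifnot(methods::is(denovo, "GRanges"))
  denovo$atac_gain <- if (length(atac_gains))
    IRanges::overlapsAny(denovo, atac_gains, ignore.strand = TRUE)
  else rep(FALSE, length(denovo))
  denovo
}

#' Assign de novo regions to superenhancers
#'
#' Sets `se_id` to the id of the superenhancer (a stitched region with
#' `is_super`) overlapping each region, or `NA` for regions outside all
#' superenhancers.
#'
#' @param denovo A `GRanges` of de novo regions.
#' @param superenhancers Output of [stitch_superenhancers()].
#' @return `denovo` with an `se_id` metadata column.
#' @export
assign_superenhancer <- function(denovo, superenhancers) {
  se <- superenhancers[superenhancers$is_super]
  hit <- GenomicRanges::findOverlaps(denovo, se, ignore.strand = TRUE,
                                     select = "first")
  denovo$se_id <- ifelse(is.na(hit), NA_character_, se$se_id[hit])
  denovo
}
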