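#' Interval algebra on genomic ranges
#'
#' Thin, convention-fixing wrappers around GenomicRanges that implement the
#' interval primitives every pipeline stage uses: gap-aware merging, overlap
#' counting with a minimum-overlap rule, and signal quantification over
#' step-function tracks. All functions are strand-agnostic: peaks are
#' unstranded and strand is dropped on entry.
#'
#' @name interval-algebra
NULL

# Drop strand and sort; the package-wide normal form for peak sets.
.unstrand_sort <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::sort(gr)
}

#' Merge intervals allowing a maximum gap
#'
#' Merges all intervals on the same chromosome whose separation is at most
#' `gap` bases (so `gap = 0` merges overlapping and bookended intervals).
#' The union of covered bases is preserved when `gap = 0`.
#'
#' @param x A [GenomicRanges::GRanges] object.
#' @param gap Non-negative integer; intervals separated by at most this many
#'   bases are merged into one.
#' @return A sorted, strandless `GRanges` with pairwise non-overlapping,
#'   non-bookended intervals.
#' @export
merge_intervals <- function(x, gap = 0L) {
  stopifnot(methods::is(x, "GRanges"))
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("'gap' must be a single non-negative integer")
  GenomicRanges::reduce(.unstrand_sort(x), min.gapwidth = gap + 1L)
}

#' Count overlap of query intervals against a subject set
#'
#' For each query interval, reports the number of bases shared with the union
#' of the subject set and whether that count reaches `min_bp`. Coordinates
#' follow the usual closed 1-based GRanges convention, so intervals that are
#' merely bookended share no base.
#'
#' @param query,subject [GenomicRanges::GRanges] objects.
#' @param min_bp Positive integer; minimum shared bases for `hit` to be TRUE.
#' @return A `data.frame` with one row per query: `overlap_bp` (exact shared
#'   base count against the subject union) and `hit` (logical).
#' @export
count_overlaps <- function(query, subject, min_bp = 1L) {
  stopifnot(methods::is(query, "GRanges"), methods::is(subject, "GRanges"))
  if (length(min_bp) != 1L || is.na(min_bp) || min_bp < 1)
    stop("'min_bp' must be a single integer >= 1")
  subj <- GenomicRanges::reduce(.unstrand_sort(subject))
  q <- query
  GenomicRanges::strand(q) <- "*"
  ov <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  bp <- rep(0, length(q))
  if (length(ov)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(ov)], subj[S4Vectors::subjectHits(ov)]
    ))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(overlap_bp = bp, hit = bp >= min_bp)
}

#' Quantify a step-function signal track over regions
#'
#' Computes, for each region, the total signal (sum over track steps of
#' value times covered bases) and the mean per-base signal (total divided by
#' region width). Track steps must be non-overlapping within one track; bases
#' not covered by any step contribute zero. Regions on chromosomes absent
#' from the track get total 0.
#'
#' @param track A `GRanges` with a numeric `score` column (e.g. from
#'   [read_bedgraph()]), non-overlapping within the track.
#' @param regions A `GRanges` of regions to quantify.
#' @return A `data.frame` with one row per region: `total` and `mean`.
#' @export
quantify_signal <- function(track, regions) {
  stopifnot(methods::is(track, "GRanges"), methods::is(regions, "GRanges"))
  if (length(track) && is.null(track$score))
    stop("'track' must carry a numeric 'score' column")
  if (length(track)) {
    self_ov <- GenomicRanges::findOverlaps(track, drop.self = TRUE,
                                           ignore.strand = TRUE)
    if (length(self_ov)) stop("'track' steps overlap within the sample")
  }
  total <- rep(0, length(regions))
  ov <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  if (length(ov)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      regions[S4Vectors::queryHits(ov)], track[S4Vectors::subjectHits(ov)]
    ))
    contrib <- w * track$score[S4Vectors::subjectHits(ov)]
    agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
    total[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(total = total, mean = total / GenomicRanges::width(regions))
}

#' Midpoint positions of regions
#'
#' The package-wide midpoint rule used for host-gene and TAD assignment:
#' for a region of width w starting at s (1-based), the midpoint is
#' s + floor(w / 2), i.e. the left-of-center base for even widths.
#'
#' @param regions A `GRanges`.
#' @return A `GRanges` of width-1 midpoints, metadata preserved.
#' @export
region_midpoints <- function(regions) {
  stopifnot(methods::is(regions, "GRanges"))
  mid <- GenomicRanges::start(regions) + GenomicRanges::width(regions) %/% 2L
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(regions),
    IRanges::IRanges(mid, width = 1L)
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(regions)
  out
}

# Base-wise voting across a list of peak GRanges: bases covered in >= k
# samples, merged. Workhorse behind consensus and recurrence calls.
.vote_bases <- function(peak_list, k) {
  stopifnot(length(peak_list) >= 1L, k >= 1L)
  grl <- GenomicRanges::GRangesList(lapply(peak_list, function(g) {
    GenomicRanges::strand(g) <- "*"
    GenomicRanges::reduce(g)
  }))
  cov <- GenomicRanges::coverage(unlist(grl))
  hi <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(hi)
  GenomicRanges::reduce(gr)
}
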