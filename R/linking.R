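#' TAD-constrained target-gene linking and coregulated gene groups
#'
#' Stage 3. Each de novo region is assigned to the TAD containing its
#' midpoint; candidate target genes share that TAD and must be up-regulated
#' in the tumor against every normal population (the cell-of-origin
#' population included) to be linked. Linked genes that are adjacent in the
#' full annotation and coexpressed across tumor samples are merged into
#' coregulated groups (pairs and longer chains).
#'
#' @name target-linking
NULL

#' Assign regions to TADs by midpoint
#'
#' @param regions A `GRanges`.
#' @param tads A `GRanges` of non-overlapping TADs with a `tad_id` column
#'   ([read_tads()]).
#' @return Character vector of TAD ids, `NA` where the region midpoint
#'   falls in an inter-TAD gap.
#' @export
assign_tad <- function(regions, tads) {
  stopifnot(methods::is(regions, "GRanges"), methods::is(tads, "GRanges"))
  mids <- region_midpoints(regions)
  hit <- GenomicRanges::findOverlaps(mids, tads, ignore.strand = TRUE,
                                     select = "first")
  ifelse(is.na(hit), NA_character_, tads$tad_id[hit])
}

#' Link de novo regions to target genes
#'
#' Candidate genes have their TSS in the region's TAD; a candidate is
#' linked when it is flagged up-regulated in the tumor (per [de_call()]:
#' q < fdr and fold change > fc) against *every* supplied normal
#' population. Regions whose midpoint falls outside all TADs fall back to
#' candidates with TSS within `fallback_window` bp of the region midpoint,
#' flagged `fallback`. All qualifying genes are linked; a region may have
#' several targets and a gene may serve several regions.
#'
#' @param regions A `GRanges` of de novo regions with a `region_id` column.
#' @param tads TADs ([read_tads()]).
#' @param genes Gene annotation ([read_gene_annotation()]).
#' @param de_list Named list of [de_call()] results, one per normal
#'   population (fold change tumor over that population).
#' @param fdr,fc Thresholds applied to every population's DE result
#'   (defaults 0.05 and 1.5).
#' @param fallback_window Window for TAD-less regions (default 1e6).
#' @return A `data.frame` of links: `region_id`, `gene_id`, `same_tad`,
#'   `fallback`, `distance_to_tss` (midpoint to TSS, bp).
#' @export
link_targets <- function(regions, tads, genes, de_list, fdr = 0.05,
                         fc = 1.5, fallback_window = 1e6) {
  if (!length(de_list)) stop("need >= 1 normal-population DE result")
  up <- Reduce(`&`, lapply(de_list, function(de) {
    v <- de$q_value < fdr & de$fold_change > fc
    v[match(genes$gene_id, de$gene_id)]
  }))
  up[is.na(up)] <- FALSE  # genes unmeasured in some comparison
  tad_of_region <- assign_tad(regions, tads)
  tss <- .tss_as_granges(genes)
  gene_tad <- assign_tad(tss, tads)
  mids <- GenomicRanges::start(region_midpoints(regions))
  links <- list()
  for (i in seq_along(regions)) {
    if (!is.na(tad_of_region[i])) {
      cand <- which(gene_tad == tad_of_region[i] & up)
      fb <- FALSE
    } else {
      same_chrom <- genes$chrom ==
        as.character(GenomicRanges::seqnames(regions))[i]
      cand <- which(same_chrom & abs(genes$tss - mids[i]) <=
                      fallback_window & up)
      fb <- TRUE
    }
    if (length(cand))
      links[[length(links) + 1L]] <- data.frame(
        region_id = regions$region_id[i],
        gene_id = genes$gene_id[cand],
        same_tad = !fb, fallback = fb,
        distance_to_tss = abs(genes$tss[cand] - mids[i]))
  }
  if (!length(links))
    return(data.frame(region_id = character(0), gene_id = character(0),
                      same_tad = logical(0), fallback = logical(0),
                      distance_to_tss = numeric(0)))
  do.call(rbind, links)
}

#' Detect coregulated adjacent coexpressed gene groups
#'
#' Genes are ordered by TSS within each chromosome using the *full*
#' annotation; a candidate pair is two target-list genes with no other
#' annotated gene's TSS strictly between them. A pair is kept when the
#' Pearson correlation of the two genes across tumor samples satisfies
#' r > `r_min` (strict) and p < `p_max` (strict). Kept pairs sharing a gene
#' are merged transitively into maximal chains, so three chained genes form
#' one triplet. Pairs involving a constant expression vector are skipped.
#'
#' @param target_genes Character vector of linked target gene ids.
#' @param genes Gene annotation ([read_gene_annotation()]).
#' @param expr_mm Expression matrix restricted to tumor samples (genes in
#'   rows); needs >= 3 columns.
#' @param r_min,p_max Correlation and significance thresholds (defaults
#'   0.5 and 0.05).
#' @return A list of groups, each a list with `genes` (ordered ids),
#'   `r` and `p` (per adjacent pair within the group), and `span_bp`
#'   (genomic span from first TSS to last TSS).
#' @export
find_coregulated <- function(target_genes, genes, expr_mm, r_min = 0.5,
                             p_max = 0.05) {
  if (ncol(expr_mm) < 3) stop("need >= 3 tumor expression samples")
  ord <- order(genes$chrom, genes$tss)
  g <- genes[ord, ]
  in_target <- g$gene_id %in% target_genes
  kept <- list()
  for (i in seq_len(nrow(g) - 1)) {
    if (!(in_target[i] && in_target[i + 1])) next
    if (g$chrom[i] != g$chrom[i + 1]) next
    a <- g$gene_id[i]; b <- g$gene_id[i + 1]
    if (!(a %in% rownames(expr_mm)) || !(b %in% rownames(expr_mm))) next
    xa <- expr_mm[a, ]; xb <- expr_mm[b, ]
    if (stats::var(xa) == 0 || stats::var(xb) == 0) {
      message("skipping pair ", a, "-", b, ": constant expression")
      next
    }
    ct <- pearson_test(xa, xb)
    if (ct$r > r_min && ct$p < p_max)
      kept[[length(kept) + 1L]] <- list(a = a, b = b, r = ct$r, p = ct$p)
  }
  if (!length(kept)) return(list())
  # transitive chaining of pairs that share a gene
  edges <- do.call(rbind, lapply(kept, function(k)
    data.frame(a = k$a, b = k$b)))
  nodes <- unique(c(edges$a, edges$b))
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (e in seq_len(nrow(edges))) {
    ca <- comp[[edges$a[e]]]; cb <- comp[[edges$b[e]]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  lapply(split(names(comp), comp), function(members) {
    idx <- match(members, g$gene_id)
    members <- members[order(idx)]
    pr <- Filter(function(k) k$a %in% members && k$b %in% members, kept)
    tss <- g$tss[match(members, g$gene_id)]
    list(genes = members,
         r = vapply(pr, `[[`, numeric(1), "r"),
         p = vapply(pr, `[[`, numeric(1), "p"),
         span_bp = max(tss) - min(tss))
  })
}
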