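#' Readers and writers for the on-disk formats the pipeline consumes
#'
#' BED3/BED5 and bedGraph go through rtracklayer; tabular formats (sample
#' sheet, gene annotation, CpG methylation, expression matrix) are plain TSV.
#' All genomic coordinates are converted to the 1-based closed GRanges
#' convention at the reader boundary and back to 0-based half-open BED on
#' write, so no off-by-one reasoning leaks into analysis code.
#'
#' @name io
NULL

# Fixed vocabularies for the study design.
.CELL_POPULATIONS <- c("pb-NBC", "t-NBC", "GCBC", "MBC", "t-PC", "bm-PC", "MM")
.BASELINE_POPULATIONS <- c("pb-NBC", "t-NBC", "GCBC", "MBC", "t-PC")
.HISTONE_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K36me3",
                    "H3K27me3", "H3K9me3")
.ASSAYS <- c(.HISTONE_MARKS, "ATAC", "WGBS", "RNA")

#' Fixed vocabularies of the study design
#'
#' `cell_populations()` returns the recognized cell-population labels (five
#' normal B-cell stages, bone-marrow plasma cells, and myeloma);
#' `baseline_populations()` the five fully profiled normal populations that
#' define the stable baseline; `histone_marks()` the six core marks;
#' `assay_types()` every assay label a sample sheet may carry.
#'
#' @return A character vector.
#' @export
cell_populations <- function() .CELL_POPULATIONS

#' @rdname cell_populations
#' @export
baseline_populations <- function() .BASELINE_POPULATIONS

#' @rdname cell_populations
#' @export
histone_marks <- function() .HISTONE_MARKS

#' @rdname cell_populations
#' @export
assay_types <- function() .ASSAYS

# Normalize chromosome-name dialects by stripping or prepending a prefix.
.normalize_chroms <- function(chroms, chrom_prefix = NULL) {
  if (is.null(chrom_prefix)) return(chroms)
  bare <- sub("^chr", "", chroms)
  if (nzchar(chrom_prefix)) paste0(chrom_prefix, bare) else bare
}

#' Read peak intervals from a BED3/BED5 file
#'
#' Tab-separated, headerless BED; the optional fifth column is kept as the
#' `score` metadata column. BED's 0-based half-open coordinates become
#' 1-based closed on the returned `GRanges`. An empty file yields an empty
#' `GRanges`.
#'
#' @param path Path to a BED file.
#' @param chrom_prefix `NULL` to keep chromosome names as-is, `""` to strip a
#'   leading "chr", or a prefix such as `"chr"` to enforce it.
#' @return A sorted, strandless `GRanges`.
#' @export
read_bed <- function(path, chrom_prefix = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  gr <- methods::as(gr, "GRanges")
  GenomeInfoDb::seqlevels(gr) <-
    .normalize_chroms(GenomeInfoDb::seqlevels(gr), chrom_prefix)
  .unstrand_sort(gr)
}

#' Write intervals to BED3/BED5
#'
#' Writes BED3 when `x` has no `score`, BED5 (with a generated name column)
#' when it does. Coordinates are converted back to 0-based half-open.
#'
#' @param x A `GRanges`, optionally with a numeric `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(methods::is(x, "GRanges"))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x)
  )
  if (!is.null(x$score)) {
    nm <- if (!is.null(x$name)) as.character(x$name)
          else sprintf("region_%d", seq_along(x))
    df$name <- if (length(x)) nm else character(0)
    df$score <- x$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Track definition lines are skipped by the parser; the fourth column
#' becomes the `score` metadata column. Steps are expected to be
#' non-overlapping within one sample (enforced by [quantify_signal()]).
#'
#' @inheritParams read_bed
#' @return A sorted `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path, chrom_prefix = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- methods::as(gr, "GRanges")
  GenomeInfoDb::seqlevels(gr) <-
    .normalize_chroms(GenomeInfoDb::seqlevels(gr), chrom_prefix)
  .unstrand_sort(gr)
}

#' Read the sample sheet
#'
#' A header TSV with columns `sample_id`, `population`, `assay`, `path`.
#' Populations and assays must come from the fixed vocabularies
#' ([cell_populations()], [assay_types()]) and `(sample_id, assay)` pairs
#' must be unique. Relative `path` entries are resolved against the sheet's
#' directory.
#'
#' @param path Path to the sample sheet TSV.
#' @return A `data.frame` with the four columns above.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "assay", "path")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  bad_pop <- setdiff(unique(ss$population), .CELL_POPULATIONS)
  if (length(bad_pop))
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "))
  bad_assay <- setdiff(unique(ss$assay), .ASSAYS)
  if (length(bad_assay))
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  key <- paste(ss$sample_id, ss$assay)
  if (anyDuplicated(key))
    stop("duplicated (sample_id, assay) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rel <- !grepl("^/", ss$path) & nzchar(ss$path)
  ss$path[rel] <- file.path(dirname(path), ss$path[rel])
  ss[need]
}

# Select sample-sheet rows for one population set and assay.
.sheet_rows <- function(sheet, populations, assay) {
  sheet[sheet$population %in% populations & sheet$assay == assay, ,
        drop = FALSE]
}

# Read the peak files for the selected rows as a named list of GRanges.
.read_peak_list <- function(rows, chrom_prefix = NULL) {
  out <- lapply(rows$path, read_bed, chrom_prefix = chrom_prefix)
  names(out) <- rows$sample_id
  out
}

#' Read gene annotation
#'
#' Accepts either the package's gene TSV (header columns `gene_id`,
#' `gene_name`, `chrom`, `start`, `end`, `strand`, with BED-style 0-based
#' half-open gene bodies) or a minimal GTF (`.gtf`/`.gff` extension; `gene`
#' features with `gene_id`/`gene_name` attributes, 1-based). Both are
#' converted to 1-based closed coordinates, and the TSS is derived from the
#' strand: body start for `+` genes, body end for `-` genes.
#'
#' @param path Path to the annotation file.
#' @return A `data.frame` with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`, `tss` (all coordinates 1-based closed).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ann <- data.frame(
      gene_id = gr$gene_id,
      gene_name = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "gene_name", "chrom", "start", "end", "strand")
    if (!all(need %in% names(ann)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    ann <- ann[need]
    ann$start <- ann$start + 1L  # 0-based half-open -> 1-based closed
  }
  if (anyDuplicated(ann$gene_id)) stop("gene_id values must be unique")
  if (!all(ann$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(ann$start > ann$end)) stop("malformed gene body coordinates")
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann
}

# Gene bodies / TSS positions as GRanges keyed by gene_id.
.genes_as_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  gr$gene_id <- genes$gene_id
  gr
}

.tss_as_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$tss, width = 1L)
  )
  gr$gene_id <- genes$gene_id
  gr
}

#' Read a per-sample CpG methylation table
#'
#' TSV with header columns `chrom`, `pos` (0-based position of the CpG
#' cytosine on the plus strand), `beta` in \[0, 1\] and non-negative integer
#' `coverage`. Positions must be unique within a chromosome.
#'
#' @param path Path to the methylation TSV.
#' @return A `data.table` with the four columns; `pos` kept 0-based as the
#'   per-CpG key used across samples.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("methylation table not found: ", path)
  mt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "beta", "coverage")
  if (!all(need %in% names(mt)))
    stop("methylation TSV must have columns: ", paste(need, collapse = ", "))
  mt <- mt[, need, with = FALSE]
  if (mt[, any(beta < 0 | beta > 1)]) stop("beta values must lie in [0, 1]")
  if (mt[, any(coverage < 0)]) stop("coverage must be non-negative")
  if (anyDuplicated(mt, by = c("chrom", "pos")))
    stop("duplicate CpG positions within one sample")
  mt
}

#' Read a gene-by-sample expression matrix
#'
#' TSV with genes as rows (first column `gene_id`) and one column per
#' sample of non-negative normalized abundances.
#'
#' @param path Path to the expression TSV.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Read topologically associating domains (TADs)
#'
#' BED3 of non-overlapping domains; overlap is an error. Each TAD gets a
#' stable id `tad_<i>` in sorted order.
#'
#' @inheritParams read_bed
#' @return A sorted `GRanges` with a `tad_id` metadata column.
#' @export
read_tads <- function(path, chrom_prefix = NULL) {
  gr <- read_bed(path, chrom_prefix = chrom_prefix)
  if (length(gr) > 1) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      ignore.strand = TRUE)
    if (length(ov)) stop("TAD intervals must not overlap")
  }
  gr$tad_id <- sprintf("tad_%d", seq_along(gr))
  gr
}

#' Read position weight matrices in MEME minimal text format
#'
#' Parses the minimal motif format: a `MEME version` header, optional
#' `ALPHABET`/`strands`/background sections, then one `MOTIF` block per
#' motif with a `letter-probability matrix` section. Only the ACGT alphabet
#' is supported.
#'
#' @param path Path to a MEME minimal text file.
#' @return A named list of PWMs; each PWM is a list with `id`, `prob` (a
#'   4 x width matrix with rows A, C, G, T; columns sum to 1) and
#'   `background` (length-4 frequency vector).
#' @export
read_meme_pwm <- function(path) {
  if (!file.exists(path)) stop("MEME motif file not found: ", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  pwms <- lapply(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines))
      stop("motif ", id, " has no letter-probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
    w <- as.integer(w)
    rows <- lines[(j + 1L):(j + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    prob <- t(mat)  # 4 x w
    dimnames(prob) <- list(c("A", "C", "G", "T"), NULL)
    colsums <- colSums(prob)
    if (any(abs(colsums - 1) > 1e-6))
      stop("motif ", id, ": probability columns must sum to 1")
    if (w < 4) stop("motif ", id, ": width must be >= 4")
    list(id = id, prob = prob, background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  pwms
}

#' Write PWMs in MEME minimal text format
#'
#' @param pwms A named list of PWMs as returned by [read_meme_pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), ""
  ), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(p$prob)), con)
    for (k in seq_len(ncol(p$prob)))
      writeLines(sprintf("%.6f %.6f %.6f %.6f",
                         p$prob[1, k], p$prob[2, k],
                         p$prob[3, k], p$prob[4, k]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read region sequences from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]. Sequence names of the form
#' `chrom:start-end` (1-based closed, as emitted by the synthetic generator)
#' carry the genomic placement used to lift motif hits back to genome
#' coordinates.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_region_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  Biostrings::readDNAStringSet(path)
}

# Parse "chrom:start-end" sequence names into a GRanges (1-based closed).
.regions_from_names <- function(nms) {
  m <- regmatches(nms, regexec("^(\\S+):(\\d+)-(\\d+)$", nms))
  ok <- lengths(m) == 4L
  if (!all(ok))
    stop("sequence names must look like 'chrom:start-end'; offending: ",
         paste(utils::head(nms[!ok], 3), collapse = ", "))
  GenomicRanges::GRanges(
    vapply(m, `[`, character(1), 2),
    IRanges::IRanges(as.integer(vapply(m, `[`, character(1), 3)),
                     as.integer(vapply(m, `[`, character(1), 4)))
  )
}
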