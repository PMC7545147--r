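#' Statistical primitives shared by all pipeline stages
#'
#' Two-sided Welch tests, Pearson correlation with significance,
#' Benjamini-Hochberg correction, threshold-based differential-expression
#' calls, and hypergeometric gene-set enrichment. Wherever base R supplies
#' the machinery (t.test, cor.test, p.adjust, phyper) it is used directly;
#' only the per-gene DE engine is a vectorized closed form for speed, and
#' the test-suite cross-checks it against stats::t.test gene by gene.
#'
#' @name stats-primitives
NULL

#' Welch's two-sample t-test (two-sided)
#'
#' Unequal-variance t-test via [stats::t.test()]. The degenerate case of two
#' zero-variance groups is handled by convention: equal means give p = 1,
#' different means give p = 0 (infinite evidence at zero noise).
#'
#' @param a,b Numeric vectors with at least two finite values each.
#' @return A list with elements `t` and `p`.
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 values")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("non-finite values in input")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(b) - mean(a)) * Inf, p = 0))
  }
  ht <- stats::t.test(b, a, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

# Vectorized Welch test over matrix rows (groups as column index vectors).
# Returns data.frame(t, df, p); rows with zero pooled variance follow the
# same convention as welch_t_test.
.row_welch <- function(m, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  a <- m[, idx_a, drop = FALSE]; b <- m[, idx_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- ifelse(mb[degen] == ma[degen], 0,
                       sign(mb[degen] - ma[degen]) * Inf)
    p[degen] <- ifelse(mb[degen] == ma[degen], 1, 0)
    df[degen] <- NA_real_
  }
  data.frame(t = t, df = df, p = p)
}

#' Pearson correlation with two-sided significance
#'
#' Wraps [stats::cor.test()]; p follows the exact t transform
#' t = r * sqrt(n - 2) / sqrt(1 - r^2). Constant vectors have no defined
#' correlation and raise an error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A list with elements `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector")
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] with input validation; the mapping back to
#' input positions is order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold-based differential expression call
#'
#' Per gene: a two-sided Welch t-test on log2(x + pseudocount) values, a
#' linear fold change on pseudocounted group means
#' (mean_b + pseudocount) / (mean_a + pseudocount), BH-adjusted q-values,
#' and a flag `is_de` that requires q < `fdr` and a two-sided linear fold
#' change beyond `fc` (i.e. > fc or < 1/fc). Genes that are all-zero in
#' both groups get p = 1 and fold change 1.
#'
#' @param expr Numeric gene-by-sample matrix of non-negative abundances.
#' @param group_a,group_b Column names or indices of the two groups
#'   (fold change is b over a), each with >= 2 samples.
#' @param fdr FDR threshold (default 0.05).
#' @param fc Linear fold-change threshold (default 1.5).
#' @param pseudocount Added before the log transform and to both means
#'   (default 1).
#' @return A `data.frame` keyed by rownames(expr): `mean_a`, `mean_b`,
#'   `fold_change`, `log2fc`, `p_value`, `q_value`, `is_de`.
#' @export
de_call <- function(expr, group_a, group_b, fdr = 0.05, fc = 1.5,
                    pseudocount = 1) {
  stopifnot(is.matrix(expr))
  a_idx <- if (is.character(group_a)) match(group_a, colnames(expr)) else group_a
  b_idx <- if (is.character(group_b)) match(group_b, colnames(expr)) else group_b
  if (anyNA(a_idx) || anyNA(b_idx)) stop("unknown sample columns")
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("each group needs >= 2 samples")
  if (fc <= 1) stop("'fc' must exceed 1")
  lg <- log2(expr + pseudocount)
  wt <- .row_welch(lg, a_idx, b_idx)
  mean_a <- rowMeans(expr[, a_idx, drop = FALSE])
  mean_b <- rowMeans(expr[, b_idx, drop = FALSE])
  fold <- (mean_b + pseudocount) / (mean_a + pseudocount)
  allzero <- mean_a == 0 & mean_b == 0 &
    rowSums(expr[, c(a_idx, b_idx), drop = FALSE] != 0) == 0
  p <- wt$p
  p[allzero] <- 1
  fold[allzero] <- 1
  q <- bh_adjust(p)
  data.frame(
    gene_id = rownames(expr),
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fold, log2fc = log2(fold),
    p_value = p, q_value = q,
    is_de = q < fdr & (fold > fc | fold < 1 / fc),
    row.names = rownames(expr)
  )
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value (including the observed overlap) for
#' each named gene set intersected with the universe, via [stats::phyper()];
#' q-values are BH-adjusted across sets.
#'
#' @param hits Character vector of hit genes, a subset of `universe`.
#' @param universe Character vector of background genes (non-empty).
#' @param gene_sets Named list of character vectors.
#' @return A `data.frame` with one row per set: `set`, `set_size` (within
#'   the universe), `overlap`, `p_value`, `q_value`.
#' @export
hypergeom_enrichment <- function(hits, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(s, hits))
    p <- stats::phyper(k - 1, length(s), n_univ - length(s), n_hits,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
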