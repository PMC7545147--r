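#' Rule-based chromatin states and transition matrices
#'
#' A fixed nine-state vocabulary assigned deterministically from the binary
#' presence of the six core histone marks, a majority-vote group state with
#' an activity-precedence tie-break, and the normal-versus-tumor state
#' transition matrix whose cells are percentages of all differential
#' regions (summing to 100).
#'
#' @name chromatin-states
NULL

# Activity precedence (most active first); also the tie-break order.
.STATES <- c("ActiveProm", "WeakProm", "BivalentProm", "ActiveEnh",
             "WeakEnh", "Transcription", "PolycombRepr", "Heterochrom",
             "LowSignal")

#' The chromatin-state vocabulary
#'
#' Nine labels in activity-precedence order (most active first). The order
#' is the total precedence used for tie-breaking in [group_state()].
#'
#' @return Character vector of the nine state labels.
#' @export
state_vocabulary <- function() .STATES

#' Assign a chromatin state from binary mark presence
#'
#' A deterministic, total rule table over the six-mark presence vector
#' (order: H3K4me3, H3K27ac, H3K4me1, H3K36me3, H3K27me3, H3K9me3):
#' H3K4me3 with H3K27me3 is a bivalent promoter; otherwise H3K4me3 with
#' H3K27ac an active promoter; otherwise H3K4me3 a weak promoter; otherwise
#' H3K4me1 with H3K27ac an active enhancer; otherwise H3K4me1 a weak
#' enhancer; otherwise H3K36me3 transcription; otherwise H3K27me3 Polycomb
#' repression; otherwise H3K9me3 heterochromatin; otherwise low signal.
#'
#' @param presence A logical vector of length 6 in the order above, or a
#'   matrix with 6 such columns (one row per region/sample).
#' @return A character vector of state labels (length 1 for a vector input,
#'   `nrow(presence)` for a matrix).
#' @export
assign_state <- function(presence) {
  if (is.vector(presence)) presence <- matrix(presence, nrow = 1)
  stopifnot(ncol(presence) == 6, is.logical(presence) ||
              all(presence %in% c(0, 1)))
  p <- matrix(as.logical(presence), ncol = 6)
  k4me3 <- p[, 1]; k27ac <- p[, 2]; k4me1 <- p[, 3]
  k36 <- p[, 4]; k27me3 <- p[, 5]; k9 <- p[, 6]
  out <- rep("LowSignal", nrow(p))
  out[k9] <- "Heterochrom"
  out[k27me3] <- "PolycombRepr"
  out[k36] <- "Transcription"
  out[k4me1] <- "WeakEnh"
  out[k4me1 & k27ac] <- "ActiveEnh"
  out[k4me3] <- "WeakProm"
  out[k4me3 & k27ac] <- "ActiveProm"
  out[k4me3 & k27me3] <- "BivalentProm"
  out
}

#' Majority state across the samples of one group
#'
#' The most frequent state wins; ties are broken by activity precedence
#' (the more active state in [state_vocabulary()] order wins).
#'
#' @param states Character vector of per-sample state labels for one region,
#'   or a matrix (regions x samples).
#' @return A character vector of group states.
#' @export
group_state <- function(states) {
  if (is.matrix(states)) return(apply(states, 1, group_state))
  if (!length(states)) stop("need >= 1 sample state")
  bad <- setdiff(unique(states), .STATES)
  if (length(bad)) stop("unknown state label(s): ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(states, levels = .STATES))
  names(counts)[which.max(counts)]  # which.max takes the first (most active)
}

#' Chromatin-state transition matrix
#'
#' Cell (tumor state, normal state) holds 100 x count / total regions, so
#' the whole matrix sums to 100: rows are the tumor group states, columns
#' the normal group states.
#'
#' @param normal_states,mm_states Character vectors of per-region group
#'   states (equal non-zero length).
#' @return A 9 x 9 numeric matrix of percentages (rows: tumor; columns:
#'   normal).
#' @export
transition_matrix <- function(normal_states, mm_states) {
  if (!length(normal_states)) stop("empty region set")
  if (length(normal_states) != length(mm_states))
    stop("state vectors must have equal length")
  tab <- table(factor(mm_states, levels = .STATES),
               factor(normal_states, levels = .STATES))
  m <- 100 * unclass(tab) / length(normal_states)
  dimnames(m) <- list(mm = .STATES, normal = .STATES)
  m
}

#' Per-sample mark presence over regions
#'
#' Builds the 6-mark presence matrix ([assign_state()] input order) for a
#' set of regions in one sample, given that sample's per-mark peak sets.
#' A mark is present when at least `min_bp` bases of the region overlap the
#' sample's peaks for that mark; marks with no peak data count as absent.
#'
#' @param regions A `GRanges`.
#' @param mark_peaks Named list of peak `GRanges` keyed by mark label
#'   (subset of [histone_marks()]).
#' @param min_bp Minimum overlap (default 1).
#' @return A logical matrix, regions x 6 marks, columns in assignment order.
#' @export
mark_presence <- function(regions, mark_peaks, min_bp = 1L) {
  order6 <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K36me3", "H3K27me3",
              "H3K9me3")
  pres <- matrix(FALSE, nrow = length(regions), ncol = 6,
                 dimnames = list(NULL, order6))
  for (mk in intersect(order6, names(mark_peaks)))
    pres[, mk] <- count_overlaps(regions, mark_peaks[[mk]],
                                 min_bp = min_bp)$hit
  pres
}
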