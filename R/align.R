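#' Alignment scoring parameters
#'
#' Scoring scheme for global (Needleman-Wunsch) alignment of reads to
#' amplicon or allele references, with affine gap costs: a gap run of length
#' L costs \code{gap_open + (L - 1) * gap_extend}. The defaults favour a
#' single long indel over scattered mismatches, which matches the structure
#' of Cas9 repair outcomes: one 1-bp gap (-20) is costlier than two
#' mismatches (-8) but a 10-bp deletion (-29) is far cheaper than ten
#' mismatches (-40).
#'
#' @param match match score (default +5).
#' @param mismatch mismatch penalty (default -4). \code{N} in a read is
#'   scored as a mismatch against every symbol, including another \code{N}.
#' @param gap_open score of the first gapped position in a run (default -20).
#' @param gap_extend score of each subsequent gapped position (default -1).
#' @return A list of class \code{"alignment_params"}.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = -20, gap_extend = -1) {
  stopifnot(match > 0, mismatch < match,
            gap_open <= gap_extend, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global pairwise alignment of a read against a reference
#'
#' Optimal global alignment under affine gap scoring (Gotoh algorithm),
#' with deterministic traceback: on score ties a mismatch is preferred over
#' a gap, and a deletion (gap in the read) over an insertion (gap in the
#' reference), so aligned strings and event lists are stable across runs.
#'
#' @param read,ref non-empty DNA strings over \code{A,C,G,T,N}.
#' @param params an [alignment_params()] object.
#' @return A list with \code{aligned_read}, \code{aligned_ref} (equal-length
#'   strings over \code{A,C,G,T,N,-}), \code{score}, and \code{events}, a
#'   data frame of runs with columns \code{op} (\code{M} match, \code{X}
#'   mismatch, \code{I} insertion relative to the reference, \code{D}
#'   deletion from the read), \code{ref_start} (0-based; for \code{I} the
#'   index of the reference base the insertion precedes) and \code{length}.
#' @export
#' @examples
#' global_align("ACGT", "AGT")$score  # one 1-bp insertion: 3*5 - 20 = -5
global_align <- function(read, ref, params = alignment_params()) {
  stopifnot(is.character(read), length(read) == 1L, nzchar(read),
            is.character(ref), length(ref) == 1L, nzchar(ref))
  r <- .nw_align_pair(read, ref, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  r$events <- alignment_events(r$aligned_read, r$aligned_ref)
  structure(r, class = "pairwise_alignment")
}

#' Event list of an alignment
#'
#' Collapses a pair of aligned strings into a run-length event list.
#'
#' @param aligned_read,aligned_ref equal-length aligned strings over
#'   \code{A,C,G,T,N,-}.
#' @return Data frame with columns \code{op}, \code{ref_start} (0-based)
#'   and \code{length}; see [global_align()].
#' @export
alignment_events <- function(aligned_read, aligned_ref) {
  a <- strsplit(aligned_read, "")[[1L]]
  r <- strsplit(aligned_ref, "")[[1L]]
  stopifnot(length(a) == length(r))
  op <- ifelse(r == "-", "I",
        ifelse(a == "-", "D",
        ifelse(a == r & a != "N", "M", "X")))
  refpos0 <- cumsum(r != "-") - 1L
  rl <- rle(op)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ref_start <- ifelse(rl$values == "I",
                      refpos0[starts] + 1L, refpos0[starts])
  data.frame(op = rl$values, ref_start = as.integer(ref_start),
             length = rl$lengths, stringsAsFactors = FALSE)
}

# Maximum number of mismatches for which a gapless alignment of an
# equal-length read is provably optimal: any gapped global alignment of
# equal-length sequences carries at least one insertion and one deletion
# run, bounding its score by match*(L-1) + 2*gap_open; the gapless score
# match*L - (match - mismatch)*m beats (or, at equality, wins the
# mismatch-over-gap tie-break against) that bound whenever
# (match - mismatch)*m <= match - 2*gap_open.
.gapless_max_mismatch <- function(params) {
  floor((params$match - 2 * params$gap_open) /
          (params$match - params$mismatch))
}

# Hamming distances of equal-length reads against a reference string.
.hamming_to_ref <- function(reads, ref) {
  if (length(reads) == 0L) return(integer(0))
  L <- nchar(ref)
  stopifnot(all(nchar(reads) == L))
  mat <- matrix(unlist(strsplit(reads, "")), ncol = L, byrow = TRUE)
  refc <- strsplit(ref, "")[[1L]]
  as.integer(rowSums(mat != rep(refc, each = nrow(mat)) | mat == "N"))
}

# Batch global alignment with a gapless fast path for near-identical
# equal-length reads (the overwhelming majority of unedited amplicon reads).
.align_batch <- function(reads, ref, params = alignment_params()) {
  n <- length(reads)
  L <- nchar(ref)
  ar <- af <- character(n)
  sc <- numeric(n)
  eq <- nchar(reads) == L
  fast <- logical(n)
  if (any(eq)) {
    ham <- .hamming_to_ref(reads[eq], ref)
    ok <- ham <= .gapless_max_mismatch(params)
    fast[eq] <- ok
    idx <- which(eq)[ok]
    ar[idx] <- reads[idx]
    af[idx] <- ref
    sc[idx] <- params$match * (L - ham[ok]) + params$mismatch * ham[ok]
  }
  slow <- which(!fast)
  if (length(slow)) {
    res <- .nw_align_batch(reads[slow], ref, params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
    ar[slow] <- res$aligned_read
    af[slow] <- res$aligned_ref
    sc[slow] <- res$score
  }
  list(aligned_read = ar, aligned_ref = af, score = sc, gapless = fast)
}

#' Best-scoring allele for a read
#'
#' Aligns a read globally against every candidate allele amplicon and
#' returns the index of the unique best-scoring allele; an exact score tie
#' across the top candidates yields \code{NA} (ambiguous).
#'
#' @param read a DNA string.
#' @param alleles character vector of two or more allele amplicon sequences.
#' @param params an [alignment_params()] object.
#' @return List with \code{allele} (integer index or \code{NA} for
#'   ambiguous) and \code{score} (the best score).
#' @export
best_allele_alignment <- function(read, alleles, params = alignment_params()) {
  stopifnot(length(alleles) >= 2L)
  sc <- vapply(alleles, function(a)
    .align_batch(read, a, params)$score, numeric(1), USE.NAMES = FALSE)
  top <- max(sc)
  hits <- which(abs(sc - top) < 1e-9)
  list(allele = if (length(hits) == 1L) hits else NA_integer_, score = top)
}
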