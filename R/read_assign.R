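#' Assign standard-length reads by direct SNV lookup
#'
#' For reads whose length equals the reference amplicon, the bases at the
#' SNV columns are read off directly; a read whose tuple exactly equals one
#' allele's phase is assigned to that allele. Reads matching no phase
#' (masked or non-reference bases at the discriminating columns) are
#' ambiguous.
#'
#' @param reads character vector of reads, all of reference length.
#' @param snv_positions 0-based SNV positions.
#' @param phases character vector of allele phases (in allele order).
#' @return Integer vector of allele indices, \code{NA} for ambiguous reads.
#' @export
assign_standard <- function(reads, snv_positions, phases) {
  if (length(reads) == 0L) return(integer(0))
  tuples <- do.call(paste0, lapply(snv_positions + 1L, function(p)
    substr(reads, p, p)))
  match(tuples, phases)
}

#' Assign diverse-length reads by alignment
#'
#' Each read is aligned globally against every allele amplicon; the unique
#' best-scoring allele wins, an exact top-score tie leaves the read
#' ambiguous.
#'
#' @param reads character vector of read sequences.
#' @param allele_seqs character vector of allele amplicons (length >= 2).
#' @param params an [alignment_params()] object.
#' @return List with \code{allele} (integer, \code{NA} = ambiguous),
#'   \code{scores} (reads x alleles matrix) and \code{alignments} (per
#'   allele, the batch alignment of all reads, for downstream reuse).
#' @export
assign_length_variant <- function(reads, allele_seqs,
                                  params = alignment_params()) {
  n <- length(reads)
  A <- length(allele_seqs)
  stopifnot(A >= 2L)
  if (n == 0L) {
    return(list(allele = integer(0),
                scores = matrix(numeric(0), 0L, A),
                alignments = lapply(seq_len(A), function(a) NULL)))
  }
  alns <- lapply(allele_seqs, function(s) .align_batch(reads, s, params))
  scores <- vapply(alns, `[[`, numeric(n), "score")
  scores <- matrix(scores, nrow = n, ncol = A)
  allele <- apply(scores, 1L, function(s) {
    hits <- which(abs(s - max(s)) < 1e-9)
    if (length(hits) == 1L) hits else NA_integer_
  })
  list(allele = as.integer(allele), scores = scores, alignments = alns)
}

# Sum of per-column alignment scores inside windows of +/- half_width
# around each given reference position. Gap runs pay gap_open on their
# first column inside the alignment (not per window) and gap_extend after.
.window_scores <- function(aligned_read, aligned_ref, positions0,
                           half_width, params) {
  a <- strsplit(aligned_read, "")[[1L]]
  r <- strsplit(aligned_ref, "")[[1L]]
  gap <- a == "-" | r == "-"
  new_run <- gap & !c(FALSE, gap[-length(gap)])
  colsc <- ifelse(gap, ifelse(new_run, params$gap_open, params$gap_extend),
                  ifelse(a == r & a != "N", params$match, params$mismatch))
  refpos0 <- cumsum(r != "-") - 1L
  colpos <- ifelse(r == "-", refpos0 + 1L, refpos0)
  vapply(positions0, function(p) {
    if (is.na(p)) return(NA_real_)
    sum(colsc[colpos >= p - half_width & colpos <= p + half_width])
  }, numeric(1))
}

#' Rescue ambiguous reads via linked SNVs
#'
#' For sites with two or more SNVs, an ambiguous read can often still be
#' placed using its non-masked ("anchor") SNVs: around each SNV a local
#' alignment window of \code{half_width} bp is scored against every allele
#' independently, and the read is rescued to the allele whose summed
#' window scores strictly dominate. An SNV is masked for a read when its
#' column is deleted in the read's alignment to every allele.
#'
#' @param reads character vector of ambiguous read sequences.
#' @param allele_set an [build_allele_amplicons()] object.
#' @param alignments optional list (per allele) of batch alignments of
#'   \code{reads} to each allele amplicon, as produced by
#'   [assign_length_variant()]; computed when missing.
#' @param half_width window half-width in bp around each SNV (default 5).
#' @param params an [alignment_params()] object.
#' @return Integer vector of allele indices, \code{NA} where the read
#'   remains ambiguous.
#' @export
rescue_multi_snv <- function(reads, allele_set, alignments = NULL,
                             half_width = 5L, params = alignment_params()) {
  n <- length(reads)
  if (n == 0L) return(integer(0))
  k <- length(allele_set$snv_positions)
  if (k < 2L) return(rep(NA_integer_, n))   # no linked SNV to rely on
  A <- nrow(allele_set$alleles)
  if (is.null(alignments)) {
    alignments <- lapply(allele_set$alleles$seq, function(s)
      .align_batch(reads, s, params))
  }
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    # masked = the SNV column is gapped in the alignment to every allele
    masked <- rep(TRUE, k)
    wsc <- matrix(NA_real_, A, k)
    for (a in seq_len(A)) {
      pos_a <- allele_set$snv_pos_allele[[a]]
      ar <- alignments[[a]]$aligned_read[i]
      af <- alignments[[a]]$aligned_ref[i]
      wsc[a, ] <- .window_scores(ar, af, pos_a, half_width, params)
      rc <- strsplit(ar, "")[[1L]]
      fc <- strsplit(af, "")[[1L]]
      refpos0 <- cumsum(fc != "-") - 1L
      for (s in seq_len(k)) {
        p <- pos_a[s]
        if (!is.na(p)) {
          sym <- rc[refpos0 == p & fc != "-"]
          if (length(sym) && sym[1L] != "-") masked[s] <- FALSE
        }
      }
    }
    use <- which(!masked)
    if (length(use) == 0L) next
    tot <- rowSums(wsc[, use, drop = FALSE], na.rm = TRUE)
    top <- which(abs(tot - max(tot)) < 1e-9)
    if (length(top) == 1L) out[i] <- top
  }
  out
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly allocate ambiguous reads by observed proportions
#'
#' Multinomial draw of an allele for each remaining ambiguous read, under
#' the proportions observed among the same sample's confidently assigned
#' reads (falling back to the mock allele frequencies when no confident
#' read exists). Reproducible under a fixed seed.
#'
#' @param n number of ambiguous reads.
#' @param proportions non-negative weights per allele, not all zero.
#' @param seed integer RNG seed.
#' @return Integer vector of length \code{n} with allele indices.
#' @export
random_assign <- function(n, proportions, seed) {
  stopifnot(length(proportions) >= 1L, all(proportions >= 0),
            sum(proportions) > 0)
  if (n == 0L) return(integer(0))
  .with_seed(seed, sample.int(length(proportions), n, replace = TRUE,
                              prob = proportions))
}

#' Ambiguity gate
#'
#' Sites where half or more of the reads needed random allocation are too
#' ambiguous to quantify confidently: only sites with strictly less than
#' the threshold fraction of random reads are kept.
#'
#' @param random_fraction fraction of reads assigned randomly, in [0, 1].
#' @param threshold gate threshold (default 0.5).
#' @return \code{TRUE} (keep) or \code{FALSE} (discard).
#' @export
ambiguity_gate <- function(random_fraction, threshold = 0.5) {
  stopifnot(random_fraction >= 0, random_fraction <= 1)
  random_fraction < threshold
}

#' Medoid of a set of activity vectors
#'
#' Index of the row minimizing the summed L1 distance to all other rows;
#' ties are broken toward the lowest row index.
#'
#' @param mat numeric matrix, one row per iteration, one column per allele.
#' @return Integer row index of the medoid.
#' @export
medoid_index <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  m <- mat
  m[is.na(m)] <- 0
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  unname(which.min(rowSums(d)))
}
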