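SYMBOLS5 <- c("A", "C", "G", "T", "-")

#' Split reads into modal-length and diverse-length sets
#'
#' Read length at a site is determined by the majority of the reads; reads
#' with any other length ("diverse-length" reads) are excluded from SNV
#' profiling and assigned to alleles later by alignment. A tie between modal
#' lengths is broken toward the longer length.
#'
#' @param reads character vector of read sequences.
#' @return List with \code{kept}, \code{diverse} (the sequences),
#'   \code{kept_idx}, \code{diverse_idx} (indices into \code{reads}) and
#'   \code{modal_length}.
#' @export
filter_majority_length <- function(reads) {
  stopifnot(length(reads) >= 1L)
  len <- nchar(reads)
  tab <- table(len)
  best <- as.integer(names(tab)[tab == max(tab)])
  modal <- max(best)               # tie -> longer length
  keep <- len == modal
  list(kept = reads[keep], diverse = reads[!keep],
       kept_idx = which(keep), diverse_idx = which(!keep),
       modal_length = modal)
}

# Per-read symbol matrix over amplicon columns: each row holds the aligned
# symbol of one read at every reference position (base, '-' for a deletion,
# 'N' for an undetermined base). Inserted read bases create no columns.
.symbol_matrix <- function(reads, amplicon, params = alignment_params()) {
  ab <- .align_batch(reads, amplicon, params)
  L <- nchar(amplicon)
  n <- length(reads)
  M <- matrix("N", n, L)
  if (any(ab$gapless)) {
    M[ab$gapless, ] <- matrix(unlist(strsplit(ab$aligned_read[ab$gapless], "")),
                              ncol = L, byrow = TRUE)
  }
  for (i in which(!ab$gapless)) {
    a <- strsplit(ab$aligned_read[i], "")[[1L]]
    r <- strsplit(ab$aligned_ref[i], "")[[1L]]
    M[i, ] <- a[r != "-"]
  }
  M
}

#' Per-position nucleotide profiles from mock reads
#'
#' Globally aligns every kept (modal-length) mock read to the reference
#' amplicon and tabulates, per reference position, the observed symbols
#' over \code{A, C, G, T, -}. A \code{-} is counted where the alignment
#' places a deletion; inserted read bases do not create columns; \code{N}
#' is excluded from the counts and the frequencies.
#'
#' @param reads character vector of kept mock read sequences.
#' @param amplicon reference amplicon string.
#' @param params an [alignment_params()] object.
#' @return Object of class \code{"position_profiles"}: a list with
#'   \code{counts} (5 x L matrix), \code{freq} (5 x L, columns summing to 1
#'   where depth > 0), \code{depth} (non-N count per column),
#'   \code{symbols} (the per-read symbol matrix), \code{n_reads} and
#'   \code{amplicon}.
#' @export
position_profiles <- function(reads, amplicon, params = alignment_params()) {
  stopifnot(length(reads) >= 1L)
  M <- .symbol_matrix(reads, amplicon, params)
  L <- ncol(M)
  counts <- t(vapply(SYMBOLS5, function(s) colSums(M == s),
                     numeric(L)))
  depth <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(depth, 1L), "/")
  structure(list(counts = counts, freq = freq, depth = depth,
                 symbols = M, n_reads = nrow(M), amplicon = amplicon),
            class = "position_profiles")
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' \eqn{H(p) = -\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 := 0}. Base 2 is
#' used throughout the package: the default SNV threshold of 0.72 bits is
#' the entropy of a 20/80 split, \eqn{H(0.2, 0.8) = 0.7219}.
#'
#' @param freqs non-negative frequency vector summing to 1.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(freqs) {
  stopifnot(all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  -sum(p * log2(p))
}

#' Call SNV positions from position profiles
#'
#' A position is called an SNV when the Shannon entropy of its symbol
#' distribution over \code{A, C, G, T, -} is at least \code{tau} bits.
#' Columns where more than half of the reads carry \code{N} are skipped.
#' Called columns whose polymorphism involves the gap symbol are flagged
#' \code{gap_allele}.
#'
#' @param profiles a [position_profiles()] object.
#' @param tau entropy threshold in bits (default 0.72, a 20/80 split).
#' @return Data frame of called positions, sorted by position: columns
#'   \code{position} (0-based), \code{entropy}, \code{bases}
#'   (observed symbols, descending frequency, as a string),
#'   \code{top_freq}, and \code{gap_allele}.
#' @export
call_snvs <- function(profiles, tau = 0.72) {
  stopifnot(inherits(profiles, "position_profiles"),
            tau > 0, tau <= log2(5) + 1e-12)
  L <- ncol(profiles$counts)
  n_dominated <- profiles$depth < profiles$n_reads / 2
  ent <- vapply(seq_len(L), function(j) {
    if (n_dominated[j] || profiles$depth[j] == 0) return(NA_real_)
    shannon_entropy(profiles$freq[, j])
  }, numeric(1))
  called <- which(!is.na(ent) & ent >= tau)
  if (length(called) == 0L) {
    return(data.frame(position = integer(0), entropy = numeric(0),
                      bases = character(0), top_freq = numeric(0),
                      gap_allele = logical(0)))
  }
  rows <- lapply(called, function(j) {
    f <- profiles$freq[, j]
    ord <- order(-f, SYMBOLS5)
    nz <- ord[f[ord] > 0]
    data.frame(position = j - 1L, entropy = ent[j],
               bases = paste(SYMBOLS5[nz], collapse = ""),
               top_freq = f[nz[1L]],
               gap_allele = "-" %in% SYMBOLS5[nz][f[nz] >= 0.01],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}
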