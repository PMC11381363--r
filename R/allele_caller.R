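#' Enumerate phased SNV combinations from mock reads
#'
#' Every kept mock read contributes the tuple of its aligned symbols at the
#' called SNV columns (its phase). Phases containing \code{N} are discarded.
#' A phase is retained when it reaches the frequency floor or the read
#' support floor; frequencies are renormalized over the retained phases.
#' With k SNV positions the possible phase space over \code{A,C,G,T,-}
#' lies between 2^k (each column biallelic) and 5^k.
#'
#' @param symbols per-read symbol matrix from [position_profiles()]
#'   (\code{$symbols}), or a [position_profiles()] object.
#' @param snv_positions integer vector of 0-based SNV positions.
#' @param min_freq frequency floor (default 0.01).
#' @param min_reads read-support floor (default 5).
#' @return Data frame with columns \code{phase}, \code{count}, \code{freq}
#'   (renormalized), sorted by descending frequency (ties broken
#'   alphabetically by phase for determinism). Zero rows if every phase was
#'   filtered.
#' @export
enumerate_phases <- function(symbols, snv_positions,
                             min_freq = 0.01, min_reads = 5) {
  if (inherits(symbols, "position_profiles")) symbols <- symbols$symbols
  stopifnot(length(snv_positions) >= 1L,
            all(snv_positions >= 0), all(snv_positions < ncol(symbols)))
  cols <- symbols[, snv_positions + 1L, drop = FALSE]
  phase <- apply(cols, 1L, paste, collapse = "")
  phase <- phase[!grepl("N", phase, fixed = TRUE)]
  if (length(phase) == 0L) {
    return(data.frame(phase = character(0), count = integer(0),
                      freq = numeric(0)))
  }
  tab <- table(phase)
  count <- as.integer(tab)
  freq <- count / sum(count)
  keep <- freq >= min_freq | count >= min_reads
  out <- data.frame(phase = names(tab)[keep], count = count[keep],
                    freq = freq[keep], stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$freq <- out$count / sum(out$count)
    out <- out[order(-out$freq, out$phase), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Coverage-entropy score of a candidate allele number
#'
#' For sorted phase frequencies \eqn{f_1 \ge \ldots \ge f_n}, keeping the
#' top \eqn{\nu} phases covers \eqn{C(\nu) = \sum_{i \le \nu} f_i} of the
#' reads, and their balance is the entropy of the renormalized top-\eqn{\nu}
#' frequencies. The entropy is normalized by \eqn{\log_2 \nu} to [0, 1];
#' without this normalization the product objective is non-decreasing in
#' \eqn{\nu} and its argmax degenerates to "all observed phases".
#' The reported score is \eqn{C(\nu)^{w_C} \cdot H_{norm}(\nu)^{w_H}}.
#'
#' @param freqs phase frequencies sorted in descending order, summing to 1.
#' @param nu candidate allele count, \code{2 <= nu <= length(freqs)}.
#' @param w_C,w_H coverage and entropy exponents (defaults 1/10 and 9/10;
#'   they must sum to 1).
#' @return List with \code{C}, \code{H_norm} and \code{score}.
#' @export
allele_score <- function(freqs, nu, w_C = 1 / 10, w_H = 9 / 10) {
  stopifnot(abs(w_C + w_H - 1) < 1e-9,
            nu >= 2L, nu <= length(freqs),
            !is.unsorted(rev(freqs)))
  C <- sum(freqs[seq_len(nu)])
  H_norm <- shannon_entropy(freqs[seq_len(nu)] / C) / log2(nu)
  list(C = C, H_norm = H_norm, score = C^w_C * H_norm^w_H)
}

#' Select the number of alleles at a site
#'
#' Exhaustive scan of the coverage-entropy objective over candidate allele
#' numbers \eqn{\nu \in [2, \min(n, max\_alleles)]}; the selected
#' \eqn{n^*} is the argmax, with ties broken toward the smaller \eqn{\nu}
#' (parsimony). Fewer than two retained phases yield \code{n_star = 1}
#' (single-allele site).
#'
#' @inheritParams allele_score
#' @param max_alleles scan cap (default 10).
#' @return List with \code{n_star} and \code{candidates}, a data frame of
#'   \code{nu}, \code{C}, \code{H_norm}, \code{score} for every scanned
#'   \eqn{\nu}.
#' @export
select_allele_number <- function(freqs, w_C = 1 / 10, w_H = 9 / 10,
                                 max_alleles = 10L) {
  n <- length(freqs)
  if (n < 2L) return(list(n_star = 1L, candidates = NULL))
  nus <- 2L:min(n, max_alleles)
  cand <- do.call(rbind, lapply(nus, function(nu) {
    s <- allele_score(freqs, nu, w_C, w_H)
    data.frame(nu = nu, C = s$C, H_norm = s$H_norm, score = s$score)
  }))
  list(n_star = cand$nu[which.max(cand$score)], candidates = cand)
}

#' Build allele amplicons from selected phases
#'
#' Substitutes each selected phase's bases into the reference amplicon at
#' the SNV columns (a \code{-} phase symbol deletes that position), yielding
#' one amplicon per allele, all pairwise distinct. Per-allele coordinates of
#' the SNV columns and of the cut site are adjusted for phase deletions.
#'
#' @param amplicon reference amplicon string.
#' @param snv_positions 0-based SNV positions.
#' @param phases data frame from [enumerate_phases()] restricted to the
#'   selected alleles (columns \code{phase}, \code{freq}, optionally
#'   \code{count}).
#' @param cut_position 0-based cut position on the reference, or \code{NA}.
#' @return Object of class \code{"allele_set"}: a list with \code{alleles}
#'   (data frame: \code{allele}, \code{phase}, \code{freq}, \code{seq}),
#'   \code{snv_positions}, \code{snv_pos_allele} (per-allele 0-based SNV
#'   coordinates, \code{NA} where the phase deletes the column),
#'   \code{cut_allele} (per-allele cut coordinate), \code{reference}.
#' @export
build_allele_amplicons <- function(amplicon, snv_positions, phases,
                                   cut_position = NA_integer_) {
  stopifnot(nrow(phases) >= 1L, !anyDuplicated(phases$phase))
  k <- length(snv_positions)
  stopifnot(all(nchar(phases$phase) == k))
  refc <- strsplit(amplicon, "")[[1L]]
  n <- nrow(phases)
  seqs <- character(n)
  snv_pos_allele <- vector("list", n)
  cut_allele <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ph <- strsplit(phases$phase[i], "")[[1L]]
    x <- refc
    x[snv_positions + 1L] <- ph
    drop <- snv_positions[ph == "-"] + 1L
    keep <- setdiff(seq_along(x), drop)
    seqs[i] <- paste(x[keep], collapse = "")
    # shift coordinates left past deleted columns
    shift <- function(p0) {
      if (is.na(p0)) return(NA_integer_)
      as.integer(p0 - sum((drop - 1L) < p0))
    }
    snv_pos_allele[[i]] <- vapply(snv_positions, function(p0) {
      if ((p0 + 1L) %in% drop) NA_integer_ else shift(p0)
    }, integer(1))
    if (!is.na(cut_position)) cut_allele[i] <- shift(cut_position)
  }
  if (anyDuplicated(seqs))
    stop("two phases yield identical allele amplicons")
  structure(list(
    alleles = data.frame(allele = seq_len(n), phase = phases$phase,
                         freq = phases$freq, seq = seqs,
                         stringsAsFactors = FALSE),
    snv_positions = as.integer(snv_positions),
    snv_pos_allele = snv_pos_allele,
    cut_allele = cut_allele,
    reference = amplicon), class = "allele_set")
}
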