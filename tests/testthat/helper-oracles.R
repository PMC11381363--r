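# Independent oracles used to freeze expected values: these deliberately
# avoid the package's own code paths.

# Exhaustive enumeration of every global alignment of two short sequences,
# scoring gap runs with affine costs; returns the optimal score.
brute_force_align_score <- function(s1, s2, match = 5, mismatch = -4,
                                    gap_open = -20, gap_extend = -1) {
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == "N" || b[j] == "N") mismatch
           else if (a[i] == b[j]) match else mismatch
      rec(i + 1L, j + 1L, "M", sc + s)
    }
    if (i <= length(a))
      rec(i + 1L, j, "I", sc + if (last == "I") gap_extend else gap_open)
    if (j <= length(b))
      rec(i, j + 1L, "D", sc + if (last == "D") gap_extend else gap_open)
  }
  rec(1L, 1L, "start", 0)
  best
}

# Reconstruct the aligned strings from an event list (round-trip check).
rebuild_alignment <- function(events, read, ref) {
  ar <- af <- character(0)
  i <- 1L  # next read base (1-based)
  for (r in seq_len(nrow(events))) {
    op <- events$op[r]
    len <- events$length[r]
    j <- events$ref_start[r] + 1L
    if (op %in% c("M", "X")) {
      ar <- c(ar, substring(read, i, i + len - 1L))
      af <- c(af, substring(ref, j, j + len - 1L))
      i <- i + len
    } else if (op == "I") {
      ar <- c(ar, substring(read, i, i + len - 1L))
      af <- c(af, strrep("-", len))
      i <- i + len
    } else {
      ar <- c(ar, strrep("-", len))
      af <- c(af, substring(ref, j, j + len - 1L))
    }
  }
  list(aligned_read = paste(ar, collapse = ""),
       aligned_ref = paste(af, collapse = ""))
}

# Direct re-evaluation of the allele-number objective over all candidate
# counts (no shared code with select_allele_number).
brute_force_n_star <- function(freqs, w_C = 1 / 10, w_H = 9 / 10) {
  scores <- vapply(2:length(freqs), function(nu) {
    C <- sum(freqs[1:nu])
    f <- freqs[1:nu] / C
    H <- -sum(f[f > 0] * log2(f[f > 0])) / log2(nu)
    C^w_C * H^w_H
  }, numeric(1))
  (2:length(freqs))[which.max(scores)]
}

# Monte-Carlo estimate of P(p1 > p2) under Beta(1,1)-Binomial posteriors.
mc_posterior_exceeds <- function(x1, n1, x2, n2, n_draws = 2e5) {
  mean(stats::rbeta(n_draws, x1 + 1, n1 - x1 + 1) >
         stats::rbeta(n_draws, x2 + 1, n2 - x2 + 1))
}

# Small deterministic site fixture: two alleles differing at two SNVs.
toy_two_allele_site <- function() {
  amp <- paste0("ACGTACGTACGTACGTACGT",            # fwd primer region
                "TTGACCTGAAGGCTCATTCGCGATT",
                "AACCGGTTAACCGGTTAACC",
                "GGCATCGATCGGCTA")
  snvs <- c(25L, 55L)
  phases <- data.frame(phase = c("CG", "TA"), count = c(60L, 40L),
                       freq = c(0.6, 0.4), stringsAsFactors = FALSE)
  stopifnot(substr(amp, 26, 26) == "C")
  build_allele_amplicons(amp, snvs, phases, cut_position = 40L)
}
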