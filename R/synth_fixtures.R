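# Synthetic multiplexed amplicon experiments with known ground truth:
# planted alleles, SNVs, allele-specific indel editing around the cut site,
# and iid per-base substitution sequencing error.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# substitute each base independently with probability eps (always to a
# different base)
.add_sub_errors <- function(seqs, eps) {
  if (eps <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), eps)
  hit <- which(n_err > 0L)
  for (i in hit) {
    x <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(length(x), n_err[i])
    x[pos] <- vapply(x[pos], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
    seqs[i] <- paste(x, collapse = "")
  }
  seqs
}

# plant one indel anchored at the cut site with +/- 2 bp jitter
.apply_indel <- function(seq, cut) {
  jitter <- sample(-2:2, 1L)
  anchor <- cut + jitter
  if (stats::runif(1) < 0.7) {
    len <- sample.int(10L, 1L)
    start <- max(anchor - floor(len / 2), 2L)       # 0-based start
    start <- min(start, nchar(seq) - len - 1L)
    paste0(substr(seq, 1L, start), substr(seq, start + len + 1L, nchar(seq)))
  } else {
    len <- sample.int(3L, 1L)
    ins <- .random_dna(len)
    at <- min(max(anchor, 1L), nchar(seq) - 1L)     # insert before base `at`
    paste0(substr(seq, 1L, at), ins, substr(seq, at + 1L, nchar(seq)))
  }
}

#' Define the ground truth of one synthetic site
#'
#' Builds a random amplicon carrying the given gRNA (with a TGG PAM) and
#' plants SNVs defining the requested alleles. Default geometry mirrors
#' typical multiplex amplicon panels: 150-250 bp amplicons, 20-bp primers
#' at the amplicon ends, SNVs placed away from both the primers and the
#' editing window so that allele identity survives library artifacts and
#' on-target indels.
#'
#' @param site_id site label.
#' @param allele_freqs allele frequencies, summing to 1 (default
#'   \code{c(0.5, 0.5)}).
#' @param editing_rates per-allele probability that a treatment read
#'   carries a cut-site indel (default 0 for all alleles).
#' @param n_snvs number of SNV positions (default: enough to distinguish
#'   the alleles; 0 forces a single-allele site and requires exactly one
#'   allele).
#' @param amplicon_length amplicon length in bp (default 200).
#' @param n_mock,n_tx read counts per sample (defaults 1000).
#' @param error_rate iid per-base substitution error probability epsilon
#'   (default 0.001; must be <= 0.05).
#' @param indel_noise_rate probability that any read (mock or treatment)
#'   carries a spurious 1-bp indel at a uniform position, emulating
#'   PCR/sequencing indel noise (default 0, so the mock-controlled null is
#'   exact).
#' @param pam_snv place one SNV inside the PAM (position of the first G),
#'   disrupting the PAM on every allele whose base differs from the
#'   reference; such alleles default to editing rate 0.
#' @param snv_positions optional explicit 0-based SNV positions.
#' @param phases optional explicit phase strings (one per allele).
#' @param seed RNG seed for amplicon construction.
#' @return List of class \code{"synthetic_truth"} with the resolved
#'   amplicon, gRNA, primers, cut position, SNV positions, phases,
#'   frequencies, and rates.
#' @export
synthetic_truth <- function(site_id = "site1",
                            allele_freqs = c(0.5, 0.5),
                            editing_rates = rep(0, length(allele_freqs)),
                            n_snvs = NULL,
                            amplicon_length = 200L,
                            n_mock = 1000L, n_tx = 1000L,
                            error_rate = 0.001,
                            indel_noise_rate = 0,
                            pam_snv = FALSE,
                            snv_positions = NULL,
                            phases = NULL,
                            seed = 42L) {
  stopifnot(abs(sum(allele_freqs) - 1) < 1e-9,
            length(editing_rates) == length(allele_freqs),
            all(editing_rates >= 0), all(editing_rates <= 1),
            error_rate >= 0, error_rate <= 0.05,
            amplicon_length >= 150L, amplicon_length <= 250L)
  n_alleles <- length(allele_freqs)
  .with_seed(seed, {
    grna <- .random_dna(20L)
    # protospacer placed mid-amplicon; PAM fixed to TGG
    s <- floor(amplicon_length / 2) - 10L
    amp <- strsplit(.random_dna(amplicon_length), "")[[1L]]
    amp[(s + 1L):(s + 20L)] <- strsplit(grna, "")[[1L]]
    amp[(s + 21L):(s + 23L)] <- c("T", "G", "G")
    cut <- s + 17L            # 0-based, 3 bp 5' of the PAM
    if (is.null(snv_positions) && n_alleles > 1L) {
      k <- if (!is.null(n_snvs)) n_snvs else
        max(2L, ceiling(log2(n_alleles)))
      if (!is.null(phases)) k <- nchar(phases[1L])
      # keep SNVs clear of primers (20 bp + margin) and of the editing
      # window extended by the widest planted indel (+/- 20 + 12 bp)
      ok <- setdiff(25L:(amplicon_length - 26L),
                    (cut - 33L):(cut + 33L))
      snv_positions <- sort(sample(ok, if (pam_snv) k - 1L else k))
      if (pam_snv) snv_positions <- sort(c(snv_positions, cut + 4L))
    }
    if (n_alleles > 1L && is.null(phases)) {
      k <- length(snv_positions)
      ref_bases <- amp[snv_positions + 1L]
      j_pam <- if (pam_snv) which(snv_positions == cut + 4L) else integer(0)
      repeat {
        mat <- matrix("", n_alleles, k)
        mat[1L, ] <- ref_bases
        for (i in 2L:n_alleles) {
          mat[i, ] <- vapply(ref_bases, function(b)
            sample(.BASES, 1L), character(1))
          # PAM-SNV sites: every non-reference allele loses the PAM
          if (length(j_pam))
            mat[i, j_pam] <- sample(setdiff(.BASES, ref_bases[j_pam]), 1L)
        }
        ph <- apply(mat, 1L, paste, collapse = "")
        # phases must be distinct and every planted position must be a
        # real SNV (polymorphic across the alleles)
        poly <- vapply(seq_len(k), function(j)
          length(unique(mat[, j])) >= 2L, logical(1))
        if (!anyDuplicated(ph) && all(poly)) break
      }
      phases <- ph
    }
    if (n_alleles == 1L) {
      snv_positions <- integer(0)
      phases <- ""
    }
    amplicon <- paste(amp, collapse = "")
    if (pam_snv) {
      # the PAM-disrupting allele(s): any allele whose base at the PAM SNV
      # differs from the reference G loses its editing
      pam_pos <- cut + 4L
      j <- which(snv_positions == pam_pos)
      disrupted <- substr(phases, j, j) != substr(amplicon, pam_pos + 1L,
                                                  pam_pos + 1L)
      editing_rates[disrupted] <- 0
    }
    allele_seqs <- vapply(phases, function(p) {
      x <- strsplit(amplicon, "")[[1L]]
      if (nchar(p)) x[snv_positions + 1L] <- strsplit(p, "")[[1L]]
      paste(x, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    structure(list(
      site_id = site_id, amplicon = amplicon, grna = grna,
      fwd_primer = substr(amplicon, 1L, 20L),
      rev_primer = .revcomp(substr(amplicon, amplicon_length - 19L,
                                   amplicon_length)),
      cut_position = cut,
      snv_positions = as.integer(snv_positions),
      phases = phases, allele_seqs = allele_seqs,
      allele_freqs = allele_freqs, editing_rates = editing_rates,
      n_mock = as.integer(n_mock), n_tx = as.integer(n_tx),
      error_rate = error_rate, indel_noise_rate = indel_noise_rate,
      seed = as.integer(seed)), class = "synthetic_truth")
  })
}

#' Generate the reads of one synthetic site
#'
#' Mock reads are drawn per allele frequency with iid per-base substitution
#' error; treatment reads additionally carry, with the allele's editing
#' rate, one indel anchored at the cut site with 2 bp of jitter (70%
#' deletions of 1-10 bp, 30% insertions of 1-3 bp). Deterministic under the
#' truth's seed.
#'
#' @param truth a [synthetic_truth()] object.
#' @return List with \code{mock} and \code{tx} read data frames (columns
#'   \code{read_id}, \code{sequence}, \code{quality}), \code{config} (a
#'   one-row panel data frame), and \code{truth} (with an added
#'   \code{$mock_allele}/\code{$tx_allele}/\code{$tx_edited} per-read truth).
#' @export
generate_site <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .with_seed(truth$seed + 1L, {
    A <- length(truth$allele_freqs)
    draw <- function(n, prefix, edited_rates = NULL) {
      allele <- sample.int(A, n, replace = TRUE, prob = truth$allele_freqs)
      seqs <- truth$allele_seqs[allele]
      seqs <- .add_sub_errors(seqs, truth$error_rate)
      edited <- rep(FALSE, n)
      if (!is.null(edited_rates)) {
        edited <- stats::runif(n) < edited_rates[allele]
        for (i in which(edited))
          seqs[i] <- .apply_indel(seqs[i], truth$cut_position)
      }
      if (truth$indel_noise_rate > 0) {
        noisy <- which(stats::runif(n) < truth$indel_noise_rate)
        for (i in noisy) {
          pos <- sample(25L:(nchar(seqs[i]) - 25L), 1L)
          if (stats::runif(1) < 0.5) {
            seqs[i] <- paste0(substr(seqs[i], 1L, pos - 1L),
                              substr(seqs[i], pos + 1L, nchar(seqs[i])))
          } else {
            seqs[i] <- paste0(substr(seqs[i], 1L, pos),
                              sample(.BASES, 1L),
                              substr(seqs[i], pos + 1L, nchar(seqs[i])))
          }
        }
      }
      list(reads = data.frame(
             read_id = sprintf("%s_%s_%06d", prefix, truth$site_id,
                               seq_len(n)),
             sequence = seqs,
             quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE),
           allele = allele, edited = edited)
    }
    mk <- draw(truth$n_mock, "mock")
    tx <- draw(truth$n_tx, "tx", truth$editing_rates)
    truth$mock_allele <- mk$allele
    truth$tx_allele <- tx$allele
    truth$tx_edited <- tx$edited
    config <- data.frame(site_id = truth$site_id, grna = truth$grna,
                         amplicon = truth$amplicon,
                         fwd_primer = truth$fwd_primer,
                         rev_primer = truth$rev_primer,
                         stringsAsFactors = FALSE)
    list(mock = mk$reads, tx = tx$reads, config = config, truth = truth)
  })
}

#' Generate a full synthetic multi-site panel experiment
#'
#' Builds \code{n_sites} synthetic sites cycling through the scenarios the
#' pipeline must handle (no-SNV, single-SNV heterozygous, PAM-SNV with
#' allele-exclusive editing, multi-SNV), each with a distinct random
#' amplicon, and pools the reads. Primer prefixes are checked for
#' collisions (regenerated with a warning if two sites' primers fall
#' within the demultiplexing tolerance).
#'
#' @param n_sites number of sites (>= 1).
#' @param n_mock,n_tx per-site read counts (defaults 500).
#' @param error_rate per-base substitution error (default 0.001).
#' @param editing_rate editing rate planted on edited alleles
#'   (default 0.2).
#' @param seed RNG seed.
#' @param out_dir when given, writes \code{mock.fastq.gz},
#'   \code{tx.fastq.gz}, \code{panel.tsv} and \code{truth.json} there.
#' @return List with \code{config}, \code{mock}, \code{tx} (pooled read
#'   data frames) and \code{truths} (per-site [synthetic_truth()]
#'   records).
#' @export
generate_panel <- function(n_sites, n_mock = 500L, n_tx = 500L,
                           error_rate = 0.001, editing_rate = 0.2,
                           seed = 42L, out_dir = NULL) {
  stopifnot(n_sites >= 1L)
  kinds <- rep(c("no_snv", "single_snv", "pam_snv", "multi_snv"),
               length.out = n_sites)
  truths <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    for (attempt in 1:20) {
      site_seed <- (seed + 101L * i + 100003L * (attempt - 1L)) %% 2147483647L
      tr <- switch(kinds[i],
        no_snv = synthetic_truth(sprintf("site%02d", i),
                                 allele_freqs = 1,
                                 editing_rates = editing_rate,
                                 n_mock = n_mock, n_tx = n_tx,
                                 error_rate = error_rate, seed = site_seed),
        single_snv = synthetic_truth(sprintf("site%02d", i),
                                     allele_freqs = c(0.5, 0.5),
                                     editing_rates = rep(editing_rate, 2),
                                     n_snvs = 1L,
                                     n_mock = n_mock, n_tx = n_tx,
                                     error_rate = error_rate,
                                     seed = site_seed),
        pam_snv = synthetic_truth(sprintf("site%02d", i),
                                  allele_freqs = c(0.5, 0.5),
                                  editing_rates = c(editing_rate,
                                                    editing_rate),
                                  n_snvs = 2L, pam_snv = TRUE,
                                  n_mock = n_mock, n_tx = n_tx,
                                  error_rate = error_rate,
                                  seed = site_seed),
        multi_snv = synthetic_truth(sprintf("site%02d", i),
                                    allele_freqs = c(0.4, 0.35, 0.25),
                                    editing_rates = rep(editing_rate, 3),
                                    n_snvs = 3L,
                                    n_mock = n_mock, n_tx = n_tx,
                                    error_rate = error_rate,
                                    seed = site_seed))
      prior <- vapply(truths[seq_len(i - 1L)], function(t)
        t$fwd_primer, character(1))
      collide <- length(prior) &&
        any(vapply(prior, function(p)
          sum(strsplit(p, "")[[1L]] !=
                strsplit(tr$fwd_primer, "")[[1L]]) <= 4L, logical(1)))
      if (!collide) break
      warning(sprintf("site %d: primer collision, regenerating", i))
    }
    truths[[i]] <- tr
  }
  gens <- lapply(truths, generate_site)
  config <- do.call(rbind, lapply(gens, `[[`, "config"))
  mock <- do.call(rbind, lapply(gens, `[[`, "mock"))
  tx <- do.call(rbind, lapply(gens, `[[`, "tx"))
  rownames(mock) <- rownames(tx) <- NULL
  out <- list(config = config, mock = mock, tx = tx,
              truths = lapply(gens, `[[`, "truth"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(mock, file.path(out_dir, "mock.fastq.gz"))
    write_fastq(tx, file.path(out_dir, "tx.fastq.gz"))
    utils::write.table(config, file.path(out_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(out$truths, function(t)
        unclass(t)[setdiff(names(t),
                           c("mock_allele", "tx_allele", "tx_edited"))]),
      file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
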