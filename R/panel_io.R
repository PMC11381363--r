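#' Pipeline parameters
#'
#' All tunable parameters of the allele-aware quantification pipeline, with
#' their defaults. \code{w_C} and \code{w_H} must sum to 1; \code{tau} is
#' in bits over the 5-symbol alphabet, so \code{0 < tau <= log2(5)}.
#'
#' @param tau SNV entropy threshold in bits (default 0.72, a 20/80 split).
#' @param w_C,w_H coverage and entropy exponents of the allele-number
#'   objective (defaults 1/10 and 9/10).
#' @param window_half_width editing-window half-width in bp around the cut
#'   site (default 20).
#' @param min_mock_reads per-site mock coverage floor (default 100).
#' @param phase_floor_freq,phase_floor_reads phase retention floors
#'   (defaults 0.01 and 5): a phase is kept when it reaches either floor.
#' @param random_iterations number of random-assignment iterations R
#'   (default 11; odd, so medoid ties are rare).
#' @param ci_alpha two-sided CI error rate (default 0.05).
#' @param max_primer_mismatch demultiplexing Hamming tolerance (default 2).
#' @param ambiguity_gate maximum tolerated random-read fraction, strict
#'   (default 0.5).
#' @param seed base RNG seed (default 42).
#' @param rescue_half_width multi-SNV rescue window half-width in bp
#'   (default 5).
#' @param max_alleles cap of the allele-number scan (default 10).
#' @param edit_posterior posterior threshold of the mock-controlled event
#'   classifier (default 0.95).
#' @param imbalance_delta,imbalance_alpha allele-imbalance flag thresholds
#'   (defaults 0.15 and 0.01).
#' @param align an [alignment_params()] object.
#' @return List of class \code{"pipeline_params"}.
#' @export
pipeline_params <- function(tau = 0.72, w_C = 1 / 10, w_H = 9 / 10,
                            window_half_width = 20L, min_mock_reads = 100L,
                            phase_floor_freq = 0.01, phase_floor_reads = 5L,
                            random_iterations = 11L, ci_alpha = 0.05,
                            max_primer_mismatch = 2L, ambiguity_gate = 0.5,
                            seed = 42L, rescue_half_width = 5L,
                            max_alleles = 10L, edit_posterior = 0.95,
                            imbalance_delta = 0.15, imbalance_alpha = 0.01,
                            align = alignment_params()) {
  stopifnot(abs(w_C + w_H - 1) < 1e-9,
            tau > 0, tau <= log2(5) + 1e-12,
            ambiguity_gate >= 0, ambiguity_gate <= 1,
            random_iterations >= 1L)
  structure(list(tau = tau, w_C = w_C, w_H = w_H,
                 window_half_width = as.integer(window_half_width),
                 min_mock_reads = as.integer(min_mock_reads),
                 phase_floor_freq = phase_floor_freq,
                 phase_floor_reads = as.integer(phase_floor_reads),
                 random_iterations = as.integer(random_iterations),
                 ci_alpha = ci_alpha,
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 ambiguity_gate = ambiguity_gate, seed = as.integer(seed),
                 rescue_half_width = as.integer(rescue_half_width),
                 max_alleles = as.integer(max_alleles),
                 edit_posterior = edit_posterior,
                 imbalance_delta = imbalance_delta,
                 imbalance_alpha = imbalance_alpha,
                 align = align), class = "pipeline_params")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Locate the Cas9 cut site of a gRNA on an amplicon
#'
#' The protospacer (or its reverse complement) must occur exactly once on
#' the amplicon; the blunt SpCas9 cut is placed 3 bp 5' of the PAM-proximal
#' protospacer end. Coordinates are 0-based: \code{cut_position} is the
#' index of the first base 3' of the cut on the plus strand.
#'
#' @param grna protospacer sequence (plus-strand orientation of the guide).
#' @param amplicon reference amplicon.
#' @return List with \code{cut_position} (\code{NA} when the guide is
#'   absent or matches more than once), \code{strand}
#'   (\code{"+"}, \code{"-"}, or \code{NA}) and \code{flag} (message).
#' @export
cut_site <- function(grna, amplicon) {
  find_all <- function(pat) {
    hits <- gregexpr(pat, amplicon, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
  }
  plus <- find_all(grna)
  minus <- find_all(.revcomp(grna))
  n_hits <- length(plus) + length(minus)
  if (n_hits == 0L) {
    return(list(cut_position = NA_integer_, strand = NA_character_,
                flag = "no cut site: gRNA absent from amplicon"))
  }
  if (n_hits > 1L) {
    return(list(cut_position = NA_integer_, strand = NA_character_,
                flag = "no cut site: gRNA matches amplicon more than once"))
  }
  k <- nchar(grna)
  if (length(plus)) {
    # protospacer at [s, s+k-1] (0-based s), PAM 3' of it: cut 3 bp upstream
    s <- plus[1L] - 1L
    list(cut_position = s + k - 3L, strand = "+", flag = "")
  } else {
    # protospacer on the minus strand: PAM is 5' of the match in plus
    # coordinates, the PAM-proximal end is the match start
    s <- minus[1L] - 1L
    list(cut_position = s + 3L, strand = "-", flag = "")
  }
}

#' Parse a panel configuration file
#'
#' Tab-delimited, one row per site, with header columns \code{site_id},
#' \code{grna}, \code{amplicon}, \code{fwd_primer}, \code{rev_primer}.
#' The cut position is derived from the gRNA placement ([cut_site()]);
#' sites whose gRNA cannot be placed uniquely are flagged and keep an
#' undefined editing window.
#'
#' @param path path to the TSV file.
#' @return Data frame with the five input columns plus \code{cut_position}
#'   (0-based), \code{strand} and \code{flag}.
#' @export
parse_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("site_id", "grna", "amplicon", "fwd_primer", "rev_primer")
  missing_cols <- setdiff(required, names(cfg))
  if (length(missing_cols))
    stop("config is missing column(s): ", paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(cfg))) {
    bad <- required[!nzchar(trimws(cfg[i, required]))]
    if (length(bad))
      stop(sprintf("config row %d (site '%s'): empty field(s): %s",
                   i, cfg$site_id[i], paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(cfg$site_id))
    stop("duplicate site_id in config: ",
         paste(unique(cfg$site_id[duplicated(cfg$site_id)]), collapse = ", "))
  if (any(grepl("[^ACGT]", cfg$amplicon)))
    stop("amplicon contains non-ACGT characters at site(s): ",
         paste(cfg$site_id[grepl("[^ACGT]", cfg$amplicon)], collapse = ", "))
  cs <- lapply(seq_len(nrow(cfg)), function(i)
    cut_site(cfg$grna[i], cfg$amplicon[i]))
  cfg$cut_position <- vapply(cs, `[[`, integer(1), "cut_position")
  cfg$strand <- vapply(cs, `[[`, character(1), "strand")
  cfg$flag <- vapply(cs, `[[`, character(1), "flag")
  cfg
}

#' Read a FASTQ file
#'
#' Plain or gzip-compressed 4-line FASTQ records; qualities are carried
#' through but never interpreted.
#'
#' @param path FASTQ path (optionally \code{.gz}).
#' @return Data frame with \code{read_id}, \code{sequence}, \code{quality}.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#'
#' @param reads data frame with \code{read_id}, \code{sequence},
#'   \code{quality} (as from [read_fastq()]).
#' @param path output path; a \code{.gz} suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
}

#' Demultiplex reads to panel sites by primer matching
#'
#' A read is assigned to the unique site whose forward primer (forward
#' orientation) or reverse primer (reverse orientation) matches the read's
#' 5' end with at most \code{max_mismatch} mismatches (Hamming distance;
#' \code{N} counts as a mismatch). Reverse-orientation reads are
#' reverse-complemented before downstream use. Reads matching no primer, or
#' two sites equally well, are counted unassigned.
#'
#' @param reads data frame from [read_fastq()].
#' @param sites data frame from [parse_config()].
#' @param max_mismatch Hamming tolerance (default 2).
#' @return List with \code{reads} (named list of per-site read data
#'   frames, orientation-corrected), \code{counts} (named integer vector)
#'   and \code{unassigned} (count). Counts always partition the input.
#' @export
demultiplex <- function(reads, sites, max_mismatch = 2L) {
  n <- nrow(reads)
  S <- nrow(sites)
  mm <- matrix(Inf, n, 2L * S)     # columns: fwd site1..S, then rev site1..S
  prefix_mm <- function(primer) {
    pl <- nchar(primer)
    out <- rep(Inf, n)
    ok <- nchar(reads$sequence) >= pl
    if (any(ok)) {
      out[ok] <- .hamming_to_ref(substr(reads$sequence[ok], 1L, pl), primer)
    }
    out
  }
  for (s in seq_len(S)) {
    mm[, s] <- prefix_mm(sites$fwd_primer[s])
    mm[, S + s] <- prefix_mm(sites$rev_primer[s])
  }
  best <- apply(mm, 1L, min)
  site_idx <- rep(NA_integer_, n)
  orient <- rep("+", n)
  assignable <- which(best <= max_mismatch)
  for (i in assignable) {
    hits <- which(mm[i, ] == best[i])
    hit_sites <- unique(((hits - 1L) %% S) + 1L)
    if (length(hit_sites) > 1L) {
      warning(sprintf("read %s matches %d sites equally well; unassigned",
                      reads$read_id[i], length(hit_sites)))
      next
    }
    site_idx[i] <- hit_sites
    orient[i] <- if (any(hits <= S)) "+" else "-"
  }
  out <- stats::setNames(vector("list", S), sites$site_id)
  for (s in seq_len(S)) {
    sel <- which(site_idx == s)
    df <- reads[sel, , drop = FALSE]
    rev <- orient[sel] == "-"
    if (any(rev)) {
      df$sequence[rev] <- .revcomp(df$sequence[rev])
      df$quality[rev] <- vapply(strsplit(df$quality[rev], ""), function(q)
        paste(rev(q), collapse = ""), character(1))
    }
    rownames(df) <- NULL
    out[[s]] <- df
  }
  counts <- vapply(out, nrow, integer(1))
  stopifnot(sum(counts) + sum(is.na(site_idx)) == n)   # conservation
  list(reads = out, counts = counts, unassigned = sum(is.na(site_idx)))
}

#' Run the full allele-aware quantification pipeline
#'
#' Demultiplexes treatment and mock FASTQ files to the panel sites, calls
#' SNVs and alleles from the mock reads of each site, assigns both
#' samples' reads to the alleles, quantifies per-allele editing activity,
#' and (when \code{out_dir} is given) writes \code{sites_summary.tsv},
#' \code{alleles.fasta} and \code{report.json}.
#'
#' @param config path to a panel TSV, or a data frame from
#'   [parse_config()].
#' @param tx_fastq,mock_fastq FASTQ paths (optionally gzipped).
#' @param out_dir output directory, created if needed; \code{NULL} writes
#'   nothing.
#' @param params a [pipeline_params()] object.
#' @return (Invisibly) a list with \code{summary} (the per-site-per-allele
#'   data frame), \code{sites} (the full \code{site_result} objects) and
#'   \code{demux} (read accounting).
#' @export
run_pipeline <- function(config, tx_fastq, mock_fastq, out_dir = NULL,
                         params = pipeline_params()) {
  sites <- if (is.character(config)) parse_config(config) else config
  if (!file.exists(mock_fastq)) stop("mock FASTQ not found: ", mock_fastq)
  if (!file.exists(tx_fastq)) stop("treatment FASTQ not found: ", tx_fastq)
  tx <- read_fastq(tx_fastq)
  mock <- read_fastq(mock_fastq)
  dm_tx <- demultiplex(tx, sites, params$max_primer_mismatch)
  dm_mock <- demultiplex(mock, sites, params$max_primer_mismatch)

  results <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    site_seed <- (params$seed + 1009L * i) %% 2147483647L
    results[[i]] <- analyze_site(site,
                                 dm_mock$reads[[i]]$sequence,
                                 dm_tx$reads[[i]]$sequence,
                                 params, seed = site_seed)
    if (results[[i]]$status == "insufficient_coverage")
      message(sprintf("site %s: %d mock reads < %d required; skipped",
                      site$site_id, nrow(dm_mock$reads[[i]]),
                      params$min_mock_reads))
  }
  summary <- do.call(rbind, lapply(results, `[[`, "report"))
  rownames(summary) <- NULL
  out <- list(summary = summary, sites = results,
              demux = list(tx = list(counts = dm_tx$counts,
                                     unassigned = dm_tx$unassigned),
                           mock = list(counts = dm_mock$counts,
                                       unassigned = dm_mock$unassigned)))
  if (!is.null(out_dir)) .write_outputs(out, out_dir, params)
  invisible(out)
}

.write_outputs <- function(out, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out$summary,
                     file.path(out_dir, "sites_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- unlist(lapply(out$sites, function(r) {
    if (is.null(r$allele_set)) return(character(0))
    al <- r$allele_set$alleles
    unlist(lapply(seq_len(nrow(al)), function(i) {
      c(sprintf(">%s|allele%d|phase=%s|freq=%.4f",
                r$site_id, i, al$phase[i], al$freq[i]),
        al$seq[i])
    }))
  }))
  writeLines(fa, file.path(out_dir, "alleles.fasta"))
  json <- list(
    params = unclass(params)[setdiff(names(params), "align")],
    alignment = unclass(params$align),
    demux = out$demux,
    sites = lapply(out$sites, function(r) {
      list(site_id = r$site_id, status = r$status,
           n_mock = r$n_mock, n_tx = r$n_tx,
           random_fraction = r$random_fraction,
           gate_keep = r$gate_keep,
           snvs = r$snvs,
           alleles = if (!is.null(r$allele_set)) r$allele_set$alleles,
           selection = r$selection,
           iterations = if (!is.null(r$iterations)) r$iterations,
           medoid = r$medoid,
           report = r$report)
    }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(NULL)
}
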