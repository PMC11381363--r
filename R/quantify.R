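# Per-site analysis: deterministic workup (SNV calling, allele calling,
# read assignment, event caching) followed by seeded quantification
# (random-assignment iterations, medoid and bounds, CIs, imbalance check).

.empty_events <- function() {
  data.frame(read = integer(0), op = character(0),
             ref_start = integer(0), length = integer(0))
}

# Subset a batch alignment result to a set of row positions.
.subset_batch <- function(ab, rows) {
  list(aligned_read = ab$aligned_read[rows],
       aligned_ref = ab$aligned_ref[rows],
       score = ab$score[rows], gapless = ab$gapless[rows])
}

# Assign one sample's reads to the alleles of a site and cache the indel
# events of every read against each allele it can end up on.
.assign_sample <- function(seqs, aset, params) {
  n <- length(seqs)
  A <- nrow(aset$alleles)
  category <- rep(NA_character_, n)
  allele <- rep(NA_integer_, n)
  ev <- rep(list(.empty_events()), A)

  if (A == 1L) {
    category[] <- "DIRECT"
    allele[] <- 1L
    if (n > 0L) {
      ab <- .align_batch(seqs, aset$alleles$seq[1L], params$align)
      ev[[1L]] <- .events_from_batch(ab, seq_len(n))
    }
    return(list(allele = allele, category = category, events = ev))
  }

  ref <- aset$reference
  L <- nchar(ref)
  std <- which(nchar(seqs) == L)
  div <- which(nchar(seqs) != L)
  amb <- integer(0)

  if (length(std)) {
    al <- assign_standard(seqs[std], aset$snv_positions, aset$alleles$phase)
    hit <- !is.na(al)
    allele[std[hit]] <- al[hit]
    category[std[hit]] <- "DIRECT"
    amb <- std[!hit]
  }
  if (length(div)) {
    lv <- assign_length_variant(seqs[div], aset$alleles$seq, params$align)
    hit <- !is.na(lv$allele)
    allele[div[hit]] <- lv$allele[hit]
    category[div[hit]] <- "ALIGNED"
    amb <- c(amb, div[!hit])
    for (a in seq_len(A)) {
      ev[[a]] <- rbind(ev[[a]], .events_from_batch(
        .subset_batch(lv$alignments[[a]], which(hit)), div[hit]))
    }
  }
  # confident DIRECT reads: events against their own allele only
  for (a in seq_len(A)) {
    da <- which(category == "DIRECT" & allele == a)
    if (length(da)) {
      ab <- .align_batch(seqs[da], aset$alleles$seq[a], params$align)
      ev[[a]] <- rbind(ev[[a]], .events_from_batch(ab, da))
    }
  }
  if (length(amb)) {
    alns <- lapply(aset$alleles$seq, function(s)
      .align_batch(seqs[amb], s, params$align))
    for (a in seq_len(A)) {
      ev[[a]] <- rbind(ev[[a]], .events_from_batch(alns[[a]], amb))
    }
    if (length(aset$snv_positions) >= 2L) {
      r <- rescue_multi_snv(seqs[amb], aset, alns,
                            params$rescue_half_width, params$align)
      hit <- !is.na(r)
      allele[amb[hit]] <- r[hit]
      category[amb[hit]] <- "RESCUED"
      amb <- amb[!hit]
    }
    category[amb] <- "RANDOM"   # allele drawn per iteration
  }
  list(allele = allele, category = category, events = ev)
}

#' Deterministic workup of one site
#'
#' Runs the seed-free stages for a single site: modal-length filtering and
#' per-position profiling of the mock reads, entropy-based SNV calling,
#' phase enumeration and allele-number selection, construction of the
#' allele amplicons, and assignment of both samples' reads to the alleles
#' (with cached indel events for quantification). The result feeds
#' [site_quantify()], which adds the seeded random-assignment iterations.
#'
#' @param site a list or one-row data frame with at least \code{site_id},
#'   \code{amplicon} and \code{cut_position} (0-based, \code{NA} when
#'   undefined).
#' @param mock_reads,tx_reads character vectors of read sequences.
#' @param params a [pipeline_params()] object.
#' @return Object of class \code{"site_workup"}.
#' @export
site_workup <- function(site, mock_reads, tx_reads,
                        params = pipeline_params()) {
  site_id <- as.character(site$site_id)
  ref <- as.character(site$amplicon)
  cut <- if (is.null(site$cut_position)) NA_integer_ else
    as.integer(site$cut_position)
  if (is.na(cut) && !is.null(site$grna))
    cut <- cut_site(as.character(site$grna), ref)$cut_position
  out <- list(site_id = site_id, amplicon = ref, cut_position = cut,
              n_mock = length(mock_reads), n_tx = length(tx_reads),
              status = "ok", snvs = NULL, allele_set = NULL,
              selection = NULL, phases = NULL)
  class(out) <- "site_workup"
  if (length(mock_reads) < params$min_mock_reads) {
    out$status <- "insufficient_coverage"
    return(out)
  }

  fl <- filter_majority_length(mock_reads)
  prof <- position_profiles(fl$kept, ref, params$align)
  snvs <- call_snvs(prof, params$tau)
  out$snvs <- snvs

  single <- nrow(snvs) == 0L
  if (!single) {
    ph <- enumerate_phases(prof, snvs$position,
                           params$phase_floor_freq, params$phase_floor_reads)
    out$phases <- ph
    if (nrow(ph) < 2L) {
      single <- TRUE
      warning(sprintf("site %s: all phases filtered; single-allele mode",
                      site_id))
    } else {
      sel <- select_allele_number(ph$freq, params$w_C, params$w_H,
                                  params$max_alleles)
      out$selection <- sel$candidates
      if (sel$n_star < 2L) {
        single <- TRUE
      } else {
        top <- ph[seq_len(sel$n_star), , drop = FALSE]
        top$freq <- top$freq / sum(top$freq)
        aset <- build_allele_amplicons(ref, snvs$position, top, cut)
      }
    }
  }
  if (single) {
    aset <- structure(list(
      alleles = data.frame(allele = 1L, phase = "", freq = 1,
                           seq = ref, stringsAsFactors = FALSE),
      snv_positions = integer(0),
      snv_pos_allele = list(integer(0)),
      cut_allele = cut, reference = ref), class = "allele_set")
  }
  out$allele_set <- aset

  out$mock <- .assign_sample(mock_reads, aset, params)
  out$tx <- .assign_sample(tx_reads, aset, params)
  n_random <- sum(out$mock$category == "RANDOM") +
    sum(out$tx$category == "RANDOM")
  out$random_fraction <- n_random / max(out$n_mock + out$n_tx, 1L)
  out$gate_keep <- ambiguity_gate(out$random_fraction, params$ambiguity_gate)
  if (!out$gate_keep) out$status <- "discarded_ambiguity"
  out
}

# Activity of every allele for one fixed full assignment of both samples.
.quantify_assignment <- function(wk, tx_allele, mock_allele, include_tx,
                                 include_mock, params) {
  A <- nrow(wk$allele_set$alleles)
  w <- params$window_half_width
  activity <- edited <- total <- rep(NA_real_, A)
  for (a in seq_len(A)) {
    cut_a <- wk$allele_set$cut_allele[a]
    T_a <- which(include_tx & tx_allele == a)
    M_a <- which(include_mock & mock_allele == a)
    total[a] <- length(T_a)
    if (length(T_a) == 0L || length(M_a) == 0L || is.na(cut_a)) next
    txe <- wk$tx$events[[a]]
    txe <- txe[txe$read %in% T_a, , drop = FALSE]
    moe <- wk$mock$events[[a]]
    moe <- moe[moe$read %in% M_a, , drop = FALSE]
    txq <- .qualifying_events(txe, cut_a, w)
    moq <- .qualifying_events(moe, cut_a, w)
    as_kind <- function(e) data.frame(
      read = e$read,
      kind = ifelse(e$op == "I", "insertion", "deletion"),
      ref_position = e$ref_start, length = e$length,
      stringsAsFactors = FALSE)
    cls <- classify_edits(as_kind(txq), as_kind(moq),
                          length(T_a), length(M_a),
                          params$edit_posterior)
    if (nrow(cls) == 0L) {
      edited[a] <- 0
    } else {
      noise_keys <- with(cls[cls$verdict == "noise", , drop = FALSE],
                         paste(kind, ref_position, length, sep = ":"))
      kq <- as_kind(txq)
      kq$key <- paste(kq$kind, kq$ref_position, kq$length, sep = ":")
      bad_reads <- unique(kq$read[kq$key %in% noise_keys])
      edited[a] <- length(setdiff(unique(kq$read), bad_reads))
    }
    activity[a] <- 100 * edited[a] / total[a]
  }
  list(activity = activity, edited = edited, total = total)
}

#' Seeded quantification of a worked-up site
#'
#' Quantifies per-allele editing activity from a [site_workup()]: first
#' with the ambiguous (randomly assignable) reads excluded entirely, then
#' over \code{random_iterations} seeded redraws of the random assignment,
#' reporting the medoid activity vector (L1 metric, ties toward the lowest
#' iteration index) with per-allele min/max bounds, a Clopper-Pearson
#' confidence interval at the medoid iteration's counts, and the
#' mock-vs-treatment allele-imbalance flag.
#'
#' @param wk a [site_workup()] object.
#' @param params a [pipeline_params()] object.
#' @param seed integer seed for the random-assignment draws (defaults to
#'   \code{params$seed}).
#' @return Object of class \code{"site_result"}; its \code{$report} is the
#'   per-allele data frame that [run_pipeline()] writes out.
#' @export
site_quantify <- function(wk, params = pipeline_params(),
                          seed = params$seed) {
  aset <- wk$allele_set
  res <- list(site_id = wk$site_id, status = wk$status,
              snvs = wk$snvs, allele_set = aset,
              selection = wk$selection,
              random_fraction = wk$random_fraction,
              gate_keep = wk$gate_keep,
              n_mock = wk$n_mock, n_tx = wk$n_tx, seed = seed)
  class(res) <- "site_result"
  if (wk$status == "insufficient_coverage") {
    res$report <- .site_report_rows(wk, NULL, NULL, NULL, NULL, NULL)
    return(res)
  }
  if (!wk$gate_keep) {
    # too ambiguous to quantify: report assignment accounting only
    res$report <- .site_report_rows(wk, NULL, NULL, NULL, NULL, params)
    return(res)
  }
  A <- nrow(aset$alleles)
  R <- params$random_iterations
  stopifnot(R >= 1L)

  conf_tx <- wk$tx$category != "RANDOM"
  conf_mock <- wk$mock$category != "RANDOM"
  amb_tx <- which(!conf_tx)
  amb_mock <- which(!conf_mock)

  prop_tx <- tabulate(wk$tx$allele[conf_tx], A)
  if (sum(prop_tx) == 0) prop_tx <- aset$alleles$freq
  prop_mock <- tabulate(wk$mock$allele[conf_mock], A)
  if (sum(prop_mock) == 0) prop_mock <- aset$alleles$freq

  # iteration 0: ambiguous reads excluded
  it0 <- .quantify_assignment(wk, wk$tx$allele, wk$mock$allele,
                              conf_tx, conf_mock, params)

  n_amb <- length(amb_tx) + length(amb_mock)
  iters <- vector("list", R)
  if (n_amb == 0L) {
    iters <- rep(list(it0), R)
  } else {
    for (it in seq_len(R)) {
      tx_allele <- wk$tx$allele
      mock_allele <- wk$mock$allele
      .with_seed(seed + it, {
        if (length(amb_tx))
          tx_allele[amb_tx] <- sample.int(A, length(amb_tx), replace = TRUE,
                                          prob = prop_tx)
        if (length(amb_mock))
          mock_allele[amb_mock] <- sample.int(A, length(amb_mock),
                                              replace = TRUE,
                                              prob = prop_mock)
      })
      iters[[it]] <- .quantify_assignment(wk, tx_allele, mock_allele,
                                          rep(TRUE, wk$n_tx),
                                          rep(TRUE, wk$n_mock), params)
    }
  }
  act_mat <- do.call(rbind, lapply(iters, `[[`, "activity"))
  med <- medoid_index(act_mat)
  bounds_low <- apply(act_mat, 2L, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  bounds_high <- apply(act_mat, 2L, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))

  imb <- allele_imbalance_check(aset$alleles$freq,
                                tabulate(wk$tx$allele[conf_tx], A),
                                params$imbalance_delta,
                                params$imbalance_alpha)
  res$iterations <- act_mat
  res$medoid <- med
  res$bounds <- cbind(low = bounds_low, high = bounds_high)
  res$confident <- it0
  res$imbalance <- imb
  res$report <- .site_report_rows(wk, iters[[med]], it0,
                                  res$bounds, imb, params)
  res
}

.site_report_rows <- function(wk, medoid_it, it0, bounds, imb, params) {
  aset <- wk$allele_set
  if (is.null(aset)) {
    return(data.frame(
      site_id = wk$site_id, allele = NA_integer_, phase = NA_character_,
      allele_freq_mock = NA_real_, n_mock = wk$n_mock, n_tx = wk$n_tx,
      n_tx_direct = NA_integer_, n_tx_aligned = NA_integer_,
      n_tx_rescued = NA_integer_, n_tx_random = NA_integer_,
      edited_reads = NA_real_, editing_pct = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      bound_low = NA_real_, bound_high = NA_real_,
      activity_confident = NA_real_, random_fraction = NA_real_,
      imbalance = FALSE, status = wk$status, stringsAsFactors = FALSE))
  }
  A <- nrow(aset$alleles)
  cat_count <- function(asg, cat, a)
    sum(asg$category == cat & !is.na(asg$allele) & asg$allele == a)
  rows <- lapply(seq_len(A), function(a) {
    if (!is.null(medoid_it)) {
      act <- editing_activity(medoid_it$edited[a], medoid_it$total[a],
                              params$ci_alpha)
    } else {
      act <- list(pct = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
    data.frame(
      site_id = wk$site_id, allele = a, phase = aset$alleles$phase[a],
      allele_freq_mock = aset$alleles$freq[a],
      n_mock = sum(wk$mock$allele == a, na.rm = TRUE),
      n_tx = if (!is.null(medoid_it)) medoid_it$total[a] else NA_real_,
      n_tx_direct = cat_count(wk$tx, "DIRECT", a),
      n_tx_aligned = cat_count(wk$tx, "ALIGNED", a),
      n_tx_rescued = cat_count(wk$tx, "RESCUED", a),
      n_tx_random = sum(wk$tx$category == "RANDOM"),
      edited_reads = if (!is.null(medoid_it)) medoid_it$edited[a] else NA_real_,
      editing_pct = act$pct, ci_low = act$ci_low, ci_high = act$ci_high,
      bound_low = if (!is.null(bounds)) bounds[a, "low"] else NA_real_,
      bound_high = if (!is.null(bounds)) bounds[a, "high"] else NA_real_,
      activity_confident = if (!is.null(it0)) it0$activity[a] else NA_real_,
      random_fraction = wk$random_fraction,
      imbalance = if (!is.null(imb)) imb$flag else FALSE,
      status = wk$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyze one site end to end
#'
#' Convenience wrapper: [site_workup()] followed by [site_quantify()].
#'
#' @inheritParams site_workup
#' @param seed seed for the random-assignment iterations.
#' @return A \code{"site_result"}; see [site_quantify()].
#' @export
analyze_site <- function(site, mock_reads, tx_reads,
                         params = pipeline_params(), seed = params$seed) {
  site_quantify(site_workup(site, mock_reads, tx_reads, params),
                params, seed)
}
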