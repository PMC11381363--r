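#' Posterior probability that one binomial rate exceeds another
#'
#' Under independent Beta(1, 1) priors and binomial likelihoods,
#' \eqn{P(p_1 > p_2 \mid x_1/n_1, x_2/n_2)} is computed by numerical
#' integration of the Beta posterior densities.
#'
#' @param x1,n1 successes and trials of the first (treatment) rate.
#' @param x2,n2 successes and trials of the second (mock) rate.
#' @return The posterior exceedance probability in [0, 1].
#' @export
posterior_rate_exceeds <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2, n1 > 0, n2 > 0)
  a1 <- x1 + 1; b1 <- n1 - x1 + 1
  a2 <- x2 + 1; b2 <- n2 - x2 + 1
  lo <- min(stats::qbeta(1e-12, a1, b1), stats::qbeta(1e-12, a2, b2))
  hi <- max(stats::qbeta(1 - 1e-12, a1, b1), stats::qbeta(1 - 1e-12, a2, b2))
  val <- stats::integrate(function(x)
    stats::dbeta(x, a1, b1) * stats::pbeta(x, a2, b2),
    lower = lo, upper = hi, rel.tol = 1e-9, subdivisions = 500L)$value
  min(max(val, 0), 1)
}

# Qualifying indel events: insertions or deletions overlapping the editing
# window [cut - w, cut + w) around the cut site (an insertion is a point
# event at its reference coordinate; boundary insertions at cut + w are
# included since they touch the window edge).
.qualifying_events <- function(events, cut, window_half_width) {
  if (is.null(events) || nrow(events) == 0L || is.na(cut)) {
    return(events[integer(0), , drop = FALSE])
  }
  lo <- cut - window_half_width
  hi <- cut + window_half_width
  keep <- (events$op == "D" &
             events$ref_start < hi & events$ref_start + events$length > lo) |
          (events$op == "I" &
             events$ref_start >= lo & events$ref_start <= hi)
  events[keep, , drop = FALSE]
}

#' Extract candidate edit events near the cut site
#'
#' Aligns reads to their allele amplicon and collects insertion/deletion
#' events overlapping the editing window \code{[cut - w, cut + w)}. A read
#' is a candidate edited read when it carries at least one such event;
#' substitutions never qualify.
#'
#' @param reads character vector of read sequences (one allele's reads).
#' @param allele_seq the allele amplicon.
#' @param cut_position 0-based cut coordinate on the allele amplicon.
#' @param window_half_width half-width in bp of the editing window
#'   (default 20).
#' @param params an [alignment_params()] object.
#' @return List with \code{events}: data frame (\code{read}, \code{kind}
#'   \code{"insertion"}/\code{"deletion"}, \code{ref_position},
#'   \code{length}), and \code{candidate}: logical per read.
#' @export
extract_edit_events <- function(reads, allele_seq, cut_position,
                                window_half_width = 20L,
                                params = alignment_params()) {
  n <- length(reads)
  if (is.na(cut_position)) stop("cut position undefined for this site")
  if (n == 0L) {
    return(list(events = data.frame(read = integer(0), kind = character(0),
                                    ref_position = integer(0),
                                    length = integer(0)),
                candidate = logical(0)))
  }
  ab <- .align_batch(reads, allele_seq, params)
  ev <- .events_from_batch(ab, seq_len(n))
  qual <- .qualifying_events(ev, cut_position, window_half_width)
  events <- data.frame(
    read = qual$read,
    kind = ifelse(qual$op == "I", "insertion", "deletion"),
    ref_position = qual$ref_start,
    length = qual$length, stringsAsFactors = FALSE)
  list(events = events, candidate = seq_len(n) %in% qual$read)
}

# Indel (I/D) events for every non-gapless read of a batch alignment,
# tagged with the read index. Gapless reads have none by construction.
.events_from_batch <- function(ab, read_ids) {
  idx <- which(!ab$gapless)
  if (length(idx) == 0L) {
    return(data.frame(read = integer(0), op = character(0),
                      ref_start = integer(0), length = integer(0)))
  }
  evs <- lapply(idx, function(i) {
    e <- alignment_events(ab$aligned_read[i], ab$aligned_ref[i])
    e <- e[e$op %in% c("I", "D"), , drop = FALSE]
    if (nrow(e)) e$read <- read_ids[i]
    e
  })
  evs <- evs[vapply(evs, nrow, integer(1)) > 0L]
  if (length(evs) == 0L) {
    return(data.frame(read = integer(0), op = character(0),
                      ref_start = integer(0), length = integer(0)))
  }
  do.call(rbind, evs)[, c("read", "op", "ref_start", "length")]
}

#' Classify candidate edit events against the mock background
#'
#' Each distinct event (kind, position, length) observed in the treatment
#' reads of an allele is compared with its rate among the same allele's
#' mock reads under a Beta(1, 1)-Binomial model. An event is called a true
#' edit when the posterior probability that its treatment rate exceeds its
#' mock rate passes \code{threshold}, or when the event is absent from the
#' mock entirely and the allele-level candidate-read rate comparison itself
#' passes the threshold (so that genuine but individually rare repair
#' outcomes at a clearly edited allele are not discarded one by one, while
#' noise events - which recur in the mock - still fail).
#'
#' @param tx_events,mock_events event data frames as returned in
#'   \code{$events} by [extract_edit_events()] for the treatment and mock
#'   reads of one allele.
#' @param n_tx,n_mock total treatment / mock reads of the allele.
#' @param threshold posterior threshold (default 0.95).
#' @return Data frame of distinct treatment events with columns
#'   \code{kind}, \code{ref_position}, \code{length}, \code{tx_count},
#'   \code{mock_count}, \code{posterior}, \code{verdict}
#'   (\code{"edit"}/\code{"noise"}), plus attribute
#'   \code{site_posterior}.
#' @export
classify_edits <- function(tx_events, mock_events, n_tx, n_mock,
                           threshold = 0.95) {
  stopifnot(n_tx > 0, n_mock > 0)
  key <- function(e) paste(e$kind, e$ref_position, e$length, sep = ":")
  if (nrow(tx_events) == 0L) {
    out <- data.frame(kind = character(0), ref_position = integer(0),
                      length = integer(0), tx_count = integer(0),
                      mock_count = integer(0), posterior = numeric(0),
                      verdict = character(0))
    attr(out, "site_posterior") <- NA_real_
    return(out)
  }
  # count reads (not occurrences) per event key
  tx_tab <- unique(tx_events[, c("read", "kind", "ref_position", "length")])
  mock_tab <- unique(mock_events[, c("read", "kind", "ref_position", "length")])
  tx_counts <- table(key(tx_tab))
  mock_counts <- table(key(mock_tab))
  site_post <- posterior_rate_exceeds(
    length(unique(tx_events$read)), n_tx,
    length(unique(mock_events$read)), n_mock)
  keys <- names(tx_counts)
  parts <- strsplit(keys, ":", fixed = TRUE)
  xm <- as.integer(mock_counts[keys])
  xm[is.na(xm)] <- 0L
  xt <- as.integer(tx_counts)
  post <- vapply(seq_along(keys), function(i)
    posterior_rate_exceeds(xt[i], n_tx, xm[i], n_mock), numeric(1))
  verdict <- ifelse(post > threshold |
                      (xm == 0L & site_post > threshold), "edit", "noise")
  out <- data.frame(
    kind = vapply(parts, `[`, character(1), 1L),
    ref_position = as.integer(vapply(parts, `[`, character(1), 2L)),
    length = as.integer(vapply(parts, `[`, character(1), 3L)),
    tx_count = xt, mock_count = xm, posterior = post,
    verdict = verdict, stringsAsFactors = FALSE)
  attr(out, "site_posterior") <- site_post
  out
}

#' Editing activity with a Clopper-Pearson confidence interval
#'
#' Percentage of edited reads with an exact two-sided binomial
#' (Clopper-Pearson) confidence interval, conservative at the near-zero
#' activities typical of off-target sites.
#'
#' @param edited number of edited reads.
#' @param total total reads (> 0; \code{NA} returned otherwise).
#' @param ci_alpha two-sided error rate (default 0.05 for a 0.95 CI).
#' @return List with \code{pct}, \code{ci_low}, \code{ci_high}, all on the
#'   percent scale.
#' @export
editing_activity <- function(edited, total, ci_alpha = 0.05) {
  if (is.na(edited) || is.na(total) || total == 0L) {
    return(list(pct = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  stopifnot(edited >= 0, edited <= total)
  lo <- if (edited == 0) 0 else
    stats::qbeta(ci_alpha / 2, edited, total - edited + 1)
  hi <- if (edited == total) 1 else
    stats::qbeta(1 - ci_alpha / 2, edited + 1, total - edited)
  list(pct = 100 * edited / total, ci_low = 100 * lo, ci_high = 100 * hi)
}

#' Check for allele-frequency imbalance between mock and treatment
#'
#' When the treated sample's confidently assigned reads distribute over the
#' alleles very differently from the mock (e.g. through allele-specific
#' selection during expansion), editing estimates can be deflected. Each
#' allele's treatment share is compared with its mock frequency by an exact
#' two-sided binomial test; the advisory flag is raised when any allele
#' shifts by more than \code{min_delta} with \code{p < alpha}.
#'
#' @param mock_freqs allele frequencies in the mock (summing to 1).
#' @param tx_counts confident treatment read counts per allele.
#' @param min_delta minimum absolute frequency shift (default 0.15).
#' @param alpha significance level (default 0.01).
#' @return List with \code{flag} (logical), \code{table} (per-allele
#'   \code{mock_freq}, \code{tx_freq}, \code{delta}, \code{p_value}) and
#'   \code{message}.
#' @export
allele_imbalance_check <- function(mock_freqs, tx_counts,
                                   min_delta = 0.15, alpha = 0.01) {
  stopifnot(length(mock_freqs) == length(tx_counts))
  if (length(mock_freqs) < 2L || sum(tx_counts) == 0L) {
    return(list(flag = FALSE, table = NULL,
                message = "not applicable (single allele or no reads)"))
  }
  n <- sum(tx_counts)
  tx_freqs <- tx_counts / n
  p <- vapply(seq_along(mock_freqs), function(i) {
    pr <- min(max(mock_freqs[i], 1e-12), 1 - 1e-12)
    stats::binom.test(tx_counts[i], n, p = pr)$p.value
  }, numeric(1))
  delta <- tx_freqs - mock_freqs
  hit <- abs(delta) > min_delta & p < alpha
  list(flag = any(hit),
       table = data.frame(allele = seq_along(mock_freqs),
                          mock_freq = mock_freqs, tx_freq = tx_freqs,
                          delta = delta, p_value = p),
       message = if (any(hit))
         "allele frequencies are imbalanced between mock and treatment; interpret per-allele activities with caution"
       else "balanced")
}
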