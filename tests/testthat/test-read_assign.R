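test_that("standard-length reads are assigned by direct SNV lookup", {
  aset <- toy_two_allele_site()
  amp <- aset$reference
  mk <- function(bases) {
    x <- strsplit(amp, "")[[1]]
    x[aset$snv_positions + 1] <- strsplit(bases, "")[[1]]
    paste(x, collapse = "")
  }
  al <- assign_standard(c(mk("CG"), mk("TA"), mk("CA"), mk("GG")),
                        aset$snv_positions, aset$alleles$phase)
  # exact phase -> allele; mixed or non-reference tuples -> ambiguous
  expect_equal(al, c(1L, 2L, NA, NA))
})

test_that("diverse-length reads are assigned by best alignment, ties ambiguous", {
  aset <- toy_two_allele_site()
  a1 <- aset$alleles$seq[1]
  a2 <- aset$alleles$seq[2]
  # allele 2 read with a 5-bp deletion away from both SNVs (positions 25/55)
  del2 <- paste0(substr(a2, 1, 35), substr(a2, 41, nchar(a2)))
  # allele 1 read trimmed by 2 bp at the end
  trim1 <- substr(a1, 1, nchar(a1) - 2)
  # deletion spanning SNV 1 only; SNV 2 bases also removed -> span both
  span <- paste0(substr(a1, 1, 20), substr(a1, 62, nchar(a1)))
  lv <- assign_length_variant(c(del2, trim1, span), c(a1, a2))
  expect_equal(lv$allele[1], 2L)
  expect_equal(lv$allele[2], 1L)
  expect_true(is.na(lv$allele[3]))   # all discriminating bases deleted
})

test_that("multi-SNV rescue uses non-masked anchor SNVs and strict dominance", {
  aset <- toy_two_allele_site()
  a2 <- aset$alleles$seq[2]
  # deletion masking SNV#1 (position 25) but keeping SNV#2 intact
  rd <- paste0(substr(a2, 1, 22), substr(a2, 30, nchar(a2)))
  r <- rescue_multi_snv(rd, aset)
  expect_equal(r, 2L)

  # all SNVs masked: still ambiguous
  rd2 <- paste0(substr(a2, 1, 22), substr(a2, 29, 52),
                substr(a2, 60, nchar(a2)))
  expect_true(is.na(rescue_multi_snv(rd2, aset)))

  # intact SNVs split 1-vs-1 between the alleles: no strict dominance
  amp <- aset$reference
  x <- strsplit(amp, "")[[1]]
  x[aset$snv_positions + 1] <- c("C", "A")   # allele1 base, allele2 base
  conflicted <- paste0(paste(x[1:70], collapse = ""))  # diverse length
  expect_true(is.na(rescue_multi_snv(conflicted, aset)))

  # single-SNV sites never rescue
  one <- build_allele_amplicons(amp, 25L,
                                data.frame(phase = c("C", "T"),
                                           freq = c(0.5, 0.5)), 40L)
  expect_true(all(is.na(rescue_multi_snv(c(rd, rd2), one))))
})

test_that("random assignment is seeded, reproducible, and unbiased", {
  a <- random_assign(100, c(0.75, 0.25), seed = 7)
  b <- random_assign(100, c(0.75, 0.25), seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, random_assign(100, c(0.75, 0.25), seed = 8)))

  big <- random_assign(1e5, c(0.75, 0.25), seed = 9)
  expect_equal(mean(big == 1L), 0.75, tolerance = 0.01)

  expect_equal(random_assign(0, c(1, 1), seed = 1), integer(0))
  expect_true(all(random_assign(50, 1, seed = 1) == 1L))
  expect_error(random_assign(10, numeric(0), seed = 1))
})

test_that("the ambiguity gate is strict at the threshold", {
  expect_true(ambiguity_gate(0.49))
  expect_false(ambiguity_gate(0.50))
  expect_true(ambiguity_gate(0))
})

test_that("the medoid minimizes summed L1 distance with ties to lowest index", {
  m <- rbind(c(0, 0), c(5, 5), c(6, 6), c(7, 7), c(20, 20))
  expect_equal(medoid_index(m), 3L)   # the L1 median row
  expect_equal(medoid_index(m[1, , drop = FALSE]), 1L)
  # exact tie between two identical rows: lowest index wins
  expect_equal(medoid_index(rbind(c(1, 1), c(1, 1), c(5, 5))), 1L)
})

test_that("iteration summary collapses when no read is ambiguous", {
  tr <- synthetic_truth("it", allele_freqs = c(0.5, 0.5),
                        editing_rates = c(0.2, 0.2), n_snvs = 2,
                        n_mock = 300, n_tx = 300, error_rate = 0,
                        seed = 41)
  g <- generate_site(tr)
  p <- pipeline_params()
  res <- analyze_site(g$config, g$mock$sequence, g$tx$sequence, p, seed = 1)
  expect_equal(res$random_fraction, 0)
  expect_equal(res$report$bound_low, res$report$editing_pct)
  expect_equal(res$report$bound_high, res$report$editing_pct)
  expect_equal(res$report$activity_confident, res$report$editing_pct)
  # bounds bracket the medoid elementwise in all cases
  expect_true(all(res$report$bound_low <= res$report$editing_pct + 1e-12))
  expect_true(all(res$report$bound_high >= res$report$editing_pct - 1e-12))
})

test_that("assignment categories partition every read of a site", {
  tr <- synthetic_truth("part", allele_freqs = c(0.5, 0.5),
                        editing_rates = c(0.3, 0.3), n_snvs = 1,
                        n_mock = 300, n_tx = 300, error_rate = 0.005,
                        seed = 43)
  g <- generate_site(tr)
  wk <- site_workup(g$config, g$mock$sequence, g$tx$sequence,
                    pipeline_params())
  for (asg in list(wk$tx, wk$mock)) {
    expect_false(any(is.na(asg$category)))
    expect_true(all(asg$category %in%
                      c("DIRECT", "ALIGNED", "RESCUED", "RANDOM")))
    expect_true(all(!is.na(asg$allele[asg$category != "RANDOM"])))
    expect_true(all(is.na(asg$allele[asg$category == "RANDOM"])))
  }
  # a 1-SNV site: no read can be RESCUED
  expect_equal(sum(wk$tx$category == "RESCUED"), 0L)
})
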