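test_that("phase enumeration counts read tuples and applies the floors", {
  # k=2: 60 CT reads, 40 GA reads
  sym <- rbind(matrix(rep(c("C", "T"), 60), ncol = 2, byrow = TRUE),
               matrix(rep(c("G", "A"), 40), ncol = 2, byrow = TRUE))
  ph <- enumerate_phases(sym, c(0L, 1L))
  expect_equal(ph$phase, c("CT", "GA"))
  expect_equal(ph$freq, c(0.6, 0.4))
  # observed phases can never exceed the 5^k phase space
  expect_lte(nrow(ph), 5^2)

  # floors: {C:9900, T:98, A:2} of 10000 -> A dropped (below both floors),
  # T kept (98 reads >= 5), frequencies renormalized
  sym2 <- matrix(c(rep("C", 9900), rep("T", 98), rep("A", 2)), ncol = 1)
  ph2 <- enumerate_phases(sym2, 0L, min_freq = 0.01, min_reads = 5)
  expect_equal(ph2$phase, c("C", "T"))
  expect_equal(ph2$freq, c(9900, 98) / 9998, tolerance = 1e-12)
})

test_that("the coverage-entropy score matches hand-computed values", {
  s <- allele_score(c(0.5, 0.5), 2)
  expect_equal(s$C, 1)
  expect_equal(s$H_norm, 1)
  expect_equal(s$score, 1)

  s3 <- allele_score(c(0.35, 0.34, 0.31), 3)
  expect_equal(s3$C, 1)
  expect_equal(s3$H_norm, 0.9988, tolerance = 1e-4)
  expect_equal(s3$score, 0.9989, tolerance = 1e-4)

  s2 <- allele_score(c(0.35, 0.34, 0.31), 2)
  expect_equal(s2$C, 0.69)
  expect_equal(s2$score, 0.9634, tolerance = 1e-4)

  expect_error(allele_score(c(0.6, 0.4), 3))
})

test_that("allele-number selection reproduces the worked regimes", {
  expect_equal(select_allele_number(c(0.75, 0.25))$n_star, 2L)
  expect_equal(select_allele_number(c(0.35, 0.34, 0.31))$n_star, 3L)
  sel <- select_allele_number(c(0.49, 0.47, 0.04))
  expect_equal(sel$n_star, 2L)
  expect_equal(sel$candidates$score, c(0.9957, 0.7796), tolerance = 1e-4)
})

test_that("selection equals the brute-force objective scan for n <= 6", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    f <- sort(stats::runif(n), decreasing = TRUE)
    f <- f / sum(f)
    expect_equal(select_allele_number(f)$n_star, brute_force_n_star(f),
                 info = paste(round(f, 3), collapse = "/"))
  }
})

test_that("a vanishing-frequency phase never increases the selected n*", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    f <- sort(stats::runif(n), decreasing = TRUE)
    f <- f / sum(f)
    base <- select_allele_number(f)$n_star
    eps <- 1e-6
    f2 <- c(f * (1 - eps), eps)
    expect_lte(select_allele_number(f2)$n_star, base)
  }
})

test_that("allele amplicons substitute phases and stay pairwise distinct", {
  amp <- strrep("ACGT", 20)
  pos <- c(10L, 25L, 46L, 63L)
  ph <- data.frame(phase = c("CCTG", "ATCA"), freq = c(0.75, 0.25),
                   stringsAsFactors = FALSE)
  aset <- build_allele_amplicons(amp, pos, ph, cut_position = 47L)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              aset$alleles$seq[1], aset$alleles$seq[2])
  expect_equal(unname(d), 4)
  expect_equal(aset$cut_allele, c(47L, 47L))

  # single SNV: amplicons differ at exactly one position
  one <- build_allele_amplicons(amp, 10L,
                                data.frame(phase = c("C", "T"),
                                           freq = c(0.5, 0.5)))
  expect_equal(sum(strsplit(one$alleles$seq[1], "")[[1]] !=
                     strsplit(one$alleles$seq[2], "")[[1]]), 1)

  # a '-' phase symbol deletes the column and shifts downstream coordinates
  gap <- build_allele_amplicons(amp, c(10L, 25L),
                                data.frame(phase = c("CG", "-T"),
                                           freq = c(0.5, 0.5)),
                                cut_position = 47L)
  expect_equal(nchar(gap$alleles$seq[2]), nchar(amp) - 1L)
  expect_equal(gap$cut_allele, c(47L, 46L))
  expect_true(is.na(gap$snv_pos_allele[[2]][1]))
  expect_equal(gap$snv_pos_allele[[2]][2], 24L)

  # identical resulting amplicons violate distinctness: deleting either of
  # two identical neighbouring bases yields the same sequence
  expect_error(build_allele_amplicons(
    strrep("A", 30), c(10L, 11L),
    data.frame(phase = c("A-", "-A"), freq = c(0.5, 0.5))),
    "identical")
})

test_that("the called allele set is invariant to read permutation", {
  tr <- synthetic_truth("perm", allele_freqs = c(0.6, 0.4), n_snvs = 2,
                        n_mock = 400, n_tx = 10, error_rate = 0.002,
                        seed = 31)
  g <- generate_site(tr)
  p <- pipeline_params(min_mock_reads = 100)
  wk1 <- site_workup(g$config, g$mock$sequence, g$tx$sequence, p)
  set.seed(1)
  wk2 <- site_workup(g$config, sample(g$mock$sequence), g$tx$sequence, p)
  expect_equal(wk2$allele_set$alleles$phase, wk1$allele_set$alleles$phase)
  expect_equal(wk2$allele_set$alleles$freq, wk1$allele_set$alleles$freq)
})
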