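test_that("global alignment reproduces hand-checkable scores and events", {
  # identity: every column a match
  id <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(id$score, 40)
  expect_equal(id$events$op, "M")

  # read one base longer than the reference: single 1-bp gap, 3*5 - 20
  a <- global_align("ACGT", "AGT")
  expect_equal(a$score, -5)
  ins <- a$events[a$events$op == "I", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$length, 1L)
  expect_equal(ins$ref_start, 1L)

  # single mismatch
  expect_equal(global_align("A", "T")$score, -4)
  expect_equal(global_align("A", "T")$events$op, "X")

  # empty sequences are rejected
  expect_error(global_align("", "ACGT"))
})

test_that("alignment equals a brute-force enumeration oracle on short pairs", {
  set.seed(101)
  for (rep in 1:25) {
    s1 <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1),
                       replace = TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1),
                       replace = TRUE), collapse = "")
    expect_equal(global_align(s1, s2)$score,
                 brute_force_align_score(s1, s2),
                 info = paste(s1, s2))
    # symmetric scoring: exchanging the sequences preserves the score
    expect_equal(global_align(s1, s2)$score, global_align(s2, s1)$score)
  }
})

test_that("alignment scores agree with an independent aligner on long pairs", {
  # Biostrings convention: a gap of length L costs gapOpening + L*gapExtension,
  # equivalent to ours with gapOpening = 19, gapExtension = 1
  mat <- matrix(-4, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat)[1:4] <- 5
  set.seed(202)
  for (rep in 1:10) {
    ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
    x <- strsplit(ref, "")[[1]]
    # plant a deletion and a couple of substitutions
    del <- sample(30:80, 1)
    x[sample(100:110, 2)] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    read <- paste(x[-(del:(del + sample(0:6, 1)))], collapse = "")
    bs <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref),
      substitutionMatrix = mat, gapOpening = 19, gapExtension = 1,
      type = "global")
    expect_equal(global_align(read, ref)$score, Biostrings::score(bs))
  }
})

test_that("event lists round-trip to the aligned strings", {
  set.seed(303)
  for (rep in 1:20) {
    ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    x <- strsplit(ref, "")[[1]]
    op <- sample(c("del", "ins", "sub"), 1)
    read <- switch(op,
      del = paste(x[-(20:24)], collapse = ""),
      ins = paste(c(x[1:30], "A", "C", "T", x[31:60]), collapse = ""),
      sub = {x[15] <- "A"; x[40] <- "T"; paste(x, collapse = "")})
    al <- global_align(read, ref)
    expect_equal(gsub("-", "", al$aligned_ref), ref)
    expect_equal(gsub("-", "", al$aligned_read), read)
    rb <- rebuild_alignment(al$events, read, ref)
    expect_equal(rb$aligned_read, al$aligned_read)
    expect_equal(rb$aligned_ref, al$aligned_ref)
  }
})

test_that("the gapless fast path returns full alignment scores", {
  params <- alignment_params()
  set.seed(404)
  ref <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  reads <- vapply(1:30, function(i) {
    x <- strsplit(ref, "")[[1]]
    pos <- sample(150, sample(0:5, 1))
    x[pos] <- sample(c("A", "C", "G", "T", "N"), length(pos), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  ab <- allelecall:::.align_batch(reads, ref, params)
  full <- allelecall:::.nw_align_batch(reads, ref, params$match,
                                       params$mismatch, params$gap_open,
                                       params$gap_extend)
  expect_equal(ab$score, full$score)
})

test_that("best_allele_alignment picks the top allele and flags exact ties", {
  a1 <- "ACGTACGTACGTACGTACGT"
  a2 <- paste0(substr(a1, 1, 8), "C", substr(a1, 10, 20))  # A->C, 0-based 8
  expect_equal(best_allele_alignment(a1, c(a1, a2))$allele, 1L)
  expect_equal(best_allele_alignment(a2, c(a1, a2))$allele, 2L)

  # read with a 2-bp insertion away from the SNV but carrying allele 2's base
  rd <- paste0(substr(a2, 1, 15), "GG", substr(a2, 16, 20))
  expect_equal(best_allele_alignment(rd, c(a1, a2))$allele, 2L)

  # the discriminating base deleted: symmetric, must be ambiguous
  rd2 <- paste0(substr(a1, 1, 8), substr(a1, 10, 20))
  expect_true(is.na(best_allele_alignment(rd2, c(a1, a2))$allele))
})
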