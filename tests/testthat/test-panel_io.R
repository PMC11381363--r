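make_config_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("site_id\tgrna\tamplicon\tfwd_primer\trev_primer", rows),
             path)
  path
}

test_that("config parsing validates rows and derives the cut position", {
  tr <- synthetic_truth("siteA", allele_freqs = 1, seed = 3)
  row <- paste(tr$site_id, tr$grna, tr$amplicon, tr$fwd_primer,
               tr$rev_primer, sep = "\t")
  cfg <- parse_config(make_config_file(row))
  expect_equal(nrow(cfg), 1L)
  expect_equal(cfg$cut_position, tr$cut_position)
  expect_equal(cfg$strand, "+")
  # blunt cut 3 bp 5' of the PAM: the PAM "TGG" starts 3 bp after the cut
  expect_equal(substr(cfg$amplicon, cfg$cut_position + 4L,
                      cfg$cut_position + 6L), "TGG")

  # missing field
  bad <- paste("siteB", tr$grna, tr$amplicon, tr$fwd_primer, sep = "\t")
  expect_error(parse_config(make_config_file(bad)))

  # duplicate site ids
  expect_error(parse_config(make_config_file(c(row, row))), "duplicate")

  # non-ACGT amplicon
  bad2 <- paste("siteC", tr$grna, "ACGTXACGT", tr$fwd_primer,
                tr$rev_primer, sep = "\t")
  expect_error(parse_config(make_config_file(bad2)), "non-ACGT")
})

test_that("a minus-strand gRNA maps the cut into plus coordinates", {
  tr <- synthetic_truth("siteR", allele_freqs = 1, seed = 4)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tr$grna)))
  # giving the guide in the opposite orientation: its protospacer sits on
  # the minus strand, whose plus-strand footprint is the original guide
  # match; the PAM-proximal end is the footprint start, cut 3 bp inside
  s <- as.integer(regexpr(tr$grna, tr$amplicon, fixed = TRUE)) - 1L
  cs <- cut_site(rc, tr$amplicon)
  expect_equal(cs$strand, "-")
  expect_equal(cs$cut_position, s + 3L)

  # absent gRNA: flagged, no cut
  cs2 <- cut_site(strrep("A", 20), "ACGTACGTACGT")
  expect_true(is.na(cs2$cut_position))
  expect_match(cs2$flag, "no cut site")
})

test_that("demultiplexing matches primers in both orientations and conserves reads", {
  tr1 <- synthetic_truth("s1", allele_freqs = 1, seed = 6)
  tr2 <- synthetic_truth("s2", allele_freqs = 1, seed = 7)
  sites <- rbind(generate_site(tr1)$config, generate_site(tr2)$config)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  mut <- function(x, k) {          # plant k mismatches in the first 20 bp
    y <- strsplit(x, "")[[1]]
    y[seq_len(k)] <- ifelse(y[seq_len(k)] == "A", "C", "A")
    paste(y, collapse = "")
  }
  reads <- data.frame(
    read_id = paste0("r", 1:5),
    sequence = c(tr1$amplicon,                 # exact forward, site 1
                 rc(tr2$amplicon),             # reverse orientation, site 2
                 mut(tr1$amplicon, 2),         # 2 mismatches: still site 1
                 mut(tr1$amplicon, 3),         # 3 mismatches: unassigned
                 strrep("ACGT", 60)),          # matches nothing
    quality = strrep("I", c(rep(nchar(tr1$amplicon), 4), 240)),
    stringsAsFactors = FALSE)
  dm <- demultiplex(reads, sites, max_mismatch = 2)
  expect_equal(unname(dm$counts), c(2L, 1L))
  expect_equal(dm$unassigned, 2L)
  expect_equal(sum(dm$counts) + dm$unassigned, nrow(reads))
  # the reverse read was reverse-complemented back to plus orientation
  expect_equal(dm$reads$s2$sequence, tr2$amplicon)
})

test_that("FASTQ io round-trips through plain and gzipped files", {
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c("ACGTN", "GGCC"),
                      quality = c("IIIII", "FFFF"),
                      stringsAsFactors = FALSE)
  for (ext in c(".fastq", ".fastq.gz")) {
    path <- tempfile(fileext = ext)
    write_fastq(reads, path)
    back <- read_fastq(path)
    expect_equal(back, reads)
  }
})

test_that("the pipeline handles null, low-coverage and no-SNV sites", {
  pan <- generate_panel(2, n_mock = 200, n_tx = 200, editing_rate = 0,
                        error_rate = 0.002, seed = 29,
                        out_dir = file.path(tempdir(), "null_panel"))
  d <- file.path(tempdir(), "null_panel")
  p <- pipeline_params(min_mock_reads = 100)
  # treatment identical to mock: all activities ~ 0
  res <- run_pipeline(file.path(d, "panel.tsv"),
                      file.path(d, "mock.fastq.gz"),
                      file.path(d, "mock.fastq.gz"),
                      out_dir = file.path(d, "out"), params = p)
  expect_true(all(res$summary$editing_pct == 0))
  expect_true(all(res$summary$status == "ok"))
  # a site whose mock reads all equal the reference: one allele, no SNVs
  no_snv <- res$sites[[1]]
  expect_equal(nrow(no_snv$snvs), 0L)
  expect_equal(nrow(no_snv$allele_set$alleles), 1L)
  expect_true(file.exists(file.path(d, "out", "sites_summary.tsv")))
  expect_true(file.exists(file.path(d, "out", "alleles.fasta")))
  expect_true(file.exists(file.path(d, "out", "report.json")))

  # below the mock floor: skipped with an "insufficient coverage" row
  p2 <- pipeline_params(min_mock_reads = 300)
  res2 <- run_pipeline(file.path(d, "panel.tsv"),
                       file.path(d, "mock.fastq.gz"),
                       file.path(d, "mock.fastq.gz"),
                       out_dir = NULL, params = p2)
  expect_true(all(res2$summary$status == "insufficient_coverage"))
  expect_true(all(is.na(res2$summary$editing_pct)))

  # missing mock file is fatal
  expect_error(run_pipeline(file.path(d, "panel.tsv"),
                            file.path(d, "tx.fastq.gz"),
                            file.path(d, "nope.fastq.gz"), NULL, p),
               "mock")
})
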