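Package: allelecall
Title: Allele-Aware Quantification of CRISPR Editing from Multiplexed
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-free, allele-specific quantification of CRISPR-Cas9
    editing activity from treatment/mock amplicon sequencing experiments.
    Single nucleotide variants are detected de novo from the unedited mock
    sample by per-position Shannon entropy, haplo-alleles are called with a
    coverage-entropy objective, treatment and mock reads are assigned to the
    called alleles (direct SNV lookup, global alignment, multi-SNV rescue,
    and seeded proportional random assignment with medoid-and-bounds
    reporting), and per-allele indel editing activity is estimated with
    mock-controlled event classification and Clopper-Pearson confidence
    intervals. Includes a synthetic amplicon experiment generator with
    planted alleles, indel spectra, and sequencing error for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
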