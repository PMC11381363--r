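# allelecall

Allele-aware quantification of CRISPR-Cas9 editing activity from
multiplexed amplicon sequencing, for anyone measuring on- and off-target
editing in samples that are not genetically uniform: heterozygous cell
lines, primary human cells, polyploid crops. A single pooled editing
percentage averages over alleles and can hide the biology completely —
most strikingly when an SNV disrupts the PAM and only one allele is
cut. `allelecall` discovers the alleles *de novo* from the unedited mock
control and reports editing activity per allele, with confidence
intervals.

## Method at a glance

Given treatment (Tx) and mock FASTQ files plus a panel configuration
(site ID, gRNA, amplicon, primers), the pipeline runs per site:

1. **SNV detection.** Mock reads of modal length are aligned to the
   amplicon; position *t* is an SNV when the Shannon entropy of its
   symbol distribution p(t) over {A, C, G, T, –} satisfies
   H(p(t)) ≥ τ, with τ = 0.72 bits (the entropy of a 20/80 split).
2. **Allele calling.** Reads are phased over the SNV columns; with
   sorted phase frequencies f₁ ≥ … ≥ fₙ, the allele number is

   n\* = argmax₍₂≤ν≤ₙ₎ C(ν)^(1/10) · H_norm(ν)^(9/10),

   where C(ν) = Σᵢ≤ν fᵢ is the read coverage of the top ν phases and
   H_norm(ν) their renormalized entropy divided by log₂ ν. One amplicon
   per allele is reconstructed.
3. **Read assignment.** Standard-length reads by direct SNV lookup;
   length-variant reads by best global alignment (affine-gap
   Needleman–Wunsch); reads with masked SNVs by a multi-SNV rescue over
   ±5 bp windows around the linked anchor SNVs; the remainder by seeded
   random allocation following the observed proportions. Sites with
   ≥ 50% randomly allocated reads are discarded as too ambiguous.
4. **Per-allele quantification.** A Tx read is edited when it carries an
   indel overlapping ±20 bp around the cut site and its events survive a
   mock-controlled Beta-Binomial classifier (posterior that the Tx rate
   exceeds the mock rate > 0.95). Activity is reported as a percentage
   with an exact Clopper–Pearson 0.95 CI, plus medoid-and-bounds
   estimates over the random-assignment iterations and an
   allele-imbalance flag.

A synthetic-data generator (`generate_site()`, `generate_panel()`)
produces full experiments with known ground truth — planted alleles,
SNVs, allele-specific editing rates, Cas9-like indel spectra, sequencing
error — so every stage is testable without external data.

## Worked example

A heterozygous off-target site (75/25 allele mix) where one SNV
disrupts the PAM: 12% editing was planted on the PAM-preserved allele,
none is possible on the other.

```r
library(allelecall)

truth <- synthetic_truth("CD33_like", allele_freqs = c(0.75, 0.25),
                         editing_rates = c(0.12, 0.12), n_snvs = 2,
                         pam_snv = TRUE, n_mock = 4000, n_tx = 4000,
                         error_rate = 0.001, seed = 12)
site <- generate_site(truth)
res <- analyze_site(site$config, site$mock$sequence, site$tx$sequence,
                    pipeline_params(), seed = 12)
res$snvs
#>    position   entropy bases top_freq gap_allele
#> G        52 0.8286752  GTAC   0.7425      FALSE
#> G1      111 0.8392757  GCAT   0.7415      FALSE
res$report[, c("allele", "phase", "allele_freq_mock", "n_tx",
               "edited_reads", "editing_pct", "ci_low", "ci_high")]
#>  allele phase allele_freq_mock n_tx edited_reads editing_pct ci_low ci_high
#>       1    GG            0.743 2986          343        11.5   10.4  12.685
#>       2    TC            0.257 1014            0         0.0    0.0   0.363
```

Two SNVs are found (positions 52 and 111; the second sits in the PAM),
two alleles are called at 74/26, and editing is confined to the
PAM-preserved `GG` allele: 11.5% with CI [10.4%, 12.7%], covering the
planted 12%, while the PAM-disrupted `TC` allele reports 0%. A pooled,
allele-blind analysis of the same reads would have reported ~8.6% and
missed the allele exclusivity.

The same analysis runs from the shell:

```sh
Rscript inst/cli/allelecall.R simulate --out sim --sites 4 --seed 42
Rscript inst/cli/allelecall.R run --config sim/panel.tsv \
    --tx sim/tx.fastq.gz --mock sim/mock.fastq.gz --out results_dir \
    --tau 0.72 --window 20 --iterations 11 --seed 42
```

writing `sites_summary.tsv` (one row per site × allele),
`alleles.fasta` (the called allele amplicons) and `report.json` (a full
machine-readable mirror).

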