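---
title: "Allele-aware quantification of CRISPR editing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-aware quantification of CRISPR editing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelecall)
```

## The problem

Multiplexed amplicon sequencing of CRISPR-Cas9 experiments compares a
treated sample (Tx) against an unedited mock control to quantify indel
formation at on- and off-target sites. When a site carries sequence
variants — a heterozygous SNV in a cell line, the three homeologous copies
of a triploid crop genome — the sample is a *mixture of alleles*, and a
single pooled editing percentage can mask biology entirely: an SNV that
disrupts the PAM abolishes cutting on one allele while the other is edited
normally, and pooling averages the two. `allelecall` quantifies editing
*per allele*, without any prior variant annotation: the mock sample itself
serves as the de facto reference from which SNVs and haplo-alleles are
discovered.

## SNV detection from the mock sample

For each site, mock reads whose length equals the modal read length are
globally aligned to the user-supplied amplicon. At every reference
position $t$ the aligned symbols over the alphabet $\{A, C, G, T, -\}$
give an empirical distribution $p(t)$ (an `N` is excluded from the
counts; the gap symbol participates, so recurrent alignment-induced
deletions can be called, flagged as gap-alleles). The position is called
an SNV when its Shannon entropy

$$H(p) = -\sum_i p_i \log_2 p_i \;\ge\; \tau$$

with $\tau = 0.72$ bits by default — the entropy of a 20/80 split, so a
minor allele needs roughly 20% frequency to be called. Entropy is
computed in base 2 throughout; the threshold is only meaningful in bits.
Per-base sequencing error at rate $\varepsilon \le 1\%$ produces columns
with entropy near $H(0.99, 0.0033, \ldots) \approx 0.1$, far below
$\tau$, which is what makes the detector robust to noise without any
database of known variants.

Diverse-length reads (typically reads carrying indels) are excluded from
profiling — they would smear columns — but are retained and assigned to
alleles later by alignment.

## Haplo-allele calling

Each profiled read contributes the tuple of its bases at the $k$ SNV
columns — its *phase*. The possible phase space lies between $2^k$ and
$5^k$. Observed phases are filtered by a support floor (kept when they
reach 1% frequency *or* 5 supporting reads; phases below both floors are
sequencing-noise artifacts) and sorted by frequency
$f_1 \ge f_2 \ge \ldots \ge f_n$.

How many of these phases are real alleles? Keeping the top $\nu$ covers
$C(\nu) = \sum_{i \le \nu} f_i$ of the reads; the balance among them is
the entropy of the renormalized top-$\nu$ frequencies. We select

$$n^* = \arg\max_{2 \le \nu \le n} \; C(\nu)^{1/10} \,
  H_{norm}(\nu)^{9/10},
\qquad H_{norm}(\nu) = \frac{H\!\left(f_1/C, \ldots, f_\nu/C\right)}
  {\log_2 \nu}.$$

The $\log_2 \nu$ normalization is a deliberate design choice: with raw
entropy the product is monotonically non-decreasing in $\nu$ (adding any
phase raises both $C$ and $H$), so the argmax would degenerate to "keep
every observed phase". Normalizing entropy to $[0, 1]$ restores the
intended coverage-versus-balance tradeoff; under it, a 75/25 pair yields
$n^* = 2$, a 35/34/31 triple yields $n^* = 3$, and a 49/47/4 triple
yields $n^* = 2$ (the 4% phase costs more balance than it buys
coverage). Ties go to the smaller $\nu$; the scan is capped at 10
candidate alleles. A vanishing-frequency phase can never increase $n^*$,
which is the noise-robustness property the floor alone cannot provide at
high depth.

The $n^*$ selected phases are substituted into the reference to build one
amplicon per allele (a `-` phase symbol deletes its column); the
amplicons are pairwise distinct by construction and the per-allele cut
and SNV coordinates are shifted accordingly.

## Assigning reads to alleles

Reads are assigned in stages, each category disjoint from the previous:

1. **DIRECT** — standard-length reads (equal to the reference length)
   whose bases at the SNV columns exactly equal one allele's phase.
2. **ALIGNED** — diverse-length reads, assigned to the allele amplicon
   with the strictly best global alignment score; exact score ties stay
   ambiguous.
3. **RESCUED** — ambiguous reads at sites with $\ge 2$ SNVs: a masked
   discriminating SNV (deleted by a nuclease-induced indel, or carrying a
   non-reference base) can be compensated by the other, linked anchor
   SNVs. A ±5 bp window around each non-masked SNV is scored against
   every allele; the read is rescued when one allele's summed window
   scores strictly dominate.
4. **RANDOM** — the remainder are allocated by a seeded multinomial draw
   following the proportions of the same sample's confident assignments
   (falling back to mock allele frequencies when no confident read
   exists). Excluding them instead would bias exactly the interesting
   sites, where an SNV near the cut is deleted in many edited reads.

Sites where the random fraction reaches 50% of reads are discarded as
too ambiguous (strict inequality: 49% passes, 50% does not).

Random assignment is not a single draw: the sample is first quantified
with the ambiguous reads excluded, then over $R = 11$ seeded redraws.
The reported point estimate is the medoid activity vector (L1 metric,
ties to the lowest iteration index) and each allele carries min/max
bounds across the iterations — a conservative envelope for the
assignment uncertainty. $R$ is odd so exact medoid ties are rare.

## Per-allele editing quantification

Reads of an allele are aligned to that allele's amplicon; a read is a
*candidate* edited read when it carries at least one insertion or
deletion overlapping the editing window of ±20 bp around the cut site
(substitutions never qualify). Candidates are then filtered by a
mock-controlled classifier. Every distinct event — (kind, position,
length) — observed in the treatment reads is compared with its rate in
the same allele's mock reads under independent Beta(1,1)-Binomial
models: the event is a true edit when
$P(p_{tx} > p_{mock} \mid \text{data}) > 0.95$. Recurrent library or
PCR artifacts (e.g. homopolymer slippage) appear at similar rates in
both samples and fail this test.

A per-event test alone, however, is blind to allele-level context: at an
allele with hundreds of clearly edited reads, a repair outcome observed
in a single read (and never in the mock) would be discarded — the flat
prior cannot push a 1-versus-0 comparison past 0.95 — and summing many
such discards biases activity downward precisely when the indel spectrum
is diverse. The classifier therefore adds a site-level gate: an event
with *zero* mock support is also accepted when the allele-level
candidate-read rate comparison itself clears the same 0.95 threshold. A
lone indel at an otherwise unedited allele still fails (both tests are
then powerless by design), which keeps the null calibrated.

Editing activity is the percentage of edited reads among the allele's
treatment reads, with an exact two-sided Clopper–Pearson 0.95 interval —
chosen over asymptotic intervals because off-target activities of
interest sit near zero, where coverage of Wald-type intervals collapses.

Finally, the mock allele frequencies are compared with the confident
treatment assignment by exact binomial tests; the report raises an
advisory imbalance flag when any allele shifts by more than 0.15 with
$p < 0.01$ — e.g. allele-specific selection during ex-vivo expansion —
without blocking output.

## The synthetic-data generator

`synthetic_truth()`/`generate_site()`/`generate_panel()` emulate the data
regime the pipeline targets: 150–250 bp amplicons with 20 bp primers at
the ends, a mid-amplicon protospacer with a TGG PAM, up to a handful of
SNVs per site, allele frequencies summing to one, and per-allele editing
rates. Mock reads are drawn per allele frequency with iid per-base
substitution error (default $\varepsilon = 0.001$); treatment reads
additionally carry, with the allele's editing rate, one indel anchored at
the cut site with ±2 bp jitter — 70% deletions of 1–10 bp, 30%
insertions of 1–3 bp, matching the locality and spectrum of Cas9 repair
outcomes. Planted SNV positions are guaranteed polymorphic (a
"planted SNV" where all alleles drew the reference base would be no SNV
at all) and are placed away from primers and from the editing window
extended by the widest plantable indel, so allele identity is not
destroyed by the planted edits themselves. Substitution-only noise is
the default so the mock-controlled classifier's null is exactly
testable; an optional `indel_noise_rate` plants spurious 1-bp indels in
both samples.

What the generator does *not* emulate: PCR chimeras and stutter,
quality-score structure (constant Q is written), strand bias, and
coverage heterogeneity along the amplicon. Passing the synthetic
recovery tests therefore demonstrates correctness of the algorithms
under the stated error model, not robustness to every real-library
artifact.

## Numerical and degenerate-case choices

* Alignment scores: +5 match, −4 mismatch, affine gaps opening at −20
  and extending at −1 (a gap of length $L$ costs $-20-(L-1)$). These
  favor one long indel over scattered mismatches, matching Cas9 repair
  structure. Traceback ties are broken deterministically — mismatch over
  gap, deletion over insertion — so event lists are byte-stable across
  runs. `N` scores as a mismatch against everything, including `N`.
* An equal-length read with at most
  $\lfloor (match + 2|gap_{open}|)/(match - mismatch) \rfloor = 5$
  mismatches is provably optimally aligned without gaps; such reads take
  a vectorized fast path that skips the dynamic program entirely.
* Sites with fewer than 100 mock reads are skipped (entropy estimates
  from a handful of reads are meaningless); sites with zero SNVs, or
  whose phases are all filtered, are quantified as a single whole-site
  allele.
* A gRNA absent from the amplicon (or matching twice) leaves the cut
  position undefined: alleles are still called, activity is reported as
  `NA`.
* Modal read-length ties break toward the longer length; medoid ties
  toward the lowest iteration index; allele-number ties toward fewer
  alleles.
* All randomness (random assignment, the generator) flows through
  explicit integer seeds; a fixed seed reproduces byte-identical TSV and
  JSON outputs.

## Problem sizes used in the validation suite

The shipped tests exercise the pipeline at the scales of its intended
regimes: a triploid site at 10 000 reads per condition (frequencies
35/34/31%, editing 70/61/58%), a heterozygous PAM-SNV site at 5 000
reads (10% vs 0%), 100 null replicates at 1 000 reads with
$\varepsilon = 1\%$, and multi-site panels at a few hundred reads per
site for the orchestration and determinism checks. `scripts/acceptance.R`
regenerates all of these from scratch at an arbitrary seed.

## Known limitations

* The per-event classifier is a deliberately simple mock-controlled
  Beta-Binomial comparison; it does not model event-specific priors
  (e.g. indel length or microhomology structure) and its 0.95 threshold
  is a configurable convention, not a calibrated FDR.
* Reads are assigned in whole units; there is no probabilistic soft
  assignment or EM re-estimation of allele frequencies.
* Paired-end merging is out of scope: the pipeline consumes merged or
  single-end FASTQ.
* Translocation detection and substitution-editing (base-editor)
  quantification are out of scope.
* Confidence intervals reflect binomial sampling of the edited fraction
  only; the random-assignment bounds are reported separately rather than
  folded into a single interval.
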