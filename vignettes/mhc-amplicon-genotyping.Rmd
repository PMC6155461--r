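---
title: "Methods: amplicon MHC class II genotyping and immunogenetic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon MHC class II genotyping and immunogenetic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

This vignette records the models, parameter choices and numerical
conventions behind `mhctyper`, in enough detail that a maintainer can
judge why each default is what it is and what the tests do and do not
demonstrate.

## The genotyping model

A sample is one diploid PCR product: every read descends from one of two
allele templates, plus artifacts. The pipeline's central assumption is
that **allele ratios carry the signal**: at a true heterozygous site the
minor base sits near 50% of reads, at a homozygous site near 0%, and
anything in between is evidence of an artifact, not of a genotype.

Two callers look at the same pileup:

* The **ratio caller** calls a heterozygote only when the minor fraction
  of the top two bases lies in `[min_minor_frac, 0.5]` and a homozygote
  only when it is at most `max_minor_frac_hom`. Defaults are 0.35 and
  0.05. The heterozygote bound is deliberately strict: a 2:1 ratio (minor
  fraction 0.33) is exactly what a PCR chimera produces in a heterozygote
  and must be flagged, not called. Both bounds are arguments of
  `caller_params()` because the right band depends on depth and expected
  contamination.
* The **likelihood caller** maximises a standard diploid likelihood: each
  read base arises from one of the two genotype alleles, with error
  probability taken from the base quality, and a uniform prior over the
  ten unordered base pairs. It happily calls genotypes in which both
  bases differ from the reference (tri-allelic sites) and reports a
  Phred-scaled confidence, gated at `min_qual = 40`.

Disagreements are resolved by `reconcile_calls()` through an explicit
error taxonomy rather than by trusting either caller: a likelihood-only
variant whose extra base is below the heterozygote band with no support
from any dominant read cluster is sequencing error; three dominant
haplotype clusters, one of which is a single-crossover recombinant of the
other two, is a PCR chimera (the recombinant's reads are removed and the
sample re-called); a variant present on one strand with at least
`strand_min_opp = 10` reads of clean opposite-strand coverage is
misalignment and the site is recomputed on the clean strand; both-non-
reference genotypes are accepted from the likelihood route; and a variant
in homopolymer context (runs of length ≥ 4) is accepted when its fraction
is consistent on both strands. A site where no rule fires is flagged for
manual review and not genotyped — the package never guesses.

Chimera detection (`detect_chimeric_haplotypes()`) is purely
combinatorial: with the two largest clusters as parents, a cluster is
chimeric iff some crossover index splits its variant-site pattern into a
parent-A prefix and a parent-B suffix (either parent order). "Dominant"
means at least `dominant_frac = 5%` of the sample's reads; below that,
stray patterns are noise and are simply outvoted. With fewer than two
variant sites chimerism is undetectable and reported as indeterminate.

Phasing (`phase_haplotypes()`) clusters reads by their bases at the
heterozygous sites. The most frequent genotype-consistent pattern is one
haplotype; the position-wise complement (the other genotype base at each
site, which handles tri-allelic sites through co-occurrence) is the
second. If a third consistent pattern has support within 10% of the
complement's, the phase is declared ambiguous and the sample errors out
rather than being guessed — ties of this kind genuinely require external
information.

### Coordinates and indels

Internally all positions are 0-based half-open; VCF output
(`write_variants()`) is 1-based per the standard, with phased `GT` and
the reconciliation class in `INFO`. Reads whose length equals the
reference take a vectorised comparison path; others are aligned glocally
with affine gaps (match +1, mismatch −2, gap open −4, gap extend −1) and
deletions are left-aligned within homopolymer runs, which removes
aligner-dialect ambiguity about where in a run a gap "is".

## The synthetic-data generator

`simulate_dataset()` emulates the data a pooled dual-barcoded amplicon
run produces: ~350 bp amplicons flanked by 10 bp barcodes (reads are
therefore ~370 bp, and the default 350 bp length filter tolerates
deletions), reads emitted in either orientation with probability 0.5,
per-base substitution errors (default 0.001) applied independently of the
written quality string (constant Q30) so that callers must work from
qualities while the simulator controls truth, strand-restricted
single-base deletions in homopolymer runs of length ≥ 4 (default rate
0.005 per run per sample; one orientation per run is affected, which is
the signature the strand-bias rule exists to catch), and single-crossover
PCR chimeras formed between the sample's own two alleles at a uniform
crossover (default rate 0.05 — a fixture choice in the plausible range
for pooled amplicon libraries, not an empirical estimate). Genotypes are
drawn from per-stratum allele frequencies; an inbreeding coefficient F
gives P(homozygote i) = p·p + F·p(1−p). Barcode hopping between pools is
not simulated. Identical configuration and seed give byte-identical
FASTQ.

What passing the round-trip tests shows: the calling stack undoes exactly
the error processes the generator implements, at realistic rates and
depths. What it does not show: robustness to error modes the generator
omits — context-dependent error hotspots, chimeras between different
samples' templates, barcode synthesis errors, coverage dropout along the
amplicon. Results on real data depend on those.

## Statistical methods and conventions

**Heterozygosity.** He uses Nei's unbiased correction,
[2n/(2n−1)](1 − Σp²), with 2n = allele copies. This reproduces
published per-stratum values exactly at three decimals from the packaged
count table, which is the reason this estimator (and not the plain
1 − Σp²) is the default.

**Hardy–Weinberg exact test.** `hwe_exact()` enumerates all genotype
tables conditional on the allele counts when the state space is at most
`max_tables = 2e5` (the exact conditional distribution, summed over
tables no more probable than the observed one); otherwise a Guo–Thompson
switch chain is used: two individuals are drawn with probability
proportional to genotype counts, their four alleles re-paired, and the
move accepted by Metropolis–Hastings with the proposal correction for
count-weighted selection and degenerate re-pairings. The chain default is
10,000 steps after 1,000 burn-in; the agreement check in the acceptance
suite runs 100,000 steps against full enumeration over a systematic grid
of two-allele tables up to 30 individuals (four sample sizes crossed with
minor-allele counts and heterozygote counts, ~40 tables), with agreement
required within ±0.02.

**FST.** `fst_wc()` implements the Weir–Cockerham variance-component
estimator θ, summed over alleles within locus and combined across loci as
the ratio of summed components. Monomorphic loci are excluded (they
contribute no information and would only add zero denominators). The
permutation test reassigns individuals (genotype pairs, not allele
copies) between the two strata, matching genotype-level permutation
practice, and reports the fraction of permuted θ at least as large as the
observed. With few alleles θ's permutation distribution is coarse and the
"fraction ≥ observed" p-value is conservative at its atoms; the
uniformity property is therefore checked on a six-allele locus (the
realistic regime for MHC loci, which here carry 6–10 alleles), 200
replicates at 500 permutations each.

**dN/dS.** `pairwise_dnds()` is Nei–Gojobori 1986 counting: per-codon
synonymous site fractions; pathway averaging over all mutation orders for
multi-position codon differences, excluding paths through stop codons
unless every path is blocked; mutations *to* stop codons counted as
nonsynonymous in site counting; Jukes–Cantor correction; and w = mean dN
over mean dS across pairs, with dS = 0 reported as an undefined flag
rather than an infinite ratio. The `tstv` variant reweights site counting
with the estimated transition/transversion ratio R (transition weighted
2R against 1 per transversion), which discounts synonymous opportunity
when transitions are favoured. The counting scan `site_dnds_scan()` is an
explicitly labelled approximation to likelihood site models: per codon
column it tallies changes against the majority (star-tree ancestral)
codon and applies a one-sided binomial test of excess nonsynonymous
change against the ancestral codon's neutral expectation. It yields the
three-way w<1 / w≈1 / w>1 labels, not posterior probabilities, and its
power depends on the number of observed changes per column.

**ts/tv.** `titv_ratio()` reports R = s/v from K2P-corrected transition
and transversion distances averaged over pairs, falling back to the raw
count ratio when divergence is too small for the correction (fewer than
~10 differences per pair, or undefined logs). The random expectation is
R = 0.5, one transition versus two transversion types.

**Codon usage.** RSCU is observed count over family mean. Nc is Wright's
estimator from family homozygosity averaged within degeneracy classes
(9 two-fold, Ile as the lone three-fold, 5 four-fold, 3 six-fold), with
the conventional substitutions when a class is unobserved, clamped to
[20, 61]. CBI follows the Bennetzen–Hall form with the expected optimal
count under uniform usage; "optimal" codons default to the most frequent
codon per amino acid in the analysed set (the convention of standard
polymorphism software) and can be overridden.

**Pocket enrichment.** The G statistic is the uncorrected two-cell
goodness-of-fit (zero cells contribute zero); the Williams correction is
available as a flag but off by default, because the uncorrected statistic
agrees with published census values within a fraction of a percent while
the corrected variants do not. Pocket residue masks ship as editable
configuration validated against the expected totals (15 residues for the
three DQA pockets, 19 for the five DQB pockets); the packaged positions
follow human-homology assignments and are data, not code, because pocket
definitions legitimately vary across studies.

**Promoter analysis.** Motif consensus sequences, windows and mismatch
tolerances are configuration (`motif_defs.tsv`), defaulting to 2
mismatches — cross-species scanning must tolerate divergence. Only the
coding strand is scanned; promoters are orientation-defined. The
duplication detector searches unit lengths from 22 down to 11 bp
(greedily preferring longer units, suppressing reports contained in an
already-found repeat) with copies separated by at most 30 bp; the net
insertion relative to an unduplicated homolog is the length difference,
which is what a duplication that also replaced flanking sequence nets
out to. Shannon entropy is computed per column on a supplied alignment
(the package does not align promoters across species); gaps are either
excluded with renormalisation (H ≤ 2 bits) or treated as a fifth state
(H ≤ log₂5), and all-gap columns are masked.

## Sanger-consensus resolution

`resolve_sanger_genotype()` treats a chromatogram consensus with two-base
IUPAC codes as the position-wise union of two alleles. It first
enumerates all unordered pairs of known alleles whose union reproduces
the consensus exactly; a unique match wins, multiple matches are decided
by summed catalogue support (frequency-weighted preference) and surface
as an error when tied. Only if no known pair works does it infer a novel
allele, and only when the complement forced by a compatible known allele
is unique; two novel alleles are never invented. This is deliberately
conservative: with highly polymorphic loci, a consensus compatible with
several distinct one-novel solutions is reported as ambiguous rather
than resolved.

## Problem sizes and runtime choices

The acceptance suite runs the full pipeline on 200 simulated samples
(four seeded batches of 50, depth 520, substitution error 0.001, chimera
rate 0.05), 150 seeded three-cluster chimera cases, 200 FST null
replicates at 500 permutations, and the MCMC-versus-enumeration grid at
100,000 steps — sizes chosen so the whole test suite completes in a few
minutes on one core while leaving the statistical checks well-powered.
The simulation defaults themselves (amplicon length 350, depth ≥ 500,
10 × 10 barcode panel) mirror the study design the package emulates.

## Known limitations

* Published allele-count tables alone do not determine individual
  genotypes, so statistics that need genotype-level data (observed
  heterozygosity, FST between the study's strata) can only be computed
  from genotype tables the user supplies, not from the packaged counts.
* The per-site selection scan is a counting approximation; it does not
  replace codon-model maximum likelihood or Bayes empirical Bayes
  posteriors, and printed values from such software are not comparable
  targets for it.
* Barcode matching is exact by design; reads with barcode synthesis
  errors are discarded rather than rescued.
* The caller assumes a single locus per amplicon: more than two true
  haplotypes per sample (paralogue co-amplification) will surface as
  chimera-negative third clusters and manual-review flags, not as
  genotypes.
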