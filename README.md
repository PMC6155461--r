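# mhctyper

Amplicon-based genotyping of MHC class II loci and downstream
immunogenetic analysis, in one tested R package.

## The problem

MHC class II genes (the DQ receptor's `DQA` and `DQB` chains in
particular) are the fastest-evolving part of the vertebrate genome and a
standard marker for how wild populations will cope with pathogens. Typing
them from pooled amplicon sequencing is harder than ordinary variant
calling: samples are diploid PCR products, so every error mode shows up
as a distorted allele ratio — PCR chimeras masquerade as a third allele,
strand-restricted homopolymer indels masquerade as variants, and
tri-allelic sites break callers that force a reference allele.

`mhctyper` implements the full workflow used in amplicon MHC studies of
bottlenose dolphin populations:

1. **Demultiplexing** — length filter, exact dual 10-bp barcode matching
   in both read orientations, fixed-width trimming, and a
   reads-per-sample cutoff with an unused-barcode-combination background
   benchmark (`filter_length()`, `demultiplex()`, `sample_qc()`).
2. **Dual variant calling** — an allele-ratio caller (heterozygote only
   when the minor base is near 50%, homozygote only near 0%) and a
   genotype-likelihood caller (diploid likelihood from base qualities,
   supports both-non-reference genotypes), reconciled through an explicit
   error-class taxonomy: sequencing error, PCR chimera, strand-biased
   misalignment, tri-allelic site, homopolymer context
   (`call_ratio()`, `call_likelihood()`, `reconcile_calls()`,
   `detect_chimeric_haplotypes()`, `call_sample()`).
3. **Read-backed phasing and allele typing** — haplotype clustering at
   heterozygous sites, a named allele catalogue with
   two-individual/ cross-method confirmation rules and stop-codon
   screening, plus parsimonious resolution of Sanger IUPAC consensus
   genotypes against known alleles (`phase_haplotypes()`,
   `build_catalogue()`, `resolve_sanger_genotype()`).
4. **Selection statistics** — partial-codon trimming and translation,
   binding-pocket enrichment G-tests, K2P transition/transversion bias,
   Nei–Gojobori pairwise dN/dS with pathway averaging and an optional
   ts/tv-weighted variant, codon-usage statistics (RSCU, CBI, Wright's
   Nc), and a counting-based per-codon selection scan
   (`exon_to_peptides()`, `pocket_enrichment_test()`, `titv_ratio()`,
   `pairwise_dnds()`, `codon_usage()`, `site_dnds_scan()`).
5. **Population genetics** — Nei's unbiased expected heterozygosity,
   Guo–Thompson Hardy–Weinberg exact tests (complete enumeration with an
   MCMC fallback), Weir–Cockerham FST with individual-level permutation
   tests, and allelic-representation summaries over geographic strata
   (`heterozygosity()`, `hwe_exact()`, `fst_wc()`,
   `allelic_representation()`).
6. **Promoter analysis** — regulatory-motif scanning (W/S, X1/X2, Y,
   NF-kB, T, TTAA boxes) with configurable consensus sequences, tandem
   motif-duplication detection (the 11–22 bp unit range seen in cetacean
   class II promoters), and per-column Shannon entropy profiles
   (`scan_motifs()`, `detect_tandem_duplications()`, `column_entropy()`).

A synthetic-data generator (`gen_allele_set()`, `sim_config()`,
`simulate_dataset()`) produces every input the pipeline needs — diploid
samples drawn from per-stratum allele frequencies with an optional
inbreeding coefficient, dual-barcoded ~350 bp amplicons in random
orientation, substitution errors, strand-restricted homopolymer
deletions, and single-crossover PCR chimeras — with complete ground-truth
bookkeeping, so every stage is testable against known answers.

Key statistics, in the field's notation: Nei's unbiased expected
heterozygosity He = [2n/(2n−1)](1 − Σᵢ pᵢ²); the two-cell goodness-of-fit
G = 2 Σᵢ Oᵢ ln(Oᵢ/Eᵢ); Weir–Cockerham θ = Σa / Σ(a+b+c) over variance
components; NG86 dN/dS with Jukes–Cantor correction; Shannon entropy
H = −Σ p log₂ p per alignment column.

## Worked example

Simulate two strata of 12 diploid individuals at a 10-allele locus and
genotype them end-to-end:

```r
library(mhctyper)
alleles <- gen_allele_set("DQAE", n_alleles = 10, length = 350,
                          n_variable_sites = 18, n_triallelic = 2)
cfg <- sim_config(n_individuals = c(ATL = 12, EST = 12),
                  allele_freqs = list(ATL = rep(0.1, 10), EST = rep(0.1, 10)),
                  reads_per_sample = 520, rng_seed = 42)
sim <- simulate_dataset(alleles, cfg)
res <- genotype_pipeline(sim$reads, sim$sample_barcodes, alleles$reference,
                         locus = "DQAE", prefix = "Sim-DQA1",
                         strata = setNames(sim$truth$stratum, sim$truth$sample_id))
res$report
#> demux report: 12480 reads; 12480 assigned to 24 samples; 0 in unused combinations; 0 unassigned
genotype_concordance(res, sim$truth, alleles)$concordance
#> [1] 1
head(res$genotypes, 3)
#>   sample_id stratum locus     allele1     allele2
#> 1   ATL_001     ATL  DQAE Sim-DQA1*01 Sim-DQA1*07
#> 2   ATL_002     ATL  DQAE Sim-DQA1*06 Sim-DQA1*08
#> 3   ATL_003     ATL  DQAE Sim-DQA1*02 Sim-DQA1*10
```

Every simulated genotype is recovered exactly (concordance 1), and
`res$callsets[[sample]]` records which error classes (chimera, strand
bias, ...) had to be reconciled along the way.

Population statistics work directly on allele-count tables. The package
ships the published per-stratum allele counts for the dolphin DQ loci
(`read_population_table()`); feeding the Atlantic DQA exon-2 column into
the unbiased-heterozygosity formula gives

```r
t2 <- read_population_table()
round(heterozygosity(t2$ATL[t2$locus == "DQAE"])$He, 3)
#> [1] 0.866
g <- pocket_enrichment_test(12, load_pocket_mask("DQA"), 82, n_in_pocket = 8)
round(g$G, 3); signif(g$p_g, 3)
#> [1] 13.519
#> [1] 0.000236
```

i.e. He = 0.866 for the Atlantic stratum, and a strongly significant
excess of amino-acid variation inside the 15 peptide-binding-pocket
residues of the 82-aa DQA peptide (G ≈ 13.5, P < 0.001) — variation is
concentrated exactly where antigen binding happens.

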