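# invexpr

Inversion genotype calling and cis-eQTL analysis for polymorphic
chromosomal inversions, built around the 17q21.31 *MAPT* locus.

## The problem

A common ~900 kb inversion at chromosome 17q21.31 segregates as two
deeply divergent haplotype clades, H1 (direct orientation) and H2
(inverted, ~20% frequency in Europeans). Recombination between
orientations is suppressed, so dozens of SNPs across the interval tag
the clades almost perfectly — and an individual's inversion genotype
(H1/H1, H1/H2, H2/H2) can be reconstructed from ordinary SNP-array data
without any molecular assay. Once genotypes are in hand, the question is
which genes in and around the inversion change expression with the
number of H1 copies, in which tissue.

`invexpr` implements that analysis as a reusable, tested pipeline for
anyone working with local haplotype structure on SNP arrays: population
and statistical geneticists reconstructing inversion or other
two-clade genotypes, and expression-QTL analysts testing dosage effects
against them.

## The method

1. **Genotype QC** — drop individuals with ≥5% missing genotypes, then
   SNPs with call rate ≤95%, MAF ≤0.05, or Hardy–Weinberg p < 10⁻⁵.
2. **EIGENSTRAT-style normalization** — per SNP *j* with mean dosage
   μⱼ and allele frequency pⱼ = μⱼ/2:
   zᵢⱼ = (gᵢⱼ − μⱼ) / √(pⱼ(1 − pⱼ)), missing set to the column mean.
3. **Local PCA** — principal components of the normalized matrix over
   the inversion interval (chr17:40,850,001–41,850,000). PC1 separates
   the three inversion genotypes into three clusters.
4. **Genotype calling** — deterministic 1-D k-means (k = 3) on PC1;
   clusters ordered by mean PC1 map to H1 dosage 2/1/0; individuals
   more than 3 SD from their own cluster mean are excluded as
   ambiguous (recombinant or poorly genotyped).
5. **HWE validation** — 1-df chi-square test of the called genotype
   counts against p², 2pq, q².
6. **Cis-eQTL regression** — for every detected probe within 1 Mb of
   the inversion (chr17:39,899,921–42,989,253), OLS of log2 expression
   on H1 dosage plus covariates:
   y = β₀ + B·dosage + Xγ + ε. B is the expression change per H1
   copy; significance is Bonferroni-controlled at α/m.
7. **Probe QC** — flag probes with common SNPs (MAF > 1%) in their
   50-mer footprint, and probes whose sequence aligns ungapped at ≥90%
   identity to transcripts of more than one gene (cross-hybridization
   to paralogs, an issue for the *LRRC37* family at the inversion
   breakpoints).

A two-clade haplotype simulator (`simulate_haplotype_pools()`,
`simulate_cohort()`, `inject_recombinants()`, `simulate_expression()`)
generates cohorts with exactly this structure — HWE clade sampling,
within-clade flips, recombinant ambiguous individuals, dosage-linked
expression — so every stage is testable with known ground truth.

## Worked example

```r
library(invexpr)
res <- run_demo(seed = 1, out_dir = "demo")   # simulate + full pipeline
cat(readLines("demo/report.txt"), sep = "\n")
```

```
Inversion genotype calls
  interval: chr17:40850001-41850000; exclusion: >3 SD from cluster mean
  H1/H1 255 (59%), H1/H2 156 (36%), H2/H2 21 (5%); 3 excluded
  Hardy-Weinberg p = 0.65

Cis-eQTL scan (whole_blood): 28 probes tested, threshold 0.0018 (alpha 0.05)
  probe001   GENE001    B =   0.23 (0.19, 0.26)  p = 2.8e-28  *
  probe002   GENE002    B =  -0.02 (-0.07, 0.03)  p = 3.9e-01
  ...
```

The demo simulates 437 individuals at H2 frequency 0.21 with one causal
probe (true effect 0.37 per H1 copy) among 28. The report shows the
three genotype clusters with their counts and percentages, the
Hardy–Weinberg p of the calls (a check that clustering recovered real
genotypes: values ≫ 0.001 are consistent with random mating), and the
per-probe dosage effects with 95% CIs. Only the causal probe crosses
the Bonferroni threshold 0.05/28 (displayed 0.0018). Its fitted B
(0.23) sits below the generative 0.37 because quantile normalization
over a 28-probe panel absorbs part of a strong single-probe effect —
see the vignette.

Step-by-step equivalents:

```r
pools  <- simulate_haplotype_pools(60, 20, divergence = 0.8, flip_rate = 0.05, seed = 1)
sim    <- simulate_cohort(pools, 431, h2_freq = 0.21, seed = 2)
calls  <- call_inversion(sim$genotypes)
glance(calls)                       # counts, exclusions, HWE chi2 and p
autoplot(calls)                     # PC1/PC2 tri-cluster scatter
covars <- simulate_covariates(431, seed = 3, individual_ids = sim$truth$individual_id)
expr   <- simulate_expression(sim$truth, c(0.37, rep(0, 27)),
                              covariates = covars, noise_sd = 0.3, seed = 4)
eqtl   <- run_cis_eqtl(preprocess_expression(expr, "blood", log2_transform = FALSE),
                       calls, covars, tissue = "whole_blood")
autoplot(eqtl)                      # per-probe B with 95% CI
```

A command-line wrapper with the same stages lives at
`inst/cli/invexpr` (subcommands `simulate`, `call-inversion`, `eqtl`,
`probe-qc`, `run`, `demo`).

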