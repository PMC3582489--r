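---
title: "Methods: inversion genotyping from SNP arrays and dosage eQTL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion genotyping from SNP arrays and dosage eQTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invexpr)
```

## The model

A polymorphic inversion suppresses recombination between its direct
(H1) and inverted (H2) orientations. Over evolutionary time the two
orientations accumulate divergent variation, so across the inverted
interval the population consists of two deeply separated haplotype
clades with strong internal linkage disequilibrium. Three consequences
drive everything this package does:

* an individual's pair of clade memberships — H1/H1, H1/H2, H2/H2 —
  behaves like a single biallelic "master genotype" even though no
  single assayed SNP encodes it;
* a principal component analysis of the local SNP dosage matrix
  concentrates the clade signal in PC1, which takes three well
  separated values, one per genotype;
* if clade membership is what PCA recovered, the three cluster sizes
  must be consistent with Hardy–Weinberg proportions p², 2pq, q² — a
  free goodness-of-fit check on the calling itself.

The expression analysis then treats the called H1 count (2/1/0) as an
ordinary allele dosage and fits, per expression probe in the flanking
cis window,

$$ y_i = \beta_0 + B \cdot d_i + X_i\gamma + \varepsilon_i,
   \qquad \varepsilon_i \sim N(0,\sigma^2), $$

where $B$ is the log2-expression change per H1 copy and $X$ holds
covariates (age, gender, and for brain data post-mortem interval,
brain bank and hybridization batch, one-hot encoded dropping the first
level). Probes are declared significant under Bonferroni control at
$\alpha/m$ with $m$ the number of probes tested in that dataset; brain
regions are tested independently, each with its own $m$.

## Normalization and PCA

Genotypes are encoded as minor-homozygote 0, heterozygote 1,
major-homozygote 2 (the dosage counts the major allele). Each SNP
column is centered at its mean $\mu_j$ and scaled by
$\sqrt{p_j(1-p_j)}$ with $p_j = \mu_j/2$, the normalization that puts
SNPs of different allele frequency on a comparable scale before PCA.
Missing entries become 0 after centering (the column mean), so they
pull no direction. The allele-frequency estimate is the plain
$\mu_j/2$; a pseudocount variant $(1+\sum g)/(2+2n)$ is available via
`pseudocount = TRUE` for small cohorts. Zero-variance columns are
dropped with a warning — they carry no information and would divide by
zero.

Scores are projections onto the top eigenvectors of the sample
covariance (computed by SVD). Eigenvector signs are arbitrary, so PC1
is oriented to correlate non-negatively with mean raw dosage across
the interval: since the major allele at divergent sites is the H1
allele in any cohort where H1 is the majority clade, higher PC1 then
means more H1-like. If H2 were the majority clade the rule would flip
the labels; supplying your own `orient` vector to
`principal_components()` (e.g. the dosage of a known tag SNP) overrides
the default.

## Genotype calling

PC1 is clustered with one-dimensional k-means, k = 3, run with Lloyd
iterations from two deterministic starts: the 1/6, 1/2, 5/6 sample
quantiles of PC1, and the same fractions of the PC1 *range*. The
lower within-cluster-SS solution is kept. Two starts matter because the
genotype classes are heavily unbalanced (roughly 62/33/4% at an H2
frequency of 0.2): mass-based quantile centers all land inside or near
the majority cluster and Lloyd can then converge to a split of that
cluster, while range-based centers handle exactly that geometry but
would be wasteful if the classes were balanced and tight. Both starts
are data-deterministic and independent of individual order, so calls
are reproducible without a random seed.

Clusters ordered by mean PC1 map to dosage 0, 1, 2 (highest = H1/H1).
After fitting — in a single pass, without refitting — any individual
farther than `sd_limit` (default 3) within-cluster standard deviations
from its own cluster mean is labeled `EXCLUDED`. These are typically
recombinant haplotypes: a single crossover inside the interval produces
a chromosome half H1-like and half H2-like whose PC1 falls between
clusters, and no integer dosage describes it. A cluster with SD 0 (the
noiseless limit) excludes nobody, by convention; raising `sd_limit`
can only shrink the excluded set. Counts and the Hardy–Weinberg test
use the remaining individuals only.

The HWE test is the 1-df chi-square: allele frequency estimated from
the counts, expected classes $Nq^2, 2Nq(1-q), N(1-q)^2$, upper-tail
p from $\chi^2_1$ (three classes, minus one for the total, minus one
for the estimated frequency). An exact test is not provided; at the
cohort sizes this analysis targets (hundreds) the chi-square
approximation is standard practice.

## Expression preprocessing

Intensities are log2 transformed and quantile normalized across
individuals (`limma::normalizeQuantiles`, ties averaged), then
detection-filtered: blood-style arrays keep probes with mean detection
value > 0.90, brain-style arrays keep probes with detection p < 0.01,
each region filtered separately. With one individual, quantile
normalization is the identity.

One behavior to know about: quantile normalization forces every
individual's expression distribution *across the probe panel* to be
identical. On a full array (tens of thousands of probes) a single
eQTL probe contributes negligibly to that distribution, but on a small
panel — such as the 28-probe demonstration cohort — a strong
dosage-linked probe shifts high-dosage individuals' distributions
enough that normalization absorbs part of the effect. The demo's
fitted B ≈ 0.23 against a generative 0.37 is this attenuation, not an
estimation bug: fitting the same simulated expression without
normalization recovers 0.37 with nominal CI coverage (the test suite
verifies both). Interpret small-panel runs accordingly.

## The regression

`fit_dosage_model()` is ordinary least squares via `lm`, with the
p-value from the t distribution at $n-k-1$ df and the 95% CI
$B \pm t_{0.975,\,df}\,\mathrm{SE}$. Degenerate cases are deliberate
conventions rather than errors: zero residual variance (possible in
noiseless simulations) reports SE = 0, p = 0 with a warning; collinear
covariates are dropped with a warning and the model refit; constant
dosage is an error, since no dosage effect is estimable. Individuals
are always matched across genotype, expression and covariate tables by
ID string — never by column position — and individuals with missing
covariates are dropped listwise for that tissue.

## The simulator

The generator is a two-prototype flip model, not a coalescent. Two
binary prototype haplotypes differ at `round(divergence × n_inside)`
inside-inversion sites; a drawn haplotype copies its clade's prototype
and flips each inside site independently with probability `flip_rate`;
outside sites are clade-independent variants with MAF uniform on
[0.05, 0.5]. Individuals receive two independent clade draws
(H2 with probability `h2_freq` — HWE by construction), genotypes are
allele sums recoded to the minor/major convention (frequency ties
break toward the H1-prototype allele, so the orientation rule stays
coherent), and missingness is injected completely at random.
`inject_recombinants()` replaces one haplotype of a chosen fraction of
individuals with a single-crossover H1/H2 mosaic and marks their truth
dosage ambiguous. Expression is the linear model above, generated
forward from true dosage.

Defaults are the study conditions the package is built around: H2
frequency 0.2 (≈0.21 in the demonstration cohort, matching the
realized frequency in a 431-individual blood cohort), 60 SNPs inside
the inversion and 20 flanking, divergence 0.8 and flip rate 0.05. The
divergence and flip values are not published quantities — no generative
parameters for within-clade diversity exist in the source material —
they are chosen once to produce the clean tri-cluster PC1 geometry real
17q21.31 data shows, and they are exposed in the config rather than
hard-coded. What the simulator does *not* model, by design: a
recombination map, mutation-rate realism, copy-number variation of the
breakpoint *LRRC37* family, or array-level intensity artifacts. Passing
tests therefore demonstrate that the statistics recover the structure
the model assumes; they do not certify behavior under CNV-driven
cross-hybridization or assay artifacts beyond the probe-level checks.

## Probe QC

Two artifact checks. First, a probe whose genomic footprint contains a
common SNP (MAF > 1%) can track genotype rather than expression; SNPs
are intersected with probe intervals on 1-based inclusive coordinates.
Second, cross-hybridization: the 50-mer probe sequence is slid over
every ungapped offset of each supplied transcript, on both strands,
scoring percent identity as matches/50 (N never matches; transcripts
shorter than the probe are scored over their best ≥25-base overlap,
else skipped). A probe hitting transcripts of more than one gene at
≥90% identity is flagged multi-target. The ungapped scan approximates
a BLAST search of the probe against a transcript database: at 50-mer
scale, hits at the 94–100% identity level that matter here are
ungapped, so gap handling and E-value statistics are omitted. The 90%
default separates that hit range from background; it is a package
choice, exposed as `min_identity`.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (UCSC browser text
  convention); BED input is converted on read.
* Default intervals: inversion chr17:40,850,001–41,850,000; cis window
  chr17:39,899,921–42,989,253 (1 Mb each side). The config validates
  that the inversion lies inside the cis window before any stage runs.
* The Bonferroni threshold is computed exactly as α/m and compared at
  full precision; the report displays it at two significant figures.
* Report percentages round half-up (so 37.5% prints as 38%); HWE p
  prints to 2 decimals, effects and CIs to 2 decimals, p-values in
  2-significant-digit scientific notation.
* The pipeline is deterministic end-to-end under a fixed config and
  seed; reruns produce byte-identical outputs.
* The orchestration layer is exposed as R functions
  (`run_pipeline()`, `run_demo()`) with a thin `Rscript` wrapper in
  `inst/cli/`; the config file is YAML.

## Problem sizes used in the test suite

Statistical guarantees are verified by simulation at sizes chosen to
be decisive yet desk-scale: CI coverage over 2,000 replicates (500 at
each of four effect-size/sample-size presets: B = 0.37 and −0.19 at
n = 431, B = 0.34 and −0.25 at n = 144, residual SD 0.3), family-wise
error over 1,000 all-null replicates of a 28-probe panel, genotype
recovery on 400-individual cohorts at divergence 0.8/flip 0.05 (and
exactness on noiseless cohorts across seeds), generator HWE
conformance over 400 cohorts of 500, and oracle agreement (OLS against
explicit normal equations, PCA against a dense eigendecomposition) to
10⁻⁸ on randomized small matrices.

## Known limitations

* The caller assumes the tri-cluster geometry exists: a cohort where
  one genotype class is absent still returns three clusters only if
  PC1 has at least three distinct values, and a missing class surfaces
  as a zero count with a warning, not as a 2-cluster refit.
* PC1 orientation relies on H1 being the majority clade unless a tag
  SNP or custom orientation vector is supplied.
* Quantile normalization on small probe panels attenuates strong
  effects (see above).
* The HWE chi-square is asymptotic; with expected class counts below
  ~5 its p-values are approximate.
* Cross-hybridization QC sees only the transcripts it is given; it
  cannot flag paralogs absent from the supplied FASTA.
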