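---
title: "Methods: ROH detection, inbreeding-depression models and the ROH-status scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, inbreeding-depression models and the ROH-status scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rohdepress` implements a genomic inbreeding-depression analysis for large
diploid SNP panels, developed around the Thoroughbred horse setting: a
binary fitness outcome (did a horse ever race before age five), dense
array genotypes on 31 autosomes totalling 2281 Mb, and a population with
high background homozygosity (mean F_ROH near 0.28). This vignette
documents the models, the tunable parameters, the synthetic cohort
generator used for validation, and the numerical choices the
implementation makes where the underlying conventions leave room.

## ROH detection

Runs of homozygosity are called with a sliding-window algorithm following
the PLINK 1.9 `--homozyg` conventions. The default `roh_params()` are
`window_snp = 30`, `min_snp = 30`, `min_kb = 300`, `max_gap_kb = 150`,
`density_kb_per_snp = 100`, `window_missing = 1`, `window_het = 1`:

* every window of 30 consecutive SNPs is *homozygous* if it contains at
  most one heterozygous and at most one missing call;
* a SNP is a candidate if at least 5% (`window_threshold = 0.05`, the
  reference tool's default for its unstated sub-parameter) of the windows
  containing it are homozygous;
* maximal candidate runs are split wherever adjacent genotyped SNPs are
  more than 150 kb apart, heterozygous/missing ends are trimmed, and each
  piece is emitted only if it has ≥ 30 SNPs, spans ≥ 300 kb, and averages
  ≤ 100 kb per SNP (density applied to the final segment, not
  per sub-window).

Windows are truncated at chromosome ends (a chromosome with fewer SNPs
than the window size uses one truncated window). Coordinates are 1-based
inclusive; segment length is `end − start + 1`. The test suite pins these
semantics to an independent brute-force enumerator over hundreds of random
instances, so the compiled scanning code and the stated rules cannot
drift apart.

F_ROH is the summed segment length divided by the total autosomal length
(2281 Mb at full scale; always the sum of the supplied chromosome
lengths). Segments split at 5 Mb into `f_roh_short` (< 5 Mb, older
haplotypes) and `f_roh_long` (≥ 5 Mb, recent ancestors); a segment of
exactly 5 Mb is long. Under a uniform 1 cM/Mb map the expected age of a
segment of length L Mb is `100/(2L)` generations (`generations_to_ancestor()`),
so the 5 Mb boundary corresponds to roughly 10 generations.
`froh_mod()` gives the leave-one-chromosome-out coefficient used in the
scan; its denominator excludes the focal chromosome's length so it remains
a proper genome fraction across chromosomes of different sizes.

## Inbreeding-depression models

`fit_binomial_glmm()` fits
`Pr(raced) = logit⁻¹(Xβ + α_year)`, `α ~ N(0, σ²)` by adaptive
Gauss–Hermite quadrature (default 15 nodes; 1 node = Laplace, the fast
mode used genome-wide). Fitting is delegated to `lme4::glmer` — the
standard tool for this model class — behind a stable interface that adds
rank-deficiency checks, separation detection (an error when coefficients
run away past ±15 without convergence), a convergence flag that
downstream predictions refuse to ignore, and Wald inference
(`z = β/se`, `p = 2Φ(−|z|)`). With no grouping (or `sigma2_zero = TRUE`)
the model collapses to ordinary logistic regression via `stats::glm`,
which the tests verify against an independent optimizer.

The model suite mirrors the analysis stages: `fit_froh_model()`
(`raced ~ f_roh + region + sex`, birth-year random intercept),
`fit_short_long_model()` (the two length components),
`fit_interaction_model()` (`f_roh × region`), and
`fit_race_count_model()` (negative binomial with log link on race counts
among raced animals; the family is a package choice made for
overdispersion robustness, with birth year as a fixed factor, and the
Poisson limit cross-checked in tests). Categorical covariates use
treatment contrasts with reference levels sex = F and region = ANZ;
`prediction_table()` evaluates fitted probabilities over an F_ROH grid at
that reference profile with the random effect at zero, and
`odds_change(β, δ)` converts a log odds ratio into the percent change in
odds for a covariate shift δ (e.g. a −5.75 slope and δ = 0.10 give −44%).

## The allele-specific ROH-status scan

At every SNP, `gwas_scan()` fits the racing outcome on two indicators —
ROH overlapping the SNP with the *minor* allele homozygous, and with the
*major* allele homozygous — plus the additive 0/1/2 dosage, F_ROHmod for
the focal chromosome, region, sex, 10 principal components of the
variance-standardized genomic relationship matrix (`grm_pca()`), and birth
year. A heterozygous or missing call inside a ROH codes (0, 0) — legal,
since windows tolerate one heterozygote. The minor allele is frozen
panel-wide from `variant_stats()` before the scan (ties at 0.5 resolve to
`allele_a`).

The per-SNP fits run in compiled code (RcppArmadillo IRLS warm-started
from the base model refitted per chromosome) with birth year as a fixed
factor — the scan fast mode; tens of thousands of mixed-model fits per
cohort are otherwise impractical on one core. The accuracy mode, `refine_hits()`, re-fits
sub-threshold candidates with the full mixed model and replaces their
effects and p-values; the tests additionally verify the compiled path
coefficient-for-coefficient against `stats::glm`.
Indicators observed in fewer than `min_count = 5` individuals report
missing p-values (rare states invite separation artifacts); unconverged
fits are flagged and excluded from threshold comparisons.

Multiple testing uses simpleM (`simple_m()`): per chromosome, SNPs are
partitioned into consecutive blocks (default 1000), the composite
genotype correlation matrix of each block is eigendecomposed, and the
smallest number of leading eigenvalues reaching 99.5% of the total
variance is summed over blocks to give the effective test count m_eff.
The genome-wide threshold is `alpha / (2 · m_eff)` — doubled because each
model contributes two ROH tests. Dosage correlations (not phased
haplotypes) are simpleM's standard input; missing dosages are
mean-imputed within SNP and constant columns are dropped with a warning.

## Haplotype screen

Around a focal SNP, `extract_window()` takes all SNPs within 500 kb on
each side from a *phased* cohort (no internal phasing; unphased input is
refused). `consensus_analysis()` defines the risk haplotype as the modal
string among the ROH + minor-homozygote individuals (ties broken
lexicographically — the screen expects one exactly shared haplotype, so
the mode is the natural estimator), reports the fraction of those
individuals homozygous for it, the mean Hamming mismatch of deviating
haplotypes, and exact-copy carrier status for every sample; near misses
(≤ 2 mismatches) are reported separately, never merged into carriers.
`group_enrichment()` compares chromosome-level copy counts between two
groups by a two-sided Fisher exact test, and `hwe_expected_counts()`
projects homozygote/carrier counts under Hardy–Weinberg proportions.

## The synthetic cohort generator

Real genotypes for this problem are proprietary, so validation uses
`simulate_cohort()`, which emulates the data structure the models assume:

* **Background ("old") homozygosity.** Founder haplotypes are mosaics
  over a small pool of ancestral haplotypes (default 3, each SNP kept polymorphic in the pool to emulate array
  ascertainment) with exponential segment lengths (mean 3 Mb). Two founder haplotypes therefore share
  ancestry over short tracts, producing the short-ROH background and
  block-wise LD. Pool size and mosaic scale were fixed once so that the
  called coefficients on a default cohort sit near the study conditions:
  mean F_ROH ≈ 0.28 with roughly equal-thirds splits drifting between
  short and long components across seeds (short ≈ 0.15, long ≈ 0.12).
* **Recent inbreeding.** An explicit pedigree phase: each generation
  draws dams uniformly and sires with weight `exp(w · kinship)` (pedigree
  kinship tracked exactly by the tabular method; `w = 5` by default, an
  exponential tilt chosen as the simplest monotone preference), then
  recombines with Poisson(L_cM/100) crossovers at uniform positions —
  1 cM/Mb throughout. Founder-haplotype ancestry is tracked along every
  chromosome, so true autozygous segments (and true F) come from
  pedigree transmission, not from genotype inspection.
* **The risk haplotype.** An exact allele string spanning 1 Mb is
  embedded in a fraction q = 0.101 of founder haplotypes. Its central SNP
  is a tag: the alternate allele occurs only on carrier haplotypes, as
  for a rare haplotype-tagging association hit. True risk homozygotes
  are samples carrying two intact copies.
* **Phenotypes.** `raced ~ Bernoulli(logit⁻¹(β₀ + β_froh F + β_hom hom +
  β_sex M + β_region EUR + α_year))` with defaults β_froh = −5.75,
  β_hom = −1.82, β₀ = 3.5 (to match an ≈ 87% raced rate at mean
  inbreeding), β_region = −0.8 (EUR raced less in the source cohort),
  β_sex = −0.1, σ_year = 0.3. Race counts are negative binomial
  (mean 16, size 3) with no inbreeding effect by default.

SNP positions form a jittered regular grid (gaps bounded by twice the
spacing), emulating an array design; at the scaled default density of
15 SNPs/Mb, uniformly random positions would produce frequent > 150 kb
gaps that fragment segments purely as a sampling artifact.

What the generator does **not** emulate: genotyping error and missing
calls, imputation artifacts, a realistic recombination map, selection
during breeding, mutation, and fine-scale demography. Passing tests
therefore show that the *methods* recover what they are designed to
recover under the assumed data structure, not that any particular
biological estimate from real data is correct.

A phenotype-only generator, `simulate_glmm_cohort()`, draws covariates
and outcomes directly from the racing GLMM with F_ROH ~
0.18 + 0.22·Beta(2, 2.4) (mean 0.28, range 0.18–0.40) and 38 birth-year
levels, for calibration studies of the fitting stage at full sample size
without genotype simulation.

## Validation scales

The package validates itself at desk scale; the suite uses sizes chosen
a priori for statistical power per check, stated here as the package's
own experiment design:

* *Caller correctness*: 200 random instances (≤ 200 SNPs) against the
  brute-force oracle — an exact, not statistical, check.
* *GLMM recovery*: 100 phenotype-level cohorts at n = 5000 with 38
  birth-year levels and β_froh = −5.75; 95% Wald coverage and relative
  bias of the slope.
* *Locus recovery*: genotype-level cohorts at n = 5000 on 4 chromosomes
  (≈ 4400 SNPs, risk haplotype q = 0.101, β_hom = −1.82, strong
  kinship-weighted mating). This n keeps the expected ROH +
  minor-homozygote count near the ~1% the screen is designed around
  while the reduced genome keeps each replicate's scan tractable; locus
  recovery is judged by whether the genome-wide minimum p for the
  minor-homozygote test falls within ±500 kb of the embedded locus, and
  specificity by permuted-phenotype scans against the simpleM threshold,
  with sub-threshold candidates adjudicated by the accuracy-mode refit
  (`refine_hits()`) and one family-wise error tolerated — the 5% rate
  the threshold is designed to admit.
* *Short/long dissociation*: cohorts at n = 1000 with the fitness effect
  tied to true autozygous segments ≥ 5 Mb; the fitted model should load
  on `f_roh_long` and not on `f_roh_short`.
* *Consensus recovery*: 50 seeded small cohorts; whenever at least three
  risk homozygotes exist, the modal haplotype must equal the embedded
  string exactly.

## Known limitations

* The scan fast mode treats birth year as fixed; with very many sparse
  year levels the Wald statistics can be slightly anticonservative
  relative to the full mixed fit. Candidate hits should be re-fitted
  with `fit_binomial_glmm()` at full quadrature.
* simpleM's block partition is positional; block size is exposed
  (`block_size`) because no canonical choice exists for arbitrary
  panels.
* `f_roh_mod`'s denominator convention (excluding the focal chromosome)
  is one of two defensible definitions; it is surfaced in the function
  documentation rather than hidden.
* The PLINK writer emits unphased genotypes; phased haplotypes live only
  in the in-memory cohort (or a phased VCF upstream of the package).
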