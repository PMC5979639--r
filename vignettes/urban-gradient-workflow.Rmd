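---
title: "Population genomics along an urbanization gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics along an urbanization gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanpopgen)
library(dplyr)
```

`urbanpopgen` implements a complete analysis chain for a question that has
become central in urban evolutionary biology: when a wild population — here
modelled on great tits (*Parus major*) breeding from a rural forest into a
city centre — is sampled along a continuous urbanization gradient, does
urbanization leave detectable marks on genome-wide diversity, on genetic
differentiation between sites, and on the allele frequencies of individual
loci? This vignette explains each model in the chain, the tunable
parameters and their defaults, the synthetic-data generator used for
testing and power analysis, and the numerical choices and limitations a
user should know about.

## The data model

Everything operates on a `genotype_matrix`: an individuals x SNPs matrix of
alternate-allele dosages (0/1/2, `NA` missing), an aligned variant table
(chromosome, 1-based position, ref/alt), and optionally per-genotype read
depths. Missingness is always a dedicated `NA`, never a zero: observed
heterozygosity, identity-by-state and the FST variance components all treat
"no call" differently from "homozygous reference". Coordinates stay 1-based
inclusive at every file boundary (VCF, GFF3) so that a write/read round
trip is bit-identical.

## Quality control

The filters mirror a conventional RAD-seq pipeline, in a fixed order with
per-stage accounting: per-genotype depth masking (default minimum 8 reads),
variant call rate (>= 90% of all individuals pooled), mean depth window
(20-100 reads, skipped when no depths are present), pooled minor allele
frequency (>= 0.05, bound inclusive), then an exact Hardy-Weinberg test
(Wigginton-style enumeration of heterozygote counts conditional on allele
counts, two-sided by probability-mass ordering, no mid-p) applied in a
single reference site only (default `ROU`, the rural forest, the largest
sample). Testing HWE only there removes genotyping artefacts and paralogs
without touching between-site differentiation, which is the signal of
interest; small urban samples would anyway have little power. Finally
individuals genotyped for fewer than 95% of loci are dropped. All filters
are idempotent: re-applying them to already-filtered data removes nothing,
so the pipeline can start from a deposited VCF that may or may not be
pre-filtered.

## Diversity, relatedness, differentiation

Observed heterozygosity is per-individual: the heterozygous fraction of
non-missing genotypes. Site differences are assessed with a one-way ANOVA
plus Tukey HSD and a compact letter display.

Identity-by-state between two individuals is the allele-sharing fraction
`mean(1 - |g_i - g_j| / 2)` over SNPs called in both — the common
SNP-toolkit convention. Close relatives (IBS > 0.80, roughly first-degree
at these allele-frequency spectra) are pruned greedily and
deterministically: repeatedly remove the individual in the most
above-threshold pairs, ties broken by lower call rate then lexicographic
id. A chain A-B, B-C loses only B. Pruning matters because related
individuals inflate between-site FST.

Differentiation uses the Weir-Cockerham (1984) moment estimator: per SNP,
variance components `a` (among populations), `b` (among individuals within
populations) and `c` (within individuals) are computed from genotype
counts with explicit correction for unequal sample sizes, and
`theta = a / (a + b + c)`. Negative per-SNP estimates are retained — they
are part of the estimator's sampling distribution — but multilocus pairwise
estimates aggregate as the ratio of summed components, the convention of
the population-genetics toolkits this estimator comes from. Significance of
pairwise estimates is by permutation of individuals between the two sites,
with the add-one p-value estimator and a required seed.

Gradient summaries regress site-mean heterozygosity on site urbanization
(sites weighted equally: one biological unit each), individual
heterozygosity on nest-level urbanization, linearized differentiation
`fst / (1 - fst)` on great-circle distance (haversine, km) and on absolute
urbanization difference, and individual-pair IBS on the same two
predictors.

## Ordination

`genotype_pca()` uses the EIGENSTRAT-style standardization: dosages
centered by twice the allele frequency and divided by
`sqrt(2 p (1 - p))` (plain centering is available for sensitivity checks).
Missing cells are mean-imputed before decomposition — deterministic and
adequate at the <= 10% post-QC missingness this pipeline targets, though it
shrinks the scores of poorly genotyped individuals toward the origin. The
decomposition runs on the individuals-by-individuals Gram matrix, so cost
scales with sample size rather than SNP count; axis signs are fixed by
making the largest-magnitude loading positive.

`rda_fit()` is constrained ordination (RDA) of the centered — not
variance-scaled — dosage matrix on latitude, longitude and urbanization;
with conditioning variables it is partial RDA (response and constraints
residualized on the conditions first). Unscaled inertia is deliberate: the
interesting quantities are sub-1% proportions of total genotypic variance,
and scaling SNP columns would reweight them. Permutation tests permute rows
freely (no blocks); marginal tests condition each variable on all others.
The model fitting is delegated to vegan; the package's tests check it
against an independently coded regression-plus-eigendecomposition oracle.

## Gene-environment association

The association model is a latent factor mixed model,
`G = U V' + x b' + E`: each SNP's dosage is regressed on the environmental
score `x` while `K` latent factors absorb residual population structure.
`K = 1` by default, reading a sample that behaves as a single genetic
cluster as one latent axis; `K` is exposed because that choice is a
modelling judgement. Two solvers are provided:

* **ridge** (default): deterministic and spectral. Factors are the top
  `K` singular vectors of the genotype matrix residualized on `x`; effects
  come from a joint regression of each SNP on `[x, U]` with a ridge
  penalty on the latent block only. With `K = 0` this is exactly per-SNP
  ordinary least squares, and as the penalty grows the latent block
  vanishes and the fit again degrades to per-SNP regression — both are
  tested identities.
* **gibbs**: a conjugate Gibbs sampler on the same model (normal priors on
  `U`, `V`, `b`; inverse-gamma on per-SNP residual variances), averaging
  z-scores over several independent runs, for users who want the
  sampling-based analogue. It is slower and stochastic; at desk scale the
  ridge solution is the reference surface, and the two rank-agree closely
  on planted-signal data.

Z-scores are genomic-inflation calibrated before p-values:
`lambda = median(z^2) / 0.456`, `p = P(chi2_1 > z^2 / lambda)`. Any
residual structure the `K` factors miss inflates the whole z distribution;
dividing by the median-based lambda restores a uniform null to a good
approximation (the tests require the null fraction of p < .05 to sit in
0.05 +/- 0.01 at 20k SNPs).

Urbanization may act at several spatial scales, so six environment codings
are run: nest-level score (test A), site-mean score (B), a binary
forest-vs-city contrast (C), and the same three with the semi-natural zoo
site removed from the design (D-F) — its individuals are re-projected in
the downstream outlier PCAs, which is informative about whether they
resemble forest or city birds at candidate loci.

Q-values are Storey's estimator: the true-null fraction pi0 comes from a
cubic smoother on the tail-uniformity grid, and q-values are the usual
monotone transform. Benjamini-Hochberg (pi0 = 1) is available; with fewer
than 100 p-values Storey's smoother is unreliable and the package falls
back to BH with a warning.

## Polygenic aggregation

Four tools summarize many weak signals: a sliding-window moving average of
z-scores (uniform kernel, 10 Mb window sliding by 10 kb, grid anchored at
the first SNP position rounded down to the step — deterministic and
independent of chromosome length; a Gaussian kernel is available behind a
flag); outlier-set algebra across the six tests (per-test sets at q < 0.05,
union, Venn cell counts, single-test-only count); the variance in
urbanization explained by PC1/PC2 of a PCA restricted to an outlier subset;
and the cumulative curve of that r-squared as SNPs are added in decreasing
|z| order, against a baseline of 10 random subsets of the same sizes
(sampled without replacement). A polygenic architecture shows the
characteristic shape: steep rise within the top-ranked SNPs, plateau, then
decline toward the small full-set value as neutral SNPs dilute the leading
axis, with the random baseline flat and low throughout.

SNP-to-gene assignment is interval containment (optionally widened by a
distance), one row per overlap, intergenic SNPs kept with a missing gene
label; term enrichment is an upper-tail hypergeometric test against a
user-supplied gene-to-term map with BH correction, using the genes
represented in the SNP panel — not the genome — as the universe.

## The synthetic-data generator

`simulate_dataset()` produces datasets with the statistical structure the
analysis assumes, so every stage is testable without field data. Defaults
are the study conditions of a six-site urban-gradient sample:

| parameter | default | why |
|---|---|---|
| sites, sizes | MNO 18, FCO 10, MOS 5, GRA 29, ROU 47, ZOO 31 | the unequal six-site design (140 birds) |
| site urbanization means | +2.32 ... -2.19 | observed range of the urbanization score |
| `urb_sd` | 0.62 | within-site nest-score spread implied by the reported between/within variance ratio (ANOVA F ~ 180) |
| `n_snps`, chromosomes | 49,969 on 32 chromosomes, ~1 Gb | RAD-seq panel shape |
| `fst` | 0.007 | genome-wide mean pairwise differentiation |
| `geo_share` | 1/3 | fraction of neutral drift aligned with longitude (below) |
| `causal_fraction`, `beta_sd` | 0.005, 0.55 | a minority of loci with modest clines; keeps realized FST at ~0.007-0.008 and association scores small, as observed |
| `family_pairs` | GRA 3, ZOO 6, ROU 6 | sibling pairs matching the pruning counts |
| `missing_rate`, depths | 0.02; NB(mean 72, size 3.5) | missingness <= 10%/locus, mean depth 72, 5th percentile ~24 |

Neutral drift has two components summing to the target F\*. A fraction
`geo_share` follows a longitude-aligned cline on the logit scale
(`delta_j ~ N(0, geo_share F / (p0 q0))`, so each SNP's cline component
contributes exactly `geo_share * F` to its differentiation); the remainder
is site-idiosyncratic Balding-Nichols drift. The cline exists because a
pure island model proved unable to reproduce a robust feature of real
urban-gradient data that the downstream analyses presuppose: with six
exchangeable sites the leading genetic axis is a *random* site contrast
whose correlation with urbanization is heavy-tailed across realizations,
whereas in the field the leading axis is geographic (longitude is the
dominant spatial driver in the RDA) and only weakly related to
urbanization. With the cline, PC1 is a stable geographic axis and the
full-SNP-set PCA explains only ~10-20% of urbanization variance, as a
geography-dominated structure should.

Causal SNPs get deterministic clines `logit(p_s) = logit(p0) + beta_j u_s`
in site urbanization; effects act on allele frequencies, not phenotypes,
because allele frequency versus urbanization is the association target.
The effect distribution is Normal by default. The canned `signal` power
fixture instead uses fixed-magnitude random-sign effects (|beta| = 0.55):
with Gaussian effects no single scale simultaneously gives the planted
loci enough power to dominate the top-100 |z| *and* keeps them from
dominating the full-set PCA — a tight effect distribution is the only
regime in which the rise-plateau-decline curve with a low random baseline
exists at this sample size. Exactly `round(pi * n_snps)` loci are planted
so the design, not the seed, fixes the causal count.

Planted families are full-sibling pairs — two offspring of two latent
parents drawn from the site frequencies, replacing two simulated
individuals — whose expected IBS (~0.82 under this frequency spectrum)
clears the 0.80 pruning threshold with margin, slightly more than
parent-offspring pairs would (~0.80).

What the generator does **not** emulate, and hence what passing tests do
not show about real data: linkage and recombination (SNPs are independent
given site frequencies, so LD-decay output on simulated data is flat at the
1/n null), RAD-seq allele-frequency ascertainment (mean IBS is ~0.69
rather than the ~0.75 typical of post-filter RAD panels), any
diversity-urbanization gradient (simulated heterozygosity is flat across
sites; the package's Ho regression is exercised on the printed six-site
summary table instead), selection dynamics through time, and batch or
sequencing artefacts beyond simple uniform missingness.

## Problem sizes and numerical choices

The test-suite and acceptance computations run at deliberately desk-scale
sizes, chosen as the package's own simulation design: calibration and power
datasets of 6 sites x 20 individuals x 20k SNPs, a study-scale emulation at
140 x 49,969 for the pipeline quantities, and an RDA size calibration of
500 null replicates at 24 x 40 with 99 permutations. Other numerical
choices worth knowing: permutation p-values always use the add-one
estimator and a required seed; the exact HWE test compares probability
masses with a 1e-12 relative tolerance for ties; PCA drops monomorphic
SNPs under binomial scaling (an all-heterozygote SNP is polymorphic and is
kept, with a zero-variance standardized column); LFMM p-values are floored
at 1e-300 to keep q-value machinery defined; genotype frequencies in the
simulator are clamped to (1e-6, 1 - 1e-6) before binomial draws; the
smoothing grid treats windows as closed on both edges at integer bp.

## Limitations

Ridge LFMM estimates factors from the environment-residualized genotype
matrix, so environment-correlated structure is attributed to the
environment — the conservative direction for discovery but one that can
inflate effect estimates when structure and environment are truly
confounded. The Gibbs solver does not attempt the label-switching or
rotation fixes a production sampler would need for interpreting `U` and
`V` themselves (only `b` summaries are used). The q-value smoother is
Storey's standard construction, not an empirical-null fit of the z-score
distribution; with strongly miscalibrated inputs the two can differ. The
greedy pruning rule is deterministic but not guaranteed minimal in
pathological relatedness graphs. Pairwise FST p-values at 1,000
permutations resolve no finer than ~0.001.
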