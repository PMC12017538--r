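---
title: "Predicting family breeding values from seedling transcriptomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting family breeding values from seedling transcriptomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Conifer breeding programs estimate parental breeding values (BVs) from
progeny field trials measured after four to six years. If patterns of gene
expression and sequence variation in pooled seedlings carry a reproducible
signature of parental genetic merit, RNA-seq of those seedlings can predict
BVs years earlier. `omicbv` implements that pipeline: replicate-level
transcript counts and family-level SNP dosages go through feature-selection
cascades into two predictors — similarity-matrix kriging and the elastic
net — evaluated on cross-batch train/test splits, with a synthetic-data
generator that carries hidden ground truth for validation.

# Data model and preprocessing

A *family* is the experimental unit: pooled seedlings sharing a seed
parent. Counts are observed per *biological replicate* (a pool of 15-30
seedlings) grown in one of three *batches* (years/sequencing platforms).
Family-level expression is `log2(mean(counts) + 1)`: the mean over
replicates is taken on the raw count scale first, then one is added (so a
zero count maps to zero), then log2. Transcripts with mean log2 family
expression below 3 are removed before any modeling.

Genotypes come from a VCF with one diploid sample per family (variants
called on merged replicate alignments). Sites are restricted to biallelic
SNVs with QUAL > 30, minor allele frequency > 0.05 across families, and no
missing genotypes, recoded to alternate-allele dosage 0/1/2.

Reproducibility of expression is summarized by pairwise Spearman
correlations (Pearson on average ranks) of log2 counts: within-family,
among-family, cross-batch, and between family means.

# Feature-selection cascades

Stages chain ALL -> setA -> setB -> setC; every phenotype-aware screen sees
*training families only*, which the API enforces by accepting only the
training phenotype table.

**Transcripts.** setA removes transcripts whose family-mean expression
shows a batch effect: a per-transcript one-way ANOVA by batch (families
grown in more than one batch are excluded from the test — their family
effect is confounded with batch — but stay in the matrix), adjusted by a
two-groups local FDR and removed at adjusted value < 0.05. setB greedily
prunes collinear transcripts at |r| > 0.5, i.e. one transcript explaining
more than 25% of another's variance: the pair with the largest |r| loses
the member with the larger mean absolute correlation to all remaining
features (ties drop the later column, making the filter deterministic).
setC keeps transcripts with |Spearman r| > 0.05 against training BVs.

**SNPs.** The ALL set removes SNPs with a batch ANOVA p < 0.05,
deliberately unadjusted; we apply the same multi-batch-family exclusion as
for transcripts, since the confounding argument is identical. setA keeps
SNPs whose dosage variance divided by mean dosage exceeds 1 (the n-1
variance; the ratio is the dispersion screen that distinguishes loci with
real among-family variation). setB prunes as above. setC keeps SNPs whose
dosage classes separate training BVs in a one-way ANOVA at unadjusted
p < 0.05; empty classes are dropped and SNPs with fewer than two classes
are untestable and removed.

**Local FDR.** The two-groups estimator: pi0 is estimated on the grid
lambda = 0.05..0.95 via `mean(p > lambda)/(1 - lambda)` and extrapolated to
lambda -> 1 with a cubic smoothing spline; the marginal density of
probit-transformed p-values is a Gaussian kernel estimate; lfdr =
min(1, pi0 * f0/f), regularized to be monotone non-increasing toward small
p. Benjamini-Hochberg is available through `run_config(adjust_method =
"BH")` when a simpler, rank-based adjustment is preferred. With fewer than
about 100 p-values the density estimate is unreliable and the function
warns.

# Prediction

**Kriging.** Sigma = theta S + (1 - theta) I on the training block;
prediction for a test family with similarity vector rho is
`mu + (theta rho)' Sigma^- (Y - mu)`. Design choices worth stating:

- *Centering.* The raw weighted average `rho' Sigma^-1 Y` is not
  location-invariant; centering on the training mean is the standard BLUP
  form and reduces to the raw form when the weights sum to one. The raw
  behavior is available with `center = FALSE`.
- *Inversion.* Sigma is inverted through its eigendecomposition with
  eigenvalues below 1e-8 of the largest truncated (a pseudo-inverse).
  When fewer features than training families survive a filter stage, a
  correlation-based Sigma is exactly rank-deficient; a small diagonal
  jitter there produces exploding weights, whereas truncation solves on
  the supported subspace.
- *Similarity.* `pearson_similarity()` standardizes features by default
  (each feature centered/scaled across families). The experiment runner
  instead defaults to the *profile correlation* (`standardize_features =
  FALSE` in `run_config()`): the plain Pearson correlation of two
  families' feature profiles. The profile correlation is what produces the
  high (0.85-0.98) family-by-family correlations characteristic of bulk
  seedling transcriptomes, and it is the construction under which batch
  artifacts show up as batch-block structure that the setA filter can then
  remove. Both are exposed; the flag exists because the choice genuinely
  changes what the similarity measures.
- *theta.* Default 1 (all weight on the omic similarity). For theta < 1
  the identity is added to the training block only and rho is scaled by
  theta, since the environmental component has no train-test covariance.

**VanRaden GRM.** G = MM' / (2 sum p(1-p)) with M centered by 2p and p the
alternate-allele frequency estimated from all input families (centering by
minor vs alternate allele flips column signs of M and leaves G unchanged).
Monomorphic SNPs carry no relationship information and are excluded. Row
sums of G vanish by construction with in-sample frequencies — a property
the tests assert to 1e-9 — and the mean diagonal is ~1 under
Hardy-Weinberg genotypes.

**Elastic net.** The objective is the 1/(2n) convention,
`(1/2n)||y - b0 - Xb||^2 + lambda(0.5(1-alpha)||b||^2 + alpha||b||_1)`,
with an unpenalized intercept; features are standardized internally (1/n
variance) and coefficients returned on the original scale, so the lambda
grid {1, 0.1, 0.01, 0.001} is interpreted on the standardized scale the
grid was designed for. The solver is cyclic coordinate descent in compiled
code with active-set cycling and, for a cold start at small lambda, a
pathwise warm start from the smallest fully-shrinking lambda — cold
coordinate descent at lambda = 0.001 with p >> n converges extremely
slowly, and the warm-started path reaches the same minimizer (the tests
verify the KKT-implied closed forms). Convergence is a maximum coefficient
change below 1e-7; the per-sweep objective is recorded and is
non-increasing by construction. Tuning bootstraps the training families 25
times (the family is the experimental unit), scores each (alpha, lambda)
by out-of-bag RMSE with the same resamples reused across the grid, and
breaks ties toward the smaller lambda, then the smaller alpha.

**Combining data types.** The combined prediction is the per-family
arithmetic mean of the transcript-based and SNP-based predictions from the
same model. No variance rescaling is applied; when one channel is much
noisier than the other (typically the SNP channel after aggressive
filtering), the combined accuracy sits between the two single-channel
accuracies rather than above both. This is a real limitation of unweighted
averaging, visible in the setC column of cross-batch experiments.

# Evaluation

Splits are by batch; families grown in more than one batch are always
assigned to training, never to the prediction set. Accuracy is the Pearson
correlation of predicted and observed BVs with the two-sided p of the
simple-regression t-test (n - 2 df). Model comparison between combined and
single-datatype predictions is a nested-model F-test (reduced:
`obs ~ single`; full: `obs ~ single + combined`; F(1, n-3)); since
"compare by ANOVA" admits more than one reading, a Hotelling-Williams test
of the dependent correlations is provided as an alternative. Degenerate
cells (constant predictions, collinear predictors, empty feature sets) are
flagged and reported as such rather than aborting the grid.

# The synthetic-data generator

`synthetic_config()` encodes the study conditions the pipeline is meant to
survive; its defaults were chosen once, from the qualitative features of
multi-batch seedling RNA-seq studies of this design, and define the test
conditions everywhere.

- **Design:** 78 families — 45 in batch one (5 of them also grown in batch
  two), 11 only in batch two, 22 in batch three — with 1-3 biological
  replicates per family and batch (probabilities 0.1/0.3/0.6).
- **Ancestry:** each family has a continuous ancestry coordinate
  q ~ N(0, 1) (a provenance gradient); SNP allele frequencies shift along
  it with differentiation fst = 0.1 at neutral loci and 0.3 at causal loci
  (directional selection shifts trait loci more than drift shifts neutral
  ones). Discrete-group structure was tried and rejected: with K groups a
  SNP's group profile and the BV's group profile are nearly orthogonal
  random vectors, so no individual marker associates with the phenotype
  and association screens retain pure noise, which contradicts how marker
  screens behave on real breeding populations. `fst = 0` recovers fully
  exchangeable families.
- **Dosage calls:** Binomial(2, p) with a heterozygote-deficit component
  (probability `hwe_f = 0.5` of a homozygous-like call), reflecting
  genotypes called from pooled-seedling alignments; this is also what
  makes the variance/mean relative-variance screen meaningful (pure
  binomial dosages have variance/mean = 1 - p < 1 always, and the screen
  would remove everything). SNPs come in LD blocks of 4 (several SNPs
  called within one expressed transcript are in near-complete LD), with
  15% per-member discordance.
- **Breeding values:** BV = sum of causal additive effects on centered
  dosages + 0.6 q (ancestry-aligned polygenic background: the assayed
  transcriptome SNPs capture only part of the genetic variance) + N(0,
  0.3) noise. 100 of 10,000 SNPs are causal; effects are N(0, 0.1) with
  10% of causal loci boosted 5-fold (a few detectable QTLs among many
  minor loci).
- **Expression:** log2 expected expression = baseline (N(5, 2), floored at
  0) + b_t z(BV) for the 5% signal transcripts (slopes N(0, 0.2) — larger
  slopes produce family-mean divergence far beyond what bulk seedling
  transcriptomes show) + batch shifts (N(0, 1) per batch) for 90% of
  transcripts + family noise (sd 0.4) + co-expression modules (half the
  transcriptome in modules of 10 sharing a family-level factor, sd 0.5,
  random-sign loadings). Replicate counts are negative binomial
  (dispersion 5) around library-size-scaled means.
- **Batch-affected transcripts are drawn from the non-signal pool:** the
  premise of the filtering cascade is that a batch-stable, heritably
  informative fraction of the transcriptome exists and can be enriched;
  with batch sensitivity assigned independently of signal, the batch
  filter would discard signal in proportion and filtering could only
  hurt. The 90% batch fraction mirrors how much of a transcriptome is
  flagged as batch-associated when batches differ in year and sequencing
  platform.
- **Batch-biased SNP calls:** 5% of SNPs are re-called with an
  allele-frequency shift of 0.3 for families genotyped in one batch.

What the generator does **not** emulate: read-level artifacts (GC/length
bias, mapping ambiguity), genuine pedigree structure (parent-offspring,
full sibs), dominance or epistasis, transcript-level LD with causal SNPs
(expression and genotype channels are linked only through the BV and
ancestry), and family-specific batch interactions. Passing tests therefore
show the machinery is correct and the cascades behave as designed under
these conditions — not that any particular accuracy will be attained on
real data.

# Validation strategy and known limitations

The test suite checks every solver against an independent oracle: kriging
against dense linear solves, the elastic net against OLS (lambda = 0) and
the orthonormal-design soft-threshold/ridge closed form, the GRM against a
hand-worked example and Hardy-Weinberg expectations, Spearman against the
rank-difference formula, every filter against an independently coded
brute-force reimplementation, and the lfdr and batch filters against null
simulations (uniform p-values; no-batch-effect genotypes; permuted
phenotypes), where nominal 5% behavior is required. Stage-trend recovery
runs the kriging arm of the pipeline over 20 simulated datasets at 2,000
transcripts and 6,000 SNPs (fractions at the defaults above; these sizes
keep the Monte-Carlo runs to minutes while leaving every stage with enough
features to be meaningful) and asserts that accuracy trends upward along
the transcript cascade and that combining data types beats the weaker
single datatype in at least 90% of runs. The elastic net is exercised on
the full 36-point, 25-bootstrap tuning grid in the single-split experiment
rather than in the 20-seed trend runs, where that grid would dominate
runtime without changing what the trend measures.

Known limitations: unweighted combining can sit below the better single
channel (above); the setC SNP screen at these problem sizes retains few
features, and kriging similarity estimated from ~100 screened markers is
noisy, so the SNP channel's accuracy can decline from setB to setC; and
the local FDR estimator, like any two-groups density method, is unstable
below ~100 p-values and warns accordingly.
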