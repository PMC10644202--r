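---
title: "Benchmarking genomic prediction in a half-sib progeny trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic prediction in a half-sib progeny trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tropical timber species are bred from progeny trials of open-pollinated
families: seeds collected from known mother trees, fathers unknown, planted
in randomized complete blocks. Genomic selection promises to shorten such
breeding cycles by predicting a seedling's genetic merit from genome-wide
SNP markers instead of waiting years for phenotypes. Before committing to a
prediction model, a breeder wants to know *which* model family works for
*which* trait, and whether a small GWAS-selected marker panel can replace
the full (expensive) genotyping assay.

`progenyGS` implements that comparison as a reusable, fully testable
pipeline: a synthetic-data generator standing in for field data, genotype
quality control, spatial adjustment of field phenotypes, genomic
heritability, a mixed-model association scan for marker ranking, twelve
predictor families, and a cross-validated benchmark of their predictive
ability (the Pearson correlation between observed and predicted values in a
held-out validation set).

## The simulated world

`sim_config()` defaults encode the trial design the package emulates: 94
open-pollinated mother trees, 5 progeny per family per block in 8 RCBD
blocks (3760 trees), 6 x 3 m spacing, ~18,000 biallelic SNPs on many short
scaffolds, pairwise linkage disequilibrium decaying to r² = 0.1 near 2.3 kb,
narrow-sense heritabilities around 0.27-0.41, a smooth spatial
micro-environment surface carrying ~10% of phenotypic variance, and ~23%
missing phenotypes from thinning and mortality. Only a few hundred survivors
are genotyped (`simulate_trial(n_genotyped = ...)`).

Design choices where no external constraint existed:

* **Founder LD.** Haplotypes follow a per-scaffold Markov copying chain:
  the allele at a locus is copied from the previous locus with probability
  `exp(-d log(10) / (2 * ld_decay_bp))`. Pairwise haplotype correlation then
  decays as `exp(-d/s)` and r² crosses 0.1 at `ld_decay_bp` by
  construction, giving the generator a directly interpretable decay knob.
  Allele frequencies are constant within a scaffold so the chain's
  correlation is exact; a repair step flips alleles until every locus meets
  the `maf_min` floor.
* **Open pollination.** Each offspring receives one recombinant gamete from
  its mother (a recorded founder-haplotype pair) and one from a random,
  unrecorded founder pair. Recombination follows a Poisson crossover
  process with expectation one crossover per scaffold, realized through the
  Haldane map between adjacent loci.
* **Trait architectures.** Genetic values are sums of additive effects on
  the -1/0/1 coding plus pairwise genotype products for epistatic pairs;
  each component is rescaled so its realized population variance equals the
  configured fraction of a unit phenotypic variance. Note that raw genotype
  products carry a substantial additive (marginal) projection — this is
  deliberate: it mirrors how biological epistasis still transmits largely
  additively between relatives, and it is why method contrasts between
  kernel and sparse-linear models are small (see below).
* **Bimodality.** One dominant-acting major QTL (carrier vs non-carrier,
  effect 1.2 phenotypic SD, MAF near 0.35) generates the bimodal phenotype
  shape of the diameter-like trait; a purely additive biallelic QTL would
  give three modes rather than two.
* **Spatial surface.** A sum of six random low-frequency 2-D cosine
  components, rescaled to `spatial_variance_fraction`. Cheap, smooth, and
  exactly what a tensor-product spline should be able to recover — a green
  surface-recovery test therefore validates the adjustment machinery, not
  the realism of real field heterogeneity (which also has row/column
  artefacts and abrupt terrain steps this generator does not emulate).
* **Missingness** is uniform random; real thinning removes trees
  deliberately (three per family), so family sizes after thinning are less
  variable in reality than under this model.

All randomness flows from one master seed through named sub-streams, so
every artifact is bit-reproducible; fixtures round-trip through VCF without
loss, including phase bars.

## Genotype QC

`read_vcf()` codes homozygous reference / heterozygous / homozygous
alternative as -1/0/1 and keeps only biallelic SNPs. `filter_sites()` uses
VCFtools `--max-missing` semantics (the argument is the *required
non-missing* proportion), a minor-allele-frequency floor, and an exact
Hardy-Weinberg test computed by full enumeration of heterozygote
configurations (no mid-p correction). Depth-based filters require read
data and are out of scope. Missing genotypes are imputed by the per-locus
mean or mode — an explicit stand-in for haplotype-based imputation, which
needs reference panels this package does not model.

Linkage disequilibrium uses composite (genotype-correlation) r² on the
coded matrix rather than EM haplotype r²: it is oracle-checkable against a
plain correlation and adequate for decay-scale estimation. The decay trend
is a local quadratic loess of r² on distance with the span chosen from
{0.1, ..., 1.0} by 4-fold cross-validation minimizing RMSE; folds are
interleaved along the distance ordering so the choice is deterministic. The
decay distance is the first downward crossing of r² = 0.1, linearly
interpolated on a 2000-point grid; a curve that never crosses returns NA.

`estimate_genome_coverage()` keeps the two worked-example inputs separate:
genome size is C-value x 0.978e9 bp, and coverage takes the decay distance
as an explicit argument rather than recomputing it, because printed
summaries of the same analysis have been known to mix nearby values.

## Spatial adjustment

The field surface is a penalized tensor-product B-spline over row/column
coordinates with basis dimensions (12, 13) by default, fitted with
`mgcv::gam(..., bs = "ps", method = "REML")`. REML optimizes the smoothing
parameter continuously; a log-spaced grid search would approximate the same
criterion with strictly less precision, so the continuous optimizer is used.
The spatial effect is the centered smooth term: subtracting it preserves the
phenotype mean, the fit is invariant to translating the grid, and the
surface is evaluated at missing trees' positions as well.

Outliers among adjusted values are removed by an iterative two-tailed
Grubbs test: the most extreme standardized deviate is compared with
`((n-1)/sqrt(n)) * sqrt(t^2/(n-2+t^2))`, `t` the `1 - alpha/(2n)` quantile
on `n-2` df, removing and repeating until no rejection. The level is not
readjusted across iterations, ties break toward the lower index, and
adjustment plus outlier removal is done per trait independently.

## Bayesian alphabet, GBLUP, RKHS

`fit_bayes()` is a Gibbs sampler over the model `y = 1 mu + X beta + e`
with family-specific marker priors: one common normal variance (BRR),
per-marker scaled-inverse-chi-square variances (BayesA), per-marker
variances with an exclusion indicator of prior probability `pi` (BayesB), a
common variance with an indicator (BayesC), and Park-Casella
double-exponential shrinkage (BL). Hyperpriors follow the customary
convention: df = 5 for both variance components and prior scales solved
from an R² = 0.5 variance partition of `var(y)`; chain defaults are 20,000
iterations, 5,000 burn-in, thinning 5, all configurable. Variances can be
held fixed, which turns the sampler into a conjugate Gaussian Gibbs sampler
whose posterior mean is the closed-form ridge solution — the test suite
exploits exactly this identity.

`genomic_heritability()` uses BRR variance components:
`sigma2_a = sigma2_beta * sum_j var(x_j)` and
`h2 = sigma2_a / (sigma2_a + sigma2_e)`, averaged over ten independent
chains with distinct seeds ("ten iterations" is read as ten chains). Two
alternatives are exposed because the convention is genuinely ambiguous:
`sigma2_a = var(X beta_hat)` and `sigma2_y = var(y)`. The two definitions
trade bias in opposite directions: with the customary df = 5 / R² = 0.5
hyperpriors, the marker-sum estimate has a prior-dominated floor on pure
noise (h² ≈ 0.15-0.25 at desk-scale n/m, never near zero) but recovers a
planted h² = 0.35 within [0.25, 0.45] at n = 280, whereas the
realized-variance definition `var(X beta_hat)` is null-calibrated
(h² < 0.1 on noise) but shrinks planted signal toward ~0.2. The marker-sum
default follows the field convention; use `sigma2_a = "var_xbeta"` when a
null-calibrated estimate matters more than unbiased recovery.

GBLUP builds the VanRaden relationship matrix
`A = W W' / (2 sum p_j (1-p_j))` and estimates variance components by REML
through the spectral decomposition of the training submatrix (a 1-D profile
over the variance ratio, grid-bracketed then refined by `optimize`).
Validation predictions are the conditional mean
`mu + K_vt (K_tt + delta I)^-1 (y_t - mu)` — equivalent to refitting with
missing responses, but deterministic and exactly equal to marker ridge
regression with the matched penalty, which is the package's strongest
internal cross-check. GBLUP therefore needs no model-construction
replicates. Validation predictions with zero variance are flagged
degenerate rather than given a correlation.

RKHS uses a Gaussian kernel `exp(-h d² / mean(d²))` on Euclidean genotype
distances with bandwidth h = 1. The mean-squared-distance normalization is
a package choice: unnormalized `exp(-d²)` underflows for thousands of
markers; the raw form remains available (`scale = "raw"`). The sampler
works in the kernel eigenbasis, where the random-effect coordinates are
conditionally independent, making the Gibbs update a single vectorized
draw; predictions again use kernel conditioning under posterior-mean
variance components. A single kernel is used (the model permits several).

## Association scan and marker selection

`mixed_scan()` is an EMMAX-style single-rotation approximation: the null
model `y = covariates + u + e` (u with covariance proportional to the
VanRaden kinship; covariates an intercept plus the leading 4 genotype PCs)
is fitted once by REML, the data are whitened with the resulting
covariance, and every SNP is tested by generalized least squares. This is a
deliberate substitution for a multi-locus empirical-Bayes scan: subset
selection only consumes a p-value ranking, and the single-locus scan is
exactly checkable against ordinary regression when the kinship is the
identity. LOD = likelihood ratio / (2 ln 10) is reported with a threshold-3
flag for plotting, but selection uses p-values only: `select_top_k()` takes
the k smallest, breaking ties deterministically by genome order.
Benjamini-Hochberg is used for "FDR correction" (the procedure is otherwise
unnamed). Within the benchmark the scan runs on the training fold only.

## Machine-learning wrappers

No random-forest, gradient-boosting or deep-learning package exists in this
environment, so `ml_models` carries minimal engines authored here: a CART
regression tree with an L2 leaf penalty; bagged trees with per-node feature
subsampling (rf); depth-wise boosting with a split-gain floor (`gbdt_a`,
xgboost-like, 8 tunable parameters including `max_depth`); best-first
leaf-wise boosting (`gbdt_b`, lightgbm-like, 8 parameters including
`num_leaves`); and a one-block convolutional network trained by Adam with
manual backpropagation (7 tuned parameters; epochs fixed at 30 with
patience 8 on the training loss). The 2-D variant consumes the two binary
phase layers as channels sharing convolution weights, and the phase axis is
summarized (averaged) at the final pooling stage — consequently a 2-channel
input with identical layers is *exactly* equivalent to the 1-channel
network, which the tests assert to 1e-10. Hyperparameters are chosen by
seeded random search over declared spaces with 3-fold inner cross-validation
maximizing Pearson r (a Parzen-style sampler is not available here; the
random-search fallback keeps the same interface). Search spaces are a
documented reconstruction, not a reproduction of any published space.

Scaling follows the training-only convention: response and genotypes
standardized with training-fold parameters for the Bayesian families, RKHS
and `cnn1d`; response only for `cnn2d` (phase input stays binary); no
scaling for the tree methods and for GBLUP genotypes. The convolutional
methods refuse the full SNP panel.

## The benchmark

`cv_plan()` fixes the comparison design: independent random 3:1 splits with
validation size `ceiling(n/4)` (forced by the worked example n = 281 -> 71),
10 splits x 10 model replicates, subset sizes 48/96/192/all from the
within-fold scan, twelve methods, GBLUP at one replicate, CNNs excluded at
"all". `count_models()` gives the closed-form fit count (8480 under the
headline design) and equals the number of rows `run_benchmark()` produces.
Cells failing at any stage record the error and the run continues;
degenerate cells contribute no value to the median. Per-cell deviation from
zero uses a two-sided Wilcoxon signed-rank test (the test is otherwise
unnamed; signed-rank is robust to the skewed, bounded correlation scale).
Splits are not family-stratified — mirroring the analyzed design, whose
validation sets share mother trees with training sets; `stratified` is
reserved as an extension flag.

On the architecture-contrast property: with epistasis simulated as rescaled
genotype products, much of the "epistatic" variance is linearly capturable,
so kernel-vs-sparse-linear differences are small — just as the real-data
gaps between method families are a few hundredths of a correlation unit.
The acceptance test therefore evaluates the *paired* difference (RKHS minus
BayesB on the same seed) and requires its median over ten seeds to be
positive, and requires GBLUP to sit within 0.05 of the best linear Bayesian
on additive traits. A green result establishes the direction of the
contrast under this generator, not its magnitude on real data.

## Numerical choices and degenerate inputs

* Variance-component profiles are maximized on a log grid (40 points,
  1e-5 to 1e6) then refined by golden-section `optimize`; eigenvalues are
  floored at zero and kernel eigenvectors below 1e-10 of the maximum are
  dropped.
* Monomorphic markers: kept with zero effect (warning) in the samplers,
  dropped from the VanRaden denominator (warning), skipped with NA in the
  scan, reported by `check_polymorphism()`.
* Zero-variance predictions are flagged, never silently correlated.
* The exact HWE test compares enumeration probabilities with a 1e-12 slack
  to keep ties stable in floating point.
* Loess fits that fail at small spans score infinite CV error instead of
  aborting span selection.

## Limitations

The generator does not simulate reads, calling error, dominance, selection,
or multi-generation breeding; imputation is marginal rather than
haplotype-based; the association scan is single-locus; CNN architectures
are a minimal reconstruction. Real-data headline numbers (heritability
tables, predictive-ability tables, the 2.3 kb decay estimate) are design
targets for the simulator, not quantities this package claims to reproduce.
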