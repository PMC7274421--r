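---
title: "Genomic and metabolic prediction in NAM populations: models and design"
author: "metaGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and metabolic prediction in NAM populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `metaGP`,
the assumptions behind the synthetic-data generator, and the numerical and
design choices a maintainer should know about.

## The scientific setting

Nested association mapping (NAM) populations cross a panel of diverse
donors — here, wild accessions — to a single recurrent elite parent, then
advance each family by one backcross and several selfing generations
(BC1S3). Genotypes are coded as dosages of the donor allele relative to
the recurrent parent (0/1/2). Because the donor allele is defined per
family, a marker that does not segregate within a family is
indistinguishable from the recurrent parent there and is coded 0
(`monomorphicFamilyRecode`). The package studies how well multi-year
agronomic traits can be predicted from (i) genome-wide SNP dosages,
(ii) leaf metabolite profiles, and (iii) both together.

## Phenotype models

**Variance components.** Plot values follow
`value = mean + genotype + year + genotype:year + error` with all effects
random. For balanced complete designs (every line in every year at a
constant replicate count) the REML solution has a closed form — the ANOVA
expected-mean-square estimators — and the package uses it exactly; this
matters because iterative optimisers plateau around 1e-5 in the component
scale, while the closed form is machine-precision and provably identical
to REML whenever the estimates are interior (all non-negative). Any
unbalanced design, or a boundary case, falls back to `lme4::lmer` with
tightened convergence tolerances (`xtol_abs = ftol_abs = 1e-12`).
Negative estimates are truncated at zero before any heritability ratio.

**Heritability and repeatability.** The entry-mean broad-sense
heritability is `h² = V_G/(V_G + V_GY/y + V_R/(y·r))`; repeatability is
`V_G/(V_G + V_R/r)`. Both are scale-invariant ratios in [0, 1]; both stop
with an explicit error when all components are zero.

**BLUEs.** One estimate per line from the fixed-effects model
`value = genotype + year + error`, solved by sparse least squares
(`Matrix`), since a dense design matrix with ~1,300 genotype levels is
wasteful. The reported BLUE is the genotype effect plus the mean year
effect, i.e. the line's estimated mean over the trial years. The model
choice (fixed year alongside fixed genotype) is a design decision: year
effects must be absorbed somewhere for multi-year means to be comparable,
and fixed year keeps the estimator a pure least-squares problem. With a
single year and balanced data the BLUEs reduce to line means; additive
year shifts leave BLUE differences untouched (both tested).

**Genomic heritability.** A three-kernel random-effect model with
additive (`X_c X_c'`), dominance (centred heterozygosity indicators) and
additive×additive epistasis (element-wise square of the additive kernel)
components, each scaled to mean diagonal 1. The REML engine profiles out
the total variance and maximises the restricted likelihood over
log-variance-ratios by Nelder–Mead (objective tolerance 1e-8, up to 500
iterations) from three starting values (ratios 0.5, 0.05, 2) to guard
against local optima; batch scoring of many metabolites can pass a single
start for speed. `h²_SNP` is a ratio of non-negative components, hence in
[0, 1] by construction. The dominance kernel is dropped automatically
when a population carries no heterozygosity.

## Whole-genome regression

**RR-BLUP.** `y = 1μ + Xg + e` with a common effect variance. The
intercept is absorbed analytically, leaving
`(X_c'X_c + λI) g = X_c'y_c`; when predictors outnumber lines the
algebraically identical kernel form
`g = X_c'(X_c X_c' + λI)^{-1} y_c` is used instead (the cheaper route is
picked automatically; both are exposed and tested for equality to 1e-8).
The default penalty is the plug-in
`λ = (σ²_R/l)/(σ²_G/m)` from the phenotypic variance components, `m` the
number of predictors and `l` the number of trial years; alternatively the
cross-validation harness can re-estimate the ridge parameter by REML
inside every training fold (`lambda = NULL`). Predictions are invariant
to constant shifts of the dosage coding because the intercept absorbs
them — recoding 0/1/2 to −1/0/1 is cosmetic.

**BayesB.** Spike-and-slab regression sampled by Gibbs, in C++ for speed,
using R's RNG so chains are bit-reproducible under a seed. Per sweep:
intercept (flat prior, normal conditional); for each predictor in fixed
index order, its slab variance (scaled inverse chi-squared conditional for
included effects, prior draw for excluded ones), its inclusion indicator
(posterior odds from the marginal likelihood with the effect integrated
out) and, if included, its effect (normal conditional), with the residual
vector updated in place for O(n) per-predictor cost; then π from its beta
conditional and the residual variance from its scaled inverse chi-squared
conditional. Divergence of the residual variance raises an error advising
predictor standardisation.

Hyperparameter defaults are package choices (the analysis this mirrors
did not publish chain settings): slab degrees of freedom `df0 = 5`; slab
scale derived so the prior slab explains half the phenotypic variance
given the mean predictor variance; `Beta(1, 9)` prior on the exclusion
probability π; residual prior df 5 with a scale matched to half the
phenotypic variance; 12,000 sweeps, 2,000 burn-in, thinning 5. All are
configurable through `bayesbPriors()` and echoed into run manifests.
Fixing π at 1 collapses the model to the intercept; fixing π at 0 with a
rigid slab (`df0` large) reproduces ridge regression — both limits are
tested.

**Predictor sets.** Metabolite intensities are column-standardised before
entering a model or the combined block; intensity scales vary over orders
of magnitude and would otherwise dominate a common-variance prior. SNP
dosages are left on their natural scale. Whether raw or Box–Cox
transformed metabolites enter the models is a config switch
(`qc$boxcox_metabolites`); the transformation chooses λ on the grid −3 to
3 by 0.25 by profile likelihood, shifting by `1 − min(x)` first when
values are not strictly positive.

## Cross-validation and experiments

"100 cross-validation runs" is realised as 20 independent stratified
5-fold partitions (20 × 5 = 100 evaluations): this guarantees every line
is tested exactly once per replicate, which a scheme of 100 independent
80/20 splits does not. Within each family, lines are allocated to folds
by shuffled cyclic labels, i.e. largest-remainder allocation when family
size is not a multiple of the fold count; families smaller than the fold
count are spread over distinct folds with a warning. An evaluation with
constant predictions records ability 0 (with a warning) rather than being
dropped, keeping the run count fixed. Model comparisons default to
Welch's two-sample t-test on the per-run accuracies at α = 0.01; a paired
test is available and preferred when two results share partitions (equal
seed, folds and runs). Since accuracy is a constant multiple of ability
within a trait, within-trait comparisons are identical on either scale.

Subset selection keeps `round(fraction · m)` predictors — top absolute
effects in "best" mode, a seeded uniform draw in "random" mode. Rounding
(rather than ceiling) matches the convention of the analysis this package
mirrors (25% of 33,005 markers is 8,251). Best-mode selection uses
effects fitted once on the full data set, exactly as in the published
procedure; this leaks information from the eventual test folds into the
selection, so a leakage-free within-fold selection mode is provided
behind `selectionWithinFold = TRUE` with a logged note.

## The synthetic-data generator

The generator's role is to provide data with *known truth* so every
estimator in the package can be tested by parameter recovery.

* **Meiosis**: crossovers are a Poisson process at 1 event per 100 cM
  without interference — the simplest map-consistent model, adequate for
  producing realistic linkage disequilibrium along chromosomes.
* **Population**: fully inbred donors, each polymorphic at a
  family-specific random subset of markers (default fraction 0.5, mimicking
  family-specific segregation), one backcross to the recurrent parent and
  s selfing generations by single-seed descent. Under this scheme the
  donor allele frequency at segregating loci is 0.25 after the backcross
  and the expected residual heterozygosity is `0.5 · (1/2)^s` (0.0625 at
  s = 3); both are verified against the simulation within three standard
  errors over families.
* **Phenotypes**: additive multi-QTL genotypic values; year main effects
  from a wide normal (they cancel in BLUEs and do not enter h²);
  genotype-by-year deviates with variance `gxyRatio · V_G`; the residual
  variance is solved so the entry-mean h² equals its target at the
  simulated design — so the generator is calibrated, not tuned.
* **Metabolites**: a small additive signal (5 QTL each, half shared with
  the trait QTL by default) plus dominant noise; per-metabolite genomic
  heritabilities follow a scaled Beta(1, (1−μ/max)/(μ/max)) distribution,
  giving mean 0.10 and a right tail toward 0.50 at the defaults —
  matching the observation that leaf metabolites are weakly heritable.
  Missingness is completely at random per metabolite. Intensities are
  shifted to be non-negative, which leaves all variance components
  untouched.

One user seed fans out into named sub-streams per operation, so each
stage can be rerun independently yet reproducibly.

What the generator does **not** emulate: selection during population
development, shared ancestry among donors, linkage between a trait QTL
and marker ascertainment, genotype-by-environment structure beyond a
single genotype-by-year variance, metabolite-metabolite correlation
networks, and non-random missingness (real metabolite gaps are often
intensity-dependent). Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not performance claims
for any real population.

## Problem sizes used in the test suite

The suite exercises the full workflow at sizes chosen to keep parameter
recovery well-identified while remaining comfortable to run routinely:
a 25-family × 52-line BC1S3 population on a 7-chromosome, 2,100-marker
map with 8 years × 2 replicates for variance-component and heritability
recovery (±15% and ±0.05 respectively), 60 metabolites for the
predictor-set orderings, 10 cross-validation evaluations per cell for the
ordering checks, and 400 × 500 instances for BayesB signal recovery.
Module tests use a 6-family × 30-line population on 240 markers.

## Known limitations

* The BayesB sampler treats the slab scale as fixed (derived or supplied),
  not sampled; posterior inference on hyperparameters beyond π is out of
  scope.
* The kernel REML engine is dense O(n³) per likelihood evaluation; for
  populations beyond a few thousand lines an eigendecomposition-based or
  average-information implementation would be needed.
* BLUEs assume a connected line-by-year design; fully disconnected
  designs raise an error rather than returning estimates on arbitrary
  contrasts.
* Repeatability is exercised on simulated data only; the package does not
  model the repeated-check-genotype layout of real trials.
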