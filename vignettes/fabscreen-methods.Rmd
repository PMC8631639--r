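---
title: "Detecting fabricated samples with digit-frequency features: models and design"
author: "fabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fabricated samples with digit-frequency features: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabscreen)
```

## The problem

Large quantitative omics tables — here, gene-level copy-number alteration
(CNA) matrices with one row per tumor sample and one column per gene — are
an attractive target for data fabrication: a forged sample is a needle in a
table of millions of floats. `fabscreen` studies this forensically from both
sides. It manufactures fake samples by three mechanisms an unscrupulous
analyst might plausibly use, and it trains classifiers to tell real samples
from fakes, using either the raw quantitative values or a compact
*digit-frequency* representation inspired by Benford's law.

Benford's first-digit law, $P(d) = \log_{10}(1 + 1/d)$, predicts that
leading digits of naturally arising numbers decay from about 30% for digit 1
to under 5% for digit 9 (`benfordExpected()`); the asymmetry follows from
relative growth — moving 1,000 to 2,000 is a 100% increase but 8,000 to
9,000 only 12.5% (`percentIncrease()`). Normalized CNA values are bounded,
so their true leading digits carry no such signal; the first *unbounded*
digits are the first and second positions after the decimal point. The
transform (`digitFrequencies()`) summarizes every sample, whatever its gene
count, by 20 features: the frequencies of digits 0–9 at decimal positions 1
and 2.

## The synthetic cohort generator

Real CNA cohorts cannot be shipped inside a package, so `generateCohort()`
simulates tables that reproduce the structural properties the detection
method actually exploits. The model, per sample and chromosome:

1. genes are laid out contiguously; a Poisson(`segmentRate`) number of
   breakpoints cuts the chromosome into segments;
2. each segment carries a shift: zero with probability `1 - eventProb`,
   otherwise Normal(0, `shiftScale`), plus a Normal(0, `segmentNoiseSd`)
   baseline wobble;
3. the whole segmental signal of a sample is multiplied by a lognormal
   factor (log-sd `sampleScaleSd`);
4. each gene adds Normal(0, $sd_g$) noise, with $sd_g$ drawn once per gene
   log-uniformly from `noiseScaleRange`, and values are clipped to
   ±`valueClip`.

Three of these choices deserve justification, because they are what make
the simulated tables behave like gene-level output of a segmentation
pipeline rather than like generic Gaussian matrices:

* **Within-segment value identity.** Segmentation assigns one mean to every
  gene of a segment, so adjacent genes in real tables are near-duplicates
  (correlation 1.0 for neighbouring gene pairs) and a single sample carries
  only dozens of *distinct* values repeated across thousands of genes. The
  default `noiseScaleRange = c(0.001, 0.01)` keeps per-gene noise below the
  two digit positions being read: same-segment genes agree in their first
  decimals, giving each real sample the spiky, sample-specific digit
  signature on which detection rests. Raising the noise floor above ~0.05
  erases that signature and makes all per-sample digit vectors collapse to
  the cohort mean.
* **Segment baseline wobble** (`segmentNoiseSd = 0.03`). Without it,
  segments with a zero event shift would leave the rank order of two
  adjacent genes to their independent per-gene noise, capping adjacent-pair
  Spearman correlation near 0.97; with a shared continuously varying
  baseline, low-noise adjacent pairs reach Spearman ≈ 1 as observed in real
  tables.
* **Per-sample scale** (`sampleScaleSd = 0.4`). Tumor purity and overall
  alteration burden vary strongly between samples; the lognormal factor
  spreads per-sample digit signatures instead of letting 2,000 i.i.d. genes
  average every sample onto the same frequency vector.

Defaults are 100 samples × 2,000 genes on 22 chromosomes,
`segmentRate = 1.5`, `eventProb = 0.7`, `shiftScale = 0.6` (copy-number
log-ratio units), `valueClip = 2.5` as a surrogate for the bounded range
normalization imposes (the true range and normalization of real cohorts is
not published with them; the clip is a documented stand-in).
`validateRealism()` checks the two properties downstream stages rely on: a
long-right-tailed first-decimal digit distribution
(freq(0) + freq(1) > 2·freq(9)) and adjacent-pair correlation exceeding
cross-chromosome correlation by more than 0.1.

What the generator does **not** emulate: allele-specific copy number, GC or
mappability bias, real breakpoint length distributions, recurrent
cancer-specific alterations, or rounding conventions of any particular
pipeline. Passing tests on synthetic cohorts therefore demonstrates the
machinery end to end under controlled conditions; they do not certify
performance on any particular real dataset.

## Fabrication mechanisms

All three methods operate gene by gene on a real cohort
(`fabricate()`):

* **random** — uniform draw within the gene's observed [min, max];
  respects marginal ranges, destroys everything else.
* **resample** — draw with replacement from the gene's observed values;
  perfect marginals, no joint structure.
* **impute** — copy a real sample, partition its genes into
  `ceiling(1/imputeBlockFraction)` disjoint random blocks (default 10),
  then round by round nullify one block and re-predict it with iterative
  random-forest imputation against the real cohort. After all rounds every
  entry has been imputed; entries that came back exactly equal to the
  source are re-perturbed by additional nullify–impute passes, so a fake
  provably shares no entry with its source sample.

The imputer (`iterativeRFImpute()`) follows the missForest algorithm:
mean-initialize, visit genes by increasing missingness, fit a
random-forest regressor per gene on the currently complete predictors,
repeat sweeps until the normalized squared change of the imputed values
rises (the previous sweep is then kept) or `imputeMaxIter` is reached.
Desk-scale controls: `imputeNTrees = 20` trees per forest,
`imputePredictorLimit = 30` predictors chosen by absolute Pearson
correlation, `imputeMaxIter = 2` — in the fabrication regime the per-gene
training rows (the real samples) never change between sweeps, so later
sweeps only re-sample bootstrap noise. All fakes of one call share the
block partition and are imputed jointly per round; since every fake is
missing the same block, each per-gene forest trains on exactly the real
rows, and predictions coincide with the one-fake-at-a-time scheme while
the cost stays nearly independent of the number of fakes.

A consequence worth stating plainly: correlation-ranked predictor capping
makes this imputer a *stronger* forger than stock missForest at 17,000
genes (which picks √p random candidate predictors per split, most of them
unrelated to the target gene). Its fakes reproduce the source sample's
segment structure so faithfully that on synthetic cohorts their
digit-frequency vectors sit inside the real population's spread, and
classifiers detect them only marginally above the majority-class baseline
— unlike random and resample fakes, which are caught essentially
perfectly. The package reports this honestly rather than weakening the
imputer to make its own detector look good.

## Benchmark protocol

`runTrials()` repeats, per trial *t* (fabrication seed `baseSeed + t`):
fabricate fakes (default 50 against 100 real), mix (`mixAndLabel()`; fake
is the positive class), optionally featurize to digit frequencies, split
each class randomly in half (`splitTrainTest()`; odd counts send the extra
sample to training), and for each classifier family run an exhaustive grid
search scored by stratified 10-fold cross-validated accuracy *on the
training half only*, ties broken toward the first-listed combination,
refit on the full training half, and score accuracy and `f1Score()` (0/0
defined as 0) on the held-out half. Aggregates are mean, sd and standard
error (sd/√trials) per family.

Families and default grids (`defaultModelGrids()`): random forest
(`ntree` ∈ {100, 300}), gradient boosting (xgboost, exact greedy splits,
`nrounds` ∈ {50, 150} × `max_depth` ∈ {2, 3}), Gaussian naive Bayes
(variance floor `var_smoothing` ∈ {1e-9, 1e-8} of the largest feature
variance), k-nearest neighbours (k ∈ {3, 5, 7}) and SVM (linear and RBF
kernels × cost ∈ {0.1, 1, 10}). Quantitative features are standardized
with training-fold statistics for the distance- and kernel-based families
(KNN, SVM) only; digit features already live in [0, 1]. Exact greedy
splits for the boosted trees matter on separable data: histogram binning
places pure-split thresholds adjacent to the training hull, which
misclassifies held-out points just outside it, whereas midpoint splits
keep the margin.

Seeds: the trial's fabrication seed is `baseSeed + t` by construction; the
split and cross-validation fold seeds derive from it by fixed offsets
(1000003 and 2000003) so the three consumers do not share an RNG stream
start. Identical base seeds reproduce an entire benchmark bit for bit.

## Downsampling study

`downsampleExperiment()` probes how few gene measurements still support
detection: per replicate, one fabrication and one stratified split; per
ladder value *k*, a fresh uniform gene subset (without replacement) is
taken from the mixed dataset *before* featurization, so training and test
see the same genes and digit frequencies are recomputed from exactly the
surviving measurements. Reported per (k, family): mean accuracy, sd and
standard error over replicates. The package's experiments use a ladder of
{2000, 1000, 500, 100, 30, 10} with 10 replicates — chosen, together with
the 100 × 2,000 cohort, 10-trial benchmarks and 20-tree imputation
forests, as the desk scale at which the full suite runs on a single CPU in
minutes while every qualitative effect is already visible.

## Numerical conventions and degenerate inputs

* Digits are read from a fixed-precision (10 decimal places,
  round-half-even) decimal rendering of |value|, so 0.1 contributes digit
  1, not its binary neighbour 0.0999…; exact zeros and integer values
  contribute digit 0 at every position; signs are ignored.
* Missing values leave both numerator and denominator of a digit
  frequency; a sample with no usable values is an error naming the sample.
* PCA (`pcaProjection()`) centers features, projects via SVD, and fixes
  each axis's sign so its largest-magnitude loading is positive, making
  coordinates reproducible; constant matrices are rejected.
* Spearman correlations use average ranks for ties throughout.
* TSV output renders doubles with `%.17g` so write–read round trips are
  bit-identical; the decimal separator is always "." and newlines are LF.
* The multiset membership guarantee of resampled fakes and the
  no-shared-entry guarantee of imputed fakes are exact float comparisons,
  not tolerances.

## Known limitations

* Imputation-based fakes are near-undetectable on digit features under the
  synthetic study conditions (see above); conclusions about imputation
  forgeries on real cohorts require real data through the TSV adapter.
* The digit transform is scale-sensitive by design: multiplying a table by
  10 shifts position-2 digits into position 1. Tables concentrated below
  0.01 need a spec with deeper positions (`digitSpec(3:4)`).
* Gaussian naive Bayes receives a variance floor because digit features
  can be constant within a class; this mirrors common implementations but
  is still a modelling choice.
* With 50 fakes per cohort, per-gene-pair Spearman estimates have a null
  sd of ~0.14; single-pair statements about "destroyed" correlation are
  therefore made on averages over pairs, not on individual pairs.
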