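# fabscreen

Forensic screening of quantitative omics tables for fabricated samples.

Large sample-by-gene tables — the package's model case is gene-level
copy-number alteration (CNA) matrices from tumor cohorts — are easy places
to hide made-up data. `fabscreen` is for researchers and data stewards who
want to study that threat quantitatively. It provides, in one package:

* a **synthetic cohort generator** that reproduces the structural
  properties of segmented CNA tables (within-segment value identity,
  near-perfect adjacent-gene correlation, long-right-tailed decimal digit
  distributions, per-sample purity/burden heterogeneity), so everything is
  testable without downloading patient data;
* three **fabrication mechanisms** of increasing sophistication: per-gene
  uniform draws within observed ranges, resampling observed values with
  replacement, and iterative random-forest (missForest-style) imputation
  that rebuilds a copied sample block by block until it shares no entry
  with its source;
* the **Benford-like digit transform**: each sample, whatever its gene
  count, becomes 20 features — the frequencies of digits 0–9 at the first
  and second positions after the decimal point. Benford's law
  P(d) = log10(1 + 1/d) motivates the representation; bounded, normalized
  values make the *post*-decimal digits the first informative ones;
* a **benchmark protocol**: stratified half split, exhaustive grid search
  with stratified 10-fold cross-validation on the training half only, five
  classifier families (random forest, gradient boosting, Gaussian naive
  Bayes, k-nearest neighbours, SVM), repeated trials with fresh fakes, and
  accuracy/F1 (fake = positive class) on the held-out half;
* **experiments and diagnostics**: feature-downsampling robustness curves
  with standard errors, PCA projections, per-digit distribution summaries,
  and gene-pair Spearman preservation checks.

## Worked example

```r
library(fabscreen)

cohort <- generateCohort(cohortConfig(seed = 1))
cohort
#> CNACohort: 2000 genes x 100 samples (100 real, 0 fake), 22 chromosomes
#>   values: [-2.500, 2.500], 0 missing

validateRealism(cohort)
#> RealismReport
#>   digit long tail : ok (freqs 0.412 0.124 0.103 0.080 0.069 0.060 0.047 0.045 0.034 0.027)
#>   adjacency       : ok (adjacent rho 0.980 vs distant -0.003)

bench <- runTrials(cohort, fabricationConfig("resample", nFake = 50),
                   featurization = "digit_frequency",
                   grids = defaultModelGrids()[c("random_forest", "knn")],
                   nTrials = 5, baseSeed = 1)
bench
#> BenchmarkResult: 5 trials x 2 families
#>         family n_trials mean_accuracy sd_accuracy se_accuracy   mean_f1
#>            knn        5     0.5066667  0.04714045  0.02108185 0.5755063
#>  random_forest        5     1.0000000  0.00000000  0.00000000 1.0000000
```

Reading the output: the realism report confirms the cohort shows the two
structures detection relies on — first-decimal digit frequencies decaying
from 0.41 (digit 0) to 0.03 (digit 9), and adjacent genes correlating at
0.98 versus ~0 for cross-chromosome pairs. The benchmark then says that a
random forest on 20 digit-frequency features separates resampled fakes
from real samples perfectly in every trial (mean held-out accuracy 1.0,
se 0), while k-nearest neighbours hovers near chance on this cohort —
family choice matters.

Fabrication quality differs sharply by mechanism: random and resampled
fakes destroy between-gene correlation and are caught essentially
perfectly, while imputation fakes preserve the source sample's segment
structure (adjacent-pair Spearman stays above 0.99) and, on synthetic
cohorts, evade digit-frequency detection almost entirely. See the methods
vignette (`vignettes/fabscreen-methods.Rmd`) for the models, parameter
meanings and design rationale.

## Command line

A thin CLI wraps the same functions:

```sh
fabscreen=$(Rscript -e 'cat(system.file("exec", "fabscreen", package = "fabscreen"))')
Rscript $fabscreen generate --samples 100 --genes 2000 --seed 1 --out real
Rscript $fabscreen fabricate --in real.tsv --method resample --n-fake 50 --seed 2 --out fake
Rscript $fabscreen featurize --in real.tsv --out digits.tsv
Rscript $fabscreen benchmark --real real.tsv --method random --features digits --trials 50 --seed 3 --out results.tsv
```

Tables travel as TSV (samples as rows, `sample_id` first column, full
round-trip float precision) with a `*.genes.tsv` metadata sidecar. An
existing real cohort in that format — for example a published CNA table
you have fetched yourself — can be supplied to any command via `--in` /
`--real`; nothing is ever downloaded.

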