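#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData colData colData<-
#' @importFrom stats predict
NULL

#' Configuration of a synthetic copy-number cohort
#'
#' Parameters of the segmental copy-number simulator. Genes are laid out
#' contiguously along chromosomes; per sample and chromosome, a Poisson number
#' of breakpoints cuts the chromosome into segments, each segment carries a
#' copy-number shift (zero with probability `1 - eventProb`, otherwise a
#' normal draw with sd `shiftScale`), and per-gene noise is added on top.
#'
#' @slot nSamples number of samples (rows of the sample-by-gene table).
#' @slot nGenes total number of genes.
#' @slot nChromosomes number of chromosomes genes are assigned to.
#' @slot segmentRate expected breakpoints per chromosome per sample.
#' @slot eventProb probability a segment carries a nonzero shift.
#' @slot shiftScale sd of segment shifts, in copy-number log-ratio units.
#' @slot segmentNoiseSd sd of a per-sample, per-segment baseline wobble
#'   shared by all genes of a segment, emulating the continuously varying
#'   segment means that segmentation pipelines assign to whole segments
#'   (this is what drives adjacent gene pairs toward Spearman 1 in real
#'   tables).
#' @slot sampleScaleSd sd (log scale) of a per-sample lognormal factor
#'   multiplying the segmental signal, emulating tumor purity and overall
#'   alteration-burden differences between samples; this is what gives each
#'   sample an individual digit-frequency signature.
#' @slot noiseScaleRange length-2 numeric, (low, high) bounds of per-gene
#'   noise sds; sds are drawn log-uniformly so digit magnitudes vary by gene.
#' @slot valueClip symmetric bound on absolute values, emulating the bounded
#'   range that normalization imposes on real copy-number tables.
#' @slot seed integer seed; the same config reproduces the cohort exactly.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nSamples = "integer", nGenes = "integer", nChromosomes = "integer",
    segmentRate = "numeric", eventProb = "numeric", shiftScale = "numeric",
    segmentNoiseSd = "numeric", sampleScaleSd = "numeric",
    noiseScaleRange = "numeric", valueClip = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 2L) msgs <- c(msgs, "nSamples: must be >= 2")
  if (object@nChromosomes < 1L) msgs <- c(msgs, "nChromosomes: must be >= 1")
  if (object@nGenes < object@nChromosomes)
    msgs <- c(msgs, "nGenes: must be >= nChromosomes")
  if (object@segmentRate < 0) msgs <- c(msgs, "segmentRate: must be >= 0")
  if (object@eventProb < 0 || object@eventProb > 1)
    msgs <- c(msgs, "eventProb: must lie in [0, 1]")
  if (object@shiftScale < 0) msgs <- c(msgs, "shiftScale: must be >= 0")
  if (object@segmentNoiseSd < 0) msgs <- c(msgs, "segmentNoiseSd: must be >= 0")
  if (object@sampleScaleSd < 0) msgs <- c(msgs, "sampleScaleSd: must be >= 0")
  if (length(object@noiseScaleRange) != 2L ||
      object@noiseScaleRange[1] <= 0 ||
      object@noiseScaleRange[1] > object@noiseScaleRange[2])
    msgs <- c(msgs, "noiseScaleRange: need 0 < low <= high")
  if (object@valueClip <= 0) msgs <- c(msgs, "valueClip: must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Configuration of sample fabrication
#'
#' Parameters for manufacturing fake samples from a real cohort. Three
#' mechanisms are supported: `"random"` (per-gene uniform draws within the
#' observed range), `"resample"` (per-gene sampling with replacement from
#' observed values) and `"impute"` (copy a real sample, then iteratively
#' nullify and re-impute blocks of genes with random-forest imputation until
#' no entry of the original copy survives).
#'
#' @slot method one of `"random"`, `"resample"`, `"impute"`.
#' @slot nFake number of fake samples to fabricate.
#' @slot seed integer seed.
#' @slot imputeBlockFraction fraction of genes nullified per imputation round
#'   (default 0.10, i.e. ten disjoint rounds cover every gene once).
#' @slot imputeMaxIter cap on imputer sweeps within one round.
#' @slot imputeNTrees trees per random-forest regressor.
#' @slot imputePredictorLimit cap on predictor genes per imputed gene,
#'   selected by absolute Pearson correlation.
#'
#' @seealso [fabricationConfig()], [fabricate()]
#' @exportClass FabricationConfig
setClass("FabricationConfig",
  representation(
    method = "character", nFake = "integer", seed = "integer",
    imputeBlockFraction = "numeric", imputeMaxIter = "integer",
    imputeNTrees = "integer", imputePredictorLimit = "integer"
  )
)

setValidity("FabricationConfig", function(object) {
  msgs <- character()
  if (!object@method %in% c("random", "resample", "impute"))
    msgs <- c(msgs, "method: must be one of 'random', 'resample', 'impute'")
  if (object@nFake < 1L) msgs <- c(msgs, "nFake: must be >= 1")
  if (object@imputeBlockFraction <= 0 || object@imputeBlockFraction > 1)
    msgs <- c(msgs, "imputeBlockFraction: must lie in (0, 1]")
  if (object@imputeMaxIter < 1L) msgs <- c(msgs, "imputeMaxIter: must be >= 1")
  if (object@imputeNTrees < 1L) msgs <- c(msgs, "imputeNTrees: must be >= 1")
  if (object@imputePredictorLimit < 1L)
    msgs <- c(msgs, "imputePredictorLimit: must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Sample-by-gene copy-number container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one assay `"cna"` with genes as rows and samples as columns.
#' `rowData` carries the gene metadata (`chromosome`, `index` = ordinal
#' position within the chromosome); `colData` carries the per-sample `label`
#' (`"real"` or `"fake"`; fake is the positive class throughout).
#' Use [cnaMatrix()] for the conventional samples-by-genes orientation.
#'
#' @seealso [cnaCohort()], [generateCohort()], [mixAndLabel()]
#' @exportClass CNACohort
setClass("CNACohort", contains = "SummarizedExperiment")

setValidity("CNACohort", function(object) {
  msgs <- character()
  if (!"cna" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'cna' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene IDs (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample IDs (colnames) must be present and unique")
  rd <- rowData(object)
  if (!all(c("chromosome", "index") %in% colnames(rd)))
    msgs <- c(msgs, "rowData must contain 'chromosome' and 'index'")
  if (!"label" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain 'label'")
  v <- assay(object, "cna")
  if (any(is.infinite(v)))
    msgs <- c(msgs, "values must be finite (NA marks missing)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Digit-extraction specification
#'
#' Which decimal positions after the decimal point are read off, and at what
#' fixed rendering precision. Digits are taken from the absolute value
#' rendered as a fixed-point decimal string (round-half-even), so binary
#' float artifacts (0.1 stored as 0.0999...) never leak into digit counts.
#'
#' @slot positions integer positions after the decimal point, each >= 1.
#' @slot precision decimal places used when rendering values.
#'
#' @seealso [digitSpec()], [digitFrequencies()]
#' @exportClass DigitSpec
setClass("DigitSpec",
  representation(positions = "integer", precision = "integer"))

setValidity("DigitSpec", function(object) {
  msgs <- character()
  if (length(object@positions) == 0L) msgs <- c(msgs, "positions: nonempty")
  if (any(object@positions < 1L)) msgs <- c(msgs, "positions: each >= 1")
  if (object@precision < 1L) msgs <- c(msgs, "precision: must be >= 1")
  if (any(object@positions > object@precision))
    msgs <- c(msgs, "positions: each <= precision")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-sample digit-frequency features
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose assay `"freq"` holds, per sample (column), the frequency of digits
#' 0-9 at each requested decimal position (rows, named `pos{p}_digit{d}`,
#' position-major). Under the default [digitSpec()] there are exactly 20
#' features, and frequencies within a position sum to one for every sample.
#' Sample labels are carried over from the source table in `colData`.
#'
#' @seealso [digitFrequencies()]
#' @exportClass DigitFrequencySet
setClass("DigitFrequencySet", contains = "SummarizedExperiment")

setValidity("DigitFrequencySet", function(object) {
  msgs <- character()
  spec <- metadata(object)$digitSpec
  if (is.null(spec)) return("metadata 'digitSpec' is required")
  want <- digitFeatureNames(spec)
  if (!identical(rownames(object), want))
    msgs <- c(msgs, "feature names must be pos{p}_digit{0-9}, position-major")
  f <- assay(object, "freq")
  if (ncol(f) > 0) {
    for (p in spec@positions) {
      s <- colSums(f[paste0("pos", p, "_digit", 0:9), , drop = FALSE])
      if (any(abs(s - 1) > 1e-9))
        msgs <- c(msgs, sprintf("position %d frequencies must sum to 1", p))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Realism diagnostics of a cohort
#'
#' Result of [validateRealism()]: does the first-decimal digit distribution
#' decay like the long right tail seen in real copy-number tables, and are
#' chromosomally adjacent genes more correlated than distant ones?
#'
#' @slot digitLongtailOk `TRUE` iff freq(0) + freq(1) > 2 * freq(9) at the
#'   first decimal position, pooled over the table.
#' @slot adjacencyOk `TRUE` iff `adjacentRho > distantRho + 0.1`.
#' @slot firstDigitFreqs named 10-vector of pooled first-position digit
#'   frequencies (sums to one).
#' @slot adjacentRho mean Spearman correlation over sampled adjacent pairs.
#' @slot distantRho mean Spearman correlation over sampled distant pairs.
#'
#' @exportClass RealismReport
setClass("RealismReport",
  representation(
    digitLongtailOk = "logical", adjacencyOk = "logical",
    firstDigitFreqs = "numeric", adjacentRho = "numeric",
    distantRho = "numeric"
  )
)

setValidity("RealismReport", function(object) {
  if (length(object@firstDigitFreqs) != 10L)
    return("firstDigitFreqs must have length 10")
  if (abs(sum(object@firstDigitFreqs) - 1) > 1e-9)
    return("firstDigitFreqs must sum to 1")
  TRUE
})

#' Hyperparameter search space for one classifier family
#'
#' @slot family one of `"gradient_boosting"`, `"naive_bayes"`,
#'   `"random_forest"`, `"knn"`, `"svm"`.
#' @slot grid named list of candidate values, expanded exhaustively by
#'   [fitWithGridSearch()].
#'
#' @seealso [modelGrid()], [defaultModelGrids()]
#' @exportClass ModelGrid
setClass("ModelGrid", representation(family = "character", grid = "list"))

setValidity("ModelGrid", function(object) {
  fams <- c("gradient_boosting", "naive_bayes", "random_forest", "knn", "svm")
  msgs <- character()
  if (!object@family %in% fams)
    msgs <- c(msgs, paste("family: must be one of", paste(fams, collapse = ", ")))
  if (length(object@grid) == 0L || any(lengths(object@grid) == 0L) ||
      is.null(names(object@grid)) || any(!nzchar(names(object@grid))))
    msgs <- c(msgs, "grid: must be a named list with nonempty candidate sets")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Repeated-trial benchmark result
#'
#' Per-(trial, family) held-out accuracy and F1 together with per-family
#' aggregates (mean, sd, standard error over trials). Access with
#' [trialResults()] and [aggregateResults()].
#'
#' @slot trials data.frame with columns `trial`, `family`, `featurization`,
#'   `fabrication`, `accuracy`, `f1`, `params` (JSON), `seed`.
#' @slot aggregates data.frame with per-family `mean_accuracy`, `sd_accuracy`,
#'   `se_accuracy`, `mean_f1`, `sd_f1`, `se_f1`, `n_trials`.
#'
#' @seealso [runTrials()]
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  representation(trials = "data.frame", aggregates = "data.frame"))

setValidity("BenchmarkResult", function(object) {
  tr <- object@trials
  need <- c("trial", "family", "accuracy", "f1")
  if (!all(need %in% colnames(tr)))
    return("trials must contain trial, family, accuracy, f1")
  if (nrow(tr) && (any(tr$accuracy < 0 | tr$accuracy > 1) ||
                   any(tr$f1 < 0 | tr$f1 > 1)))
    return("accuracy and f1 must lie in [0, 1]")
  TRUE
})

#' Feature-downsampling study result
#'
#' Mean held-out accuracy with standard error per (feature count, classifier
#' family), over replicate random feature subsets. Access the curve with
#' [downsampleCurve()].
#'
#' @slot curve data.frame with `k`, `family`, `mean_accuracy`, `sd_accuracy`,
#'   `se_accuracy`, `n_replicates`.
#' @slot ladder the strictly decreasing feature counts used.
#'
#' @seealso [downsampleExperiment()]
#' @exportClass DownsampleResult
setClass("DownsampleResult",
  representation(curve = "data.frame", ladder = "integer"))

setValidity("DownsampleResult", function(object) {
  if (length(object@ladder) > 1L && any(diff(object@ladder) >= 0))
    return("ladder must be strictly decreasing")
  TRUE
})
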