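#' @rdname cnaMatrix
#' @export
setGeneric("cnaMatrix", function(x) standardGeneric("cnaMatrix"))

#' @rdname sampleLabels
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname geneMeta
#' @export
setGeneric("geneMeta", function(x) standardGeneric("geneMeta"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname trialResults
#' @export
setGeneric("trialResults", function(x) standardGeneric("trialResults"))

#' @rdname trialResults
#' @export
setGeneric("aggregateResults", function(x) standardGeneric("aggregateResults"))

#' @rdname downsampleCurve
#' @export
setGeneric("downsampleCurve", function(x) standardGeneric("downsampleCurve"))

#' Samples-by-genes value matrix of a cohort
#'
#' Returns the copy-number values in the conventional orientation of the
#' screening pipeline: samples as rows, genes as columns.
#'
#' @param x a [CNACohort-class].
#' @return numeric matrix, `nSamples x nGenes`, dimnames sample/gene IDs.
#' @rdname cnaMatrix
#' @export
setMethod("cnaMatrix", "CNACohort", function(x) t(assay(x, "cna")))

#' Per-sample real/fake labels
#'
#' @param x a [CNACohort-class] or [DigitFrequencySet-class].
#' @return factor with levels `c("real", "fake")`; fake is the positive class.
#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "SummarizedExperiment", function(x) {
  factor(as.character(colData(x)$label), levels = c("real", "fake"))
})

#' Gene metadata of a cohort
#'
#' @param x a [CNACohort-class].
#' @return data.frame with `gene_id`, `chromosome`, `index`.
#' @rdname geneMeta
#' @export
setMethod("geneMeta", "CNACohort", function(x) {
  rd <- rowData(x)
  data.frame(gene_id = rownames(x),
             chromosome = as.character(rd$chromosome),
             index = as.integer(rd$index),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Samples-by-features matrix for classification
#'
#' The classifier-facing view of an object: one row per sample. For a
#' [CNACohort-class] these are the quantitative copy-number values; for a
#' [DigitFrequencySet-class] the digit frequencies.
#'
#' @param x a [CNACohort-class] or [DigitFrequencySet-class].
#' @return numeric matrix, samples as rows.
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "CNACohort", function(x) t(assay(x, "cna")))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "DigitFrequencySet", function(x) t(assay(x, "freq")))

#' Per-trial and aggregate benchmark tables
#'
#' @param x a [BenchmarkResult-class].
#' @return data.frame; see [BenchmarkResult-class] for the columns.
#' @rdname trialResults
#' @export
setMethod("trialResults", "BenchmarkResult", function(x) x@trials)

#' @rdname trialResults
#' @export
setMethod("aggregateResults", "BenchmarkResult", function(x) x@aggregates)

#' Accuracy-versus-feature-count curve
#'
#' @param x a [DownsampleResult-class].
#' @return data.frame with one row per (k, family).
#' @rdname downsampleCurve
#' @export
setMethod("downsampleCurve", "DownsampleResult", function(x) x@curve)

setMethod("show", "CNACohort", function(object) {
  lab <- table(sampleLabels(object))
  cat(sprintf(
    "CNACohort: %d genes x %d samples (%d real, %d fake), %d chromosomes\n",
    nrow(object), ncol(object), lab[["real"]], lab[["fake"]],
    length(unique(rowData(object)$chromosome))))
  v <- assay(object, "cna")
  cat(sprintf("  values: [%.3f, %.3f], %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "DigitFrequencySet", function(object) {
  spec <- metadata(object)$digitSpec
  cat(sprintf(
    "DigitFrequencySet: %d features (positions %s) x %d samples\n",
    nrow(object), paste(spec@positions, collapse = ","), ncol(object)))
})

setMethod("show", "RealismReport", function(object) {
  cat("RealismReport\n")
  cat(sprintf("  digit long tail : %s (freqs %s)\n",
              if (object@digitLongtailOk) "ok" else "NOT ok",
              paste(sprintf("%.3f", object@firstDigitFreqs), collapse = " ")))
  cat(sprintf("  adjacency       : %s (adjacent rho %.3f vs distant %.3f)\n",
              if (object@adjacencyOk) "ok" else "NOT ok",
              object@adjacentRho, object@distantRho))
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: %d trials x %d families\n",
              length(unique(object@trials$trial)),
              length(unique(object@trials$family))))
  print(object@aggregates, row.names = FALSE)
})

setMethod("show", "DownsampleResult", function(object) {
  cat(sprintf("DownsampleResult: ladder %s\n",
              paste(object@ladder, collapse = " > ")))
  print(object@curve, row.names = FALSE)
})
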