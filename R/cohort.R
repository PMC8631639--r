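#' Create a cohort simulation configuration
#'
#' Defaults describe a desk-scale stand-in for a tumor copy-number cohort:
#' 100 samples by 2,000 genes on 22 chromosomes, sparse segmental events and
#' small per-gene noise, values clipped at +/- 2.5 to emulate the bounded
#' range that normalization imposes. See [CohortConfig-class] for the meaning
#' of each parameter.
#'
#' @param nSamples,nGenes,nChromosomes cohort dimensions.
#' @param segmentRate expected breakpoints per chromosome per sample.
#' @param eventProb probability a segment carries a nonzero shift.
#' @param shiftScale sd of segment shifts.
#' @param segmentNoiseSd sd of the per-sample, per-segment baseline wobble
#'   shared by all genes of a segment.
#' @param sampleScaleSd sd (log scale) of the per-sample lognormal factor on
#'   the segmental signal (tumor purity / alteration burden surrogate).
#' @param noiseScaleRange `(low, high)` per-gene noise sds, drawn
#'   log-uniformly.
#' @param valueClip symmetric bound on absolute values.
#' @param seed integer seed.
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSamples = 20, nGenes = 200, seed = 7)
#' @export
cohortConfig <- function(nSamples = 100L, nGenes = 2000L, nChromosomes = 22L,
                         segmentRate = 1.5, eventProb = 0.7, shiftScale = 0.6,
                         segmentNoiseSd = 0.03, sampleScaleSd = 0.4,
                         noiseScaleRange = c(0.001, 0.01), valueClip = 2.5,
                         seed = 1L) {
  cfg <- new("CohortConfig",
    nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
    nChromosomes = as.integer(nChromosomes),
    segmentRate = as.numeric(segmentRate), eventProb = as.numeric(eventProb),
    shiftScale = as.numeric(shiftScale),
    segmentNoiseSd = as.numeric(segmentNoiseSd),
    sampleScaleSd = as.numeric(sampleScaleSd),
    noiseScaleRange = as.numeric(noiseScaleRange),
    valueClip = as.numeric(valueClip), seed = as.integer(seed))
  msg <- validObject(cfg, test = TRUE)
  if (!isTRUE(msg)) stop("invalid CohortConfig -- ", msg, call. = FALSE)
  cfg
}

#' Construct a cohort from a samples-by-genes matrix
#'
#' @param values numeric matrix, samples as rows, genes as columns.
#' @param sampleIds,geneIds unique ID vectors; defaults are generated.
#' @param chromosome,index per-gene metadata; defaults place all genes on one
#'   chromosome in column order (sufficient for digit work, not for
#'   adjacency diagnostics).
#' @param label per-sample label, `"real"` or `"fake"`, recycled.
#' @return a [CNACohort-class].
#' @examples
#' co <- cnaCohort(matrix(rnorm(40), 4, 10))
#' @export
cnaCohort <- function(values,
                      sampleIds = rownames(values),
                      geneIds = colnames(values),
                      chromosome = NULL, index = NULL,
                      label = "real") {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample_%d", seq_len(nrow(values)))
  if (is.null(geneIds)) geneIds <- sprintf("gene_%d", seq_len(ncol(values)))
  if (length(sampleIds) != nrow(values) || length(geneIds) != ncol(values))
    stop("ID lengths must match matrix dimensions", call. = FALSE)
  if (anyDuplicated(sampleIds)) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(geneIds)) stop("duplicate gene IDs", call. = FALSE)
  if (is.null(chromosome)) chromosome <- rep("chr1", length(geneIds))
  if (is.null(index)) {
    index <- integer(length(geneIds))
    for (ch in unique(chromosome)) {
      w <- if (is.na(ch)) is.na(chromosome)
           else !is.na(chromosome) & chromosome == ch
      index[w] <- seq_len(sum(w))
    }
  }
  m <- t(values)
  dimnames(m) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment(
    assays = list(cna = m),
    rowData = DataFrame(chromosome = as.character(chromosome),
                        index = as.integer(index), row.names = geneIds),
    colData = DataFrame(label = rep_len(as.character(label), length(sampleIds)),
                        row.names = sampleIds))
  new("CNACohort", se)
}

#' Simulate a copy-number cohort with segmental structure
#'
#' Genes are assigned to chromosomes contiguously. For every sample and
#' chromosome a Poisson(`segmentRate`) number of breakpoints cuts the gene
#' sequence into segments; each segment carries a shift that is zero with
#' probability `1 - eventProb` and otherwise drawn from
#' `Normal(0, shiftScale)`, plus a small `Normal(0, segmentNoiseSd)` baseline
#' wobble shared by the whole segment (segmentation pipelines assign one
#' continuously varying mean to every gene of a segment, which is what makes
#' adjacent gene pairs in real tables correlate near-perfectly). A gene's
#' value is its segment shift, multiplied by a per-sample lognormal factor
#' (`sampleScaleSd`; tumor purity and alteration burden vary from sample to
#' sample, which gives every sample its own digit-frequency signature), plus
#' `Normal(0, sd_g)` noise, with `sd_g` drawn once per gene log-uniformly
#' from `noiseScaleRange`; values are clipped to `+/- valueClip`. The default
#' noise range sits below the first two decimal positions because gene-level
#' tables from segmentation pipelines assign near-identical values to all
#' genes of a segment -- a real sample carries only dozens of distinct
#' values, which is precisely the spiky per-sample digit signature that
#' separates real samples from fabricated ones. The
#' construction makes chromosomally adjacent genes share segments (hence
#' correlate) while concentrating values near zero, which yields the decaying
#' "long right tail" of first-decimal digits seen in real copy-number tables.
#'
#' @param config a [CohortConfig-class]; the same config (including seed)
#'   reproduces the cohort bit for bit.
#' @return a [CNACohort-class] with all labels `"real"`.
#' @examples
#' co <- generateCohort(cohortConfig(nSamples = 10, nGenes = 100, seed = 1))
#' @seealso [validateRealism()]
#' @export
generateCohort <- function(config) {
  if (!is(config, "CohortConfig"))
    stop("'config' must be a CohortConfig", call. = FALSE)
  msg <- validObject(config, test = TRUE)
  if (!isTRUE(msg)) stop("invalid CohortConfig -- ", msg, call. = FALSE)
  n <- config@nSamples
  g <- config@nGenes
  # contiguous, near-equal chromosome blocks
  bounds <- round(seq(0L, g, length.out = config@nChromosomes + 1L))
  sizes <- diff(bounds)
  chrom <- rep(sprintf("chr%d", seq_len(config@nChromosomes)), times = sizes)
  index <- unlist(lapply(sizes, seq_len), use.names = FALSE)

  values <- withSeed(config@seed, {
    lo <- log(config@noiseScaleRange[1])
    hi <- log(config@noiseScaleRange[2])
    noiseSd <- exp(stats::runif(g, lo, hi))
    sampleScale <- exp(stats::rnorm(n, 0, config@sampleScaleSd))
    shifts <- matrix(0, n, g)
    offsets <- c(0L, cumsum(sizes))
    for (s in seq_len(n)) {
      for (ch in seq_len(config@nChromosomes)) {
        len <- sizes[ch]
        if (len == 0L) next
        nb <- stats::rpois(1L, config@segmentRate)
        nb <- min(nb, len - 1L)
        cuts <- if (nb > 0L) sort(sample.int(len - 1L, nb)) else integer()
        segLen <- diff(c(0L, cuts, len))
        segShift <- ifelse(stats::runif(length(segLen)) < config@eventProb,
                           stats::rnorm(length(segLen), 0, config@shiftScale),
                           0) +
          stats::rnorm(length(segLen), 0, config@segmentNoiseSd)
        shifts[s, offsets[ch] + seq_len(len)] <- rep(segShift, times = segLen)
      }
    }
    noise <- matrix(stats::rnorm(n * g), n, g) *
      matrix(noiseSd, n, g, byrow = TRUE)
    pmin(pmax(shifts * sampleScale + noise, -config@valueClip),
         config@valueClip)
  })
  cnaCohort(values,
            sampleIds = sprintf("sample_%03d", seq_len(n)),
            geneIds = sprintf("gene_%05d", seq_len(g)),
            chromosome = chrom, index = index, label = "real")
}

#' Check that a cohort shows the digit and adjacency structure of real data
#'
#' Computes (i) first-decimal digit frequencies pooled over the whole table
#' and (ii) mean Spearman correlation over sampled chromosomally adjacent
#' gene pairs versus sampled distant pairs. The long-tail flag requires
#' `freq(0) + freq(1) > 2 * freq(9)`; the adjacency flag requires the
#' adjacent mean to exceed the distant mean by more than 0.1.
#'
#' @param table a [CNACohort-class] with at least 2 samples and 50 genes.
#' @param nPairs pairs sampled per group (default 200).
#' @param seed seed for pair sampling.
#' @return a [RealismReport-class].
#' @export
validateRealism <- function(table, nPairs = 200L, seed = 1L) {
  stopIfNotCohort(table)
  if (ncol(table) < 2L || nrow(table) < 50L)
    stop("need >= 2 samples and >= 50 genes", call. = FALSE)
  meta <- geneMeta(table)
  if (anyNA(meta$chromosome) || anyNA(meta$index))
    stop("gene metadata (chromosome, index) is missing", call. = FALSE)
  X <- cnaMatrix(table)

  d1 <- digitsAtPosition(as.vector(X), 1L, 10L)
  d1 <- d1[!is.na(d1)]
  freqs <- tabulate(d1 + 1L, 10L) / length(d1)
  names(freqs) <- as.character(0:9)

  ord <- order(meta$chromosome, meta$index)
  adjacentIdx <- ord[-length(ord)]
  adjacentNext <- ord[-1]
  sameChrom <- meta$chromosome[adjacentIdx] == meta$chromosome[adjacentNext]
  adjPairs <- cbind(adjacentIdx[sameChrom], adjacentNext[sameChrom])

  rho <- withSeed(seed, {
    take <- sample.int(nrow(adjPairs), min(nPairs, nrow(adjPairs)))
    adjRho <- vapply(take, function(i)
      stats::cor(X[, adjPairs[i, 1]], X[, adjPairs[i, 2]],
                 method = "spearman"), numeric(1))
    # distant: cross-chromosome where possible, else maximally separated
    nDist <- as.integer(nPairs)
    if (length(unique(meta$chromosome)) > 1L) {
      i <- sample.int(nrow(meta), 4L * nDist, replace = TRUE)
      j <- sample.int(nrow(meta), 4L * nDist, replace = TRUE)
      keep <- which(meta$chromosome[i] != meta$chromosome[j])[seq_len(nDist)]
      keep <- keep[!is.na(keep)]
      distPairs <- cbind(i[keep], j[keep])
    } else {
      sep <- abs(outer(meta$index, meta$index, "-"))
      far <- which(sep >= max(meta$index) / 2, arr.ind = TRUE)
      distPairs <- far[sample.int(nrow(far), min(nDist, nrow(far))), ,
                       drop = FALSE]
    }
    distRho <- vapply(seq_len(nrow(distPairs)), function(r)
      stats::cor(X[, distPairs[r, 1]], X[, distPairs[r, 2]],
                 method = "spearman"), numeric(1))
    list(adj = meanOrNA(adjRho[!is.na(adjRho)]),
         dist = meanOrNA(distRho[!is.na(distRho)]))
  })

  new("RealismReport",
      digitLongtailOk = unname(freqs[1] + freqs[2] > 2 * freqs[10]),
      adjacencyOk = unname(rho$adj > rho$dist + 0.1),
      firstDigitFreqs = freqs,
      adjacentRho = rho$adj, distantRho = rho$dist)
}
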