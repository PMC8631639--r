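#' Restrict a table to a random subset of genes
#'
#' Uniform sampling without replacement; with `k` equal to the gene count
#' the result is a column permutation of the input. Used by the
#' downsampling study to probe how few measurements still support
#' digit-frequency detection.
#'
#' @param table a [CNACohort-class].
#' @param k number of genes to keep, `1 <= k <= nGenes`.
#' @param seed integer seed.
#' @return a [CNACohort-class] with `k` genes.
#' @export
downsampleFeatures <- function(table, k, seed = 1L) {
  stopIfNotCohort(table)
  k <- as.integer(k)
  if (k < 1L || k > nrow(table))
    stop("k must lie in 1..", nrow(table),
         " (cannot select ", k, " distinct genes from ", nrow(table), ")",
         call. = FALSE)
  idx <- withSeed(seed, sample.int(nrow(table), k))
  table[idx, ]
}

#' Feature-downsampling robustness study
#'
#' For each feature count `k` in a strictly decreasing ladder and each of
#' `nReplicates` replicates: fabricate a fresh set of fakes, mix with the
#' real cohort, keep a fresh uniform subset of `k` genes, recompute
#' digit-frequency features from the surviving genes, split stratified in
#' half, grid-search-fit each classifier family on the training half and
#' score accuracy on the held-out half. One fabrication and one split per
#' replicate are shared across the ladder so curves differ only in `k`.
#'
#' @param real a [CNACohort-class] of real samples.
#' @param fabCfg a [FabricationConfig-class]; seed overridden per replicate.
#' @param ladder strictly decreasing feature counts, max <= gene count.
#' @param nReplicates replicates per feature count (default 50).
#' @param grids named list of [ModelGrid-class] objects.
#' @param baseSeed integer base seed.
#' @param cvFolds cross-validation folds.
#' @param spec [DigitSpec-class] for featurization.
#' @return a [DownsampleResult-class] with mean accuracy and standard error
#'   per (k, family).
#' @export
downsampleExperiment <- function(real, fabCfg, ladder, nReplicates = 50L,
                                 grids = defaultModelGrids(),
                                 baseSeed = 0L, cvFolds = 10L,
                                 spec = digitSpec()) {
  stopIfNotCohort(real, "real")
  ladder <- as.integer(ladder)
  if (length(ladder) > 1L && any(diff(ladder) >= 0L))
    stop("ladder must be strictly decreasing", call. = FALSE)
  if (max(ladder) > nrow(real))
    stop("ladder exceeds the number of genes", call. = FALSE)
  if (is.null(names(grids)))
    names(grids) <- vapply(grids, function(g) g@family, character(1))

  rows <- list()
  for (r in seq_len(nReplicates)) {
    seedR <- as.integer(baseSeed + r)
    cfgR <- fabCfg; cfgR@seed <- seedR
    mixed <- mixAndLabel(real, fabricate(real, cfgR))
    for (k in ladder) {
      down <- downsampleFeatures(mixed, k, seed = seedR + 7L * k)
      ds <- digitFrequencies(down, spec)
      halves <- splitTrainTest(ds, seed = seedR + .SEED_SPLIT)
      yTest <- sampleLabels(halves$test)
      for (fam in names(grids)) {
        fit <- tryCatch(
          fitWithGridSearch(halves$train, grids[[fam]], cvFolds,
                            seed = seedR + .SEED_CV),
          error = function(e)
            stop("k = ", k, ", replicate ", r, ": ", conditionMessage(e),
                 call. = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, replicate = r, family = fam,
          accuracy = accuracyScore(predictLabels(fit, halves$test), yTest),
          stringsAsFactors = FALSE)
      }
    }
  }
  per <- do.call(rbind, rows)
  curve <- do.call(rbind, lapply(split(per, list(per$k, per$family)),
    function(d) {
      n <- nrow(d)
      data.frame(k = d$k[1], family = d$family[1], n_replicates = n,
                 mean_accuracy = mean(d$accuracy),
                 sd_accuracy = stats::sd(d$accuracy),
                 se_accuracy = stats::sd(d$accuracy) / sqrt(n),
                 stringsAsFactors = FALSE)
    }))
  curve <- curve[order(match(curve$family, names(grids)), -curve$k), ]
  rownames(curve) <- NULL
  new("DownsampleResult", curve = curve, ladder = ladder)
}

#' Two-dimensional PCA projection of a mixed dataset
#'
#' Centers features and projects samples onto the first two principal axes
#' via singular-value decomposition. The sign of each axis is fixed so that
#' its largest-magnitude feature loading is positive, making coordinates
#' reproducible across runs and platforms. Random-method fakes separate
#' visibly from real samples in this projection; resampled and imputed fakes
#' cluster with the real data.
#'
#' @param mixed a labeled [CNACohort-class] (or any object with a
#'   [featureMatrix()] method), >= 3 samples and >= 2 features.
#' @return data.frame with `sample_id`, `label`, `PC1`, `PC2`.
#' @export
pcaProjection <- function(mixed) {
  X <- featureMatrix(mixed)
  if (nrow(X) < 3L || ncol(X) < 2L)
    stop("need >= 3 samples and >= 2 features", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  if (all(abs(Xc) < .Machine$double.eps * 100))
    stop("constant matrix has no principal axes", call. = FALSE)
  sv <- svd(Xc, nu = 2L, nv = 2L)
  flip <- vapply(1:2, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2L) %*% diag(flip, 2L)
  data.frame(sample_id = rownames(X),
             label = as.character(sampleLabels(mixed)),
             PC1 = scores[, 1], PC2 = scores[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation of gene pairs across tables
#'
#' Evaluates whether fabrication preserves between-gene relationships: for
#' every named table and every gene pair, the Spearman rank correlation
#' (average ranks for ties) of the two genes' values across samples.
#'
#' @param tables named list of [CNACohort-class] objects.
#' @param pairs data.frame (or 2-column matrix) of gene ID pairs; all genes
#'   must exist in all tables.
#' @return data.frame with `table`, `gene1`, `gene2`, `rho`.
#' @export
genePairCorrelation <- function(tables, pairs) {
  if (!is.list(tables) || is.null(names(tables)) || !all(nzchar(names(tables))))
    stop("'tables' must be a named list of cohorts", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  g1 <- as.character(pairs[[1]]); g2 <- as.character(pairs[[2]])
  out <- lapply(names(tables), function(nm) {
    co <- tables[[nm]]
    stopIfNotCohort(co, nm)
    if (ncol(co) < 3L) stop("table '", nm, "' has < 3 samples", call. = FALSE)
    missing <- setdiff(unique(c(g1, g2)), rownames(co))
    if (length(missing))
      stop("gene(s) not found in table '", nm, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- cnaMatrix(co)
    data.frame(table = nm, gene1 = g1, gene2 = g2,
               rho = vapply(seq_along(g1), function(i)
                 stats::cor(X[, g1[i]], X[, g2[i]], method = "spearman"),
                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summary of per-sample first-position digit frequencies
#'
#' For each digit 0-9, the mean, sd and quartiles of the per-sample
#' frequency of that digit at the first position after the decimal point --
#' the distribution whose decaying, long-right-tailed shape distinguishes
#' real copy-number tables from crudely fabricated ones.
#'
#' @param table a [CNACohort-class].
#' @param spec a [DigitSpec-class]; only its first requested position and
#'   precision are used.
#' @return data.frame with `digit`, `mean`, `sd`, `q25`, `median`, `q75`;
#'   attribute `longtail` carries the decay flag
#'   (`freq(0) + freq(1) > 2 * freq(9)` on the means).
#' @export
digitDistributionSummary <- function(table, spec = digitSpec()) {
  stopIfNotCohort(table)
  p1 <- spec@positions[1]
  f <- featureMatrix(digitFrequencies(table, digitSpec(p1, spec@precision)))
  out <- data.frame(
    digit = 0:9,
    mean = colMeans(f),
    sd = apply(f, 2L, stats::sd),
    q25 = apply(f, 2L, stats::quantile, 0.25),
    median = apply(f, 2L, stats::median),
    q75 = apply(f, 2L, stats::quantile, 0.75),
    row.names = NULL)
  attr(out, "longtail") <- unname(out$mean[1] + out$mean[2] > 2 * out$mean[10])
  out
}
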