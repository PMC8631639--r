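#' Create a fabrication configuration
#'
#' See [FabricationConfig-class] for slot meanings. The imputation controls
#' only matter for `method = "impute"`: by default 10% of a fake's genes are
#' nullified per round (ten disjoint rounds cover every gene exactly once),
#' each missing gene is re-predicted by a random forest of `imputeNTrees`
#' trees on at most `imputePredictorLimit` correlated predictor genes, and
#' sweeps within one round stop when the missForest-style convergence
#' criterion rises or `imputeMaxIter` is reached.
#'
#' @param method `"random"`, `"resample"` or `"impute"`.
#' @param nFake fake samples to fabricate.
#' @param seed integer seed.
#' @param imputeBlockFraction fraction of genes nullified per round.
#' @param imputeMaxIter cap on imputer sweeps per round.
#' @param imputeNTrees trees per random-forest regressor.
#' @param imputePredictorLimit max predictor genes per imputed gene.
#' @return a validated [FabricationConfig-class].
#' @export
fabricationConfig <- function(method = c("random", "resample", "impute"),
                              nFake = 50L, seed = 1L,
                              imputeBlockFraction = 0.10,
                              imputeMaxIter = 2L, imputeNTrees = 20L,
                              imputePredictorLimit = 30L) {
  cfg <- new("FabricationConfig",
    method = match.arg(method), nFake = as.integer(nFake),
    seed = as.integer(seed),
    imputeBlockFraction = as.numeric(imputeBlockFraction),
    imputeMaxIter = as.integer(imputeMaxIter),
    imputeNTrees = as.integer(imputeNTrees),
    imputePredictorLimit = as.integer(imputePredictorLimit))
  msg <- validObject(cfg, test = TRUE)
  if (!isTRUE(msg)) stop("invalid FabricationConfig -- ", msg, call. = FALSE)
  cfg
}

.fakeCohort <- function(values, real, method, sources = NA_character_,
                        seed) {
  ids <- sprintf("fake_%s_%03d", method, seq_len(nrow(values)))
  meta <- geneMeta(real)
  fake <- cnaCohort(values, sampleIds = ids, geneIds = meta$gene_id,
                    chromosome = meta$chromosome, index = meta$index,
                    label = "fake")
  metadata(fake)$provenance <- data.frame(
    fake_sample_id = ids, method = method,
    source_sample_id = rep_len(sources, length(ids)),
    seed = seed, stringsAsFactors = FALSE)
  fake
}

#' Fabricate fake samples by per-gene uniform random draws
#'
#' For every gene, the observed minimum and maximum across the real cohort
#' define a range; each fake sample draws every gene value uniformly within
#' that gene-specific range. This is the crudest mechanism: marginal ranges
#' are respected but the joint structure (between-gene correlation, the
#' concentration of values near zero) is destroyed.
#'
#' @param real a [CNACohort-class] with >= 2 samples and no missing values.
#' @param cfg a [FabricationConfig-class] with `method = "random"`.
#' @return a [CNACohort-class] of `nFake` fake samples (labels `"fake"`,
#'   provenance in `metadata()$provenance`).
#' @export
fabricateRandom <- function(real, cfg) {
  stopIfNotCohort(real, "real")
  if (cfg@method != "random") stop("cfg$method must be 'random'", call. = FALSE)
  X <- cnaMatrix(real)
  if (nrow(X) < 2L) stop("need >= 2 real samples", call. = FALSE)
  if (anyNA(X))
    stop("missing values make per-gene ranges undefined", call. = FALSE)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  vals <- withSeed(cfg@seed, {
    matrix(stats::runif(cfg@nFake * ncol(X),
                        rep(lo, each = cfg@nFake),
                        rep(hi, each = cfg@nFake)),
           nrow = cfg@nFake)
  })
  .fakeCohort(vals, real, "random", seed = cfg@seed)
}

#' Fabricate fake samples by resampling observed values with replacement
#'
#' Each gene of a fake sample is drawn uniformly, with replacement, from the
#' multiset of values observed for that gene across the real cohort. Every
#' fabricated value is therefore an exact float copy of some observed value;
#' marginals are preserved perfectly, joint structure is not.
#'
#' @inheritParams fabricateRandom
#' @param cfg a [FabricationConfig-class] with `method = "resample"`.
#' @return a [CNACohort-class] of fake samples.
#' @export
fabricateResample <- function(real, cfg) {
  stopIfNotCohort(real, "real")
  if (cfg@method != "resample")
    stop("cfg$method must be 'resample'", call. = FALSE)
  X <- cnaMatrix(real)
  if (nrow(X) < 2L) stop("need >= 2 real samples", call. = FALSE)
  if (anyNA(X)) stop("missing values in real cohort", call. = FALSE)
  vals <- withSeed(cfg@seed, {
    idx <- matrix(sample.int(nrow(X), cfg@nFake * ncol(X), replace = TRUE),
                  nrow = cfg@nFake)
    col <- matrix(rep(seq_len(ncol(X)), each = cfg@nFake), nrow = cfg@nFake)
    matrix(X[cbind(as.vector(idx), as.vector(col))], nrow = cfg@nFake)
  })
  .fakeCohort(vals, real, "resample", seed = cfg@seed)
}

#' Fabricate fake samples by iterative nullify-and-impute
#'
#' Each fake starts as a copy of a randomly chosen real sample. Its genes are
#' partitioned into `ceiling(1 / imputeBlockFraction)` disjoint random
#' blocks; round by round, one block is set to missing and re-predicted with
#' [iterativeRFImpute()] against the real cohort, so after all rounds every
#' entry has been imputed at least once. Any entry that still equals the
#' original copied value exactly is re-perturbed by additional
#' nullify-impute passes, guaranteeing that a fake shares no entry with its
#' source. Because each gene is predicted from correlated neighbours, this
#' is the only mechanism that preserves between-gene correlation -- and the
#' hardest to detect.
#'
#' All fakes of one call share the block partition and are imputed jointly
#' per round (every fake is missing the same block, so each per-gene forest
#' is trained on the real rows only); this keeps the cost independent of
#' `nFake` up to prediction.
#'
#' @param real a [CNACohort-class] with >= 10 samples, no missing values.
#' @param cfg a [FabricationConfig-class] with `method = "impute"`.
#' @return a [CNACohort-class] of fake samples; `metadata()$provenance`
#'   records the source sample per fake and `metadata()$imputationRound` the
#'   round in which each gene's block was nullified.
#' @export
fabricateImpute <- function(real, cfg) {
  stopIfNotCohort(real, "real")
  if (cfg@method != "impute") stop("cfg$method must be 'impute'", call. = FALSE)
  X <- cnaMatrix(real)
  if (nrow(X) < 10L) stop("need >= 10 real samples", call. = FALSE)
  if (anyNA(X)) stop("missing values in real cohort", call. = FALSE)
  g <- ncol(X)
  nBlocks <- ceiling(1 / cfg@imputeBlockFraction)
  if (nBlocks > g)
    stop("imputeBlockFraction yields empty blocks for ", g, " genes",
         call. = FALSE)

  res <- withSeed(cfg@seed, {
    sources <- sample.int(nrow(X), cfg@nFake, replace = cfg@nFake > nrow(X))
    blocks <- split(sample.int(g), rep(seq_len(nBlocks), length.out = g))
    Forig <- X[sources, , drop = FALSE]
    F <- Forig
    fakeRows <- nrow(X) + seq_len(cfg@nFake)
    rounds <- integer(g)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      rounds[idx] <- b
      M <- rbind(X, F)
      M[fakeRows, idx] <- NA_real_
      M <- rfImputeMatrix(M, cfg)
      F[, idx] <- M[fakeRows, idx, drop = FALSE]
    }
    # re-perturb entries that came back exactly equal to the source copy
    for (pass in seq_len(10L)) {
      eq <- F == Forig
      if (!any(eq)) break
      if (pass == 10L)
        stop("could not remove all source-identical entries; ",
             "is a gene constant across the cohort?", call. = FALSE)
      M <- rbind(X, F)
      M[fakeRows, ][eq] <- NA_real_
      M <- rfImputeMatrix(M, cfg)
      F[eq] <- M[fakeRows, , drop = FALSE][eq]
    }
    list(F = F, sources = rownames(X)[sources], rounds = rounds)
  })
  fake <- .fakeCohort(res$F, real, "impute", sources = res$sources,
                      seed = cfg@seed)
  metadata(fake)$imputationRound <- stats::setNames(res$rounds,
                                                    colnames(X))
  fake
}

#' Fabricate fake samples by the configured method
#'
#' Dispatches to [fabricateRandom()], [fabricateResample()] or
#' [fabricateImpute()] according to `cfg@method`.
#'
#' @inheritParams fabricateRandom
#' @param cfg a [FabricationConfig-class].
#' @return a [CNACohort-class] of fake samples.
#' @export
fabricate <- function(real, cfg) {
  switch(cfg@method,
         random = fabricateRandom(real, cfg),
         resample = fabricateResample(real, cfg),
         impute = fabricateImpute(real, cfg))
}

#' Combine a real and a fabricated cohort into one labeled dataset
#'
#' Row-concatenates the two cohorts (the canonical mix is 100 real + 50
#' fake). Gene lists must agree exactly, in order; sample IDs must remain
#' unique across the union. Labels come from each cohort's `colData`.
#'
#' @param real,fake [CNACohort-class] objects over identical gene lists.
#' @return a [CNACohort-class] containing both, labels preserved.
#' @export
mixAndLabel <- function(real, fake) {
  stopIfNotCohort(real, "real")
  stopIfNotCohort(fake, "fake")
  if (!identical(rownames(real), rownames(fake)))
    stop("gene lists differ between real and fake cohorts", call. = FALSE)
  if (any(colnames(fake) %in% colnames(real)))
    stop("duplicate sample IDs across real and fake cohorts", call. = FALSE)
  se <- SummarizedExperiment(
    assays = list(cna = cbind(assay(real, "cna"), assay(fake, "cna"))),
    rowData = rowData(real),
    colData = rbind(colData(real)[, "label", drop = FALSE],
                    colData(fake)[, "label", drop = FALSE]))
  metadata(se)$provenance <- metadata(fake)$provenance
  new("CNACohort", se)
}
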