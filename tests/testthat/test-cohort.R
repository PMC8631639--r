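test_that("the same config reproduces a cohort bit for bit", {
  cfg <- cohortConfig(nSamples = 30, nGenes = 300, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cnaMatrix(a), cnaMatrix(b))
  expect_identical(geneMeta(a), geneMeta(b))
  c <- generateCohort(cohortConfig(nSamples = 30, nGenes = 300, seed = 8))
  expect_false(identical(cnaMatrix(a), cnaMatrix(c)))
})

test_that("cohort dimensions, IDs and value bounds honour the config", {
  cfg <- cohortConfig(nSamples = 25, nGenes = 240, nChromosomes = 6,
                      valueClip = 1.5, seed = 3)
  co <- generateCohort(cfg)
  X <- cnaMatrix(co)
  expect_equal(dim(X), c(25L, 240L))
  expect_false(anyDuplicated(rownames(X)) > 0)
  expect_false(anyDuplicated(colnames(X)) > 0)
  expect_true(all(is.finite(X)))
  expect_true(all(abs(X) <= 1.5))
  m <- geneMeta(co)
  expect_equal(length(unique(m$chromosome)), 6L)
  # genes are assigned to chromosomes contiguously, indexed from 1
  expect_true(all(unlist(tapply(m$index, m$chromosome, identity)) ==
                  unlist(tapply(m$index, m$chromosome,
                                function(i) seq_along(i)))))
})

test_that("without events or segment wobble every gene is pure noise", {
  co <- generateCohort(cohortConfig(
    nSamples = 100, nGenes = 300, eventProb = 0, segmentNoiseSd = 0,
    noiseScaleRange = c(0.1, 0.1), seed = 5))
  sds <- apply(cnaMatrix(co), 2, sd)
  # per-column sd estimate has se ~ 0.1/sqrt(2*99); the mean over 300
  # columns pins the noise scale tightly
  expect_equal(mean(sds), 0.1, tolerance = 0.01)
  expect_true(all(abs(sds - 0.1) < 0.04))
})

test_that("adjacent genes correlate more than cross-chromosome genes", {
  co <- generateCohort(cohortConfig(seed = 11))
  X <- cnaMatrix(co)
  pairs <- adjacentPairs(co)
  set.seed(1)
  take <- sample(nrow(pairs), 200)
  adjRho <- vapply(take, function(i)
    cor(X[, pairs[i, 1]], X[, pairs[i, 2]], method = "spearman"), numeric(1))
  m <- geneMeta(co)
  crossRho <- replicate(200, {
    repeat {
      ij <- sample(ncol(X), 2)
      if (m$chromosome[ij[1]] != m$chromosome[ij[2]]) break
    }
    cor(X[, ij[1]], X[, ij[2]], method = "spearman")
  })
  expect_gt(mean(adjRho), mean(crossRho))
  expect_gt(mean(adjRho), 0.5)
})

test_that("invalid configs are rejected naming the offending field", {
  expect_error(cohortConfig(nSamples = 1), "nSamples")
  expect_error(cohortConfig(nGenes = 3, nChromosomes = 5), "nGenes")
  expect_error(cohortConfig(eventProb = 1.2), "eventProb")
  expect_error(cohortConfig(noiseScaleRange = c(0, 0.1)), "noiseScaleRange")
  expect_error(cohortConfig(noiseScaleRange = c(0.2, 0.1)), "noiseScaleRange")
})

test_that("realism report flags the structure of a default cohort", {
  co <- generateCohort(cohortConfig(seed = 1))
  rep <- validateRealism(co)
  expect_s4_class(rep, "RealismReport")
  expect_equal(sum(rep@firstDigitFreqs), 1, tolerance = 1e-9)
  expect_true(rep@digitLongtailOk)
  expect_true(rep@adjacencyOk)
  expect_gt(rep@adjacentRho, 0.5)
})

test_that("identical columns give perfect correlation everywhere, no adjacency signal", {
  base <- rnorm(20)
  co <- cnaCohort(matrix(base, 20, 60),
                  chromosome = rep(c("chr1", "chr2"), each = 30))
  rep <- validateRealism(co)
  expect_equal(rep@adjacentRho, 1.0)
  expect_equal(rep@distantRho, 1.0)
  expect_false(rep@adjacencyOk)
})

test_that("uniform(0,1) noise has flat first-digit frequencies and no long tail", {
  set.seed(2)
  co <- cnaCohort(matrix(runif(100 * 1000), 100, 1000),
                  chromosome = rep(c("chr1", "chr2"), each = 500))
  rep <- validateRealism(co)
  expect_true(all(abs(rep@firstDigitFreqs - 0.1) < 0.02))
  expect_false(rep@digitLongtailOk)
})

test_that("realism checks demand gene metadata and minimum size", {
  co <- tinyCohort()
  expect_error(validateRealism(co[1:10, ]), "50 genes")
  noMeta <- cnaCohort(matrix(rnorm(200), 2, 100),
                      chromosome = rep(NA_character_, 100))
  expect_error(validateRealism(noMeta), "metadata")
})
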