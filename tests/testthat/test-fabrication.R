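test_that("random fakes stay inside per-gene observed ranges", {
  co <- tinyCohort()
  X <- cnaMatrix(co)
  fake <- fabricateRandom(co, fabricationConfig("random", nFake = 30, seed = 1))
  F <- cnaMatrix(fake)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  expect_true(all(F >= matrix(lo, 30, ncol(X), byrow = TRUE)))
  expect_true(all(F <= matrix(hi, 30, ncol(X), byrow = TRUE)))
  expect_identical(colnames(F), colnames(X))
  expect_equal(as.character(sampleLabels(fake)), rep("fake", 30))
})

test_that("a constant gene fabricates constantly under both cheap methods", {
  X <- cbind(rep(0.5, 10), matrix(rnorm(10 * 5), 10, 5))
  co <- cnaCohort(X)
  r <- cnaMatrix(fabricateRandom(co, fabricationConfig("random", nFake = 20,
                                                       seed = 2)))
  s <- cnaMatrix(fabricateResample(co, fabricationConfig("resample",
                                                         nFake = 20, seed = 2)))
  expect_true(all(r[, 1] == 0.5))
  expect_true(all(s[, 1] == 0.5))
})

test_that("random draws on a [0,1] gene have the uniform mean", {
  co <- cnaCohort(cbind(c(0, 1), matrix(rnorm(4), 2, 2)))
  fake <- fabricateRandom(co, fabricationConfig("random", nFake = 1e4,
                                                seed = 3))
  expect_lt(abs(mean(cnaMatrix(fake)[, 1]) - 0.5), 0.02)
})

test_that("resampled values are exact members of the per-gene multisets", {
  co <- tinyCohort()
  X <- cnaMatrix(co)
  fake <- fabricateResample(co, fabricationConfig("resample", nFake = 30,
                                                  seed = 4))
  F <- cnaMatrix(fake)
  for (j in seq_len(ncol(X)))
    expect_true(all(F[, j] %in% X[, j]))   # exact float equality
})

test_that("resampling respects multiset proportions", {
  co <- cnaCohort(cbind(c(rep(0.1, 90), rep(0.9, 10)),
                        matrix(rnorm(200), 100, 2)))
  fake <- fabricateResample(co, fabricationConfig("resample", nFake = 1e4,
                                                  seed = 5))
  expect_lt(abs(mean(cnaMatrix(fake)[, 1] == 0.9) - 0.10), 0.01)
})

test_that("fabrication is seed-deterministic and seed-sensitive", {
  co <- tinyCohort()
  for (method in c("random", "resample")) {
    a <- fabricate(co, fabricationConfig(method, nFake = 10, seed = 7))
    b <- fabricate(co, fabricationConfig(method, nFake = 10, seed = 7))
    c <- fabricate(co, fabricationConfig(method, nFake = 10, seed = 8))
    expect_identical(cnaMatrix(a), cnaMatrix(b))
    expect_false(identical(cnaMatrix(a), cnaMatrix(c)))
  }
})

test_that("random and resample fakes lose adjacent-gene correlation", {
  co <- generateCohort(cohortConfig(nSamples = 100, nGenes = 400,
                                    nChromosomes = 8, seed = 21))
  pairs <- adjacentPairs(co)
  for (method in c("random", "resample")) {
    F <- cnaMatrix(fabricate(co, fabricationConfig(method, nFake = 50,
                                                   seed = 22)))
    rhos <- vapply(seq_len(nrow(pairs)), function(i)
      cor(F[, pairs[i, 1]], F[, pairs[i, 2]], method = "spearman"),
      numeric(1))
    expect_lt(mean(abs(rhos)), 0.3)
  }
})

test_that("mixing keeps counts, labels and unique IDs", {
  co <- tinyCohort(nSamples = 10)
  fake <- fabricateRandom(co, fabricationConfig("random", nFake = 5, seed = 1))
  mixed <- mixAndLabel(co, fake)
  expect_equal(ncol(mixed), 15L)
  expect_equal(sum(sampleLabels(mixed) == "fake"), 5L)
  expect_identical(rownames(mixed), rownames(co))

  one <- mixAndLabel(co[, 1], fake[, 1])
  expect_equal(ncol(one), 2L)
  expect_setequal(as.character(sampleLabels(one)), c("real", "fake"))

  clash <- cnaCohort(cnaMatrix(fake), sampleIds = colnames(co)[1:5],
                     label = "fake")
  expect_error(mixAndLabel(co, clash), "duplicate sample ID")
  expect_error(mixAndLabel(co[1:50, ], fake), "gene lists differ")
})

test_that("fabrication configs validate their fields", {
  expect_error(fabricationConfig("random", nFake = 0), "nFake")
  expect_error(fabricationConfig("impute", imputeBlockFraction = 0),
               "imputeBlockFraction")
  expect_error(fabricationConfig("typo"), "arg")
})
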