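mixedToy <- function(nReal = 100L, nFake = 50L, nFeatures = 20L, seed = 17L) {
  set.seed(seed)
  real <- cnaCohort(matrix(rnorm(nReal * nFeatures), nReal),
                    sampleIds = sprintf("real_%03d", seq_len(nReal)))
  fake <- cnaCohort(matrix(rnorm(nFake * nFeatures, mean = 3), nFake),
                    sampleIds = sprintf("fake_%03d", seq_len(nFake)),
                    label = "fake")
  mixAndLabel(real, fake)
}

test_that("the stratified half split reproduces the canonical 50/25 halves", {
  mixed <- mixedToy()
  h <- splitTrainTest(mixed, seed = 1)
  expect_equal(as.integer(table(sampleLabels(h$train))), c(50L, 25L))
  expect_equal(as.integer(table(sampleLabels(h$test))), c(50L, 25L))
  expect_length(intersect(colnames(h$train), colnames(h$test)), 0L)
  expect_setequal(c(colnames(h$train), colnames(h$test)), colnames(mixed))
})

test_that("odd class counts put the extra sample in training", {
  mixed <- mixedToy(nReal = 7L, nFake = 4L)
  h <- splitTrainTest(mixed, seed = 2)
  expect_equal(sum(sampleLabels(h$train) == "real"), 4L)
  expect_equal(sum(sampleLabels(h$test) == "real"), 3L)
})

test_that("splits are seed-deterministic and seed-sensitive", {
  mixed <- mixedToy()
  a <- splitTrainTest(mixed, seed = 3)
  b <- splitTrainTest(mixed, seed = 3)
  c <- splitTrainTest(mixed, seed = 4)
  expect_identical(colnames(a$train), colnames(b$train))
  expect_false(identical(colnames(a$train), colnames(c$train)))
})

test_that("single-class data cannot be stratified", {
  real <- cnaCohort(matrix(rnorm(40), 4), label = "real")
  expect_error(splitTrainTest(real), "class")
})

test_that("a single-combination grid is chosen as-is", {
  mixed <- blobDataset()
  fit <- fitWithGridSearch(mixed, modelGrid("knn", k = 5), cvFolds = 5,
                           seed = 1)
  expect_equal(fit$params$k, 5)
})

test_that("every family separates well-separated blobs perfectly in CV", {
  mixed <- blobDataset()
  for (grid in defaultModelGrids()) {
    fit <- fitWithGridSearch(mixed, grid, cvFolds = 5, seed = 1)
    expect_equal(fit$cvAccuracy, 1.0, info = grid@family)
    # chosen combination is an element of the declared space
    for (p in names(fit$params))
      expect_true(fit$params[[p]] %in% grid@grid[[p]], info = grid@family)
    pred <- predictLabels(fit, mixed)
    expect_equal(accuracyScore(pred, sampleLabels(mixed)), 1.0,
                 info = grid@family)
  }
})

test_that("grid search never sees test samples and audits what it saw", {
  mixed <- mixedToy(nReal = 20L, nFake = 10L)
  h <- splitTrainTest(mixed, seed = 5)
  fit <- fitWithGridSearch(h$train, modelGrid("random_forest", ntree = 50),
                           cvFolds = 5, seed = 6)
  expect_setequal(fit$trainIds, colnames(h$train))
  expect_length(intersect(fit$trainIds, colnames(h$test)), 0L)
})

test_that("fold counts beyond the minority class are refused", {
  mixed <- mixedToy(nReal = 20L, nFake = 6L)
  h <- splitTrainTest(mixed, seed = 7)   # 3 fakes in train
  expect_error(fitWithGridSearch(h$train, modelGrid("knn", k = 3),
                                 cvFolds = 10, seed = 8), "minority")
})

test_that("accuracy is the exact fraction correct", {
  labels <- rep(c("real", "fake"), c(50, 25))
  expect_equal(accuracyScore(labels, labels), 1.0)
  allReal <- rep("real", 75)
  expect_equal(accuracyScore(allReal, labels), 50 / 75)
  expect_equal(accuracyScore(rep("fake", 75), labels), 1 - 50 / 75)
  expect_error(accuracyScore(allReal, labels[1:10]), "equal")
})

test_that("F1 treats fake as the positive class with the 0/0 convention", {
  labels <- rep(c("real", "fake"), c(50, 25))
  expect_equal(f1Score(rep("real", 75), labels), 0)
  expect_equal(f1Score(labels, labels), 1.0)
  pred <- rep(c("fake", "real", "fake", "real"), c(20, 5, 5, 45))
  truth <- rep(c("fake", "fake", "real", "real"), c(20, 5, 5, 45))
  expect_equal(f1Score(pred, truth), 0.8)   # TP 20, FP 5, FN 5
})

test_that("repeated trials have the right shape and fresh fakes per trial", {
  co <- tinyCohort(nSamples = 30, nGenes = 150)
  grids <- defaultModelGrids()[c("random_forest", "knn")]
  res <- runTrials(co, fabricationConfig("random", nFake = 10),
                   featurization = "digit_frequency", grids = grids,
                   nTrials = 2, baseSeed = 100, cvFolds = 5)
  tr <- trialResults(res)
  expect_equal(nrow(tr), 4L)
  expect_setequal(tr$family, c("random_forest", "knn"))
  expect_true(all(tr$accuracy >= 0 & tr$accuracy <= 1))
  agg <- aggregateResults(res)
  expect_equal(agg$n_trials, c(2L, 2L))
  expect_equal(agg$se_accuracy, agg$sd_accuracy / sqrt(2))
  # trial seeds are baseSeed + t, so fakes differ between trials
  f1 <- fabricate(co, fabricationConfig("random", nFake = 10, seed = 101))
  f2 <- fabricate(co, fabricationConfig("random", nFake = 10, seed = 102))
  expect_false(identical(cnaMatrix(f1), cnaMatrix(f2)))
})

test_that("the full benchmark is reproducible from the base seed", {
  co <- tinyCohort(nSamples = 30, nGenes = 150)
  grids <- defaultModelGrids()["naive_bayes"]
  args <- list(co, fabricationConfig("resample", nFake = 10),
               featurization = "digit_frequency", grids = grids,
               nTrials = 2, baseSeed = 55, cvFolds = 5)
  a <- do.call(runTrials, args)
  b <- do.call(runTrials, args)
  expect_identical(trialResults(a), trialResults(b))
})
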