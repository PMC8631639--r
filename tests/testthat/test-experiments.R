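test_that("downsampling selects distinct genes without invention", {
  co <- tinyCohort()
  full <- downsampleFeatures(co, nrow(co), seed = 1)
  expect_setequal(rownames(full), rownames(co))   # a permutation, all present
  ten <- downsampleFeatures(co, 10, seed = 2)
  expect_equal(nrow(ten), 10L)
  expect_false(anyDuplicated(rownames(ten)) > 0)
  expect_true(all(rownames(ten) %in% rownames(co)))
  a <- downsampleFeatures(co, 10, seed = 3)
  b <- downsampleFeatures(co, 10, seed = 3)
  c <- downsampleFeatures(co, 10, seed = 4)
  expect_identical(rownames(a), rownames(b))
  expect_false(identical(rownames(a), rownames(c)))
  expect_error(downsampleFeatures(co, nrow(co) + 1), "distinct genes")
  expect_error(downsampleFeatures(co, 0), "distinct genes")
})

test_that("the downsampling study reports one aggregate row per (k, family)", {
  co <- tinyCohort(nSamples = 30, nGenes = 120)
  res <- downsampleExperiment(
    co, fabricationConfig("random", nFake = 10),
    ladder = c(120, 50, 10), nReplicates = 2,
    grids = defaultModelGrids()[c("random_forest", "knn")],
    baseSeed = 9, cvFolds = 5)
  curve <- downsampleCurve(res)
  expect_equal(nrow(curve), 6L)
  expect_equal(curve$n_replicates, rep(2L, 6))
  expect_equal(curve$se_accuracy, curve$sd_accuracy / sqrt(2))
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 1))
  expect_error(downsampleExperiment(
    co, fabricationConfig("random", nFake = 10), ladder = c(50, 120),
    nReplicates = 1), "decreasing")
})

test_that("PCA maps duplicated samples to identical coordinates", {
  set.seed(41)
  X <- matrix(rnorm(5 * 8), 5, 8)
  co <- cnaCohort(rbind(X, X[1, , drop = FALSE]),
                  sampleIds = c(sprintf("s%d", 1:5), "s1_dup"))
  pr <- pcaProjection(co)
  expect_equal(unlist(pr[6, c("PC1", "PC2")]),
               unlist(pr[1, c("PC1", "PC2")]), tolerance = 1e-9)
})

test_that("PCA reproduces pairwise distances of a rank-2 matrix exactly", {
  set.seed(42)
  scores <- scale(matrix(rnorm(12 * 2), 12, 2), scale = FALSE)
  loadings <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))   # orthonormal columns
  X <- scores %*% t(loadings)
  pr <- pcaProjection(cnaCohort(X))
  expect_equal(unname(as.matrix(dist(pr[, c("PC1", "PC2")]))),
               unname(as.matrix(dist(X))), tolerance = 1e-8)
})

test_that("PCA separates random-method fakes from the real cohort", {
  co <- generateCohort(cohortConfig(nSamples = 100, nGenes = 500,
                                    nChromosomes = 10, seed = 51))
  fake <- fabricateRandom(co, fabricationConfig("random", nFake = 50,
                                                seed = 52))
  pr <- pcaProjection(mixAndLabel(co, fake))
  real <- pr[pr$label == "real", ]
  fk <- pr[pr$label == "fake", ]
  # random fakes are symmetric about the per-gene range midpoints, so the
  # two centroids nearly coincide; the separation is radial -- a tight real
  # cluster inside a widely scattered fake cloud
  cen <- c(mean(real$PC1), mean(real$PC2))
  dReal <- sqrt((real$PC1 - cen[1])^2 + (real$PC2 - cen[2])^2)
  dFake <- sqrt((fk$PC1 - cen[1])^2 + (fk$PC2 - cen[2])^2)
  expect_gt(median(dFake), 1.5 * median(dReal))
})

test_that("PCA is invariant to sample order and rejects degenerate input", {
  set.seed(43)
  X <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(sprintf("s%d", 1:6), NULL))
  perm <- sample(6)
  pr1 <- pcaProjection(cnaCohort(X))
  pr2 <- pcaProjection(cnaCohort(X[perm, ]))
  reord <- pr2[match(pr1$sample_id, pr2$sample_id), ]
  expect_equal(reord$PC1, pr1$PC1, tolerance = 1e-9)
  expect_equal(reord$PC2, pr1$PC2, tolerance = 1e-9)
  expect_error(pcaProjection(cnaCohort(matrix(1, 5, 4))), "constant")
})

test_that("gene-pair Spearman handles the canonical cases and matches the rank oracle", {
  set.seed(44)
  x <- rnorm(30)
  co <- cnaCohort(cbind(a = x, b = x, c = -x,
                        matrix(rnorm(30 * 7), 30, 7)),
                  geneIds = c("a", "b", "c", sprintf("g%d", 1:7)))
  pc <- genePairCorrelation(list(t = co),
                            data.frame(g1 = c("a", "a"), g2 = c("b", "c")))
  expect_equal(pc$rho, c(1, -1))
  X <- cnaMatrix(co)
  pairs <- t(replicate(100, sample(colnames(X), 2)))
  pc2 <- genePairCorrelation(list(t = co), pairs)
  oracle <- vapply(seq_len(100), function(i)
    oracleSpearman(X[, pairs[i, 1]], X[, pairs[i, 2]]), numeric(1))
  expect_equal(pc2$rho, oracle, tolerance = 1e-12)
  expect_error(genePairCorrelation(list(t = co),
                                   data.frame("a", "missing_gene")),
               "not found")
})

test_that("digit distribution summaries behave on constants and cohorts", {
  co <- cnaCohort(matrix(0.1, 5, 60))
  s <- digitDistributionSummary(co)
  expect_equal(s$mean[s$digit == 1], 1.0)
  expect_equal(sum(s$mean), 1, tolerance = 1e-9)
  expect_equal(s$sd[s$digit == 1], 0)

  synth <- digitDistributionSummary(tinyCohort(nSamples = 30, nGenes = 200))
  expect_equal(sum(synth$mean), 1, tolerance = 1e-9)
  expect_true(attr(synth, "longtail"))
})
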