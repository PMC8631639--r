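# Fixtures are built in code; nothing is read from disk.

# Small cohort for unit tests (4 chromosomes keeps adjacency testable).
tinyCohort <- function(nSamples = 20L, nGenes = 120L, seed = 42L, ...) {
  generateCohort(cohortConfig(nSamples = nSamples, nGenes = nGenes,
                              nChromosomes = 4L, seed = seed, ...))
}

# Two well-separated Gaussian blobs as a labeled cohort; every sane
# classifier should be perfect on these.
blobDataset <- function(nPerClass = 20L, nFeatures = 5L, separation = 10,
                        seed = 9L) {
  set.seed(seed)
  vals <- rbind(
    matrix(stats::rnorm(nPerClass * nFeatures), nPerClass),
    matrix(stats::rnorm(nPerClass * nFeatures, mean = separation), nPerClass))
  real <- cnaCohort(vals[seq_len(nPerClass), , drop = FALSE],
                    sampleIds = sprintf("real_%02d", seq_len(nPerClass)))
  fake <- cnaCohort(vals[nPerClass + seq_len(nPerClass), , drop = FALSE],
                    sampleIds = sprintf("fake_%02d", seq_len(nPerClass)),
                    label = "fake")
  mixAndLabel(real, fake)
}

# Independent brute-force digit-frequency oracle: renders each value,
# locates the decimal point by string search, and counts characters
# digit by digit in per-sample loops.
oracleDigitFreq <- function(X, positions = c(1L, 2L), precision = 10L) {
  out <- matrix(0, nrow(X), 10L * length(positions))
  for (i in seq_len(nrow(X))) {
    vals <- X[i, ]
    vals <- vals[!is.na(vals)]
    strs <- formatC(abs(vals), format = "f", digits = precision)
    for (pi in seq_along(positions)) {
      p <- positions[pi]
      digs <- vapply(strs, function(s) {
        dot <- as.integer(regexpr(".", s, fixed = TRUE))
        as.integer(substr(s, dot + p, dot + p))
      }, integer(1), USE.NAMES = FALSE)
      for (d in 0:9)
        out[i, (pi - 1L) * 10L + d + 1L] <- sum(digs == d) / length(vals)
    }
  }
  out
}

# Rank-then-Pearson Spearman oracle (average ranks for ties).
oracleSpearman <- function(x, y) stats::cor(rank(x), rank(y))

# Adjacent within-chromosome gene-pair index pairs of a cohort.
adjacentPairs <- function(cohort) {
  m <- geneMeta(cohort)
  same <- m$chromosome[-nrow(m)] == m$chromosome[-1]
  i <- which(same)
  cbind(i, i + 1L)
}
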