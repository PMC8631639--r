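# Iterative random-forest imputation (the missForest algorithm), desk-scaled
# with a predictor cap so imputing one gene fits a forest on its most
# correlated neighbours rather than on all genes.

# Matrix engine. X: samples x genes with NAs; returns a completed matrix.
# Consumes the R RNG stream (forest bootstraps), so callers wrap in withSeed.
rfImputeMatrix <- function(X, cfg) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  nObs <- colSums(!miss)
  if (any(nObs == 0L))
    stop("gene(s) with no observed values cannot be imputed: ",
         paste(colnames(X)[nObs == 0L], collapse = ", "), call. = FALSE)
  targets <- which(colSums(miss) > 0L)
  targets <- targets[order(colSums(miss)[targets])]  # least missing first

  # mean initialization
  Ximp <- X
  for (gIdx in targets) {
    m <- mean(X[, gIdx], na.rm = TRUE)
    Ximp[miss[, gIdx], gIdx] <- m
  }

  prevDiff <- Inf
  for (sweep in seq_len(cfg@imputeMaxIter)) {
    Xprev <- Ximp
    for (gIdx in targets) {
      obs <- !miss[, gIdx]
      cand <- setdiff(seq_len(ncol(X)), gIdx)
      if (length(cand) > cfg@imputePredictorLimit) {
        r <- suppressWarnings(
          stats::cor(Ximp[obs, cand, drop = FALSE], Ximp[obs, gIdx]))
        r[is.na(r)] <- 0
        cand <- cand[order(abs(r), decreasing = TRUE)[
          seq_len(cfg@imputePredictorLimit)]]
      }
      fit <- randomForest::randomForest(
        x = Ximp[obs, cand, drop = FALSE], y = Ximp[obs, gIdx],
        ntree = cfg@imputeNTrees)
      Ximp[!obs, gIdx] <- stats::predict(
        fit, Ximp[!obs, cand, drop = FALSE])
    }
    denom <- sum(Ximp[miss]^2)
    diff <- if (denom > 0) sum((Ximp[miss] - Xprev[miss])^2) / denom
            else sum((Ximp[miss] - Xprev[miss])^2)
    if (diff > prevDiff) return(Xprev)  # criterion rose: keep last good sweep
    if (diff == 0) break
    prevDiff <- diff
  }
  Ximp
}

#' Iterative random-forest imputation of missing entries
#'
#' Completes a table with missing values by the missForest procedure:
#' missing entries start at per-gene means; genes are visited in order of
#' increasing missingness; each gene with missing entries is re-predicted by
#' a random-forest regressor fit on the rows where it is observed, using at
#' most `imputePredictorLimit` predictor genes ranked by absolute Pearson
#' correlation; sweeps repeat until the normalized sum of squared changes in
#' the imputed values increases (the result of the previous sweep is then
#' returned) or `imputeMaxIter` is reached.
#'
#' @param table a [CNACohort-class] whose assay may contain `NA`s; every
#'   gene needs at least one observed value.
#' @param cfg a [FabricationConfig-class] supplying the imputation controls.
#' @param seed integer seed for the forest bootstraps.
#' @return a fully observed [CNACohort-class]; tables without missing
#'   entries are returned unchanged.
#' @seealso [fabricateImpute()], which repurposes this for fabrication.
#' @export
iterativeRFImpute <- function(table, cfg = fabricationConfig("impute"),
                              seed = cfg@seed) {
  stopIfNotCohort(table)
  X <- cnaMatrix(table)
  if (!anyNA(X)) return(table)
  Ximp <- withSeed(seed, rfImputeMatrix(X, cfg))
  out <- table
  SummarizedExperiment::assay(out, "cna") <- t(Ximp)
  out
}
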