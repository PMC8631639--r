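#' Define a hyperparameter grid for one classifier family
#'
#' @param family one of `"gradient_boosting"`, `"naive_bayes"`,
#'   `"random_forest"`, `"knn"`, `"svm"`.
#' @param ... named candidate vectors, expanded exhaustively. Recognized
#'   parameters: random_forest `ntree`; gradient_boosting `nrounds`,
#'   `max_depth`, `eta`; knn `k`; svm `kernel` (`"linear"`/`"radial"`),
#'   `cost`; naive_bayes `var_smoothing` (variance floor as a fraction of
#'   the largest feature variance, as in common Gaussian NB
#'   implementations).
#' @return a [ModelGrid-class].
#' @examples
#' modelGrid("knn", k = c(3, 5, 7))
#' @export
modelGrid <- function(family, ...) {
  grid <- list(...)
  g <- new("ModelGrid", family = family, grid = grid)
  msg <- validObject(g, test = TRUE)
  if (!isTRUE(msg)) stop("invalid ModelGrid -- ", msg, call. = FALSE)
  g
}

#' Default search spaces for the five classifier families
#'
#' Modest grids per family: tree counts \{100, 300\} for random forest,
#' boosting rounds \{50, 150\} x depth \{2, 3\}, k in \{3, 5, 7\} for KNN,
#' linear and RBF kernels x cost \{0.1, 1, 10\} for the SVM, and two
#' variance-smoothing levels for Gaussian naive Bayes.
#'
#' @return named list of [ModelGrid-class] objects.
#' @export
defaultModelGrids <- function() {
  list(
    gradient_boosting = modelGrid("gradient_boosting",
                                  nrounds = c(50, 150), max_depth = c(2, 3)),
    naive_bayes = modelGrid("naive_bayes", var_smoothing = c(1e-9, 1e-8)),
    random_forest = modelGrid("random_forest", ntree = c(100, 300)),
    knn = modelGrid("knn", k = c(3, 5, 7)),
    svm = modelGrid("svm", kernel = c("linear", "radial"),
                    cost = c(0.1, 1, 10))
  )
}

#' Stratified half split into train and test
#'
#' Within each class, samples are randomly halved; with an odd class count
#' the extra sample goes to the training side. The canonical mix of 100 real
#' + 50 fake therefore yields 50 real + 25 fake in each half.
#'
#' @param dataset a labeled [CNACohort-class] or [DigitFrequencySet-class]
#'   with both classes present (>= 2 samples each).
#' @param seed integer seed; the same seed reproduces the split.
#' @return list with elements `train` and `test`, column subsets of the
#'   input; disjoint, union = input.
#' @export
splitTrainTest <- function(dataset, seed = 1L) {
  y <- sampleLabels(dataset)
  if (anyNA(y)) stop("dataset has unlabeled samples", call. = FALSE)
  if (any(table(y) < 2L))
    stop("each class needs >= 2 samples to stratify", call. = FALSE)
  testIdx <- withSeed(seed, {
    unlist(lapply(levels(y), function(cl) {
      w <- which(y == cl)
      sample(w, floor(length(w) / 2))
    }), use.names = FALSE)
  })
  list(train = dataset[, -testIdx], test = dataset[, sort(testIdx)])
}

# ---- model backends -------------------------------------------------------
# Each returns list(predict = function(newX) factor("real","fake")).
# SVM and KNN are distance/kernel-based and get train-fitted standardization;
# tree models and NB see raw features.

.scaleBy <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2L, center), 2L, scale, "/")
}

.fitFamily <- function(family, params, X, y) {
  lv <- c("real", "fake")
  switch(family,
    random_forest = {
      fit <- randomForest::randomForest(x = X, y = y,
                                        ntree = as.integer(params$ntree))
      list(predict = function(newX)
        factor(as.character(stats::predict(fit, newX)), levels = lv))
    },
    gradient_boosting = {
      eta <- if (is.null(params$eta)) 0.3 else params$eta
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "fake"),
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = as.integer(params$max_depth),
                      eta = eta, tree_method = "exact", nthread = 1),
        data = dtrain, nrounds = as.integer(params$nrounds), verbose = 0)
      list(predict = function(newX)
        factor(ifelse(stats::predict(fit, xgboost::xgb.DMatrix(
                 newX, nthread = 1)) > 0.5, "fake", "real"),
               levels = lv))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(X), y = y)
      # variance floor relative to the largest feature variance, so constant
      # within-class features cannot produce degenerate densities
      vmax <- max(apply(X, 2L, stats::var))
      eps <- params$var_smoothing * max(vmax, .Machine$double.eps)
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2L] <- sqrt(tb[, 2L]^2 + eps)
        tb
      })
      list(predict = function(newX)
        factor(as.character(stats::predict(fit, as.data.frame(newX))),
               levels = lv))
    },
    knn = {
      center <- colMeans(X); scl <- apply(X, 2L, stats::sd)
      Xs <- .scaleBy(X, center, scl)
      list(predict = function(newX)
        factor(as.character(class::knn(Xs, .scaleBy(newX, center, scl),
                                       cl = y, k = as.integer(params$k))),
               levels = lv))
    },
    svm = {
      center <- colMeans(X); scl <- apply(X, 2L, stats::sd)
      Xs <- .scaleBy(X, center, scl)
      fit <- e1071::svm(x = Xs, y = y, kernel = as.character(params$kernel),
                        cost = params$cost, scale = FALSE)
      list(predict = function(newX)
        factor(as.character(stats::predict(fit, .scaleBy(newX, center, scl))),
               levels = lv))
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Scores every parameter combination of the grid by mean cross-validated
#' accuracy on the training set only (stratified folds), breaks ties in
#' favour of the first-listed combination, and refits the winner on the full
#' training set. Test data never enters this routine; the returned model
#' records the sample IDs seen during fitting for auditability.
#'
#' @param train a labeled [CNACohort-class] or [DigitFrequencySet-class].
#' @param grid a [ModelGrid-class].
#' @param cvFolds folds (default 10); must not exceed the minority-class
#'   count.
#' @param seed integer seed for fold assignment and model stochasticity.
#' @return an object of class `fabscreenModel`: list with `family`,
#'   `params` (chosen combination), `cvAccuracy`, `model`, `trainIds`.
#' @seealso [predictLabels()]
#' @export
fitWithGridSearch <- function(train, grid, cvFolds = 10L, seed = 1L) {
  X <- featureMatrix(train)
  y <- sampleLabels(train)
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  if (cvFolds > min(table(y)))
    stop("cvFolds exceeds the minority-class count", call. = FALSE)
  combos <- expand.grid(grid@grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)

  res <- withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {   # stratified folds
      w <- which(y == cl)
      fold[w] <- sample(rep_len(seq_len(cvFolds), length(w)))
    }
    cvAcc <- vapply(seq_len(nrow(combos)), function(i) {
      params <- as.list(combos[i, , drop = FALSE])
      mean(vapply(seq_len(cvFolds), function(f) {
        inTr <- fold != f
        fit <- .fitFamily(grid@family, params, X[inTr, , drop = FALSE],
                          droplevels(y[inTr]))
        accuracyScore(fit$predict(X[!inTr, , drop = FALSE]), y[!inTr])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cvAcc)  # ties: first-listed combination
    params <- as.list(combos[best, , drop = FALSE])
    list(params = params, cv = cvAcc[best],
         model = .fitFamily(grid@family, params, X, y))
  })
  structure(list(family = grid@family, params = res$params,
                 cvAccuracy = res$cv, model = res$model,
                 trainIds = colnames(train)),
            class = "fabscreenModel")
}

#' Predict real/fake labels with a fitted model
#'
#' @param object a `fabscreenModel` from [fitWithGridSearch()].
#' @param newdata a [CNACohort-class], [DigitFrequencySet-class], or a
#'   samples-by-features matrix matching the training features.
#' @return factor of predictions with levels `c("real", "fake")`.
#' @export
predictLabels <- function(object, newdata) {
  X <- if (is.matrix(newdata)) newdata else featureMatrix(newdata)
  object$model$predict(X)
}

#' Classification accuracy
#'
#' The fraction of correct predictions. A classifier stuck on the majority
#' class scores exactly 2/3 on the canonical 50-real/25-fake test half.
#'
#' @param predictions,labels equal-length vectors or factors.
#' @return fraction in \[0, 1\].
#' @export
accuracyScore <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L)
    stop("predictions and labels must have equal nonzero length",
         call. = FALSE)
  mean(as.character(predictions) == as.character(labels))
}

#' F1 score for the fake (positive) class
#'
#' Harmonic mean of precision and recall, with the 0/0 convention that a
#' classifier producing no true positives, no false positives and fakes
#' present scores 0 (an all-real predictor has F1 = 0).
#'
#' @inheritParams accuracyScore
#' @param positive the positive class (default `"fake"`).
#' @return score in \[0, 1\].
#' @export
f1Score <- function(predictions, labels, positive = "fake") {
  if (length(predictions) != length(labels) || length(labels) == 0L)
    stop("predictions and labels must have equal nonzero length",
         call. = FALSE)
  p <- as.character(predictions) == positive
  t <- as.character(labels) == positive
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Repeated fabricate-train-test trials over classifier families
#'
#' The full benchmarking protocol: per trial, fabricate a fresh set of fakes
#' (seed `baseSeed + trial`), mix with the real cohort, optionally transform
#' to digit-frequency features, split stratified in half, grid-search-fit
#' each family with cross-validation on the training half only, and score
#' accuracy and F1 on the held-out half. Aggregates report mean, sd and
#' standard error per family over trials.
#'
#' @param real a [CNACohort-class] of real samples.
#' @param fabCfg a [FabricationConfig-class]; its `seed` slot is overridden
#'   per trial by `baseSeed + trial`.
#' @param featurization `"digit_frequency"` or `"quantitative"`.
#' @param grids named list of [ModelGrid-class] objects
#'   (default [defaultModelGrids()]).
#' @param nTrials number of repeated trials (the headline protocol uses 50).
#' @param baseSeed integer; trial t uses fabrication seed `baseSeed + t`,
#'   with split and CV seeds derived by fixed offsets.
#' @param cvFolds cross-validation folds (default 10).
#' @param spec [DigitSpec-class] used when featurizing.
#' @return a [BenchmarkResult-class].
#' @export
runTrials <- function(real, fabCfg,
                      featurization = c("digit_frequency", "quantitative"),
                      grids = defaultModelGrids(), nTrials = 50L,
                      baseSeed = 0L, cvFolds = 10L, spec = digitSpec()) {
  stopIfNotCohort(real, "real")
  featurization <- match.arg(featurization)
  if (nTrials < 1L) stop("nTrials must be >= 1", call. = FALSE)
  if (is.null(names(grids)))
    names(grids) <- vapply(grids, function(g) g@family, character(1))

  rows <- vector("list", nTrials * length(grids))
  ri <- 0L
  for (t in seq_len(nTrials)) {
    seedT <- as.integer(baseSeed + t)
    cfgT <- fabCfg; cfgT@seed <- seedT
    mixed <- tryCatch(mixAndLabel(real, fabricate(real, cfgT)),
                      error = function(e)
                        stop("trial ", t, ": ", conditionMessage(e),
                             call. = FALSE))
    ds <- if (featurization == "digit_frequency")
      digitFrequencies(mixed, spec) else mixed
    halves <- splitTrainTest(ds, seed = seedT + .SEED_SPLIT)
    yTest <- sampleLabels(halves$test)
    for (fam in names(grids)) {
      fit <- tryCatch(
        fitWithGridSearch(halves$train, grids[[fam]], cvFolds,
                          seed = seedT + .SEED_CV),
        error = function(e)
          stop("trial ", t, ", family ", fam, ": ", conditionMessage(e),
               call. = FALSE))
      pred <- predictLabels(fit, halves$test)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        trial = t, family = fam, featurization = featurization,
        fabrication = fabCfg@method,
        accuracy = accuracyScore(pred, yTest),
        f1 = f1Score(pred, yTest),
        params = as.character(jsonlite::toJSON(fit$params,
                                               auto_unbox = TRUE)),
        seed = seedT, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  new("BenchmarkResult", trials = trials,
      aggregates = aggregateTrials(trials))
}

# Per-family mean/sd/standard error over trials.
aggregateTrials <- function(trials) {
  agg <- do.call(rbind, lapply(split(trials, trials$family), function(d) {
    n <- nrow(d)
    data.frame(
      family = d$family[1], n_trials = n,
      mean_accuracy = mean(d$accuracy),
      sd_accuracy = stats::sd(d$accuracy),
      se_accuracy = stats::sd(d$accuracy) / sqrt(n),
      mean_f1 = mean(d$f1), sd_f1 = stats::sd(d$f1),
      se_f1 = stats::sd(d$f1) / sqrt(n), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}
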