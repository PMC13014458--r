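# The ensemble regression surrogate: nested-CV tuning, Monte-Carlo outer
# evaluation, and prediction with tree-spread uncertainty.

#' Random-forest hyperparameter grid
#'
#' The grid searched by the inner cross-validation loop. Defaults: 400 or
#' 500 trees; maximum depth 10, 20, 30 or 50; minimum node size 10, 20 or
#' 30. The number of descriptors considered per split is always
#' `floor(sqrt(n_features))`, promoting diversity among trees. No pruning,
#' leaf-count restriction or sample weighting is applied.
#'
#' `minSamplesSplit` controls the granularity at which trees stop splitting;
#' it is realised as \pkg{ranger}'s `min.node.size`.
#'
#' @param nEstimators integer set of ensemble sizes.
#' @param maxDepth integer set of maximum tree depths.
#' @param minSamplesSplit integer set of minimum node sizes.
#' @return a list of class `TuningGrid`.
#' @export
tuningGrid <- function(nEstimators = c(400L, 500L),
                       maxDepth = c(10L, 20L, 30L, 50L),
                       minSamplesSplit = c(10L, 20L, 30L)) {
  stopifnot(length(nEstimators) > 0, length(maxDepth) > 0,
            length(minSamplesSplit) > 0)
  structure(list(nEstimators = sort(as.integer(nEstimators)),
                 maxDepth = sort(as.integer(maxDepth)),
                 minSamplesSplit = sort(as.integer(minSamplesSplit))),
            class = "TuningGrid")
}

# Grid points in deterministic search order: nEstimators, then maxDepth,
# then minSamplesSplit, each ascending.
.gridPoints <- function(grid) {
  pts <- expand.grid(min_samples_split = grid$minSamplesSplit,
                     max_depth = grid$maxDepth,
                     n_estimators = grid$nEstimators)
  pts[order(pts$n_estimators, pts$max_depth, pts$min_samples_split),
      c("n_estimators", "max_depth", "min_samples_split"), drop = FALSE]
}

.fitForest <- function(x, y, nTrees, maxDepth, minNode, seed) {
  ranger::ranger(y = y, x = x, num.trees = nTrees,
                 mtry = max(1L, floor(sqrt(ncol(x)))),
                 max.depth = maxDepth, min.node.size = minNode,
                 seed = as.integer(seed), num.threads = 1L)
}

.trainTargets <- function(train) {
  y <- moleculeScores(train)
  bad <- names(y)[!is.finite(y)]
  if (length(bad))
    stop("non-finite training targets for ids: ",
         paste(head(bad, 10), collapse = ", "))
  y
}

#' Tune hyperparameters and fit the surrogate
#'
#' Runs a k-fold inner cross-validated grid search minimising mean CV mean
#' squared error, then refits a single ensemble on the full training set with
#' the winning hyperparameters. Ties are resolved to the first point in
#' deterministic grid order (ascending `n_estimators`, `max_depth`,
#' `min_samples_split`). A grid collapsed to one point skips the search
#' entirely.
#'
#' @param train a scored [MoleculePool-class] (all scores valid and finite).
#' @param grid a [tuningGrid()].
#' @param innerFolds number of inner CV folds (default 5).
#' @param seed integer seed controlling fold assignment and forest growth.
#' @return a [SurrogateModel-class].
#' @export
tuneAndTrain <- function(train, grid = tuningGrid(), innerFolds = 5L,
                         seed = 1L) {
  stopifnot(is(train, "MoleculePool"), inherits(grid, "TuningGrid"))
  x <- descriptorMatrix(train)
  y <- .trainTargets(train)
  n <- length(y)
  if (n < innerFolds)
    stop(sprintf("need at least %d training molecules for %d-fold inner CV",
                 innerFolds, innerFolds))
  pts <- .gridPoints(grid)
  tuningTable <- data.frame()
  if (nrow(pts) == 1L) {
    best <- pts[1L, ]
  } else {
    folds <- withSeed(streamSeed(seed, "innerfolds"),
                      sample(rep(seq_len(innerFolds), length.out = n)))
    mseMean <- numeric(nrow(pts))
    for (g in seq_len(nrow(pts))) {
      mseFold <- numeric(innerFolds)
      for (f in seq_len(innerFolds)) {
        hold <- folds == f
        fit <- .fitForest(x[!hold, , drop = FALSE], y[!hold],
                          pts$n_estimators[g], pts$max_depth[g],
                          pts$min_samples_split[g],
                          streamSeed(seed, sprintf("inner_%d_%d", g, f)))
        pred <- predict(fit, x[hold, , drop = FALSE],
                        num.threads = 1L)$predictions
        mseFold[f] <- mean((pred - y[hold])^2)
      }
      mseMean[g] <- mean(mseFold)
    }
    tuningTable <- cbind(pts, inner_cv_mse = mseMean)
    rownames(tuningTable) <- NULL
    best <- pts[which.min(mseMean), ]  # which.min takes the first minimum
  }
  fit <- .fitForest(x, y, best$n_estimators, best$max_depth,
                    best$min_samples_split, streamSeed(seed, "refit"))
  new("SurrogateModel", fit = fit,
      hyperparams = list(n_estimators = best$n_estimators,
                         max_depth = best$max_depth,
                         min_samples_split = best$min_samples_split,
                         mtry = max(1L, floor(sqrt(ncol(x))))),
      featureNames = colnames(x),
      trainSize = n,
      trainHash = digest::digest(list(poolIds(train), unname(y))),
      tuningTable = tuningTable)
}

#' Monte-Carlo outer cross-validated performance
#'
#' Repeatedly (default 50 times) splits the training data into random
#' 70:30 train/test partitions, tunes and fits the surrogate on the 70%
#' ([tuneAndTrain()]), and evaluates on the held-back 30% with
#' [computeMetrics()]. Reported as a distribution of outer-fold metric
#' reports and their means. This is a reporting tool: the model used for
#' acquisition is always a full-data refit.
#'
#' @param train a scored [MoleculePool-class].
#' @param grid a [tuningGrid()].
#' @param nResamples number of Monte-Carlo resamples.
#' @param trainFrac fraction used for training in each resample.
#' @param innerFolds inner CV folds passed to [tuneAndTrain()].
#' @param seed integer seed.
#' @return list with `perResample` (data.frame of per-resample metrics) and
#'   `mean` (named numeric; Pearson R averaged over the resamples where it is
#'   defined, `NA` if never).
#' @export
mccvEvaluate <- function(train, grid = tuningGrid(), nResamples = 50L,
                         trainFrac = 0.7, innerFolds = 5L, seed = 1L) {
  stopifnot(is(train, "MoleculePool"), nResamples >= 1)
  n <- poolSize(train)
  nTest <- n - floor(trainFrac * n)
  if (nTest < 2)
    stop("degenerate split: the test fold must hold at least 2 molecules")
  y <- .trainTargets(train)
  rows <- vector("list", nResamples)
  for (r in seq_len(nResamples)) {
    idx <- withSeed(streamSeed(seed, paste0("mccv", r)),
                    sample(n, floor(trainFrac * n)))
    model <- tuneAndTrain(train[idx], grid, innerFolds = innerFolds,
                          seed = streamSeed(seed, paste0("mccvfit", r)))
    pred <- predict(model@fit,
                    descriptorMatrix(train)[-idx, , drop = FALSE],
                    num.threads = 1L)$predictions
    m <- computeMetrics(pred, y[-idx])
    rows[[r]] <- data.frame(resample = r, mse = m$mse, rmse = m$rmse,
                            bias = m$bias, sdep = m$sdep,
                            pearson_r = m$pearson_r, n = m$n)
  }
  perResample <- do.call(rbind, rows)
  means <- c(mse = mean(perResample$mse), rmse = mean(perResample$rmse),
             bias = mean(perResample$bias), sdep = mean(perResample$sdep),
             pearson_r = if (all(is.na(perResample$pearson_r))) NA_real_
                         else mean(perResample$pearson_r, na.rm = TRUE),
             n = mean(perResample$n))
  list(perResample = perResample, mean = means)
}

#' Predict with ensemble uncertainty
#'
#' Per molecule: the per-tree predictions, their arithmetic mean, and the
#' ensemble uncertainty
#' `sigma = sqrt((1/T) * sum_t (yhat_t - yhat_mean)^2)` -- the population
#' standard deviation (divisor T, not T-1) across the T trees of the forest.
#'
#' @param model a [SurrogateModel-class].
#' @param pool a [MoleculePool-class] carrying the model's descriptor
#'   dimensions.
#' @return an [S4Vectors::DataFrame] with columns `id`, `yMean`, `sigma` and
#'   the per-tree prediction matrix `yMembers` (one column per tree).
#' @export
predictWithUncertainty <- function(model, pool) {
  stopifnot(is(model, "SurrogateModel"), is(pool, "MoleculePool"))
  d <- descriptorMatrix(pool)
  missing <- setdiff(model@featureNames, colnames(d))
  if (length(missing))
    stop("pool lacks descriptor dimensions required by the model: ",
         paste(missing, collapse = ", "))
  members <- predict(model@fit, d[, model@featureNames, drop = FALSE],
                     predict.all = TRUE, num.threads = 1L)$predictions
  yMean <- rowMeans(members)
  sigma <- sqrt(rowMeans((members - yMean)^2))
  out <- DataFrame(id = poolIds(pool), yMean = yMean, sigma = sigma)
  out$yMembers <- members
  out
}
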