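# The iterative DMTA driver: predict -> select -> score -> append -> retrain
# -> evaluate.

#' Configure a simulated DMTA run
#'
#' Bundles everything one closed-loop run needs: the initial (scored)
#' training pool, the unscored candidate pool, the oracle, the surrogate
#' tuning grid, the query strategy and the evaluation sets. Iteration-count
#' defaults follow the batch size: 150 iterations at batch 10, 30 at batch
#' 50 (equal numbers of molecules added either way).
#'
#' The retrospective hit set is computed once, from the noise-free,
#' failure-free landscape evaluated on the full candidate pool, unless
#' `hitSet` is supplied (mandatory when `oracle` is a function).
#'
#' @param acquisition an [AcquisitionSpec-class].
#' @param initialTrain scored [MoleculePool-class]; disjoint by id from the
#'   candidate pool.
#' @param candidatePool unscored [MoleculePool-class] available for
#'   selection.
#' @param oracle a [SyntheticLandscape-class], or a function
#'   `function(pool)` returning a score data.frame like [scoreBatch()].
#' @param grid a [tuningGrid()]; collapse it to one point for desk-scale
#'   runs.
#' @param nIterations number of DMTA iterations.
#' @param holdout scored [MoleculePool-class] excluded from selection, used
#'   for generalisation metrics (optional).
#' @param topSubset scored [MoleculePool-class]: the best-scoring subset of
#'   the hold-out set (optional).
#' @param hitSet character vector of hit ids; computed from the landscape if
#'   `NULL`.
#' @param hitFraction fraction defining the hit set (default 1%).
#' @param topK size of the predicted top list compared against the hit set.
#' @param mccvResamples Monte-Carlo outer resamples per iteration (50 for
#'   full fidelity; reduce for desk-scale runs). 0 disables internal MCCV.
#' @param innerFolds inner CV folds for tuning.
#' @param uncertaintyEdges sigma bin edges for the per-iteration
#'   [binUncertainty()] summary.
#' @param seed global run seed; spawns independent named streams for the
#'   oracle, acquisition, surrogate fits and splits. Replicate seeds (see
#'   [runReplicates()]) vary the oracle and acquisition streams only;
#'   ensemble-construction randomness stays keyed to the configuration seed,
#'   so a deterministic strategy with a noise-free, failure-free oracle
#'   replicates identically across run seeds.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(acquisition, initialTrain, candidatePool, oracle,
                      grid = tuningGrid(),
                      nIterations = if (acquisition@batchSize >= 50) 30L
                                    else 150L,
                      holdout = NULL, topSubset = NULL, hitSet = NULL,
                      hitFraction = 0.01, topK = 50L, mccvResamples = 50L,
                      innerFolds = 5L,
                      uncertaintyEdges = c(0.2, 0.4, 0.6, 0.8),
                      seed = 1L) {
  stopifnot(is(acquisition, "AcquisitionSpec"),
            is(initialTrain, "MoleculePool"),
            is(candidatePool, "MoleculePool"))
  if (length(intersect(poolIds(initialTrain), poolIds(candidatePool))))
    stop("initialTrain and candidatePool must be disjoint by id")
  if (!is.null(holdout) &&
      length(intersect(poolIds(holdout), poolIds(candidatePool))))
    stop("holdout must be disjoint from the candidate pool")
  if (is.function(oracle) && is.null(hitSet))
    stop("a function oracle requires an explicit hitSet")
  if (!is.function(oracle) && !is(oracle, "SyntheticLandscape"))
    stop("oracle must be a SyntheticLandscape or a function")
  if (any(is.na(moleculeScores(initialTrain))))
    stop("initialTrain must be fully scored")
  structure(list(acquisition = acquisition, initialTrain = initialTrain,
                 candidatePool = candidatePool, oracle = oracle, grid = grid,
                 nIterations = as.integer(nIterations), holdout = holdout,
                 topSubset = topSubset, hitSet = hitSet,
                 hitFraction = hitFraction, topK = as.integer(topK),
                 mccvResamples = as.integer(mccvResamples),
                 innerFolds = as.integer(innerFolds),
                 uncertaintyEdges = uncertaintyEdges,
                 seed = as.integer(seed),
                 surrogateSeed = as.integer(seed)),
            class = "SimConfig")
}

# Append validly scored molecules (by id) from `batch` to `train`.
.appendScored <- function(train, batch, scores) {
  ok <- !is.na(scores$score)
  if (!any(ok)) return(train)
  add <- batch[scores$id[ok]]
  add@scores <- scores$score[ok]
  new("MoleculePool",
      ids = c(train@ids, add@ids),
      smiles = c(train@smiles, add@smiles),
      descriptors = rbind(train@descriptors, add@descriptors),
      properties = rbind(train@properties, add@properties),
      scores = c(train@scores, add@scores),
      failed = c(train@failed, add@failed))
}

.pficOf <- function(pool) {
  pr <- moleculeProperties(pool)
  setNames(pr$logp + pr$n_aromatic_rings, poolIds(pool))
}

# One iteration's evaluation block: metric rows + uncertainty summaries.
.evaluateIteration <- function(it, model, train, config, poolPred) {
  metricRow <- function(set, m)
    data.frame(iteration = it, set = set,
               metric = c("mse", "rmse", "bias", "sdep", "pearson_r", "n"),
               value = c(m$mse, m$rmse, m$bias, m$sdep, m$pearson_r, m$n))
  rows <- list()
  if (config$mccvResamples > 0) {
    mc <- mccvEvaluate(train, config$grid,
                       nResamples = config$mccvResamples,
                       innerFolds = config$innerFolds,
                       seed = streamSeed(config$surrogateSeed,
                                         paste0("mccv", it)))
    m <- as.list(mc$mean)
    rows$internal <- metricRow("internal", m)
  }
  bins <- data.frame()
  for (set in c("holdout", "top_subset")) {
    ev <- if (set == "holdout") config$holdout else config$topSubset
    if (is.null(ev)) next
    pred <- predictWithUncertainty(model, ev)
    m <- computeMetrics(pred$yMean, unname(moleculeScores(ev)))
    rows[[set]] <- metricRow(set, m)
    if (set == "holdout") {
      b <- binUncertainty(pred$yMean, unname(moleculeScores(ev)),
                          pred$sigma, config$uncertaintyEdges)
      bins <- rbind(bins,
                    data.frame(iteration = it, kind = "sigma_bin",
                               bin = b$bin, n = b$n, value = b$rmse))
    }
  }
  pb <- meanUncertaintyByPrediction(poolPred$yMean, poolPred$sigma)
  bins <- rbind(bins,
                data.frame(iteration = it, kind = "prediction_bin",
                           bin = sprintf("(%.3f,%.3f]", pb$bin_lo, pb$bin_hi),
                           n = pb$n, value = pb$mean_sigma))
  list(metrics = do.call(rbind, unname(rows)), bins = bins)
}

#' Run one simulated DMTA trajectory
#'
#' Iteration t: (1) predict on the remaining candidate pool; (2) select a
#' batch with the configured query strategy; (3) score the batch with the
#' oracle; (4) remove all selected molecules from the pool; (5) append the
#' validly scored ones to the training set (failed evaluations consume their
#' batch slots and are not replaced -- a failed synthesis still spends the
#' slot); (6) retrain the surrogate; (7) evaluate. Iteration 0 records the
#' baseline evaluation of the initial model before any additions.
#'
#' Two runs with identical seed and configuration produce identical
#' trajectories. If the pool runs out before `nIterations`, the trajectory
#' is truncated with a warning.
#'
#' @param config a [simConfig()].
#' @param seed run seed (defaults to `config$seed`).
#' @return a [DmtaTrajectory-class].
#' @export
runOnce <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  seed <- as.integer(seed)
  config$seed <- seed
  spec <- config$acquisition
  pool <- config$candidatePool
  train <- config$initialTrain

  oracleFun <- if (is.function(config$oracle)) config$oracle else {
    land <- config$oracle
    land@seed <- streamSeed(seed, "oracle")
    function(batch) scoreBatch(batch, land)
  }
  hitSet <- config$hitSet
  if (is.null(hitSet)) {
    true <- config$oracle
    true@noiseSd <- 0; true@failureProb <- 0
    hitSet <- defineHitSet(scoreBatch(pool, true), config$hitFraction)
  }

  available <- rep(TRUE, poolSize(pool))
  names(available) <- poolIds(pool)
  needMpo <- grepl("MPO", spec@strategy)
  pfic <- if (needMpo) .pficOf(pool) else NULL

  records <- list(); metrics <- list(); binRows <- list()
  selections <- list(); scoredIds <- character(0)
  initialSize <- poolSize(train)

  fitSeed <- function(it) streamSeed(config$surrogateSeed, paste0("fit", it))
  model <- tuneAndTrain(train, config$grid, innerFolds = config$innerFolds,
                        seed = fitSeed(0L))
  nIter <- config$nIterations
  for (it in 0:nIter) {
    poolPred <- predictWithUncertainty(model, pool)
    ev <- .evaluateIteration(it, model, train, config, poolPred)
    ho <- hitOverlap(poolPred, hitSet, config$topK)
    hp <- model@hyperparams
    records[[it + 1L]] <- data.frame(
      iteration = it, train_size = poolSize(train),
      cumulative_added = poolSize(train) - initialSize,
      n_selected = if (it == 0) 0L else length(selections[[it]]),
      hit_count = ho$count, hit_rate_percent = ho$rate_percent,
      n_estimators = hp$n_estimators, max_depth = hp$max_depth,
      min_samples_split = hp$min_samples_split)
    metrics[[it + 1L]] <- ev$metrics
    binRows[[it + 1L]] <- ev$bins
    if (it == nIter) break

    remainingIds <- names(available)[available]
    if (length(remainingIds) < spec@batchSize) {
      warning(sprintf(
        "candidate pool exhausted after %d iterations (%d remaining)",
        it, length(remainingIds)))
      nIter <- it
      break
    }
    remPred <- poolPred[match(remainingIds, poolPred$id), , drop = FALSE]
    sel <- selectBatch(spec, remPred, pfic,
                       seed = streamSeed(seed, paste0("acq", it + 1L)))
    stopifnot(!any(sel %in% scoredIds))  # never score a molecule twice
    scores <- oracleFun(pool[sel])
    available[sel] <- FALSE
    scoredIds <- c(scoredIds, sel)
    selections[[it + 1L]] <- sel
    train <- .appendScored(train, pool[sel], scores)
    model <- tuneAndTrain(train, config$grid,
                          innerFolds = config$innerFolds,
                          seed = fitSeed(it + 1L))
  }

  cfgSnapshot <- list(strategy = spec@strategy, batchSize = spec@batchSize,
                      poolFraction = if (length(spec@poolFraction))
                        spec@poolFraction else NA_real_,
                      hybridRatio = spec@hybridRatio,
                      nIterations = nIter, topK = config$topK,
                      hitFraction = config$hitFraction,
                      mccvResamples = config$mccvResamples,
                      initialTrainSize = initialSize,
                      poolSize = poolSize(pool))
  new("DmtaTrajectory",
      records = do.call(rbind, records),
      metrics = do.call(rbind, metrics),
      uncertaintyBins = do.call(rbind, binRows),
      selections = selections,
      config = cfgSnapshot,
      seed = seed)
}

#' Run replicate trajectories and aggregate
#'
#' Runs [runOnce()] for each seed and aggregates every scalar per-iteration
#' field (records and metrics) to a mean and standard deviation across
#' seeds. Trajectories of unequal length are aligned on the shortest, with a
#' warning.
#'
#' @param config a [simConfig()].
#' @param seeds integer vector of run seeds.
#' @return list with `perSeed` (list of [DmtaTrajectory-class]) and
#'   `summary` (long data.frame: iteration, set, metric, mean, sd).
#' @export
runReplicates <- function(config, seeds) {
  stopifnot(length(seeds) >= 1)
  perSeed <- lapply(seeds, function(s) runOnce(config, seed = s))
  lens <- vapply(perSeed, function(t) nrow(t@records), integer(1))
  if (length(unique(lens)) > 1) {
    warning("trajectories have unequal lengths; aligning on the shortest")
    keep <- min(lens)
    perSeed <- lapply(perSeed, function(t) {
      t@records <- t@records[seq_len(keep), , drop = FALSE]
      t@metrics <- t@metrics[t@metrics$iteration < keep, , drop = FALSE]
      t
    })
  }
  long <- do.call(rbind, lapply(perSeed, .trajectoryRows))
  agg <- aggregate(value ~ iteration + set + metric, data = long,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  summary <- data.frame(iteration = agg$iteration, set = agg$set,
                        metric = agg$metric,
                        mean = agg$value[, "mean"],
                        sd = ifelse(is.na(agg$value[, "sd"]), 0,
                                    agg$value[, "sd"]))
  summary <- summary[order(summary$iteration, summary$set, summary$metric,
                           method = "radix"), ]
  rownames(summary) <- NULL
  list(perSeed = perSeed, summary = summary)
}
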