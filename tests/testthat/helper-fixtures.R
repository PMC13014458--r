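# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk.

# A pool of n molecules with named standard-normal descriptors.
randomPool <- function(n, p = 6, seed = 1, prefix = "m") {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("d%02d", seq_len(p))))
  moleculePool(sprintf("%s%04d", prefix, seq_len(n)), descriptors = x)
}

# A scored pool whose targets are a fixed linear function of the
# descriptors (optionally noisy): the simplest learnable landscape.
linearScoredPool <- function(n, p = 6, noise = 0, seed = 1, prefix = "m") {
  pool <- randomPool(n, p, seed, prefix)
  x <- descriptorMatrix(pool)
  set.seed(seed + 1)
  pool@scores <- -7 + x[, 1] - 0.5 * x[, 2] + rnorm(n, 0, noise)
  pool
}

# The six-record property table used by the filter tests: four molecules
# pass all five filters (one exactly at every boundary), one exceeds the
# molecular weight budget only, one exceeds the HBD limit only.
sixRecordFilterFixture <- function() {
  props <- data.frame(
    mol_weight       = c(600, 350.0, 600.1, 410.0, 500.0, 250.0),
    n_aromatic_rings = c(3,   2,     1,     0,     2,     1),
    logp             = c(5,   1.5,   0.0,   2.0,   3.0,   -1.0),
    n_hbd            = c(6,   2,     1,     3,     7,     0),
    n_hba            = c(11,  4,     2,     5,     6,     1))
  moleculePool(paste0("f", 1:6), properties = props)
}

# Predictions table in the shape returned by predictWithUncertainty().
predTable <- function(ids, yMean, sigma = rep(0, length(ids))) {
  data.frame(id = ids, yMean = yMean, sigma = sigma,
             stringsAsFactors = FALSE)
}

# A tiny benchmark + config for fast closed-loop tests.
tinySimConfig <- function(strategy = "MU", batchSize = 10L, nIterations = 3L,
                          failureProb = 0, mccvResamples = 0L, seed = 11L,
                          nPool = 250L, nTrain = 60L) {
  bench <- makeShiftedBenchmark(nPool = nPool, nTrain = nTrain,
                                nHoldout = 60L, nTopSubset = 20L,
                                failureProb = failureProb, seed = seed)
  spec <- acquisitionSpec(strategy, batchSize = batchSize)
  simConfig(spec, bench$initialTrain, bench$candidatePool, bench$landscape,
            grid = tuningGrid(100L, 20L, 10L), nIterations = nIterations,
            holdout = bench$holdout, topSubset = bench$topSubset,
            mccvResamples = mccvResamples, seed = seed)
}
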