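test_that("identical seed and config reproduce the trajectory exactly", {
  cfg <- tinySimConfig("RMP", batchSize = 8L, nIterations = 3L,
                       failureProb = 0.2)
  t1 <- runOnce(cfg)
  t2 <- runOnce(cfg)
  expect_identical(t1@records, t2@records)
  expect_identical(t1@selections, t2@selections)
  expect_identical(t1@metrics, t2@metrics)
})

test_that("with no oracle failures the training set grows by batch x iterations", {
  cfg <- tinySimConfig("MP", batchSize = 10L, nIterations = 4L,
                       failureProb = 0)
  traj <- runOnce(cfg)
  rec <- traj@records
  expect_equal(rec$train_size, rec$train_size[1] + 10L * (0:4))
  expect_equal(rec$cumulative_added[nrow(rec)], 40L)
})

test_that("failed oracle evaluations consume slots without replacement", {
  cfg <- tinySimConfig("MU", batchSize = 10L, nIterations = 3L,
                       failureProb = 0.4)
  traj <- runOnce(cfg)
  rec <- traj@records
  # every iteration selects exactly batchSize, but appends only valid scores
  expect_true(all(rec$n_selected[-1] == 10L))
  added <- diff(rec$train_size)
  expect_true(all(added <= 10L))
  expect_lt(sum(added), 30L)  # with failureProb 0.4, some slots must be lost
  # conservation: selections partition out of the candidate pool
  sel <- unlist(traj@selections)
  expect_equal(anyDuplicated(sel), 0L)
  expect_length(sel, 30L)
  expect_true(all(sel %in% poolIds(cfg$candidatePool)))
})

test_that("no molecule is scored twice and the pool shrinks monotonically", {
  cfg <- tinySimConfig("R", batchSize = 12L, nIterations = 4L,
                       failureProb = 0.3)
  traj <- runOnce(cfg)
  sel <- unlist(traj@selections)
  expect_equal(length(sel), length(unique(sel)))
  expect_false(any(sel %in% poolIds(cfg$initialTrain)))
  expect_true(validObject(traj))
})

test_that("zero iterations yields only the baseline evaluation", {
  cfg <- tinySimConfig("MP", nIterations = 0L)
  traj <- runOnce(cfg)
  expect_equal(nrow(traj@records), 1L)
  expect_equal(traj@records$iteration, 0L)
  expect_equal(traj@records$cumulative_added, 0L)
  expect_length(traj@selections, 0L)
})

test_that("an exhausted pool truncates the trajectory with a warning", {
  cfg <- tinySimConfig("MP", batchSize = 40L, nIterations = 10L,
                       nPool = 100L, nTrain = 40L)
  expect_warning(traj <- runOnce(cfg), "exhausted")
  expect_lt(nrow(traj@records), 11L)
})

test_that("replicate aggregation: one seed gives sd 0, means stay in the envelope", {
  cfg <- tinySimConfig("R", batchSize = 6L, nIterations = 2L,
                       failureProb = 0.2)
  one <- runReplicates(cfg, seeds = 42L)
  expect_length(one$perSeed, 1L)
  expect_true(all(one$summary$sd == 0))

  reps <- runReplicates(cfg, seeds = c(1L, 2L, 3L))
  hits <- sapply(reps$perSeed, function(t) t@records$hit_count)
  hitMean <- reps$summary[reps$summary$metric == "hit_count", ]
  expect_equal(hitMean$mean, rowMeans(hits))
  expect_true(all(hitMean$mean >= apply(hits, 1, min) - 1e-12))
  expect_true(all(hitMean$mean <= apply(hits, 1, max) + 1e-12))
})

test_that("deterministic strategy + noise-free oracle replicates identically across seeds", {
  bench <- makeShiftedBenchmark(nPool = 200L, nTrain = 50L, nHoldout = 40L,
                                nTopSubset = 10L, noiseSd = 0,
                                failureProb = 0, seed = 3L)
  cfg <- simConfig(acquisitionSpec("MP", batchSize = 8L),
                   bench$initialTrain, bench$candidatePool, bench$landscape,
                   grid = tuningGrid(60L, 20L, 10L), nIterations = 2L,
                   holdout = bench$holdout, mccvResamples = 0L, seed = 3L)
  reps <- runReplicates(cfg, seeds = c(10L, 20L, 30L))
  hitSd <- reps$summary[reps$summary$metric == "hit_count", "sd"]
  expect_true(all(hitSd == 0))
})

test_that("MPO-based selection uses the pool PFIc values", {
  cfg <- tinySimConfig("MPO", batchSize = 6L, nIterations = 1L,
                       failureProb = 0)
  traj <- runOnce(cfg)
  expect_equal(nrow(traj@records), 2L)
  expect_length(traj@selections[[1]], 6L)
})

test_that("uncertainty summaries are recorded per iteration", {
  cfg <- tinySimConfig("MU", batchSize = 5L, nIterations = 2L)
  traj <- runOnce(cfg)
  ub <- traj@uncertaintyBins
  expect_true(all(c("sigma_bin", "prediction_bin") %in% ub$kind))
  pb <- ub[ub$kind == "prediction_bin" & ub$iteration == 0, ]
  expect_equal(sum(pb$n), poolSize(cfg$candidatePool))
  sb <- ub[ub$kind == "sigma_bin" & ub$iteration == 0, ]
  expect_equal(sum(sb$n), poolSize(cfg$holdout))
})

test_that("config validation catches overlapping pools and unscored training data", {
  bench <- makeShiftedBenchmark(nPool = 100L, nTrain = 30L, nHoldout = 20L,
                                nTopSubset = 5L, seed = 2L)
  spec <- acquisitionSpec("MP", batchSize = 5L)
  expect_error(simConfig(spec, bench$initialTrain, bench$initialTrain,
                         bench$landscape), "disjoint")
  unscored <- bench$initialTrain
  unscored@scores[1] <- NA
  expect_error(simConfig(spec, unscored, bench$candidatePool,
                         bench$landscape), "fully scored")
  expect_error(simConfig(spec, bench$initialTrain, bench$candidatePool,
                         function(p) NULL), "hitSet")
})
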