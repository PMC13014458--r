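test_that("MPO rewards potency and penalises non-drug-like character", {
  expect_equal(scoreMPO(-9, 8), 4.5)          # sigmoid is exactly 1/2 at 8
  expect_equal(scoreMPO(0, 3), 0)             # zero numerator
  expect_equal(scoreMPO(0, 123), 0)
  expect_equal(scoreMPO(-9, 5), 9 / (1 + exp(-3)), tolerance = 1e-12)
  expect_error(scoreMPO(NaN, 1), "finite")
  # monotone: better predicted score or lower PFIc never lowers MPO
  expect_gt(scoreMPO(-10, 6), scoreMPO(-9, 6))
  expect_gt(scoreMPO(-9, 5), scoreMPO(-9, 6))
})

test_that("rankings order by basis with lexicographic id tie-breaks", {
  preds <- predTable(c("a", "b", "c"), c(-9, -7, -8), c(0.5, 0.9, 0.7))
  expect_identical(rankPool(preds, "predicted_score"), c("a", "c", "b"))
  expect_identical(rankPool(preds[1:2, ], "uncertainty"), c("b", "a"))
  tied <- predTable(c("b", "a", "c"), c(-5, -5, -5))
  expect_identical(rankPool(tied, "predicted_score"), c("a", "b", "c"))
  pfic <- c(a = 2, b = 2, c = 2)
  expect_identical(rankPool(preds, "mpo", pfic), c("a", "c", "b"))
  # a high PFIc can demote an otherwise best-scoring molecule
  pfic2 <- c(a = 12, b = 2, c = 2)
  expect_identical(rankPool(preds, "mpo", pfic2)[1], "c")
  expect_error(rankPool(preds, "mpo"), "requires pfic")
  expect_error(rankPool(preds, "mpo", c(a = 1, b = 2)), "missing PFIc.*c")
})

test_that("batches have exact size, no duplicates, and honour determinism", {
  preds <- predTable(sprintf("m%03d", 1:100), seq(-9, -5, length.out = 100),
                     runif(100))
  for (strategy in c("MP", "MU", "R", "RMP", "RMU")) {
    spec <- acquisitionSpec(strategy, batchSize = 10L)
    sel <- selectBatch(spec, preds, seed = 5)
    expect_length(sel, 10L)
    expect_equal(anyDuplicated(sel), 0L)
  }
  # deterministic strategies are rng-independent, bit-for-bit
  mp <- acquisitionSpec("MP", batchSize = 7L)
  expect_identical(selectBatch(mp, preds), selectBatch(mp, preds, seed = 1))
  expect_identical(selectBatch(mp, preds),
                   rankPool(preds, "predicted_score")[1:7])
  # stochastic strategies demand a seed
  expect_error(selectBatch(acquisitionSpec("R", batchSize = 5L), preds),
               "seed")
})

test_that("randomised strategies stay inside their top-fraction window", {
  set.seed(33)
  preds <- predTable(sprintf("m%03d", 1:200), rnorm(200, -7), runif(200))
  spec <- acquisitionSpec("RMP", batchSize = 10L, poolFraction = 0.10)
  window <- rankPool(preds, "predicted_score")[1:ceiling(0.10 * 200)]
  for (s in 1:25) {
    sel <- selectBatch(spec, preds, seed = s)
    expect_true(all(sel %in% window))
  }
  specMU <- acquisitionSpec("RMU", batchSize = 10L, poolFraction = 0.25)
  windowMU <- rankPool(preds, "uncertainty")[1:ceiling(0.25 * 200)]
  for (s in 1:10)
    expect_true(all(selectBatch(specMU, preds, seed = s) %in% windowMU))
  # window smaller than the batch is an error
  tight <- acquisitionSpec("RMP", batchSize = 30L, poolFraction = 0.10)
  expect_error(selectBatch(tight, preds, seed = 1), "window")
})

test_that("a window of exactly the batch size reduces RMP to MP", {
  preds <- predTable(sprintf("m%03d", 1:100), seq(-9, -5, length.out = 100))
  spec <- acquisitionSpec("RMP", batchSize = 10L, poolFraction = 0.10)
  mp <- acquisitionSpec("MP", batchSize = 10L)
  # ceiling(0.10 * 100) = 10 = batch: deterministic without any draw
  expect_identical(selectBatch(spec, preds), selectBatch(mp, preds))
})

test_that("RMP at pool fraction 1 makes the same draws as R", {
  set.seed(8)
  preds <- predTable(sprintf("m%03d", 1:60), rnorm(60, -7), runif(60))
  rmp1 <- acquisitionSpec("RMP", batchSize = 12L, poolFraction = 1)
  r <- acquisitionSpec("R", batchSize = 12L)
  for (s in c(2, 19, 77))
    expect_identical(selectBatch(rmp1, preds, seed = s),
                     selectBatch(r, preds, seed = s))
})

test_that("hybrid quotas are exact for every ratio at batches 10 and 50", {
  set.seed(12)
  n <- 400
  preds <- predTable(sprintf("m%04d", 1:n), rnorm(n, -7), runif(n))
  for (ratio in list(c(8, 2), c(5, 5), c(2, 8))) {
    for (batch in c(10L, 50L)) {
      spec <- acquisitionSpec("MP:MU", batchSize = batch,
                              hybridRatio = ratio)
      quota <- spec@hybridRatio
      expect_equal(sum(quota), batch)            # proportional scaling
      expect_equal(quota / sum(quota), ratio / sum(ratio))
      sel <- selectBatch(spec, preds)
      expect_length(sel, batch)
      expect_equal(anyDuplicated(sel), 0L)
      # first quota comes from the head of the MP ranking ...
      mpRank <- rankPool(preds, "predicted_score")
      expect_identical(sel[seq_len(quota[1])], mpRank[seq_len(quota[1])])
      # ... second quota from the MU ranking head after exclusion
      rest <- preds[!(preds$id %in% sel[seq_len(quota[1])]), ]
      muRank <- rankPool(rest, "uncertainty")
      expect_identical(sel[(quota[1] + 1):batch], muRank[seq_len(quota[2])])
    }
  }
})

test_that("randomised hybrids draw each quota from its own window", {
  set.seed(4)
  n <- 500
  preds <- predTable(sprintf("m%04d", 1:n), rnorm(n, -7), runif(n))
  spec <- acquisitionSpec("RMP:RMU", batchSize = 10L, hybridRatio = c(8, 2),
                          poolFraction = 0.10)
  rmpWindow <- rankPool(preds, "predicted_score")[1:ceiling(0.10 * n)]
  sel <- selectBatch(spec, preds, seed = 31)
  expect_length(sel, 10L)
  first <- sel[1:8]
  expect_true(all(first %in% rmpWindow))
  rest <- preds[!(preds$id %in% first), ]
  rmuWindow <- rankPool(rest, "uncertainty")[1:ceiling(0.10 * nrow(rest))]
  expect_true(all(sel[9:10] %in% rmuWindow))
})

test_that("within-window sampling is uniform (chi-square at 1e4 draws)", {
  preds <- predTable(sprintf("m%03d", 1:200), seq(-9, -5, length.out = 200))
  spec <- acquisitionSpec("RMP", batchSize = 5L, poolFraction = 0.10)
  window <- rankPool(preds, "predicted_score")[1:20]
  counts <- setNames(rep(0L, 20), window)
  nDraws <- 10000L
  for (s in seq_len(nDraws)) {
    sel <- selectBatch(spec, preds, seed = s)
    counts[sel] <- counts[sel] + 1L
  }
  expect_equal(sum(counts), nDraws * 5L)
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("acquisition specs validate their fields", {
  expect_error(acquisitionSpec("XX"), "unknown strategy.*RMP:RMU")
  expect_error(acquisitionSpec("MP:MU", batchSize = 10L), "hybridRatio")
  expect_error(acquisitionSpec("MP:MU", batchSize = 24L,
                               hybridRatio = c(8, 2)),
               "does not scale")
  scaled <- acquisitionSpec("MP:MU", batchSize = 25L, hybridRatio = c(8, 2))
  expect_equal(scaled@hybridRatio, c(20L, 5L))
  expect_error(acquisitionSpec("RMP", poolFraction = 1.2), "poolFraction")
  expect_silent(acquisitionSpec("RMP:RMU", batchSize = 10L,
                                hybridRatio = c(5, 5)))
})
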