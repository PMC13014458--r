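# Reference synthetic study conditions: a broad candidate pool, a biased
# initial training set, and a bimodal docking-score landscape.

#' Synthetic shifted-distribution benchmark
#'
#' Builds the package's reference study conditions for comparing query
#' strategies: a broad candidate pool, an initial training set drawn from a
#' shifted region of descriptor space, and a bimodal synthetic docking-score
#' landscape whose shallower well sits under the training region while a
#' deeper well hides in a part of descriptor space the training set never
#' saw. This emulates the regime of real projects whose starting data come
#' from known chemical matter that is narrower than (and offset from) the
#' generated candidate space -- the regime in which explorative selection
#' outperforms greedy selection.
#'
#' Descriptors are standard-normal in the pool; the first `nActive`
#' dimensions carry the landscape signal through their sum `u`. The score
#' surface is
#' `-7.0 - 1.2 exp(-(u - 4)^2 / (2 * 1.5^2)) - 2.8 exp(-(u + 4)^2 / (2 * 1.5^2))`
#' (kcal/mol) plus Gaussian observation noise, which places scores in the
#' familiar docking range of roughly -10 to -7 kcal/mol. The training set's
#' active dimensions are drawn at mean `trainShift` (default +1.0, sd 0.8),
#' putting it on the shoulder of the shallow well at `u = +4`; the deep well
#' at `u = -4` is populated only by the pool. Molecules also receive
#' synthetic filter properties (molecular weight, rings, log P, HBD/HBA) so
#' property-aware strategies (MPO) and filters are exercisable.
#'
#' Defaults mirror a desk-scale version of a realistic campaign: a 5,000
#' molecule pool, 1,054 initial training molecules, a 500-molecule docked
#' hold-out set whose best `nTopSubset` true scores form the
#' "top-performing" subset, observation noise of 0.15 kcal/mol and a 0.3393
#' oracle failure rate.
#'
#' @param nPool candidate-pool size.
#' @param nTrain initial training-set size.
#' @param nHoldout hold-out set size (docked up-front; oracle failures are
#'   dropped from it).
#' @param nTopSubset size of the top-performing hold-out subset.
#' @param nDescriptors descriptor dimensionality.
#' @param nActive number of signal-carrying dimensions.
#' @param trainShift mean of the training set's active dimensions.
#' @param trainSd standard deviation of the training set's active dimensions.
#' @param noiseSd oracle observation noise, kcal/mol.
#' @param failureProb oracle failure probability.
#' @param seed integer seed.
#' @return list with `candidatePool`, `initialTrain`, `holdout`, `topSubset`
#'   (all [MoleculePool-class]) and `landscape`
#'   ([SyntheticLandscape-class]).
#' @export
makeShiftedBenchmark <- function(nPool = 5000L, nTrain = 1054L,
                                 nHoldout = 500L, nTopSubset = 100L,
                                 nDescriptors = 16L, nActive = 4L,
                                 trainShift = 1.0, trainSd = 0.8,
                                 noiseSd = 0.15, failureProb = 0.3393,
                                 seed = 1L) {
  stopifnot(nActive <= nDescriptors)
  dims <- sprintf("d%02d", seq_len(nDescriptors))
  mkDescriptors <- function(n, shifted, streamName) {
    withSeed(streamSeed(seed, streamName), {
      x <- matrix(rnorm(n * nDescriptors), n, nDescriptors,
                  dimnames = list(NULL, dims))
      if (shifted)
        x[, seq_len(nActive)] <- matrix(
          rnorm(n * nActive, trainShift, trainSd), n, nActive)
      x
    })
  }
  mkProperties <- function(n, streamName) {
    withSeed(streamSeed(seed, streamName), data.frame(
      mol_weight = runif(n, 250, 550),
      n_aromatic_rings = sample(0:3, n, replace = TRUE),
      logp = pmin(pmax(rnorm(n, 2.5, 1.2), -2), 7),
      n_hbd = sample(0:5, n, replace = TRUE),
      n_hba = sample(1:10, n, replace = TRUE)))
  }
  mkPool <- function(n, prefix, shifted) {
    moleculePool(sprintf("%s_%05d", prefix, seq_len(n)),
                 descriptors = mkDescriptors(n, shifted, paste0("x_", prefix)),
                 properties = mkProperties(n, paste0("p_", prefix)))
  }
  weights <- setNames(c(rep(1, nActive), rep(0, nDescriptors - nActive)),
                      dims)
  weights <- weights[weights != 0]
  landscape <- syntheticLandscape(
    weights = weights, bias = 0, nonlinearity = "double_well",
    nlParams = list(center = -7.0, depth1 = 1.2, c1 = 4, s1 = 1.5,
                    depth2 = 2.8, c2 = -4, s2 = 1.5),
    noiseSd = noiseSd, failureProb = failureProb,
    seed = streamSeed(seed, "oracle"))

  candidatePool <- mkPool(nPool, "pool", shifted = FALSE)
  initialTrain <- mkPool(nTrain, "train", shifted = TRUE)
  holdout <- mkPool(nHoldout, "hold", shifted = FALSE)

  # the initial training set arrives fully scored (projects start from
  # molecules whose measurements succeeded): no failures, noise retained
  trainLand <- landscape
  trainLand@failureProb <- 0
  initialTrain@scores <- scoreBatch(initialTrain, trainLand)$score

  # the hold-out set is docked up-front; failures are dropped
  hs <- scoreBatch(holdout, landscape)
  holdout <- holdout[!hs$failed]
  holdout@scores <- hs$score[!hs$failed]
  topIds <- defineHitSet(hs[!hs$failed, ],
                         fraction = min(1, nTopSubset / poolSize(holdout)))
  topSubset <- holdout[topIds]

  list(candidatePool = candidatePool, initialTrain = initialTrain,
       holdout = holdout, topSubset = topSubset, landscape = landscape)
}
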