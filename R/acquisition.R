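# Query strategies: greedy, uncertainty, MPO, randomised-window and hybrid
# batch selection.

#' Construct an AcquisitionSpec
#'
#' @param strategy strategy code: `R`, `MP`, `MPO`, `MU`, `RMP`, `RMPO`,
#'   `RMU`, `MP:MU` or `RMP:RMU` (see [AcquisitionSpec-class]).
#' @param batchSize molecules selected per iteration (commonly 10 or 50).
#' @param poolFraction window fraction for randomised strategies (default
#'   0.10 where applicable).
#' @param hybridRatio integer pair for hybrid strategies, e.g. `c(8, 2)`.
#'   Ratios quoted for batch 10 are scaled proportionally to other batch
#'   sizes (8:2 at batch 50 becomes 40:10); the scaled pair must be integral.
#' @param seed integer seed for stochastic strategies (may be omitted and
#'   supplied at selection time instead).
#' @return an [AcquisitionSpec-class].
#' @export
#' @examples
#' acquisitionSpec("MU", batchSize = 50)
#' acquisitionSpec("MP:MU", batchSize = 50, hybridRatio = c(8, 2))
acquisitionSpec <- function(strategy, batchSize = 10L, poolFraction = NULL,
                            hybridRatio = NULL, seed = NA_integer_) {
  strategy <- as.character(strategy)
  if (!strategy %in% .STRATEGIES)
    stop("unknown strategy '", strategy, "'; valid abbreviations: ",
         paste(.STRATEGIES, collapse = ", "))
  batchSize <- as.integer(batchSize)
  if (strategy %in% .HYBRID_STRATEGIES) {
    if (is.null(hybridRatio))
      stop("hybrid strategy ", strategy, " requires hybridRatio")
    hybridRatio <- as.integer(hybridRatio)
    if (sum(hybridRatio) != batchSize) {
      scale <- batchSize / sum(hybridRatio)
      scaled <- hybridRatio * scale
      if (any(scaled != round(scaled)))
        stop("hybridRatio ", paste(hybridRatio, collapse = ":"),
             " does not scale to an integer split of batch ", batchSize)
      hybridRatio <- as.integer(round(scaled))
    }
  } else hybridRatio <- integer(0)
  if (strategy %in% .RANDOM_WINDOW_STRATEGIES) {
    if (is.null(poolFraction)) poolFraction <- 0.10
  } else poolFraction <- numeric(0)
  new("AcquisitionSpec", strategy = strategy, batchSize = batchSize,
      poolFraction = as.numeric(poolFraction), hybridRatio = hybridRatio,
      seed = as.integer(seed))
}

#' Multiparameter-optimisation acquisition score
#'
#' Rewards a strong predicted docking score while penalising non-drug-like
#' character: `MPO = -P / (1 + exp(PFIc - 8))`, where `P` is the predicted
#' docking score (kcal/mol, negative = good) and PFIc the computed Property
#' Forecast Index of the molecule. Higher MPO is better; the sigmoid halves
#' the reward at PFIc = 8 and suppresses it beyond.
#'
#' @param pm predicted docking score(s), kcal/mol.
#' @param pfic computed Property Forecast Index value(s).
#' @return the MPO score, vectorised.
#' @export
#' @examples
#' scoreMPO(-9, 8)  # 4.5: the sigmoid is exactly 1/2 at PFIc = 8
scoreMPO <- function(pm, pfic) {
  if (any(!is.finite(pm)) || any(!is.finite(pfic)))
    stop("scoreMPO: inputs must be finite")
  -pm / (1 + exp(pfic - 8))
}

#' Rank a prediction pool under an acquisition basis
#'
#' Orders molecule ids by the requested basis: `"predicted_score"` ascending
#' (most negative predicted docking score first), `"mpo"` descending MPO, or
#' `"uncertainty"` descending ensemble sigma. Ties are broken by id in
#' lexicographic (C-locale) order, making rankings stable and reproducible.
#'
#' @param predictions a data.frame/DataFrame with columns `id`, `yMean`,
#'   `sigma` (as from [predictWithUncertainty()]).
#' @param basis `"predicted_score"`, `"mpo"` or `"uncertainty"`.
#' @param pfic named numeric vector of PFIc values (required for `"mpo"`).
#' @return character vector of ids, best first.
#' @export
rankPool <- function(predictions,
                     basis = c("predicted_score", "mpo", "uncertainty"),
                     pfic = NULL) {
  basis <- match.arg(basis)
  ids <- as.character(predictions$id)
  value <- switch(basis,
    predicted_score = predictions$yMean,
    uncertainty = -predictions$sigma,
    mpo = {
      if (is.null(pfic)) stop("basis 'mpo' requires pfic values")
      v <- pfic[ids]
      if (anyNA(v))
        stop("missing PFIc for ids: ",
             paste(head(ids[is.na(v)], 10), collapse = ", "))
      -scoreMPO(predictions$yMean, v)
    })
  if (anyNA(value))
    stop("missing ", basis, " values for ids: ",
         paste(head(ids[is.na(value)], 10), collapse = ", "))
  ids[order(value, ids, method = "radix")]
}

# Map a strategy code to its single-component pieces.
.componentBasis <- function(code) {
  switch(code,
    MP = "predicted_score", RMP = "predicted_score",
    MPO = "mpo", RMPO = "mpo",
    MU = "uncertainty", RMU = "uncertainty",
    R = NA_character_,
    stop("unknown component code: ", code))
}

# Select `k` ids for one component strategy from `predictions`.
# Stochastic draws sample from id-sorted candidate sets, so strategies that
# share a window (e.g. R and RMP at fraction 1) make identical draws under a
# shared RNG stream.
.selectComponent <- function(code, k, predictions, pfic, fraction, hasRng) {
  if (k == 0L) return(character(0))
  ids <- as.character(predictions$id)
  if (length(ids) < k)
    stop("pool (", length(ids), ") smaller than requested batch (", k, ")")
  if (code == "R") {
    if (!hasRng) stop("strategy R requires a random seed")
    return(sample(sort(ids, method = "radix"), k))
  }
  ranking <- rankPool(predictions, .componentBasis(code), pfic)
  if (code %in% c("MP", "MPO", "MU")) return(ranking[seq_len(k)])
  # randomised-window strategies
  window <- ranking[seq_len(ceiling(fraction * length(ranking)))]
  if (length(window) < k)
    stop(sprintf(
      "top-fraction window (%d) smaller than the %d molecules requested",
      length(window), k))
  if (length(window) == k) return(window)  # sampling k from k: deterministic
  if (!hasRng) stop("strategy ", code, " requires a random seed")
  sample(sort(window, method = "radix"), k)
}

#' Select a batch of molecules under a query strategy
#'
#' Implements every strategy code of [AcquisitionSpec-class]. Randomised
#' strategies draw uniformly without replacement from the top
#' `ceiling(poolFraction * poolsize)` window of the relevant ranking; at
#' `poolFraction = 1` they coincide with purely random selection. Hybrids
#' fill the first component's quota, remove those molecules, then fill the
#' second quota from the remaining pool (windows are recomputed on the
#' reduced pool). The returned ids preserve selection order and never
#' contain duplicates.
#'
#' @param spec an [AcquisitionSpec-class].
#' @param predictions predictions covering the candidate pool (see
#'   [rankPool()]).
#' @param pfic named PFIc vector, required by MPO-based strategies.
#' @param seed seed for stochastic strategies; defaults to `spec@seed`.
#' @return character vector of `spec@batchSize` selected ids.
#' @export
selectBatch <- function(spec, predictions, pfic = NULL, seed = NULL) {
  stopifnot(is(spec, "AcquisitionSpec"))
  if (is.null(seed) && !is.na(spec@seed)) seed <- spec@seed
  hasRng <- !is.null(seed)
  parts <- strsplit(spec@strategy, ":", fixed = TRUE)[[1]]
  quotas <- if (length(parts) == 2) spec@hybridRatio else spec@batchSize
  fraction <- if (length(spec@poolFraction)) spec@poolFraction else NA_real_
  doSelect <- function() {
    selected <- character(0)
    remaining <- predictions
    for (p in seq_along(parts)) {
      picks <- .selectComponent(parts[p], quotas[p], remaining, pfic,
                                fraction, hasRng)
      selected <- c(selected, picks)
      remaining <- remaining[!(as.character(remaining$id) %in% picks), ,
                             drop = FALSE]
    }
    selected
  }
  if (hasRng) withSeed(seed, doSelect()) else doSelect()
}
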