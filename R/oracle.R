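# The "Test" stage: synthetic docking-score landscape, score-table replay,
# and hit-set definition.

#' Construct a synthetic docking-score landscape
#'
#' The landscape scores a molecule with descriptor vector x as
#' `g(w . x + bias) + Normal(0, noiseSd)`, or fails with probability
#' `failureProb`. Available transforms `g`:
#' \describe{
#'   \item{identity}{`g(u) = u`.}
#'   \item{tanh}{mildly saturating: `g(u) = center + span * tanh((u - u0) / scale)`
#'     with `nlParams = list(center, span, u0, scale)`.}
#'   \item{double_well}{a bimodal affinity surface:
#'     `g(u) = center - depth1 * exp(-(u - c1)^2 / (2 s1^2))
#'                    - depth2 * exp(-(u - c2)^2 / (2 s2^2))` with
#'     `nlParams = list(center, depth1, c1, s1, depth2, c2, s2)`. Two score
#'     "wells" of different depths let a biased training set sit on a local
#'     optimum while a deeper optimum hides elsewhere in descriptor space --
#'     the regime in which explorative selection pays off.}
#' }
#'
#' Noise and failure are keyed per `(seed, id)`, so scoring is independent of
#' batch composition and evaluation order, and re-scoring a molecule always
#' reproduces the same outcome. With `noiseSd = 0` and `failureProb = 0` the
#' oracle is a deterministic function of the descriptors.
#'
#' @param weights named numeric vector over descriptor dimensions.
#' @param bias offset added to the linear term (kcal/mol scale).
#' @param nonlinearity `"identity"`, `"tanh"` or `"double_well"`.
#' @param nlParams parameter list for the transform.
#' @param noiseSd observation noise standard deviation (kcal/mol).
#' @param failureProb probability a molecule fails to score; the default
#'   0.3393 matches the empirical failure rate of a large docking campaign
#'   (97,289 valid of 147,248 attempted).
#' @param seed integer keying the per-molecule streams.
#' @return a [SyntheticLandscape-class].
#' @export
syntheticLandscape <- function(weights, bias = 0,
                               nonlinearity = c("identity", "tanh",
                                                "double_well"),
                               nlParams = list(), noiseSd = 0,
                               failureProb = 0.3393, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  new("SyntheticLandscape", weights = weights, bias = bias,
      nonlinearity = nonlinearity, nlParams = nlParams,
      noiseSd = noiseSd, failureProb = failureProb, seed = as.integer(seed))
}

.applyNonlinearity <- function(u, nonlinearity, p) {
  switch(nonlinearity,
    identity = u,
    tanh = (p$center %||% 0) + (p$span %||% 1) *
      tanh((u - (p$u0 %||% 0)) / (p$scale %||% 1)),
    double_well = (p$center %||% 0) -
      (p$depth1 %||% 1) * exp(-(u - (p$c1 %||% 0))^2 / (2 * (p$s1 %||% 1)^2)) -
      (p$depth2 %||% 1) * exp(-(u - (p$c2 %||% 0))^2 / (2 * (p$s2 %||% 1)^2)),
    stop("unknown nonlinearity: ", nonlinearity))
}

# Deterministic part of the landscape for a descriptor matrix.
.landscapeMean <- function(landscape, descriptors) {
  w <- landscape@weights
  missing <- setdiff(names(w), colnames(descriptors))
  if (length(missing))
    stop("landscape dimensions absent from pool descriptors: ",
         paste(missing, collapse = ", "))
  u <- drop(descriptors[, names(w), drop = FALSE] %*% w) + landscape@bias
  .applyNonlinearity(u, landscape@nonlinearity, landscape@nlParams)
}

#' Score a batch of molecules with a synthetic landscape
#'
#' Each molecule receives `g(w . x + bias)` plus a keyed Gaussian noise draw,
#' or a failure marker with probability `failureProb`. Outcomes depend only
#' on `(landscape seed, molecule id)`, never on batch order.
#'
#' @param pool a [MoleculePool-class] whose descriptors cover the landscape's
#'   weighted dimensions.
#' @param landscape a [SyntheticLandscape-class].
#' @return data.frame with columns `id`, `score` (`NA` when failed), `failed`
#'   and `source = "synthetic"`.
#' @export
scoreBatch <- function(pool, landscape) {
  stopifnot(is(pool, "MoleculePool"), is(landscape, "SyntheticLandscape"))
  mu <- .landscapeMean(landscape, descriptorMatrix(pool))
  ids <- poolIds(pool)
  if (landscape@noiseSd > 0 || landscape@failureProb > 0) {
    draws <- keyedDraws(landscape@seed, ids)
    failed <- draws$u < landscape@failureProb
    score <- mu + landscape@noiseSd * draws$z
  } else {
    failed <- rep(FALSE, length(ids))
    score <- mu
  }
  score[failed] <- NA_real_
  data.frame(id = ids, score = score, failed = failed,
             source = "synthetic", stringsAsFactors = FALSE)
}

#' Replay scores from a user-supplied table
#'
#' Molecules present in the table receive its score; absent molecules get a
#' failure marker. Supports running the simulator against real docking
#' outputs instead of the synthetic landscape.
#'
#' @param pool a [MoleculePool-class].
#' @param scoreTable data.frame with columns `id` and `score` (e.g. from
#'   [loadScoreTable()]).
#' @return data.frame with columns `id`, `score`, `failed`,
#'   `source = "table"`.
#' @export
replayScores <- function(pool, scoreTable) {
  stopifnot(is(pool, "MoleculePool"),
            all(c("id", "score") %in% names(scoreTable)))
  dup <- unique(scoreTable$id[duplicated(scoreTable$id)])
  if (length(dup))
    stop("duplicate ids in score table: ", paste(dup, collapse = ", "))
  idx <- match(poolIds(pool), scoreTable$id)
  score <- scoreTable$score[idx]
  data.frame(id = poolIds(pool), score = score, failed = is.na(idx),
             source = "table", stringsAsFactors = FALSE)
}

#' Load a score table from CSV
#'
#' @param path CSV file with header `id,score`.
#' @return data.frame with character `id` and numeric `score`.
#' @export
loadScoreTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "score") %in% names(tab)))
    stop("score table must have columns id,score")
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(is.na(score) & nzchar(tab$score))
  if (length(bad))
    stop("non-numeric score values at rows: ", paste(bad, collapse = ", "))
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicate ids in score table: ", paste(dup, collapse = ", "))
  data.frame(id = tab$id, score = score, stringsAsFactors = FALSE)
}

#' Define the retrospective hit set
#'
#' A hit is a molecule whose true score lies within the best `fraction`
#' (default top 1%) of all validly scored molecules. The hit-set size is
#' `fraction * N_valid` rounded half-up to the nearest integer (97,289 valid
#' scores at 1% gives 973). Failed evaluations are excluded from `N_valid`.
#' Ties at the cutoff are broken by id order, and the result is invariant to
#' the input ordering.
#'
#' @param scores data.frame with columns `id` and `score` (`NA` = failed), as
#'   returned by [scoreBatch()] or [replayScores()].
#' @param fraction fraction of valid scores counted as hits, in (0, 1].
#' @return character vector of hit ids (best = most negative scores).
#' @export
defineHitSet <- function(scores, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  valid <- scores[!is.na(scores$score), , drop = FALSE]
  if (!nrow(valid)) stop("no valid scores: cannot define a hit set")
  k <- as.integer(floor(fraction * nrow(valid) + 0.5))  # round half-up
  k <- max(k, 0L)
  if (k == 0L) return(character(0))
  ord <- order(valid$score, valid$id, method = "radix")
  valid$id[ord[seq_len(k)]]
}
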