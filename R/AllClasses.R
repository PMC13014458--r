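#' MoleculePool: a set of candidate molecules with descriptors
#'
#' The central container of the package. A pool holds molecule identities,
#' optional SMILES structure strings, a numeric descriptor matrix (one row per
#' molecule, named columns shared by the whole pool), a property table used by
#' the drug-likeness filters (molecular weight, aromatic ring count, computed
#' log10 P, hydrogen-bond donors/acceptors) and, when known, oracle scores.
#'
#' Scores follow the docking convention: kcal/mol, more negative = better.
#' `NA` in the `scores` slot means "not scored"; a molecule that was sent to
#' the oracle but failed is recorded in `failed`.
#'
#' @slot ids character vector of unique molecule identifiers.
#' @slot smiles character vector of structure strings (`NA` for purely
#'   synthetic descriptor records).
#' @slot descriptors numeric matrix, one row per molecule, named columns.
#' @slot properties data.frame with columns `mol_weight`, `n_aromatic_rings`,
#'   `logp`, `n_hbd`, `n_hba` (rows parallel to `ids`; `NA` allowed).
#' @slot scores numeric vector of oracle scores (`NA` = unscored/failed).
#' @slot failed logical vector: oracle evaluation attempted but failed.
#'
#' @seealso [moleculePool()], [poolIds()], [descriptorMatrix()]
#' @exportClass MoleculePool
setClass("MoleculePool",
  representation(
    ids = "character",
    smiles = "character",
    descriptors = "matrix",
    properties = "data.frame",
    scores = "numeric",
    failed = "logical"
  )
)

setValidity("MoleculePool", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate molecule ids: %s",
      paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (length(object@smiles) != n) msg <- c(msg, "smiles length != ids length")
  if (nrow(object@descriptors) != n)
    msg <- c(msg, "descriptor matrix rows != ids length")
  if (ncol(object@descriptors) > 0 && is.null(colnames(object@descriptors)))
    msg <- c(msg, "descriptor dimensions must be named")
  if (nrow(object@properties) != n)
    msg <- c(msg, "property table rows != ids length")
  if (length(object@scores) != n) msg <- c(msg, "scores length != ids length")
  if (length(object@failed) != n) msg <- c(msg, "failed length != ids length")
  pr <- object@properties
  for (col in c("n_aromatic_rings", "n_hbd", "n_hba")) {
    if (col %in% names(pr) && any(pr[[col]] < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("%s must be non-negative", col))
  }
  if ("mol_weight" %in% names(pr)) {
    bad <- !is.na(object@smiles) & !is.na(pr$mol_weight) & pr$mol_weight <= 0
    if (any(bad)) msg <- c(msg, "mol_weight must be positive for structures")
  }
  if (length(msg)) msg else TRUE
})

#' FilterSpec: drug-likeness property thresholds
#'
#' Inclusive upper bounds used to remove molecules with less desirable
#' features: molecular weight budget, aromatic ring count, the computed
#' Property Forecast Index (PFIc = log10 P + number of aromatic rings),
#' hydrogen-bond donors and acceptors. A molecule passes a filter iff its
#' value is less than or equal to the threshold.
#'
#' @slot maxMolWeight maximum molecular weight, a.m.u.
#' @slot maxAromaticRings maximum number of aromatic rings.
#' @slot maxPfic maximum PFIc.
#' @slot maxHbd maximum hydrogen-bond donor count.
#' @slot maxHba maximum hydrogen-bond acceptor count.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(
    maxMolWeight = "numeric",
    maxAromaticRings = "numeric",
    maxPfic = "numeric",
    maxHbd = "numeric",
    maxHba = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  v <- c(object@maxMolWeight, object@maxAromaticRings, object@maxPfic,
         object@maxHbd, object@maxHba)
  if (any(!is.finite(v)) || any(v < 0))
    "all thresholds must be finite and non-negative" else TRUE
})

#' SyntheticLandscape: a synthetic docking-score oracle
#'
#' Replaces a physical docking engine with a deterministic scoring surface
#' plus optional observation noise and a calibrated failure rate. The true
#' score of a molecule with descriptor vector x is
#' `g(w . x + b) + Normal(0, noise_sd)`, where g is a named smooth transform
#' of the linear term, or a failure with probability `failureProb`. Noise and
#' failure draws are keyed on `(seed, id)` so results are independent of
#' evaluation order and of how molecules are batched.
#'
#' The default failure probability, 0.3393, matches the observed fraction of
#' docking runs that fail to return a valid score in a large-scale docking
#' campaign (97,289 valid scores out of 147,248 attempts).
#'
#' @slot weights named numeric vector over descriptor dimensions.
#' @slot bias scalar offset added to the linear term before the transform.
#' @slot nonlinearity one of `"identity"`, `"tanh"`, `"double_well"`.
#' @slot nlParams named list of parameters for the transform (see
#'   [syntheticLandscape()]).
#' @slot noiseSd standard deviation of additive observation noise (kcal/mol).
#' @slot failureProb probability that scoring a molecule fails.
#' @slot seed integer seed keying the per-molecule random streams.
#' @exportClass SyntheticLandscape
setClass("SyntheticLandscape",
  representation(
    weights = "numeric",
    bias = "numeric",
    nonlinearity = "character",
    nlParams = "list",
    noiseSd = "numeric",
    failureProb = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticLandscape", function(object) {
  msg <- character(0)
  if (is.null(names(object@weights)) || any(!nzchar(names(object@weights))))
    msg <- c(msg, "weights must be a named vector over descriptor dimensions")
  if (!object@nonlinearity %in% c("identity", "tanh", "double_well"))
    msg <- c(msg, "unknown nonlinearity")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@failureProb < 0 || object@failureProb > 1)
    msg <- c(msg, "failureProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SurrogateModel: a tuned random-forest ensemble surrogate
#'
#' Wraps a fitted \pkg{ranger} forest together with the hyperparameters chosen
#' by the inner cross-validated grid search, the descriptor dimension names it
#' was trained on, and a fingerprint (size + hash) of the training set used
#' for reproducibility bookkeeping.
#'
#' @slot fit the fitted ranger object.
#' @slot hyperparams named list: `n_estimators`, `max_depth`,
#'   `min_samples_split`, `mtry`.
#' @slot featureNames descriptor dimension names the model accepts.
#' @slot trainSize number of training molecules.
#' @slot trainHash digest of the training ids and targets.
#' @slot tuningTable data.frame of grid points and their mean inner-CV MSE
#'   (zero rows when the grid was collapsed to a single point).
#' @exportClass SurrogateModel
setClass("SurrogateModel",
  representation(
    fit = "ANY",
    hyperparams = "list",
    featureNames = "character",
    trainSize = "integer",
    trainHash = "character",
    tuningTable = "data.frame"
  )
)

#' AcquisitionSpec: a query-strategy specification
#'
#' Encodes which rule picks the next batch of molecules. Strategy codes:
#' \describe{
#'   \item{R}{uniform random selection from the whole pool.}
#'   \item{MP}{greedy: best (most negative) predicted docking score.}
#'   \item{MPO}{greedy on the multiparameter-optimisation score
#'     `-P / (1 + exp(PFIc - 8))` (higher is better).}
#'   \item{MU}{explorative: highest ensemble uncertainty.}
#'   \item{RMP, RMPO, RMU}{uniform random selection within the top
#'     `poolFraction` of the corresponding ranking.}
#'   \item{MP:MU, RMP:RMU}{concurrent hybrids: the first component fills its
#'     quota, then the second draws from the remaining pool.}
#' }
#'
#' @slot strategy one of the codes above.
#' @slot batchSize molecules selected per iteration.
#' @slot poolFraction fraction in (0, 1] defining the randomised-selection
#'   window (R* strategies and R*-hybrid components; default 0.10).
#' @slot hybridRatio integer pair summing to `batchSize` (hybrids only).
#' @slot seed integer seed for stochastic strategies (`NA` = caller supplies).
#' @exportClass AcquisitionSpec
setClass("AcquisitionSpec",
  representation(
    strategy = "character",
    batchSize = "integer",
    poolFraction = "numeric",
    hybridRatio = "integer",
    seed = "integer"
  )
)

.STRATEGIES <- c("R", "MP", "MPO", "MU", "RMP", "RMPO", "RMU",
                 "MP:MU", "RMP:RMU")
.RANDOM_WINDOW_STRATEGIES <- c("RMP", "RMPO", "RMU", "RMP:RMU")
.HYBRID_STRATEGIES <- c("MP:MU", "RMP:RMU")

setValidity("AcquisitionSpec", function(object) {
  msg <- character(0)
  if (!object@strategy %in% .STRATEGIES)
    msg <- c(msg, sprintf("unknown strategy '%s'; valid: %s",
                          object@strategy, paste(.STRATEGIES, collapse = ", ")))
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  isHybrid <- object@strategy %in% .HYBRID_STRATEGIES
  if (isHybrid) {
    if (length(object@hybridRatio) != 2 || any(object@hybridRatio < 0))
      msg <- c(msg, "hybrid strategies need a non-negative ratio pair")
    else if (sum(object@hybridRatio) != object@batchSize)
      msg <- c(msg, "hybridRatio must sum to batchSize")
  } else if (length(object@hybridRatio) != 0) {
    msg <- c(msg, "hybridRatio is only meaningful for hybrid strategies")
  }
  needsFraction <- object@strategy %in% .RANDOM_WINDOW_STRATEGIES
  if (needsFraction) {
    if (length(object@poolFraction) != 1 ||
        !is.finite(object@poolFraction) ||
        object@poolFraction <= 0 || object@poolFraction > 1)
      msg <- c(msg, "poolFraction must lie in (0, 1]")
  } else if (length(object@poolFraction) != 0) {
    msg <- c(msg, "poolFraction is only meaningful for RMP/RMPO/RMU/RMP:RMU")
  }
  if (length(msg)) msg else TRUE
})

#' DmtaTrajectory: the record of one simulated DMTA run
#'
#' Per-iteration bookkeeping of a closed-loop run: training-set size, selected
#' ids, oracle outcomes, chosen hyperparameters, metric reports on each
#' evaluation set, top-k hit overlap with the retrospective hit set, and
#' uncertainty summaries. Iteration 0 is the baseline evaluation of the
#' initial model before any additions.
#'
#' @slot records data.frame, one row per iteration (core scalar fields).
#' @slot metrics long data.frame: iteration, set, metric, value.
#' @slot uncertaintyBins long data.frame of per-bin summaries.
#' @slot selections list of character vectors, ids selected at each iteration.
#' @slot config list snapshot of the run configuration.
#' @slot seed the run seed.
#' @exportClass DmtaTrajectory
setClass("DmtaTrajectory",
  representation(
    records = "data.frame",
    metrics = "data.frame",
    uncertaintyBins = "data.frame",
    selections = "list",
    config = "list",
    seed = "integer"
  )
)

setValidity("DmtaTrajectory", function(object) {
  msg <- character(0)
  if (nrow(object@records) > 0 && is.unsorted(object@records$train_size))
    msg <- c(msg, "training-set size must be non-decreasing")
  sel <- unlist(object@selections, use.names = FALSE)
  if (anyDuplicated(sel))
    msg <- c(msg, "a molecule may be selected in at most one iteration")
  if (length(msg)) msg else TRUE
})
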