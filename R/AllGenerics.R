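#' @name pool-accessors
#' @title Accessors for MoleculePool objects
#' @description `poolIds` returns molecule identifiers, `poolSize` the number
#'   of molecules, `descriptorMatrix` the numeric descriptor matrix,
#'   `moleculeProperties` the property table, `moleculeScores` the oracle
#'   scores (`NA` = unscored) and `moleculeSmiles` the structure strings.
#' @param x a [MoleculePool-class] object.
#' @return see description.
#' @aliases poolIds poolSize descriptorMatrix moleculeProperties
#'   moleculeScores moleculeSmiles
NULL

#' @rdname pool-accessors
#' @export
setGeneric("poolIds", function(x) standardGeneric("poolIds"))
#' @rdname pool-accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))
#' @rdname pool-accessors
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))
#' @rdname pool-accessors
#' @export
setGeneric("moleculeProperties",
           function(x) standardGeneric("moleculeProperties"))
#' @rdname pool-accessors
#' @export
setGeneric("moleculeScores", function(x) standardGeneric("moleculeScores"))
#' @rdname pool-accessors
#' @export
setGeneric("moleculeSmiles", function(x) standardGeneric("moleculeSmiles"))

#' @rdname pool-accessors
setMethod("poolIds", "MoleculePool", function(x) x@ids)
#' @rdname pool-accessors
setMethod("poolSize", "MoleculePool", function(x) length(x@ids))
#' @rdname pool-accessors
setMethod("descriptorMatrix", "MoleculePool", function(x) x@descriptors)
#' @rdname pool-accessors
setMethod("moleculeProperties", "MoleculePool", function(x) x@properties)
#' @rdname pool-accessors
setMethod("moleculeScores", "MoleculePool",
          function(x) setNames(x@scores, x@ids))
#' @rdname pool-accessors
setMethod("moleculeSmiles", "MoleculePool",
          function(x) setNames(x@smiles, x@ids))

#' Subset a MoleculePool
#'
#' Pools subset like vectors, by position, logical mask or molecule id.
#'
#' @param x a [MoleculePool-class].
#' @param i index vector (integer, logical or character ids).
#' @param j,drop,... ignored.
#' @return a [MoleculePool-class] with the selected molecules.
#' @export
setMethod("[", "MoleculePool", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@ids)
    if (anyNA(idx))
      stop("unknown molecule ids: ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("MoleculePool",
      ids = x@ids[i],
      smiles = x@smiles[i],
      descriptors = x@descriptors[i, , drop = FALSE],
      properties = x@properties[i, , drop = FALSE],
      scores = x@scores[i],
      failed = x@failed[i])
})

setMethod("show", "MoleculePool", function(object) {
  cat(sprintf("MoleculePool with %d molecules, %d descriptor dimensions\n",
              length(object@ids), ncol(object@descriptors)))
  nScored <- sum(!is.na(object@scores))
  cat(sprintf("  scored: %d valid, %d failed\n", nScored, sum(object@failed)))
  if (length(object@ids))
    cat("  ids: ", paste(head(object@ids, 4), collapse = ", "),
        if (length(object@ids) > 4) ", ..." else "", "\n", sep = "")
})

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec (inclusive upper bounds)\n")
  cat(sprintf("  mol weight <= %g a.m.u; aromatic rings <= %g; PFIc <= %g\n",
              object@maxMolWeight, object@maxAromaticRings, object@maxPfic))
  cat(sprintf("  HBD <= %g; HBA <= %g\n", object@maxHbd, object@maxHba))
})

setMethod("show", "SyntheticLandscape", function(object) {
  cat(sprintf(
    "SyntheticLandscape: %d weighted dims, bias %.3g, transform '%s'\n",
    sum(object@weights != 0), object@bias, object@nonlinearity))
  cat(sprintf("  noise sd %.3g kcal/mol, failure prob %.4f, seed %d\n",
              object@noiseSd, object@failureProb, object@seed))
})

setMethod("show", "SurrogateModel", function(object) {
  hp <- object@hyperparams
  cat(sprintf(
    "SurrogateModel: %d trees, max depth %s, min node %d, mtry %d\n",
    hp$n_estimators, as.character(hp$max_depth), hp$min_samples_split,
    hp$mtry))
  cat(sprintf("  trained on %d molecules x %d descriptors (hash %s)\n",
              object@trainSize, length(object@featureNames),
              substr(object@trainHash, 1, 8)))
})

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf("AcquisitionSpec: strategy %s, batch %d",
              object@strategy, object@batchSize))
  if (length(object@poolFraction))
    cat(sprintf(", pool fraction %.3g", object@poolFraction))
  if (length(object@hybridRatio))
    cat(sprintf(", ratio %d:%d", object@hybridRatio[1], object@hybridRatio[2]))
  cat("\n")
})

setMethod("show", "DmtaTrajectory", function(object) {
  nIter <- nrow(object@records) - 1L
  cat(sprintf("DmtaTrajectory: %d iterations (+ baseline), seed %d\n",
              max(nIter, 0L), object@seed))
  if (nrow(object@records)) {
    last <- object@records[nrow(object@records), ]
    cat(sprintf("  final training size %d, final top-%d hit count %d (%.1f%%)\n",
                last$train_size, object@config$topK %||% 50L,
                last$hit_count, last$hit_rate_percent))
  }
})
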