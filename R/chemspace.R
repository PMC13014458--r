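# Molecule records, drug-likeness filtering and the toy combinatorial
# library generator.

#' Construct a MoleculePool
#'
#' @param ids character vector of unique molecule identifiers.
#' @param smiles optional structure strings (recycled `NA` if absent).
#' @param descriptors numeric matrix (rows = molecules, named columns) or
#'   `NULL` for a zero-column matrix.
#' @param properties data.frame of filter properties; missing columns are
#'   filled with `NA`.
#' @param scores optional numeric oracle scores.
#' @param failed optional logical failure flags.
#' @return a [MoleculePool-class].
#' @export
#' @examples
#' p <- moleculePool(c("m1", "m2"),
#'                   descriptors = matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))))
#' poolSize(p)
moleculePool <- function(ids, smiles = NULL, descriptors = NULL,
                         properties = NULL, scores = NULL, failed = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (is.null(smiles)) smiles <- rep(NA_character_, n)
  if (is.null(descriptors))
    descriptors <- matrix(numeric(0), nrow = n, ncol = 0)
  descriptors <- as.matrix(descriptors)
  storage.mode(descriptors) <- "double"
  propCols <- c("mol_weight", "n_aromatic_rings", "logp", "n_hbd", "n_hba")
  if (is.null(properties)) properties <- data.frame(row.names = seq_len(n))
  for (col in setdiff(propCols, names(properties)))
    properties[[col]] <- NA_real_
  properties <- properties[, propCols, drop = FALSE]
  rownames(properties) <- NULL
  if (is.null(scores)) scores <- rep(NA_real_, n)
  if (is.null(failed)) failed <- rep(FALSE, n)
  new("MoleculePool", ids = ids, smiles = as.character(smiles),
      descriptors = descriptors, properties = properties,
      scores = as.numeric(scores), failed = as.logical(failed))
}

#' Computed Property Forecast Index (PFIc)
#'
#' The Property Forecast Index measures how "fat and flat" a molecule is; the
#' computed variant used here is simply the calculated log10 P plus the number
#' of aromatic rings. Lower values indicate more drug-like character. The
#' log10 P estimator is supplied by the descriptor provider, so any estimator
#' can be injected.
#'
#' @param logp computed log10 P (unitless), finite.
#' @param nAromaticRings non-negative integer count of aromatic rings.
#' @return `logp + nAromaticRings`, vectorised.
#' @export
#' @examples
#' computePFIC(3.0, 3)    # 6
#' computePFIC(-1.25, 2)  # 0.75
computePFIC <- function(logp, nAromaticRings) {
  if (any(!is.finite(logp)))
    stop("computePFIC: logp must be finite")
  if (any(nAromaticRings < 0))
    stop("computePFIC: nAromaticRings must be non-negative")
  logp + nAromaticRings
}

#' Construct a drug-likeness FilterSpec
#'
#' Defaults are the standard relaxed rule-of-five style thresholds used to
#' prune combinatorial libraries: molecular weight <= 600 a.m.u, at most 3
#' aromatic rings, PFIc <= 8, at most 6 hydrogen-bond donors and 11
#' acceptors. All comparisons are inclusive.
#'
#' @param maxMolWeight,maxAromaticRings,maxPfic,maxHbd,maxHba thresholds.
#' @return a [FilterSpec-class].
#' @export
filterSpec <- function(maxMolWeight = 600, maxAromaticRings = 3, maxPfic = 8,
                       maxHbd = 6, maxHba = 11) {
  new("FilterSpec", maxMolWeight = maxMolWeight,
      maxAromaticRings = maxAromaticRings, maxPfic = maxPfic,
      maxHbd = maxHbd, maxHba = maxHba)
}

#' Apply drug-likeness filters to a pool
#'
#' Each molecule is tested against all five inclusive thresholds of the
#' [FilterSpec-class]; survivors keep their input order. Every violated
#' filter is named in the rejection log. A molecule missing a property needed
#' by a filter is rejected with reason `"missing_property"`.
#'
#' Filtering is idempotent: applying the same spec to the survivors changes
#' nothing.
#'
#' @param pool a [MoleculePool-class] with populated properties.
#' @param spec a [FilterSpec-class].
#' @return a list with `survivors` (a [MoleculePool-class]) and `rejections`
#'   (data.frame with columns `id` and `reasons`, a list-column of violated
#'   filter names).
#' @export
applyFilters <- function(pool, spec = filterSpec()) {
  stopifnot(is(pool, "MoleculePool"), is(spec, "FilterSpec"))
  pr <- moleculeProperties(pool)
  pfic <- ifelse(is.finite(pr$logp) & !is.na(pr$n_aromatic_rings),
                 pr$logp + pr$n_aromatic_rings, NA_real_)
  checks <- list(
    molecular_weight = pr$mol_weight <= spec@maxMolWeight,
    aromatic_rings   = pr$n_aromatic_rings <= spec@maxAromaticRings,
    pfic             = pfic <= spec@maxPfic,
    hbd              = pr$n_hbd <= spec@maxHbd,
    hba              = pr$n_hba <= spec@maxHba
  )
  n <- poolSize(pool)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    for (nm in names(checks)) {
      ok <- checks[[nm]][i]
      if (is.na(ok)) r <- c(r, "missing_property")
      else if (!ok) r <- c(r, nm)
    }
    reasons[[i]] <- unique(r)
  }
  keep <- lengths(reasons) == 0
  rejections <- data.frame(id = poolIds(pool)[!keep])
  rejections$reasons <- reasons[!keep]
  list(survivors = pool[keep], rejections = rejections)
}

#' Specify a toy combinatorial R-group library
#'
#' A stand-in for large-scale fragment-based molecule generation: substituent
#' fragments are attached at up to two predefined attachment points of a
#' scaffold, giving mono- (R1 or R2) and di- (R1 and R2) substituted
#' products. The scaffold is written as a SMILES string containing the
#' literal placeholders `{R1}` and `{R2}`; an unused placeholder (and any
#' enclosing empty parentheses) is removed.
#'
#' The default scaffold is 3,5-dimethyl-4-phenylisoxazole, a known
#' bromodomain-binding warhead, with both attachment points on the phenyl
#' ring.
#'
#' @param scaffold SMILES with `{R1}` and `{R2}` placeholders.
#' @param r1Fragments,r2Fragments character vectors of substituent SMILES.
#' @param modes subset of `c("mono_r1", "mono_r2", "di")`.
#' @return a list of class `ToyLibrarySpec`.
#' @export
toyLibrarySpec <- function(scaffold = "Cc1noc(C)c1-c1ccc({R1})cc1{R2}",
                           r1Fragments = character(0),
                           r2Fragments = character(0),
                           modes = c("mono_r1", "mono_r2", "di")) {
  modes <- match.arg(modes, c("mono_r1", "mono_r2", "di"), several.ok = TRUE)
  if (("mono_r1" %in% modes || "di" %in% modes) && !length(r1Fragments))
    stop("r1Fragments must be non-empty for the enabled modes")
  if (("mono_r2" %in% modes || "di" %in% modes) && !length(r2Fragments))
    stop("r2Fragments must be non-empty for the enabled modes")
  if (!grepl("{R1}", scaffold, fixed = TRUE) ||
      !grepl("{R2}", scaffold, fixed = TRUE))
    stop("scaffold must contain both {R1} and {R2} attachment points")
  structure(list(scaffold = scaffold, r1Fragments = r1Fragments,
                 r2Fragments = r2Fragments, modes = modes),
            class = "ToyLibrarySpec")
}

.substituteRGroup <- function(scaffold, slot, fragment) {
  token <- paste0("{", slot, "}")
  if (is.na(fragment)) {
    # unused attachment point: drop the token, and a "(token)" group entirely
    out <- gsub(paste0("(", token, ")"), "", scaffold, fixed = TRUE)
    gsub(token, "", out, fixed = TRUE)
  } else {
    gsub(token, fragment, scaffold, fixed = TRUE)
  }
}

#' Enumerate a toy combinatorial library
#'
#' Produces `|R1|` mono-R1 + `|R2|` mono-R2 + `|R1| x |R2|` di-substituted
#' molecule records for the enabled modes. Identifiers are deterministic
#' functions of the scaffold and fragment indices
#' (`"<scaffoldhash>_<mode>_<i>_<j>"`), so repeated enumerations agree across
#' processes.
#'
#' @param spec a [toyLibrarySpec()].
#' @return a [MoleculePool-class] with SMILES set (descriptors and properties
#'   unset; see [computeDescriptors()]).
#' @export
#' @examples
#' spec <- toyLibrarySpec(r1Fragments = c("C", "O", "N"),
#'                        r2Fragments = c("F", "Cl", "C", "OC"))
#' poolSize(enumerateToyLibrary(spec))  # 3 + 4 + 12 = 19
enumerateToyLibrary <- function(spec) {
  stopifnot(inherits(spec, "ToyLibrarySpec"))
  shash <- sprintf("%08x",
                   abs(digest::digest2int(spec$scaffold)) %% 0xffffffff)
  ids <- character(0); smis <- character(0)
  addRecord <- function(mode, i, j, smi) {
    ids <<- c(ids, sprintf("%s_%s_%d_%d", shash, mode, i, j))
    smis <<- c(smis, smi)
  }
  if ("mono_r1" %in% spec$modes)
    for (i in seq_along(spec$r1Fragments)) {
      smi <- .substituteRGroup(spec$scaffold, "R1", spec$r1Fragments[i])
      addRecord("m1", i, 0L, .substituteRGroup(smi, "R2", NA))
    }
  if ("mono_r2" %in% spec$modes)
    for (j in seq_along(spec$r2Fragments)) {
      smi <- .substituteRGroup(spec$scaffold, "R2", spec$r2Fragments[j])
      addRecord("m2", 0L, j, .substituteRGroup(smi, "R1", NA))
    }
  if ("di" %in% spec$modes)
    for (i in seq_along(spec$r1Fragments))
      for (j in seq_along(spec$r2Fragments)) {
        smi <- .substituteRGroup(spec$scaffold, "R1", spec$r1Fragments[i])
        addRecord("di", i, j, .substituteRGroup(smi, "R2", spec$r2Fragments[j]))
      }
  if (!length(ids)) stop("toy library is empty: no modes enabled")
  moleculePool(ids, smiles = smis)
}

#' Populate descriptor vectors and filter properties
#'
#' Two providers are available. `"synthetic"` passes through descriptor
#' vectors already present on the pool (an error if absent) -- the normal
#' path for simulation studies. `"openbabel"` parses the SMILES with
#' \pkg{ChemmineR}/\pkg{ChemmineOB} and attaches a compact physicochemical
#' 2D descriptor set (molecular weight, log P, TPSA, molar refractivity,
#' H-bond donor/acceptor counts, fluorine count, ring and aromatic-ring
#' counts) together with the filter properties. Molecules whose structure
#' cannot be parsed are excluded and reported; non-finite descriptor values
#' are imputed to 0 and reported, so downstream tree ensembles never see
#' `NaN`.
#'
#' @param pool a [MoleculePool-class].
#' @param provider `"synthetic"` or `"openbabel"`.
#' @return a list with `pool` (populated [MoleculePool-class]), `invalid`
#'   (character ids excluded) and `imputed` (data.frame of id/dimension pairs
#'   imputed to 0).
#' @export
computeDescriptors <- function(pool, provider = c("synthetic", "openbabel")) {
  provider <- match.arg(provider)
  imputed <- data.frame(id = character(0), dimension = character(0))
  if (provider == "synthetic") {
    if (ncol(descriptorMatrix(pool)) == 0)
      stop("synthetic provider requires descriptor vectors to be present")
    d <- descriptorMatrix(pool)
    bad <- which(!is.finite(d), arr.ind = TRUE)
    if (nrow(bad)) {
      imputed <- data.frame(id = poolIds(pool)[bad[, 1]],
                            dimension = colnames(d)[bad[, 2]])
      d[!is.finite(d)] <- 0
      pool@descriptors <- d
    }
    return(list(pool = pool, invalid = character(0), imputed = imputed))
  }
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("provider 'openbabel' requires the ", pkg, " package")
  smis <- moleculeSmiles(pool)
  if (anyNA(smis)) stop("openbabel provider requires SMILES for all records")
  parseOne <- function(smi, id) {
    tryCatch(ChemmineR::smiles2sdf(setNames(smi, id)),
             error = function(e) NULL)
  }
  sdfs <- mapply(parseOne, smis, poolIds(pool), SIMPLIFY = FALSE)
  ok <- !vapply(sdfs, is.null, logical(1))
  invalid <- poolIds(pool)[!ok]
  if (!any(ok)) stop("no valid structures in pool")
  pool <- pool[ok]
  sdfset <- suppressWarnings(Reduce(c, unname(sdfs[ok])))
  ChemmineR::cid(sdfset) <- poolIds(pool)
  props <- ChemmineR::propOB(sdfset)
  ringCounts <- ChemmineR::rings(sdfset, type = "count", arom = TRUE)
  desc <- cbind(
    mol_weight = props$MW, logp = props$logP, tpsa = props$TPSA,
    molar_refractivity = props$MR, n_hbd = props$HBD, n_hba = props$HBA2,
    n_fluorine = props$nF, n_rings = ringCounts[, "RINGS"],
    n_aromatic_rings = ringCounts[, "AROMATIC"])
  rownames(desc) <- poolIds(pool)
  bad <- which(!is.finite(desc), arr.ind = TRUE)
  if (nrow(bad)) {
    imputed <- data.frame(id = poolIds(pool)[bad[, 1]],
                          dimension = colnames(desc)[bad[, 2]])
    desc[!is.finite(desc)] <- 0
  }
  pool@descriptors <- desc
  pool@properties <- data.frame(
    mol_weight = desc[, "mol_weight"],
    n_aromatic_rings = desc[, "n_aromatic_rings"],
    logp = desc[, "logp"],
    n_hbd = desc[, "n_hbd"],
    n_hba = desc[, "n_hba"],
    row.names = NULL)
  list(pool = pool, invalid = invalid, imputed = imputed)
}
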