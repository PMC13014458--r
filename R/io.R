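# Pool and score readers/writers, run manifests.

#' Load a molecule pool
#'
#' CSV pools must have a header `id,smiles` with an optional `score` column;
#' malformed rows (wrong field count) and duplicate ids are rejected with
#' informative errors rather than coerced. SDF pools (requires
#' \pkg{ChemmineR}/\pkg{ChemmineOB}) take ids from the SDF compound names and
#' convert structures back to SMILES.
#'
#' @param path input file.
#' @param format `"csv"` or `"sdf"` (default: guessed from the extension).
#' @return a [MoleculePool-class] (descriptors unset; see
#'   [computeDescriptors()]).
#' @export
loadPool <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "sdf") {
    for (pkg in c("ChemmineR", "ChemmineOB"))
      if (!requireNamespace(pkg, quietly = TRUE))
        stop("SDF input requires the ", pkg, " package")
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfset)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate ids in SDF: ", paste(dup, collapse = ", "))
    smis <- as.character(ChemmineR::sdf2smiles(sdfset))
    return(moleculePool(ids, smiles = smis))
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1)
    stop("malformed CSV rows (wrong field count) at lines: ",
         paste(which(nf != nf[1]), collapse = ", "))
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "smiles") %in% names(tab)))
    stop("pool CSV must have columns id,smiles")
  blank <- which(!nzchar(trimws(tab$id)))
  if (length(blank))
    stop("empty ids at lines: ", paste(blank + 1L, collapse = ", "))
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicate ids in pool: ", paste(dup, collapse = ", "))
  scores <- NULL
  if ("score" %in% names(tab)) {
    scores <- suppressWarnings(as.numeric(tab$score))
    bad <- which(is.na(scores) & nzchar(tab$score))
    if (length(bad))
      stop("non-numeric scores at lines: ", paste(bad + 1L, collapse = ", "))
  }
  moleculePool(tab$id, smiles = tab$smiles, scores = scores)
}

#' Write a pool to CSV
#'
#' Writes `id,smiles[,score]`; the canonical interchange format of the
#' package.
#'
#' @param pool a [MoleculePool-class].
#' @param path output path.
#' @param scores include the score column?
#' @return `path`, invisibly.
#' @export
writePoolCsv <- function(pool, path, scores = any(!is.na(pool@scores))) {
  tab <- data.frame(id = poolIds(pool), smiles = unname(moleculeSmiles(pool)))
  if (scores) tab$score <- unname(moleculeScores(pool))
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export pool structures to SDF
#'
#' Requires parseable SMILES and the \pkg{ChemmineR}/\pkg{ChemmineOB}
#' packages. Molecule ids are stored as the SDF compound names, so
#' [loadPool()] round-trips the id set.
#'
#' @param pool a [MoleculePool-class] with SMILES.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportSDF <- function(pool, path) {
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("SDF export requires the ", pkg, " package")
  smis <- moleculeSmiles(pool)
  if (anyNA(smis)) stop("SDF export requires SMILES for all records")
  sdfset <- ChemmineR::smiles2sdf(smis)
  ChemmineR::cid(sdfset) <- poolIds(pool)
  ChemmineR::write.SDF(sdfset, path, cid = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run exactly: a configuration
#' snapshot, the seeds used, the package version, digests of the input
#' files, and start/end timestamps. Written once per run directory as
#' `manifest.json`.
#'
#' @param outDir run output directory (created if needed).
#' @param config list: configuration snapshot.
#' @param seeds integer vector of seeds used.
#' @param inputs character vector of input file paths to digest.
#' @param started,finished POSIXct timestamps.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(outDir, config, seeds, inputs = character(0),
                          started = Sys.time(), finished = Sys.time()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "dmtasim",
    version = as.character(packageVersion("dmtasim")),
    config = config,
    seeds = as.integer(seeds),
    input_digests = digests,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Mirrors the [simConfig()] fields that are plain values (strategy, batch
#' size, iterations, pool fraction, hybrid ratio, MCCV resamples, seed, and
#' the benchmark-generator sizes); see the package vignette for the schema.
#'
#' @param path YAML file.
#' @return a named list of configuration values.
#' @export
readConfigYaml <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
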