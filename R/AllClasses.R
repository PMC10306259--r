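## S4 class definitions for the package's central data objects.

#' PrepConfig: molecule-preparation settings
#'
#' Holds the standardization/filtering window and fragmentation settings.
#' The drug-like training window defaults to 200-1000 Da; fragmentation
#' defaults to BRICS. `maxSubsets` caps the number of fragment subsets
#' enumerated per molecule (sampled deterministically under `subsetSeed`
#' when the cap binds), keeping the corpus size linear in molecule count.
#'
#' @slot minWeight,maxWeight molecular-weight window in Da.
#' @slot fragMethod "BRICS" or "RECAP".
#' @slot maxFragments largest fragment-subset size enumerated per molecule.
#' @slot allowedElements elements admitted by the organic filter.
#' @slot maxSubsets cap on fragment subsets per molecule.
#' @slot subsetSeed seed used when subset sampling is capped.
#' @export
setClass("PrepConfig",
  representation(minWeight = "numeric", maxWeight = "numeric",
                 fragMethod = "character", maxFragments = "integer",
                 allowedElements = "character", maxSubsets = "integer",
                 subsetSeed = "integer"),
  validity = function(object) {
    if (object@minWeight >= object@maxWeight)
      return("minWeight must be smaller than maxWeight")
    if (!object@fragMethod %in% c("BRICS", "RECAP"))
      return("fragMethod must be 'BRICS' or 'RECAP'")
    if (object@maxFragments < 1L) return("maxFragments must be >= 1")
    TRUE
  })

#' Construct a PrepConfig
#'
#' @param minWeight,maxWeight molecular-weight window in Da (defaults 200,
#'   1000).
#' @param fragMethod fragmentation rule set, `"BRICS"` (default) or
#'   `"RECAP"`.
#' @param maxFragments largest fragment-subset size per molecule.
#' @param allowedElements element whitelist for the organic filter.
#' @param maxSubsets cap on enumerated fragment subsets per molecule.
#' @param subsetSeed seed for deterministic subset sampling when capped.
#' @return a [PrepConfig-class] object.
#' @export
prepConfig <- function(minWeight = 200, maxWeight = 1000,
                       fragMethod = c("BRICS", "RECAP"),
                       maxFragments = 4L,
                       allowedElements = c("H", "B", "C", "N", "O", "P", "S",
                                           "F", "Cl", "Br", "I"),
                       maxSubsets = 16L, subsetSeed = 42L) {
  new("PrepConfig", minWeight = as.numeric(minWeight),
      maxWeight = as.numeric(maxWeight),
      fragMethod = match.arg(fragMethod),
      maxFragments = as.integer(maxFragments),
      allowedElements = allowedElements,
      maxSubsets = as.integer(maxSubsets),
      subsetSeed = as.integer(subsetSeed))
}

#' MoleculeSet: standardized molecule records
#'
#' One row per input molecule: the raw input string, the canonical SMILES
#' after standardization (empty when unparsable), the average molecular
#' weight in Da, and validity/organic flags.
#'
#' @slot records data.frame with columns `raw`, `canonical`, `molWeight`,
#'   `isValid`, `isOrganic`.
#' @export
setClass("MoleculeSet",
  representation(records = "data.frame"),
  validity = function(object) {
    need <- c("raw", "canonical", "molWeight", "isValid", "isOrganic")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    r <- object@records
    bad <- r$isValid & (!nzchar(r$canonical) | is.na(r$molWeight) |
                          r$molWeight <= 0)
    if (any(bad))
      return("valid records must have non-empty canonical SMILES and MW > 0")
    TRUE
  })

setMethod("show", "MoleculeSet", function(object) {
  r <- object@records
  cat("MoleculeSet with", nrow(r), "molecules;",
      sum(r$isValid), "valid,", sum(r$isValid & r$isOrganic), "organic\n")
  if (nrow(r)) {
    head <- utils::head(r$canonical[r$isValid], 3)
    if (length(head)) cat("  e.g.", paste(head, collapse = ", "), "\n")
  }
})

setMethod("length", "MoleculeSet", function(x) nrow(x@records))

setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  new("MoleculeSet", records = x@records[i, , drop = FALSE])
})

#' @describeIn MoleculeSet-class the full record table.
#' @param x a `MoleculeSet`.
#' @export
records <- function(x) {
  r <- x@records
  rownames(r) <- NULL
  r
}

#' ScoreTable: per-molecule objective scores and rewards
#'
#' Rectangular result of scoring a batch: raw per-objective scores (`NA` for
#' invalid molecules or failed scorers), modified desirability scores in
#' \[0,1\] (0 for invalid molecules), the all-thresholds `desired` verdict,
#' and the scalar reward assigned by the ranking scheme.
#'
#' @slot smiles character vector of scored molecules.
#' @slot raw,modified numeric matrices, one column per objective.
#' @slot desired logical vector.
#' @slot reward numeric vector in \[0,1\].
#' @slot thresholds per-objective desirability thresholds.
#' @export
setClass("ScoreTable",
  representation(smiles = "character", raw = "matrix", modified = "matrix",
                 desired = "logical", reward = "numeric",
                 thresholds = "numeric"),
  validity = function(object) {
    n <- length(object@smiles)
    if (nrow(object@raw) != n || nrow(object@modified) != n)
      return("score matrices must have one row per molecule")
    if (length(object@desired) != n) return("desired must have length n")
    m <- object@modified[is.finite(object@modified)]
    if (length(m) && (min(m) < 0 || max(m) > 1))
      return("modified scores must lie in [0, 1]")
    TRUE
  })

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", length(object@smiles), "molecules x",
      ncol(object@modified), "objectives;",
      sum(object@desired), "desired\n")
})

#' @describeIn ScoreTable-class desired flags.
#' @param x a `ScoreTable`.
#' @export
desired <- function(x) x@desired

#' @describeIn ScoreTable-class scalar rewards.
#' @export
rewards <- function(x) x@reward

#' @describeIn ScoreTable-class modified (desirability) score matrix.
#' @export
modifiedScores <- function(x) x@modified

#' @describeIn ScoreTable-class raw score matrix.
#' @export
rawScores <- function(x) x@raw
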