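## Molecule standardization, drug-likeness filtering and fragment-pair
## enumeration: the preprocessing stage that turns raw SMILES input into
## training corpora.

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Standardize one raw input string; returns a one-row record list.
.standardizeOne <- function(raw, allowedElements) {
  rec <- list(raw = raw, canonical = "", molWeight = NA_real_,
              isValid = FALSE, isOrganic = FALSE)
  can <- canonicalSmiles(raw)
  if (!nzchar(can)) return(rec)
  ## keep the largest covalent component (most heavy atoms; ties broken by
  ## MW, then alphabetically) before the organic test
  parts <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(parts) > 1L) {
    graphs <- lapply(parts, mgFromSmiles)
    keep <- !vapply(graphs, is.null, logical(1))
    parts <- parts[keep]; graphs <- graphs[keep]
    if (!length(parts)) return(rec)
    sz <- vapply(graphs, function(g) nrow(g$atoms), integer(1))
    mw <- vapply(graphs, mgMolWeight, numeric(1))
    ord <- order(-sz, -mw, parts)
    can <- parts[ord[1]]
  }
  g <- mgFromSmiles(can)
  if (is.null(g)) return(rec)
  ## neutralize charges where a simple proton add/remove suffices
  changed <- FALSE
  for (i in seq_len(nrow(g$atoms))) {
    e <- g$atoms$element[i]; q <- g$atoms$charge[i]
    if (!(e %in% c("N", "O", "S", "P"))) next
    if (q > 0L && g$atoms$implicitH[i] >= q) {
      g$atoms$charge[i] <- 0L; changed <- TRUE
    } else if (q < 0L) {
      g$atoms$charge[i] <- 0L; changed <- TRUE
    }
  }
  if (changed) {
    g <- mgPerceive(g)
    can2 <- mgToSmiles(g)
    if (nzchar(can2)) {
      can <- can2
      g <- mgFromSmiles(can)
      if (is.null(g)) return(rec)
    }
  }
  rec$canonical <- can
  rec$isValid <- TRUE
  props <- .obProps(can)
  rec$molWeight <- if (!is.null(props)) as.numeric(props$MW) else mgMolWeight(g)
  rec$isOrganic <- all(g$atoms$element %in% allowedElements) &&
    any(g$atoms$element == "C")
  rec
}

#' Standardize raw molecule inputs
#'
#' Canonicalizes each input SMILES, strips salts/solvents (keeping the
#' largest covalent component), neutralizes simple protonation charges, and
#' flags validity and organic character (all elements within the allowed set
#' and at least one carbon). Unparsable input yields an invalid record,
#' never an error.
#'
#' @param raw character vector of input SMILES.
#' @param config a [PrepConfig-class]; only `allowedElements` is used here.
#' @return a [MoleculeSet-class].
#' @export
#' @examples
#' ms <- standardizeMolecules(c("CC(=O)Nc1ccc(O)cc1", "not_a_smiles"))
#' records(ms)
standardizeMolecules <- function(raw, config = prepConfig()) {
  recs <- lapply(as.character(raw), .standardizeOne,
                 allowedElements = config@allowedElements)
  new("MoleculeSet", records = do.call(rbind, lapply(recs, function(r) {
    data.frame(raw = r$raw, canonical = r$canonical, molWeight = r$molWeight,
               isValid = r$isValid, isOrganic = r$isOrganic,
               stringsAsFactors = FALSE)
  })) %||% data.frame(raw = character(0), canonical = character(0),
                      molWeight = numeric(0), isValid = logical(0),
                      isOrganic = logical(0)))
}

#' Filter a standardized corpus to the drug-like training window
#'
#' Keeps valid, organic molecules whose molecular weight lies within the
#' configured window (200-1000 Da by default), deduplicated on canonical
#' SMILES with input order of first occurrence preserved. An empty result is
#' allowed and raises a warning, not an error.
#'
#' @param mols a [MoleculeSet-class] of standardized records.
#' @param config a [PrepConfig-class].
#' @return the filtered [MoleculeSet-class].
#' @export
filterCorpus <- function(mols, config = prepConfig()) {
  r <- mols@records
  keep <- r$isValid & r$isOrganic &
    !is.na(r$molWeight) &
    r$molWeight >= config@minWeight & r$molWeight <= config@maxWeight
  r <- r[keep, , drop = FALSE]
  r <- r[!duplicated(r$canonical), , drop = FALSE]
  if (nrow(r) == 0L) warning("filterCorpus: no molecules left after filtering")
  rownames(r) <- NULL
  new("MoleculeSet", records = r)
}

#' Enumerate fragment-molecule training pairs
#'
#' Fragments each molecule with the configured rule set and emits one
#' training pair per non-empty subset of its distinct leaf fragments, up to
#' `maxFragments` fragments per subset. When a molecule admits more than
#' `maxSubsets` subsets, a deterministic sample (under `subsetSeed`) is
#' taken. Fragments are reported with attachment points stripped and joined
#' by `"."` in the `Frags` column.
#'
#' @param mols a [MoleculeSet-class] (or character vector of valid SMILES).
#' @param config a [PrepConfig-class].
#' @return data.frame with columns `Frags`, `SMILES`, `nFrags`.
#' @export
enumerateFragmentPairs <- function(mols, config = prepConfig()) {
  smiles <- if (is(mols, "MoleculeSet")) {
    r <- mols@records
    r$canonical[r$isValid]
  } else {
    as.character(mols)
  }
  out <- list()
  for (mi in seq_along(smiles)) {
    s <- smiles[mi]
    frags <- tryCatch(fragmentMolecule(s, config@fragMethod),
                      error = function(e) character(0))
    if (!length(frags)) next
    leaves <- unique(stripAttachment(frags))
    leaves <- leaves[nzchar(leaves)]
    if (!length(leaves)) next
    nl <- length(leaves)
    sizes <- seq_len(min(nl, config@maxFragments))
    subsets <- unlist(lapply(sizes, function(k) {
      utils::combn(nl, k, simplify = FALSE)
    }), recursive = FALSE)
    if (length(subsets) > config@maxSubsets) {
      idx <- .withSeed(config@subsetSeed + mi,
                       sample.int(length(subsets), config@maxSubsets))
      subsets <- subsets[sort(idx)]
    }
    for (ss in subsets) {
      out[[length(out) + 1L]] <- data.frame(
        Frags = paste(leaves[ss], collapse = "."),
        SMILES = s, nFrags = length(ss), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(Frags = character(0), SMILES = character(0),
                      nFrags = integer(0)))
  }
  do.call(rbind, out)
}

#' Read molecules from a SMILES text or TSV file
#'
#' Accepts either a plain text file with one SMILES per line or a
#' tab-separated file with a header containing a column named `SMILES`
#' (case-insensitive).
#'
#' @param path file path.
#' @return character vector of raw SMILES strings.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(character(0))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  col <- which(toupper(trimws(header)) == "SMILES")
  if (length(col)) {
    vapply(strsplit(lines[-1], "\t", fixed = TRUE),
           function(x) if (length(x) >= col[1]) trimws(x[col[1]]) else "",
           character(1))
  } else {
    vapply(strsplit(lines, "[ \t]+"), `[`, character(1), 1L)
  }
}

#' Write a corpus TSV
#'
#' RNN corpora have a single `SMILES` column; transformer corpora have
#' `Frags` and `SMILES` columns (UTF-8, tab-separated, header row).
#'
#' @param x a [MoleculeSet-class], character vector, or the data.frame
#'   returned by [enumerateFragmentPairs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorpusFile <- function(x, path) {
  if (is(x, "MoleculeSet")) {
    r <- x@records
    x <- data.frame(SMILES = r$canonical[r$isValid], stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    x <- data.frame(SMILES = x, stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
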