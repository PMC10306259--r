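## Thin wrappers around ChemmineOB / Open Babel. All chemistry I/O funnels
## through here so the rest of the package only sees canonical SMILES,
## molblocks and numeric properties.

## Cheap syntactic screen applied before handing a string to Open Babel:
## catches the bulk of malformed generated SMILES (unbalanced parentheses or
## brackets, unpaired ring closures, dangling bonds) without library noise.
.smilesPreCheck <- function(s) {
  if (!nzchar(s)) return(FALSE)
  if (grepl("^[)=#/\\\\%0-9+.-]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; inBracket <- FALSE
  digits <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (inBracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") inBracket <- FALSE
    } else if (ch == "[") {
      inBracket <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > length(chars)) return(FALSE)
      digits <- c(digits, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 2L
    } else if (ch %in% as.character(0:9)) {
      digits <- c(digits, as.integer(ch))
    }
    i <- i + 1L
  }
  if (depth != 0L || inBracket) return(FALSE)
  if (length(digits) && any(table(digits) %% 2L != 0L)) return(FALSE)
  if (grepl("[=#([]$|[=#]\\)", s)) return(FALSE)
  TRUE
}

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to Open Babel canonical SMILES. Unparsable input
#' yields an empty string, never an error; parse diagnostics emitted by the
#' underlying library are informational only.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES ("" where unparsable).
#' @export
#' @examples
#' canonicalSmiles("OCC")  # "CCO"
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    if (!.smilesPreCheck(s)) return("")
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) "")
    .obStripTitle(out)
  }, character(1), USE.NAMES = FALSE)
}

## Open Babel appends "\t<title>\n"; strip it.
.obStripTitle <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return("")
  sub("[ \t\n].*$", "", x)
}

.obSmilesToMolblock <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = smiles)),
    error = function(e) "")
  if (!nzchar(out)) return(NULL)
  out
}

.obMolblockToSmiles <- function(molblock) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", source = molblock)),
    error = function(e) "")
  .obStripTitle(out)
}

.obMolRef <- function(smiles) {
  tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
}

## Properties (average MW, logP, formula, ...) for one SMILES; NULL if invalid.
.obProps <- function(smiles) {
  ref <- .obMolRef(smiles)
  if (is.null(ref)) return(NULL)
  p <- tryCatch(suppressWarnings(ChemmineOB::prop_OB(ref)),
                error = function(e) NULL)
  if (is.null(p) || nrow(p) == 0L) return(NULL)
  p
}

## Count of substructure matches of `smarts` in `smiles` (SMILES used as
## SMARTS gives plain substructure semantics). NA if molecule invalid.
.obSmartsCount <- function(smiles, smarts) {
  ref <- .obMolRef(smiles)
  if (is.null(ref)) return(NA_integer_)
  n <- tryCatch(suppressWarnings(ChemmineOB::smartsSearch_OB(ref, smarts)),
                error = function(e) NA_integer_)
  as.integer(n)
}

#' Substructure test
#'
#' Tests whether `pattern` (a SMILES fragment, attachment points removed)
#' occurs as a substructure of `smiles`.
#'
#' @param smiles a single SMILES string.
#' @param pattern a single SMILES substructure pattern.
#' @return `TRUE`/`FALSE`; `NA` if either input is unparsable.
#' @export
hasSubstructure <- function(smiles, pattern) {
  if (!nzchar(smiles) || !nzchar(pattern)) return(NA)
  n <- .obSmartsCount(smiles, pattern)
  if (is.na(n)) return(NA)
  n > 0L
}
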