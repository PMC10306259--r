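## SMILES tokenization and sequence encoding with an invertible vocabulary.

.SV_PAD <- "<PAD>"; .SV_GO <- "<GO>"; .SV_EOS <- "<EOS>"; .SV_SEP <- "<SEP>"
.SV_CONTROL <- c(.SV_PAD, .SV_GO, .SV_EOS, .SV_SEP)

#' SmilesVocabulary: token set for SMILES language models
#'
#' Ordered token list with the control tokens `<PAD>`, `<GO>`, `<EOS>`,
#' `<SEP>` first (codes 1-4), followed by the chemical tokens in sorted
#' order. Token/code mapping is bijective by construction.
#'
#' @slot tokens character vector, controls first.
#' @export
setClass("SmilesVocabulary",
  representation(tokens = "character"),
  validity = function(object) {
    if (length(object@tokens) < 5L) return("vocabulary has no chemical tokens")
    if (!identical(object@tokens[1:4], .SV_CONTROL))
      return("first four tokens must be the control tokens")
    if (anyDuplicated(object@tokens)) return("tokens must be unique")
    TRUE
  })

setMethod("show", "SmilesVocabulary", function(object) {
  cat("SmilesVocabulary:", length(object@tokens) - 4L, "chemical tokens +",
      "4 controls\n")
})

#' @describeIn SmilesVocabulary-class number of tokens (controls included).
#' @param x a vocabulary.
#' @export
vocabSize <- function(x) length(x@tokens)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically atomic tokens: bracket atoms
#' (`[NH3+]`) and two-character ring closures (`%12`) are single tokens, the
#' two-letter elements Cl and Br are kept intact, everything else is one
#' character.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
tokenizeSmiles <- function(smiles) {
  out <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j < 0) stop("tokenizeSmiles: unmatched '[' in ", smiles)
      out <- c(out, substr(smiles, i, i + j - 1L))
      i <- i + j
    } else if (ch == "%") {
      out <- c(out, substr(smiles, i, i + 2L))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n &&
               substr(smiles, i + 1L, i + 1L) %in% c("l", "r") &&
               substr(smiles, i, i + 1L) %in% c("Cl", "Br")) {
      out <- c(out, substr(smiles, i, i + 1L))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Build a SMILES vocabulary from a corpus
#'
#' Collects every token observed in the corpus; ordering is deterministic
#' (controls first, then sorted chemical tokens).
#'
#' @param corpus character vector of SMILES.
#' @return a [SmilesVocabulary-class].
#' @export
buildSmilesVocab <- function(corpus) {
  if (!length(corpus)) stop("buildSmilesVocab: empty corpus")
  ## "." is always present: it separates fragments in combination inputs
  toks <- sort(unique(c(".", unlist(lapply(corpus, tokenizeSmiles)))))
  new("SmilesVocabulary", tokens = c(.SV_CONTROL, toks))
}

.svCode <- function(vocab, token) {
  code <- match(token, vocab@tokens)
  if (anyNA(code)) {
    stop("token(s) not in vocabulary: ",
         paste(unique(token[is.na(code)]), collapse = ", "))
  }
  code
}

#' Encode a SMILES string as a padded token-code sequence
#'
#' Produces `GO + codes + EOS`, padded with `PAD` to `maxLen`. Sequences
#' start with GO, end with EOS, and PAD occurs only after EOS.
#'
#' @param smiles a single SMILES string.
#' @param vocab a [SmilesVocabulary-class].
#' @param maxLen total sequence length.
#' @return integer vector of length `maxLen`.
#' @export
encodeSmiles <- function(smiles, vocab, maxLen = 100L) {
  toks <- tokenizeSmiles(smiles)
  if (length(toks) + 2L > maxLen)
    stop("SMILES too long for maxLen ", maxLen, ": ", smiles)
  codes <- .svCode(vocab, toks)
  go <- .svCode(vocab, .SV_GO); eos <- .svCode(vocab, .SV_EOS)
  pad <- .svCode(vocab, .SV_PAD)
  c(go, codes, eos, rep(pad, maxLen - length(codes) - 2L))
}

#' Decode a token-code sequence back to SMILES
#'
#' Inverse of [encodeSmiles()]: control tokens are dropped, decoding stops
#' at the first EOS.
#'
#' @param codes integer vector of token codes.
#' @param vocab a [SmilesVocabulary-class].
#' @return the decoded SMILES string (possibly chemically invalid).
#' @export
decodeSmiles <- function(codes, vocab) {
  toks <- vocab@tokens[codes]
  eos <- which(toks == .SV_EOS)
  if (length(eos)) toks <- toks[seq_len(eos[1] - 1L)]
  paste(toks[!toks %in% .SV_CONTROL], collapse = "")
}

## Deterministic rolling hash of a character vector (vocabulary identity).
.strHash <- function(x) {
  h <- 5381
  for (ch in utf8ToInt(paste(x, collapse = "\x01"))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write / read a vocabulary file
#'
#' Plain-text format: a versioned header comment line, then one token per
#' line, controls first. Graph vocabularies use `atom:` / `bond:` prefixes.
#'
#' @param vocab a [SmilesVocabulary-class] or [GraphVocabulary-class].
#' @param path file path.
#' @return `writeVocabulary` returns `path` invisibly; `readVocabulary`
#'   returns the vocabulary object.
#' @export
writeVocabulary <- function(vocab, path) {
  if (is(vocab, "SmilesVocabulary")) {
    writeLines(c("# deNovoMol smiles-vocabulary v1", vocab@tokens), path)
  } else {
    writeLines(c("# deNovoMol graph-vocabulary v1",
                 paste0("atom:", vocab@atomTypes),
                 paste0("bond:", vocab@bondTypes)), path)
  }
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  body <- lines[-1]
  if (grepl("smiles-vocabulary", header)) {
    new("SmilesVocabulary", tokens = body)
  } else if (grepl("graph-vocabulary", header)) {
    new("GraphVocabulary",
        atomTypes = sub("^atom:", "", grep("^atom:", body, value = TRUE)),
        bondTypes = sub("^bond:", "", grep("^bond:", body, value = TRUE)))
  } else {
    stop("not a deNovoMol vocabulary file: ", path)
  }
}
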