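## Five-row graph-matrix codec for fragment-conditioned graph generation.
##
## A molecule is encoded as a 5 x L integer matrix laid out in four column
## blocks: a GO column, a fragment block of width d = L - 2 - nLink holding
## one column per atom (plus ring-closure columns), an EOS column, and a
## linking block whose columns restore the bonds cleaved between fragments.
## Row semantics per column:
##   r1  atom-type code (or GO/EOS control code)
##   r2  0-based atom index (a new atom's index is always previous max + 1;
##       a column whose r2 refers to an existing atom encodes a ring closure)
##   r3  0-based index of the neighbor the column bonds to (fragment-start
##       columns have r3 = r2)
##   r4  bond-type code (0 none, 1 single, 2 double, 3 triple, 4 aromatic)
##   r5  1-based index of the fragment being encoded (0 in the linking block)
## The codec operates on kekulized structures, so bond code 4 is reserved
## but unused by default; this keeps per-step valence checking local, which
## is what guarantees that masked sampling can only produce valid molecules.

.GV_PAD <- 0L; .GV_GO <- 1L; .GV_EOS <- 2L
.GV_NCTRL <- 2L            # one GO column + one EOS column

#' GraphVocabulary: atom- and bond-type codes for the graph codec
#'
#' Atom types are element plus formal charge (e.g. `"C"`, `"N+1"`,
#' `"O-1"`); explicit hydrogens are folded into the valence model. Bond
#' types are single, double, triple and aromatic. Code 0 is reserved for
#' padding, codes 1 and 2 for the GO/EOS controls; atom-type codes start
#' at 3.
#'
#' @slot atomTypes character vector of atom-type descriptors.
#' @slot bondTypes character vector of bond-type names.
#' @export
setClass("GraphVocabulary",
  representation(atomTypes = "character", bondTypes = "character"),
  validity = function(object) {
    if (!length(object@atomTypes)) return("no atom types")
    if (anyDuplicated(object@atomTypes)) return("atom types must be unique")
    TRUE
  })

setMethod("show", "GraphVocabulary", function(object) {
  cat("GraphVocabulary:", length(object@atomTypes), "atom types,",
      length(object@bondTypes), "bond types\n")
})

.gvAtomTypeOf <- function(element, charge) {
  ifelse(charge == 0L, element,
         paste0(element, ifelse(charge > 0L, "+", ""), charge))
}

.gvParseAtomType <- function(type) {
  m <- regmatches(type, regexec("^([A-Za-z*]+)([+-]?[0-9]+)?$", type))[[1]]
  list(element = m[2],
       charge = if (nzchar(m[3] %||% "")) as.integer(m[3]) else 0L)
}

.gvAtomCode <- function(vocab, type) {
  code <- match(type, vocab@atomTypes)
  if (anyNA(code)) {
    stop("atom type(s) not in graph vocabulary: ",
         paste(unique(type[is.na(code)]), collapse = ", "))
  }
  code + .GV_NCTRL
}

#' Build a graph vocabulary from a corpus
#'
#' Scans the (kekulized) molecular graphs of the corpus and collects all
#' element + formal-charge atom types, in sorted order.
#'
#' @param corpus character vector of valid SMILES.
#' @return a [GraphVocabulary-class].
#' @export
buildGraphVocab <- function(corpus) {
  if (!length(corpus)) stop("buildGraphVocab: empty corpus")
  types <- unique(unlist(lapply(corpus, function(s) {
    g <- mgFromSmiles(s)
    if (is.null(g)) return(character(0))
    .gvAtomTypeOf(g$atoms$element, g$atoms$charge)
  })))
  new("GraphVocabulary", atomTypes = sort(types),
      bondTypes = c("single", "double", "triple", "aromatic"))
}

## BFS traversal of one fragment's atom set; returns columns (without r5).
## Each visited atom contributes a new-atom column; bonds among already
## visited atoms contribute ring-closure columns right after the atom that
## completes them.
.graphTraverseFragment <- function(g, atomSet, vocab, indexOf) {
  adj <- mgAdjacency(g)
  cols <- list()
  visited <- integer(0)
  start <- min(atomSet)
  queue <- start
  pending <- setdiff(atomSet, start)
  parent <- c()
  parent[as.character(start)] <- start
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    if (a %in% visited) next
    p <- parent[[as.character(a)]]
    code <- .gvAtomCode(vocab, .gvAtomTypeOf(g$atoms$element[a],
                                             g$atoms$charge[a]))
    ord <- if (p == a) 0L else {
      g$bonds$order[(g$bonds$a1 == a & g$bonds$a2 == p) |
                    (g$bonds$a2 == a & g$bonds$a1 == p)][1]
    }
    idx <- length(indexOf$map)
    indexOf$map[[as.character(a)]] <- idx
    cols[[length(cols) + 1L]] <-
      c(code, idx, indexOf$map[[as.character(p)]], ord)
    visited <- c(visited, a)
    nb <- adj[[a]]
    sel <- order(nb$nbr)
    for (k in sel) {
      b <- nb$nbr[k]
      if (!(b %in% atomSet)) next
      if (b %in% visited && b != p) {
        ## ring closure within the fragment
        cols[[length(cols) + 1L]] <-
          c(code, idx, indexOf$map[[as.character(b)]], nb$order[k])
      } else if (!(b %in% visited) && !(b %in% queue)) {
        parent[as.character(b)] <- a
        queue <- c(queue, b)
      } else if (!(b %in% visited) && is.null(parent[[as.character(b)]])) {
        parent[as.character(b)] <- a
      }
    }
  }
  cols
}

#' Encode a fragment-molecule pair as a 5 x L graph matrix
#'
#' Fragments the molecule with the given rule set, orders the leaf
#' fragments so that the pair's input fragments come first, and writes the
#' block layout described in [GraphVocabulary-class]. The cleaved
#' inter-fragment bonds go into the linking block so that decoding
#' reconstructs the complete molecule.
#'
#' @param molecule a valid SMILES string.
#' @param fragments character vector of input fragments (attachment points
#'   stripped) to order first; may be `NULL` to keep natural leaf order.
#' @param vocab a [GraphVocabulary-class].
#' @param L total number of columns (default 400).
#' @param nLink width of the linking block (default 38).
#' @param method fragmentation rule set.
#' @return integer matrix with 5 rows and L columns.
#' @export
encodeGraph <- function(molecule, fragments = NULL, vocab,
                        L = 400L, nLink = 38L,
                        method = c("BRICS", "RECAP")) {
  method <- match.arg(method)
  g <- mgFromSmiles(molecule)
  if (is.null(g)) stop("encodeGraph: unparsable molecule: ", molecule)
  fr <- mgFragment(g, method)
  sets <- fr$atomSets
  ## order leaf fragments: those matching the supplied input fragments first
  if (!is.null(fragments) && length(sets) > 1L) {
    leafSmiles <- vapply(sets, function(idx) {
      mgToSmiles(mgSubgraph(g, idx, addDummies = FALSE))
    }, character(1))
    want <- canonicalSmiles(fragments)
    first <- integer(0)
    for (w in want) {
      hit <- setdiff(which(leafSmiles == w), first)
      if (length(hit)) first <- c(first, hit[1])
    }
    sets <- c(sets[first], sets[setdiff(seq_along(sets), first)])
  }
  d <- L - .GV_NCTRL - nLink
  mat <- matrix(0L, nrow = 5L, ncol = L)
  mat[1, 1] <- .GV_GO
  indexOf <- new.env()
  indexOf$map <- list()
  col <- 2L
  for (f in seq_along(sets)) {
    cols <- .graphTraverseFragment(g, sets[[f]], vocab, indexOf)
    for (cc in cols) {
      if (col > 1L + d) stop("encodeGraph: molecule needs more than d = ",
                             d, " fragment columns")
      mat[, col] <- as.integer(c(cc, f))
      col <- col + 1L
    }
  }
  mat[1, 2L + d] <- .GV_EOS
  ## linking block: cleaved inter-fragment bonds
  cb <- fr$cutBonds
  if (nrow(cb) > nLink)
    stop("encodeGraph: more cleaved bonds (", nrow(cb),
         ") than linking columns (", nLink, ")")
  for (i in seq_len(nrow(cb))) {
    a <- cb$a1[i]; b <- cb$a2[i]
    code <- .gvAtomCode(vocab, .gvAtomTypeOf(g$atoms$element[a],
                                             g$atoms$charge[a]))
    mat[, 2L + d + i] <- as.integer(c(code, indexOf$map[[as.character(a)]],
                                      indexOf$map[[as.character(b)]],
                                      cb$order[i], 0L))
  }
  mat
}

#' Decode a 5 x L graph matrix to a canonical SMILES
#'
#' Rebuilds atoms and bonds column by column, merging fragments through the
#' linking block. Structurally inconsistent matrices (dangling neighbor
#' indices, valence-violating bonds, no atoms) raise an error; a
#' structurally consistent matrix always yields a valid molecule.
#'
#' @param mat integer matrix with 5 rows.
#' @param vocab the [GraphVocabulary-class] used for encoding.
#' @return canonical SMILES of the decoded molecule.
#' @export
decodeGraph <- function(mat, vocab) {
  if (nrow(mat) != 5L) stop("decodeGraph: matrix must have 5 rows")
  atoms <- data.frame(element = character(0), charge = integer(0),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  nAtoms <- 0L
  for (col in seq_len(ncol(mat))) {
    v <- mat[, col]
    if (v[1] %in% c(.GV_PAD, .GV_GO, .GV_EOS)) next
    type <- vocab@atomTypes[v[1] - .GV_NCTRL]
    if (is.na(type)) stop("decodeGraph: unknown atom-type code ", v[1])
    if (v[2] == nAtoms) {
      ## new atom
      at <- .gvParseAtomType(type)
      atoms <- rbind(atoms, data.frame(element = at$element,
                                       charge = at$charge,
                                       stringsAsFactors = FALSE))
      nAtoms <- nAtoms + 1L
      if (v[3] != v[2]) {
        if (v[3] >= nAtoms - 1L && v[3] != v[2])
          stop("decodeGraph: dangling neighbor index in column ", col)
        bonds <- rbind(bonds, data.frame(a1 = v[2] + 1L, a2 = v[3] + 1L,
                                         order = v[4]))
      }
    } else if (v[2] < nAtoms) {
      ## ring closure or inter-fragment link between existing atoms
      if (v[3] >= nAtoms)
        stop("decodeGraph: dangling neighbor index in column ", col)
      bonds <- rbind(bonds, data.frame(a1 = v[2] + 1L, a2 = v[3] + 1L,
                                       order = v[4]))
    } else {
      stop("decodeGraph: atom index ", v[2], " skips ahead in column ", col)
    }
  }
  if (nrow(atoms) == 0L) stop("decodeGraph: matrix encodes no atoms")
  g <- list(atoms = atoms, bonds = bonds)
  ## valence audit: every bond must be admissible
  bs <- mgBondSums(g)
  for (i in seq_len(nrow(atoms))) {
    v <- mgValence(atoms$element[i], atoms$charge[i], bs[i])
    if (!is.na(v) && bs[i] > v)
      stop("decodeGraph: valence violation at atom ", i)
  }
  smi <- mgToSmiles(g)
  if (!nzchar(smi)) stop("decodeGraph: decoded structure rejected")
  smi
}

#' Validate the structural invariants of a graph matrix
#'
#' Checks the five-row shape, the consecutive-new-atom-index rule, the
#' non-decreasing fragment index within the fragment block, and that
#' padding appears only as all-zero columns.
#'
#' @param mat an encoded graph matrix.
#' @return `TRUE` (invisibly) or an error.
#' @export
validateGraphMatrix <- function(mat) {
  stopifnot(nrow(mat) == 5L)
  used <- mat[1, ] != 0L
  zero <- colSums(mat != 0L) == 0L
  if (any(!used & !zero)) stop("non-padding column with zero atom code")
  maxIdx <- -1L
  lastFrag <- 0L
  inLink <- FALSE
  for (col in which(used)) {
    v <- mat[, col]
    if (v[1] %in% c(.GV_GO, .GV_EOS)) { if (v[1] == .GV_EOS) inLink <- TRUE; next }
    if (v[2] == maxIdx + 1L) maxIdx <- maxIdx + 1L
    else if (v[2] > maxIdx + 1L) stop("atom index skips ahead")
    if (!inLink) {
      if (v[5] < lastFrag) stop("fragment index decreases")
      lastFrag <- v[5]
    }
  }
  invisible(TRUE)
}
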