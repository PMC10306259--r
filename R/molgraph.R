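## Internal molecular-graph layer.
##
## A "molgraph" is a plain list:
##   atoms: data.frame(element, charge, aromatic, inRing)
##   bonds: data.frame(a1, a2, order)   (1-based atom indices, order 1/2/3)
## Structures are kept kekulized (orders 1/2/3); aromaticity is a perceived
## per-atom flag used by the fragmentation rules only. Dummy (attachment)
## atoms use element "*".

.MG_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                 F = 1, Cl = 1, Br = 1, I = 1, `*` = 1)

.MG_ORGANIC_DEFAULT <- c("H", "B", "C", "N", "O", "P", "S",
                         "F", "Cl", "Br", "I")

## V2000 charge-column codes (overridden by M CHG when present).
.MG_CHGCODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

mgParseMolblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nAtoms) || is.na(nBonds)) return(NULL)
  if (nAtoms == 0L) {
    return(list(atoms = data.frame(element = character(0),
                                   charge = integer(0)),
                bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0))))
  }
  atomLines <- lines[4 + seq_len(nAtoms)]
  element <- trimws(substr(atomLines, 32, 34))
  chgcode <- trimws(substr(atomLines, 37, 39))
  charge <- unname(.MG_CHGCODE[chgcode])
  charge[is.na(charge)] <- 0L
  if (nBonds > 0L) {
    bondLines <- lines[4 + nAtoms + seq_len(nBonds)]
    a1 <- as.integer(substr(bondLines, 1, 3))
    a2 <- as.integer(substr(bondLines, 4, 6))
    order <- as.integer(substr(bondLines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  ## M CHG property lines override the atom-block charge column
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- scan(text = sub("^M  CHG", "", ln), quiet = TRUE)
    n <- toks[1]
    for (i in seq_len(n)) {
      charge[toks[2 * i]] <- as.integer(toks[2 * i + 1])
    }
  }
  ## order 4 (aromatic in some writers) should not occur in Open Babel SDF
  ## output, but map it to alternating single as a defensive fallback
  order[order == 4L] <- 1L
  list(atoms = data.frame(element = element, charge = charge,
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

## Parse a SMILES into a molgraph (kekulized), or NULL if unparsable.
mgFromSmiles <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  mb <- .obSmilesToMolblock(smiles)
  if (is.null(mb)) return(NULL)
  g <- mgParseMolblock(mb)
  if (is.null(g) || nrow(g$atoms) == 0L) return(NULL)
  mgPerceive(g)
}

## Adjacency list: for each atom, data.frame(nbr, order)
mgAdjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- replicate(n, list(nbr = integer(0), order = integer(0)),
                   simplify = FALSE)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]]$nbr <- c(adj[[b$a1[i]]]$nbr, b$a2[i])
    adj[[b$a1[i]]]$order <- c(adj[[b$a1[i]]]$order, b$order[i])
    adj[[b$a2[i]]]$nbr <- c(adj[[b$a2[i]]]$nbr, b$a1[i])
    adj[[b$a2[i]]]$order <- c(adj[[b$a2[i]]]$order, b$order[i])
  }
  adj
}

## Smallest ring (<= maxSize) through each bond; returns list of integer
## vectors of atom indices, unique rings only.
mgRings <- function(g, maxSize = 8L) {
  adj <- mgAdjacency(g)
  n <- nrow(g$atoms)
  rings <- list()
  seen <- character(0)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    s <- b$a1[i]; t <- b$a2[i]
    ## BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(dist[t])) break
      if (dist[v] >= maxSize - 1L) next
      for (w in adj[[v]]$nbr) {
        if (v == s && w == t) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[t])) next
    path <- t
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    if (path[1] != s) next
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

## Perceive ring membership, a Hueckel-style aromaticity flag, and implicit
## hydrogens. The aromaticity rule handles the common 5/6-membered systems
## (benzenoid, pyridine-like, furan/thiophene/pyrrole-like, fused benzenoids)
## which covers the chemistry this package constructs.
mgPerceive <- function(g) {
  n <- nrow(g$atoms)
  rings <- mgRings(g)
  inRing <- rep(FALSE, n)
  for (r in rings) inRing[r] <- TRUE
  aromatic <- rep(FALSE, n)
  adj <- mgAdjacency(g)
  for (r in rings) {
    sz <- length(r)
    if (!(sz %in% c(5L, 6L))) next
    if (!all(g$atoms$element[r] %in% c("C", "N", "O", "S"))) next
    pi <- 0L
    ok <- TRUE
    for (a in r) {
      nb <- adj[[a]]
      hasCyclicDouble <- any(nb$order >= 2L & inRing[nb$nbr])
      hasExoDouble <- any(nb$order >= 2L & !inRing[nb$nbr])
      if (hasCyclicDouble) {
        pi <- pi + 1L
      } else if (g$atoms$element[a] %in% c("N", "O", "S") && !hasExoDouble) {
        pi <- pi + 2L
      } else if (hasExoDouble) {
        pi <- pi + 0L   # e.g. pyridone carbonyl carbon
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi == 6L) aromatic[r] <- TRUE
  }
  g$atoms$aromatic <- aromatic
  g$atoms$inRing <- inRing
  g$atoms$implicitH <- mgImplicitH(g)
  g
}

## Allowed valence for an atom given element + formal charge, taking the
## bond-order sum into account for hypervalent S/P.
mgValence <- function(element, charge, bondSum = 0L) {
  v <- unname(.MG_VALENCE[element])
  if (is.na(v)) return(NA_integer_)
  if (element %in% c("N", "O", "P", "S", "F", "Cl", "Br", "I")) {
    v <- v + charge
  } else if (element == "C") {
    v <- v - abs(charge)
  } else if (element == "B") {
    v <- v - charge   # borate B- is tetravalent
  }
  if (element == "S" && bondSum > v && bondSum %in% c(4L, 6L)) v <- bondSum
  if (element == "P" && bondSum > v && bondSum == 5L) v <- bondSum
  max(v, 0L)
}

mgBondSums <- function(g) {
  n <- nrow(g$atoms)
  bs <- rep(0L, n)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    bs[b$a1[i]] <- bs[b$a1[i]] + b$order[i]
    bs[b$a2[i]] <- bs[b$a2[i]] + b$order[i]
  }
  bs
}

mgImplicitH <- function(g) {
  bs <- mgBondSums(g)
  vapply(seq_len(nrow(g$atoms)), function(i) {
    v <- mgValence(g$atoms$element[i], g$atoms$charge[i], bs[i])
    if (is.na(v)) return(0L)
    as.integer(max(0L, v - bs[i]))
  }, integer(1))
}

mgDegree <- function(g) {
  n <- nrow(g$atoms)
  d <- rep(0L, n)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    d[b$a1[i]] <- d[b$a1[i]] + 1L
    d[b$a2[i]] <- d[b$a2[i]] + 1L
  }
  d
}

## Serialize a molgraph to a V2000 molblock (dummy coordinates).
mgToMolblock <- function(g) {
  n <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  header <- c("", " deNovoMol", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atomLines <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$atoms$element[i])
  }, character(1))
  bondLines <- vapply(seq_len(nb), function(i) {
    sprintf("%3d%3d%3d  0  0  0  0",
            g$bonds$a1[i], g$bonds$a2[i], g$bonds$order[i])
  }, character(1))
  chg <- which(g$atoms$charge != 0L)
  chgLines <- character(0)
  if (length(chg)) {
    ## up to 8 entries per M CHG line
    idx <- split(chg, ceiling(seq_along(chg) / 8))
    chgLines <- vapply(idx, function(ii) {
      paste0("M  CHG", sprintf("%3d", length(ii)),
             paste0(vapply(ii, function(i) {
               sprintf("%4d%4d", i, g$atoms$charge[i])
             }, character(1)), collapse = ""))
    }, character(1))
  }
  paste(c(header, counts, atomLines, bondLines, chgLines, "M  END", "$$$$", ""),
        collapse = "\n")
}

## Canonical SMILES of a molgraph ("" if Open Babel rejects it).
mgToSmiles <- function(g) {
  if (nrow(g$atoms) == 0L) return("")
  .obMolblockToSmiles(mgToMolblock(g))
}

## Induced subgraph on `atomIdx`; bonds leaving the set become attachment
## dummies ("*") when addDummies is TRUE. Atom order follows atomIdx.
mgSubgraph <- function(g, atomIdx, addDummies = TRUE) {
  remap <- match(seq_len(nrow(g$atoms)), atomIdx)
  atoms <- g$atoms[atomIdx, c("element", "charge"), drop = FALSE]
  rownames(atoms) <- NULL
  keep <- g$bonds$a1 %in% atomIdx & g$bonds$a2 %in% atomIdx
  bonds <- data.frame(a1 = remap[g$bonds$a1[keep]],
                      a2 = remap[g$bonds$a2[keep]],
                      order = g$bonds$order[keep])
  if (addDummies) {
    cut <- g$bonds[xor(g$bonds$a1 %in% atomIdx, g$bonds$a2 %in% atomIdx), ,
                   drop = FALSE]
    for (i in seq_len(nrow(cut))) {
      inAtom <- if (cut$a1[i] %in% atomIdx) cut$a1[i] else cut$a2[i]
      atoms <- rbind(atoms, data.frame(element = "*", charge = 0L))
      bonds <- rbind(bonds, data.frame(a1 = remap[inAtom],
                                       a2 = nrow(atoms),
                                       order = cut$order[i]))
    }
  }
  list(atoms = atoms, bonds = bonds)
}

## Strip attachment dummies from a fragment SMILES and recanonicalize.
#' Remove attachment points from a fragment SMILES
#'
#' BRICS/RECAP fragments carry `*` dummy atoms marking the cut bonds. This
#' removes them and returns the canonical SMILES of the bare fragment.
#'
#' @param fragment character vector of fragment SMILES.
#' @return character vector of canonical SMILES without attachment atoms.
#' @export
stripAttachment <- function(fragment) {
  vapply(fragment, function(f) {
    g <- mgFromSmiles(f)
    if (is.null(g)) return("")
    keep <- which(g$atoms$element != "*")
    if (!length(keep)) return("")
    mgToSmiles(mgSubgraph(g, keep, addDummies = FALSE))
  }, character(1), USE.NAMES = FALSE)
}

## Connected components as a list of atom-index vectors (stable order:
## component of the lowest-numbered unassigned atom first).
mgComponents <- function(g) {
  n <- nrow(g$atoms)
  adj <- mgAdjacency(g)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) {
        if (is.na(comp[w])) { comp[w] <- k; queue <- c(queue, w) }
      }
    }
  }
  split(seq_len(n), comp)
}

.MG_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
              P = 30.974, S = 32.06, F = 18.998, Cl = 35.45, Br = 79.904,
              I = 126.904, `*` = 0)

## Average molecular weight from the graph (implicit H included).
mgMolWeight <- function(g) {
  sum(.MG_MASS[g$atoms$element], na.rm = TRUE) +
    1.008 * sum(g$atoms$implicitH %||% mgImplicitH(g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- circular (Morgan-style) fingerprint -----------------------------------

## 2048-bit circular fingerprint, radius 2, on the kekulized graph. Atom
## invariants: element, charge, degree, implicit H, ring flag. Deterministic
## integer hashing in double arithmetic (stays well below 2^53).
mgMorganFingerprint <- function(g, nBits = 2048L, radius = 2L) {
  bits <- logical(nBits)
  if (is.null(g) || nrow(g$atoms) == 0L) return(bits)
  if (is.null(g$atoms$implicitH)) g <- mgPerceive(g)
  adj <- mgAdjacency(g)
  deg <- mgDegree(g)
  mix <- function(h, x) ((h * 31 + x) %% 2147483647)
  inv <- vapply(seq_len(nrow(g$atoms)), function(i) {
    h <- match(g$atoms$element[i], names(.MG_MASS))
    h <- mix(h, g$atoms$charge[i] + 10)
    h <- mix(h, deg[i])
    h <- mix(h, g$atoms$implicitH[i])
    mix(h, as.integer(g$atoms$inRing[i]))
  }, numeric(1))
  setBit <- function(h) bits[(h %% nBits) + 1L] <<- TRUE
  for (h in inv) setBit(h)
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- cur
    for (i in seq_along(cur)) {
      nb <- adj[[i]]
      if (!length(nb$nbr)) next
      ord <- order(nb$order * 1e9 + cur[nb$nbr])
      h <- mix(cur[i], r)
      for (j in ord) h <- mix(h, mix(nb$order[j], cur[nb$nbr[j]]))
      nxt[i] <- h
      setBit(h)
    }
    cur <- nxt
  }
  bits
}

#' Tanimoto similarity of two molecules
#'
#' Computes the Tanimoto coefficient between circular fingerprints
#' (2048-bit, radius 2) of two molecules.
#'
#' @param smiles1,smiles2 SMILES strings.
#' @return similarity in \[0, 1\]; `NA` if either molecule is unparsable.
#' @export
tanimotoSimilarity <- function(smiles1, smiles2) {
  g1 <- mgFromSmiles(smiles1)
  g2 <- mgFromSmiles(smiles2)
  if (is.null(g1) || is.null(g2)) return(NA_real_)
  f1 <- mgMorganFingerprint(g1)
  f2 <- mgMorganFingerprint(g2)
  u <- sum(f1 | f2)
  if (u == 0) return(0)
  sum(f1 & f2) / u
}
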