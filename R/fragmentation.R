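## Retrosynthetic fragmentation: BRICS and RECAP bond-cleavage rules.
##
## BRICS assigns each atom a set of chemical-environment labels (L1..L16) and
## cleaves acyclic single bonds whose two end labels form an allowed pair
## (plus the olefin 7-7 double-bond rule). The label predicates below
## implement the published SMARTS environments on the package's kekulized
## molecular graph; upper-case environments are aliphatic, lower-case
## aromatic, following SMARTS semantics.

.BRICS_PAIRS <- rbind(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16), c(16, 16))

## Environment labels for every atom. Returns a list of integer vectors.
.bricsLabels <- function(g) {
  adj <- mgAdjacency(g)
  deg <- mgDegree(g)
  at <- g$atoms
  n <- nrow(at)
  ringBond <- function(i, j) at$inRing[i] && at$inRing[j] &&
    .bondInRing(g, i, j)
  hasDoubleTo <- function(i, elem) {
    nb <- adj[[i]]
    any(nb$order == 2L & at$element[nb$nbr] %in% elem)
  }
  anyDouble <- function(i) any(adj[[i]]$order >= 2L)
  lab <- vector("list", n)
  for (i in seq_len(n)) {
    e <- at$element[i]; arom <- at$aromatic[i]
    nb <- adj[[i]]
    L <- integer(0)
    if (e == "C" && !arom) {
      if (deg[i] == 3L && hasDoubleTo(i, "O")) {
        L <- c(L, 1L)                                      # acyl
        if (!at$inRing[i]) L <- c(L, 6L)
      }
      if (deg[i] >= 2L && !anyDouble(i)) {
        if (any(at$element[nb$nbr] == "C")) L <- c(L, 4L)
        if (!at$inRing[i]) L <- c(L, 8L)
      }
      if (deg[i] %in% c(2L, 3L) && hasDoubleTo(i, "C") && !at$inRing[i])
        L <- c(L, 7L)                                      # olefin end
      if (at$inRing[i]) {
        inRingNbr <- vapply(seq_along(nb$nbr), function(k) {
          nb$order[k] == 1L && ringBond(i, nb$nbr[k])
        }, logical(1))
        rn <- nb$nbr[inRingNbr]
        if (length(rn) >= 2L) {
          if (any(at$element[rn] %in% c("N", "O", "S"))) L <- c(L, 13L)
          if (sum(at$element[rn] == "C") >= 2L) L <- c(L, 15L)
        }
      }
    }
    if (e == "C" && arom) {
      aromNbr <- nb$nbr[at$aromatic[nb$nbr] &
                        vapply(nb$nbr, function(j) ringBond(i, j), logical(1))]
      if (any(at$element[aromNbr] %in% c("N", "O", "S"))) L <- c(L, 14L)
      if (sum(at$element[aromNbr] == "C") >= 2L) L <- c(L, 16L)
    }
    if (e == "N" && !arom) {
      nbrOk <- all(at$element[nb$nbr] %in% c("C", "S", "*", "H"))
      lactam <- at$inRing[i] && any(vapply(seq_along(nb$nbr), function(k) {
        j <- nb$nbr[k]
        at$element[j] == "C" && at$inRing[j] && ringBond(i, j) &&
          any(adj[[j]]$order == 2L & at$element[adj[[j]]$nbr] == "O")
      }, logical(1)))
      if (deg[i] >= 2L && !anyDouble(i) && nbrOk && !lactam) L <- c(L, 5L)
      if (lactam) L <- c(L, 10L)
    }
    if (e == "N" && arom && at$charge[i] == 0L) L <- c(L, 9L)
    if (e == "O" && !arom && deg[i] == 2L &&
        any(nb$order == 1L & at$element[nb$nbr] %in% c("C", "*")))
      L <- c(L, 3L)
    if (e == "S" && !arom) {
      if (deg[i] == 2L && any(at$element[nb$nbr] %in% c("C", "*")))
        L <- c(L, 11L)
      if (deg[i] == 4L && sum(nb$order == 2L & at$element[nb$nbr] == "O") == 2L)
        L <- c(L, 12L)
    }
    lab[[i]] <- L
  }
  lab
}

.bondInRing <- function(g, i, j) {
  ## a bond is cyclic iff removing it leaves i and j connected
  adj <- mgAdjacency(g)
  seen <- rep(FALSE, nrow(g$atoms))
  seen[i] <- TRUE
  queue <- i
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]$nbr) {
      if (v == i && w == j) next
      if (!seen[w]) {
        if (w == j) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

## Indices (rows of g$bonds) of BRICS-cleavable bonds.
.bricsCleavableBonds <- function(g) {
  lab <- .bricsLabels(g)
  b <- g$bonds
  out <- integer(0)
  for (i in seq_len(nrow(b))) {
    if (.bondInRing(g, b$a1[i], b$a2[i])) next
    la <- lab[[b$a1[i]]]; lb <- lab[[b$a2[i]]]
    if (!length(la) || !length(lb)) next
    if (b$order[i] == 1L) {
      ok <- any(apply(.BRICS_PAIRS, 1, function(p) {
        (p[1] %in% la && p[2] %in% lb) || (p[1] %in% lb && p[2] %in% la)
      }))
      if (ok) out <- c(out, i)
    } else if (b$order[i] == 2L) {
      if (7L %in% la && 7L %in% lb) out <- c(out, i)
    }
  }
  out
}

## RECAP implemented as a reduced rule set over acyclic bonds: amide, ester,
## amine, urea (via amide), ether, olefin, quaternary N, aromatic N-aliphatic
## C, lactam N-aliphatic C, biaryl, sulfonamide.
.recapCleavableBonds <- function(g) {
  adj <- mgAdjacency(g)
  at <- g$atoms
  deg <- mgDegree(g)
  hasDoubleO <- function(i) any(adj[[i]]$order == 2L &
                                at$element[adj[[i]]$nbr] == "O")
  b <- g$bonds
  out <- integer(0)
  for (i in seq_len(nrow(b))) {
    a1 <- b$a1[i]; a2 <- b$a2[i]
    if (.bondInRing(g, a1, a2)) next
    e1 <- at$element[a1]; e2 <- at$element[a2]
    cut <- FALSE
    if (b$order[i] == 2L && e1 == "C" && e2 == "C" &&
        !at$aromatic[a1] && !at$aromatic[a2] &&
        deg[a1] >= 2L && deg[a2] >= 2L) cut <- TRUE          # olefin
    if (b$order[i] == 1L) {
      pr <- function(x, y) (e1 == x && e2 == y) || (e1 == y && e2 == x)
      ci <- if (e1 == "C") a1 else a2
      ni <- if (e1 == "N") a1 else if (e2 == "N") a2 else NA
      oi <- if (e1 == "O") a1 else if (e2 == "O") a2 else NA
      si <- if (e1 == "S") a1 else if (e2 == "S") a2 else NA
      if (pr("C", "N")) {
        nAr <- at$aromatic[ni]; cAr <- at$aromatic[ci]
        if (hasDoubleO(ci) && !cAr) cut <- TRUE              # amide / urea
        else if (at$charge[ni] == 1L && deg[ni] == 4L) cut <- TRUE  # quat N
        else if (nAr && !cAr) cut <- TRUE                    # arom N - aliph C
        else if (at$inRing[ni] && !cAr &&
                 any(vapply(adj[[ni]]$nbr, function(j)
                   at$element[j] == "C" && at$inRing[j] && hasDoubleO(j),
                   logical(1)))) cut <- TRUE                 # lactam N - C
        else if (!nAr && !cAr && deg[ni] >= 2L &&
                 !hasDoubleO(ci) &&
                 !any(vapply(adj[[ni]]$nbr, hasDoubleO, logical(1))))
          cut <- TRUE                                        # amine
      }
      if (!cut && pr("C", "O") && !at$aromatic[oi] && deg[oi] == 2L) {
        nbrC <- adj[[oi]]$nbr[at$element[adj[[oi]]$nbr] == "C"]
        if (length(nbrC) == 2L) {
          if (any(vapply(nbrC, hasDoubleO, logical(1)))) {
            ## ester: cut the O-C(sp3) bond, not the O-acyl bond
            if (!hasDoubleO(ci)) cut <- TRUE
          } else if (!at$inRing[oi]) cut <- TRUE             # ether
        }
      }
      if (!cut && pr("C", "C") && at$aromatic[a1] && at$aromatic[a2])
        cut <- TRUE                                          # biaryl
      if (!cut && !is.na(si) && !is.na(ni) &&
          sum(adj[[si]]$order == 2L &
              at$element[adj[[si]]$nbr] == "O") == 2L) cut <- TRUE # sulfonamide
    }
    if (cut) out <- c(out, i)
  }
  out
}

## Fragment a molecule graph; returns list(atomSets, cutBonds) where atomSets
## is a list of atom-index vectors (leaf fragments) and cutBonds the rows of
## g$bonds that were cleaved.
mgFragment <- function(g, method = c("BRICS", "RECAP")) {
  method <- match.arg(method)
  cut <- switch(method,
                BRICS = .bricsCleavableBonds(g),
                RECAP = .recapCleavableBonds(g))
  g2 <- g
  if (length(cut)) g2$bonds <- g$bonds[-cut, , drop = FALSE]
  comps <- mgComponents(g2)
  list(atomSets = comps, cutBonds = g$bonds[cut, , drop = FALSE])
}

#' Fragment a molecule with BRICS or RECAP rules
#'
#' Cleaves all bonds matched by one pass of the named retrosynthetic rule set
#' and returns the resulting leaf fragments as SMILES with `*` attachment
#' atoms marking the former bonds. A molecule with no cleavable bond is
#' returned unchanged as a single fragment. Deterministic for a fixed
#' canonical input.
#'
#' @param smiles a single valid SMILES string.
#' @param method `"BRICS"` (default) or `"RECAP"`.
#' @return character vector of fragment SMILES (duplicates kept).
#' @export
#' @examples
#' fragmentMolecule("CC(=O)Nc1ccc(O)cc1")  # 3 fragments
fragmentMolecule <- function(smiles, method = c("BRICS", "RECAP")) {
  method <- match.arg(method)
  g <- mgFromSmiles(smiles)
  if (is.null(g)) stop("fragmentMolecule: unparsable SMILES: ", smiles)
  fr <- mgFragment(g, method)
  if (length(fr$atomSets) == 1L && nrow(fr$cutBonds) == 0L) {
    return(canonicalSmiles(smiles))
  }
  vapply(fr$atomSets, function(idx) mgToSmiles(mgSubgraph(g, idx)),
         character(1), USE.NAMES = FALSE)
}
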