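## Deterministic toy corpus generation. Molecules are assembled from curated
## drug-like building blocks (aromatic/saturated rings, amide/ester/ether/
## sulfonamide/alkyl linkers, small substituents) combined combinatorially,
## which guarantees chemical validity without any external download. The
## generator emulates a small drug-like screening series: 2-3 ring systems
## joined by short synthetic linkers, MW tunable via the weight window.

## Ring patterns carry a "9" ring-closure digit (replaced per unit so nested
## rings never collide) and one "%s" attachment slot.
.FIX_RING_PAT <- c(
  "c9ccc(%s)cc9", "c9cc(%s)ccn9", "c9cc(F)cc(%s)c9", "c9cc(Cl)cc(%s)c9",
  "c9cc(C)cc(%s)c9", "c9cc(OC)cc(%s)c9", "C9CCN(%s)CC9", "C9CCC(%s)CC9",
  "C9CN(%s)CCO9", "c9csc(%s)c9")

.FIX_LINK_PAT <- c(
  "C(=O)N%s", "NC(=O)%s", "S(=O)(=O)N%s", "NS(=O)(=O)%s", "C(=O)OC%s",
  "OC(=O)%s", "CC%s", "CCC%s", "OCC%s", "OC%s", "N(C)C%s", "CNC(=O)%s",
  "C(=O)%s", "NC%s")

.FIX_RING_TERM <- c(
  "c9ccccc9", "c9ccncc9", "c9ccc(F)cc9", "c9ccc(Cl)cc9", "c9ccc(OC)cc9",
  "c9ccc(C)cc9", "C9CCCCC9", "C9CCOCC9", "c9ccc(C(F)(F)F)cc9", "c9ccsc9",
  "c9ccc(C#N)cc9", "c9ccc(O)cc9", "C9CCN(C)CC9")

.fixSampleBlock <- function(blocks, bias) {
  w <- rep(1, length(blocks))
  if (length(bias)) {
    for (el in names(bias)) {
      pat <- if (el %in% c("Cl", "Br")) el else
        ## match aromatic (lower-case) or aliphatic symbol, but not a symbol
        ## that merely prefixes a two-letter element (e.g. C in Cl)
        paste0("[", toupper(el), tolower(el), "](?![a-z])")
      hit <- grepl(pat, blocks, perl = TRUE)
      w[hit] <- w[hit] * bias[[el]]
    }
  }
  blocks[sample.int(length(blocks), 1L, prob = w / sum(w))]
}

#' Generate a deterministic toy corpus of drug-like molecules
#'
#' Assembles `n` unique, valid, organic molecules from curated building
#' blocks, all with molecular weight inside `weightRange`. Reproducible
#' under a fixed seed. `elementBias` multiplies the sampling weight of
#' building blocks containing the named elements, e.g. `c(N = 4)` enriches
#' nitrogen-containing output.
#'
#' @param n number of molecules.
#' @param seed integer RNG seed.
#' @param weightRange length-2 numeric, admissible MW window in Da.
#' @param elementBias optional named numeric vector of element weights.
#' @return character vector of `n` canonical SMILES.
#' @export
#' @examples
#' head(makeCorpus(5, seed = 1))
makeCorpus <- function(n, seed = 1L, weightRange = c(200, 500),
                       elementBias = NULL) {
  stopifnot(n >= 1L, length(weightRange) == 2L,
            weightRange[1] < weightRange[2])
  if (weightRange[2] < 120)
    stop("makeCorpus: infeasible weight range (no building-block ",
         "combination is that light)")
  out <- character(0)
  .withSeed(seed, {
    tries <- 0L
    maxTries <- 400L * n
    while (length(out) < n && tries < maxTries) {
      tries <- tries + 1L
      nRings <- sample(2:3, 1L)
      units <- character(0)
      for (k in seq_len(nRings - 1L)) {
        units <- c(units, .fixSampleBlock(.FIX_RING_PAT, elementBias),
                   .fixSampleBlock(.FIX_LINK_PAT, elementBias))
      }
      units <- c(units, .fixSampleBlock(.FIX_RING_TERM, elementBias))
      ## assign a distinct ring digit per unit, innermost last
      smi <- "%s"
      for (k in seq_along(units)) {
        u <- gsub("9", as.character(k), units[k], fixed = TRUE)
        smi <- sprintf(smi, u)
      }
      can <- canonicalSmiles(smi)
      if (!nzchar(can) || can %in% out) next
      props <- .obProps(can)
      if (is.null(props)) next
      mw <- as.numeric(props$MW)
      if (mw < weightRange[1] || mw > weightRange[2]) next
      out <- c(out, can)
    }
  })
  if (length(out) < n)
    stop("makeCorpus: could not assemble ", n,
         " unique molecules in the requested weight range")
  out
}

#' Toy two-objective scoring environment
#'
#' A small environment used throughout the test suite and examples:
#' molecular weight passed through a Smooth Hump modifier with full score
#' between 250 and 400 Da, and a binary contains-nitrogen objective with an
#' identity modifier; both thresholds 0.5. Ranking scheme is the dynamic
#' weighted sum unless overridden.
#'
#' @param scheme ranking scheme, one of `"WS"`, `"PRCD"`, `"PRTD"`.
#' @return a [ScoringEnvironment-class].
#' @export
makeEnvToy <- function(scheme = c("WS", "PRCD", "PRTD")) {
  scheme <- match.arg(scheme)
  scoringEnvironment(
    objectives = list(
      objective(scorerMolWeight(),
                modifierSmoothHump(lower = 250, upper = 400, width = 50),
                threshold = 0.5),
      objective(scorerElementPresence("N"), modifierIdentity(),
                threshold = 0.5)),
    scheme = scheme)
}
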