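## Multiobjective reward schemes: dynamic weighted sum (WS) and Pareto
## ranking with crowding-distance (PRCD) or Tanimoto-distance (PRTD)
## intra-front ordering.

#' Dynamic weighted-sum reward
#'
#' Per-batch weights are proportional to one minus each objective's column
#' mean, so the worst-performing objective of the current population gets
#' the largest weight; rewards are the weighted row sums. With a single
#' objective the column is returned unchanged.
#'
#' @param modified n x k matrix of modified scores in \[0, 1\].
#' @return numeric vector of n rewards in \[0, 1\].
#' @export
weightedSumReward <- function(modified) {
  modified <- as.matrix(modified)
  k <- ncol(modified)
  if (k == 0L) stop("weightedSumReward: at least one objective required")
  w <- 1 - colMeans(modified)
  if (sum(w) == 0) w <- rep(1, k)   # every column perfect: equal weights
  w <- w / sum(w)
  as.numeric(modified %*% w)
}

#' Non-dominated sorting into Pareto fronts
#'
#' All objectives are maximized. Front 1 holds the non-dominated points;
#' each later front is non-dominated once earlier fronts are removed.
#' Identical rows share a front. Standard domination-count sorting.
#'
#' @param modified n x k matrix of finite scores.
#' @return list of integer vectors (row indices), front 1 first.
#' @export
nonDominatedSort <- function(modified) {
  modified <- as.matrix(modified)
  n <- nrow(modified)
  if (n == 0L) return(list())
  dominates <- function(i, j) {
    all(modified[i, ] >= modified[j, ]) && any(modified[i, ] > modified[j, ])
  }
  domCount <- rep(0L, n)
  dominated <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) dominated[[i]] <- c(dominated[[i]], j)
      else if (dominates(j, i)) domCount[i] <- domCount[i] + 1L
    }
  }
  fronts <- list()
  cur <- which(domCount == 0L)
  while (length(cur)) {
    fronts[[length(fronts) + 1L]] <- cur
    nxt <- integer(0)
    for (i in cur) {
      for (j in dominated[[i]]) {
        domCount[j] <- domCount[j] - 1L
        if (domCount[j] == 0L) nxt <- c(nxt, j)
      }
    }
    cur <- sort(unique(nxt))
  }
  fronts
}

#' NSGA-II crowding distance within one front
#'
#' Boundary points on any objective get infinite distance; interior points
#' get the sum over objectives of the normalized gap between their two
#' neighbors in that objective's sorted order.
#'
#' @param frontScores m x k matrix of scores of one front's members.
#' @return numeric vector of m distances (may contain `Inf`).
#' @export
crowdingDistance <- function(frontScores) {
  frontScores <- as.matrix(frontScores)
  m <- nrow(frontScores)
  if (m <= 2L) return(rep(Inf, m))
  d <- rep(0, m)
  for (j in seq_len(ncol(frontScores))) {
    ord <- order(frontScores[, j])
    rng <- frontScores[ord[m], j] - frontScores[ord[1], j]
    d[ord[c(1, m)]] <- Inf
    if (rng > 0) {
      for (i in 2:(m - 1)) {
        d[ord[i]] <- d[ord[i]] +
          (frontScores[ord[i + 1], j] - frontScores[ord[i - 1], j]) / rng
      }
    }
  }
  d
}

#' Structural-diversity ranking within a Pareto front
#'
#' Scores each molecule by its mean Tanimoto distance (1 - similarity on
#' 2048-bit circular fingerprints) to the other members of the front; more
#' distant (more structurally distinctive) molecules rank better. Ties are
#' broken deterministically on canonical SMILES order.
#'
#' @param smiles SMILES of the front's members.
#' @return integer ranking permutation: position 1 is the best-ranked
#'   member's index.
#' @export
tanimotoDistanceRank <- function(smiles) {
  m <- length(smiles)
  if (m <= 1L) return(seq_len(m))
  fps <- lapply(smiles, function(s) mgMorganFingerprint(mgFromSmiles(s)))
  meanDist <- vapply(seq_len(m), function(i) {
    mean(vapply(seq_len(m)[-i], function(j) {
      u <- sum(fps[[i]] | fps[[j]])
      1 - if (u == 0) 0 else sum(fps[[i]] & fps[[j]]) / u
    }, numeric(1)))
  }, numeric(1))
  order(-meanDist, canonicalSmiles(smiles))
}

#' Map Pareto fronts and intra-front order to scalar rewards
#'
#' Builds the global order (front rank first, intra-front distance order
#' within each front) and assigns rewards by linear interpolation: desired
#' compounds are spread over \[0.5, 1\] (best first), undesired compounds
#' over \[0, 0.5). Within each class the mapping is order-isomorphic.
#'
#' @param fronts list of index vectors from [nonDominatedSort()].
#' @param intraOrder list parallel to `fronts`: for each front, a ranking
#'   permutation of its members (best first), e.g. from
#'   [crowdingDistance()] order or [tanimotoDistanceRank()].
#' @param desiredFlags logical vector over all molecules.
#' @return numeric rewards in \[0, 1\].
#' @export
rankToReward <- function(fronts, intraOrder, desiredFlags) {
  globalOrder <- unlist(lapply(seq_along(fronts), function(f) {
    fronts[[f]][intraOrder[[f]]]
  }))
  n <- length(desiredFlags)
  stopifnot(length(globalOrder) == n)
  reward <- numeric(n)
  des <- globalOrder[desiredFlags[globalOrder]]
  und <- globalOrder[!desiredFlags[globalOrder]]
  nd <- length(des); nu <- length(und)
  if (nd == 1L) reward[des] <- 1
  else if (nd > 1L) reward[des] <- 1 - 0.5 * (seq_len(nd) - 1) / (nd - 1)
  if (nu > 0L) reward[und] <- 0.5 * (nu - seq_len(nu)) / nu
  reward
}

#' Assign scalar rewards to a scored batch
#'
#' Applies the environment's ranking scheme to the modified-score matrix of
#' `tab`. `"WS"` uses [weightedSumReward()]; `"PRCD"` and `"PRTD"` sort the
#' batch into Pareto fronts and rank within fronts by crowding distance or
#' mean Tanimoto distance respectively, then map the global order to
#' \[0, 1\] with [rankToReward()].
#'
#' @param env a [ScoringEnvironment-class].
#' @param tab a [ScoreTable-class].
#' @return `tab` with its reward slot filled.
#' @export
assignRewards <- function(env, tab) {
  mod <- tab@modified
  if (env@scheme == "WS") {
    tab@reward <- weightedSumReward(mod)
    return(tab)
  }
  fronts <- nonDominatedSort(mod)
  intra <- lapply(fronts, function(f) {
    if (env@scheme == "PRCD") {
      d <- crowdingDistance(mod[f, , drop = FALSE])
      order(-d, canonicalSmiles(tab@smiles[f]))
    } else {
      tanimotoDistanceRank(tab@smiles[f])
    }
  })
  tab@reward <- rankToReward(fronts, intra, tab@desired)
  tab
}
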