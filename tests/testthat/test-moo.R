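test_that("weighted-sum rewards use dynamic worst-objective weights", {
  ## single objective: rewards are the column itself
  m <- matrix(c(0.2, 0.9, 0.5), ncol = 1)
  expect_equal(weightedSumReward(m), as.numeric(m))
  ## equal column means: equal weights, reward = row mean
  m2 <- rbind(c(0.2, 0.8), c(0.8, 0.2))
  expect_equal(weightedSumReward(m2), rowMeans(m2))
  ## column means 0.9 and 0.1: weights (1-0.9, 1-0.1)/sum = (0.1, 0.9),
  ## so the worst-performing objective dominates the reward
  m3 <- rbind(c(0.9, 0.1), c(0.9, 0.1))
  expect_equal(weightedSumReward(m3), rep(0.1 * 0.9 + 0.9 * 0.1, 2))
  expect_error(weightedSumReward(matrix(numeric(0), 2, 0)), "objective")
})

test_that("weighted sum is row-permutation equivariant", {
  set.seed(5)
  m <- matrix(runif(30), 10, 3)
  perm <- sample(10)
  expect_equal(weightedSumReward(m[perm, ]), weightedSumReward(m)[perm])
})

test_that("non-dominated sorting handles canonical configurations", {
  ## mutually non-dominating triangle
  f <- nonDominatedSort(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  expect_length(f, 1)
  expect_setequal(f[[1]], 1:3)
  ## a dominating point takes front 1 alone
  f2 <- nonDominatedSort(rbind(c(1, 1), c(0.3, 0.9)))
  expect_identical(f2, list(1L, 2L))
  ## identical rows share a front
  f3 <- nonDominatedSort(rbind(c(1, 0), c(1, 0)))
  expect_length(f3, 1)
})

test_that("non-dominated sorting matches the brute-force oracle", {
  set.seed(42)
  for (rep in seq_len(200)) {
    n <- sample(5:60, 1)
    k <- sample(2:4, 1)
    m <- matrix(round(runif(n * k), 2), n, k)
    got <- nonDominatedSort(m)
    want <- oracleParetoFronts(m)
    expect_identical(lapply(got, sort), lapply(want, sort))
  }
})

test_that("adding a dominated point never changes front 1", {
  set.seed(7)
  for (rep in seq_len(20)) {
    m <- matrix(runif(24), 8, 3)
    front1 <- sort(nonDominatedSort(m)[[1]])
    dominated <- pmax(m[sample(8, 1), ] - 0.2, 0)
    m2 <- rbind(m, dominated)
    expect_identical(sort(nonDominatedSort(m2)[[1]]), front1)
  }
})

test_that("crowding distance follows the NSGA-II definition", {
  expect_identical(crowdingDistance(matrix(0.3, 1, 2)), Inf)
  expect_identical(crowdingDistance(rbind(c(0, 0), c(1, 1))), c(Inf, Inf))
  ## five points on one objective: interior distances are the normalized
  ## neighbor gaps, boundaries infinite
  m <- matrix(c(0, 0.1, 0.4, 0.8, 1), ncol = 1)
  d <- crowdingDistance(m)
  expect_identical(d[c(1, 5)], c(Inf, Inf))
  expect_equal(d[2:4], c(0.4 - 0, 0.8 - 0.1, 1 - 0.4), tolerance = 1e-12)
})

test_that("Tanimoto intra-front ranking favors the structural outlier", {
  ## duplicates tie at distance 0; the dissimilar molecule ranks first
  front <- c("CCO", "CCO", "c1ccc(cc1)C(F)(F)F")
  rk <- tanimotoDistanceRank(front)
  expect_identical(rk[1], 3L)
  expect_identical(tanimotoDistanceRank("CCO"), 1L)
  ## identical molecules: deterministic tie-break
  expect_identical(tanimotoDistanceRank(c("CCO", "CCO")),
                   tanimotoDistanceRank(c("CCO", "CCO")))
})

test_that("rank-to-reward maps the global order into [0, 1]", {
  ## all desired, single front of three: 1.0, 0.75, 0.5
  r <- rankToReward(list(1:3), list(1:3), rep(TRUE, 3))
  expect_equal(r, c(1, 0.75, 0.5))
  ## single compound: 1 when desired, 0 when not
  expect_equal(rankToReward(list(1L), list(1L), TRUE), 1)
  expect_equal(rankToReward(list(1L), list(1L), FALSE), 0)
  ## undesired compounds stay below 0.5, desired at or above
  des <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  r2 <- rankToReward(list(1:5), list(1:5), des)
  expect_true(all(r2[des] >= 0.5))
  expect_true(all(r2[!des] < 0.5))
  expect_true(all(r2 >= 0 & r2 <= 1))
  ## order isomorphism within each class
  expect_true(all(diff(r2[des]) < 0))
  expect_true(all(diff(r2[!des]) < 0))
})

test_that("all three schemes reward a perfect compound maximally", {
  smi <- c("NCCc1ccc(O)cc1", "CCO", "CCCC")
  mod <- rbind(c(1, 1), c(0.4, 0.2), c(0.1, 0.9))
  des <- c(TRUE, FALSE, FALSE)
  for (scheme in c("WS", "PRCD", "PRTD")) {
    env <- scoringEnvironment(list(
      objective(scorerElementPresence("N"), modifierIdentity(), 0.5),
      objective(scorerElementPresence("O"), modifierIdentity(), 0.5)),
      scheme = scheme)
    tab <- new("ScoreTable", smiles = smi, raw = mod, modified = mod,
               desired = des, reward = rep(0, 3), thresholds = c(0.5, 0.5))
    r <- rewards(assignRewards(env, tab))
    expect_true(all(r >= 0 & r <= 1))
    expect_identical(which.max(r), 1L)
  }
})
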