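test_that("clipped linear modifier follows the ramp contract", {
  m <- modifierClipped(0, 10)
  expect_equal(m(10), 1)
  expect_equal(m(5), 0.5)       # midpoint of the linear ramp
  expect_equal(m(-3), 0)
  ## reversed ramp: low > high means smaller raw scores are better
  r <- modifierClipped(2, 1)
  expect_equal(r(1.5), 0.5)
  expect_equal(r(1), 1)
  expect_equal(r(2), 0)
  expect_error(modifierClipped(1, 1), "differ")
})

test_that("Gaussian modifier has unit peak and exponential decay", {
  g <- modifierGaussian(center = 3, sigma = 2)
  expect_equal(g(3), 1)
  expect_equal(g(5), exp(-1 / 2), tolerance = 1e-12)
  ## monotone decreasing in the distance from the center
  d <- sort(unique(abs(seq(-10, 16, length.out = 101) - 3)))
  expect_true(all(diff(g(3 + d)) <= 1e-12))
  expect_true(all(diff(g(3 - d)) <= 1e-12))
  expect_error(modifierGaussian(0, 0), "positive")
})

test_that("smooth hump plateaus at 1 between its bounds and is symmetric", {
  h <- modifierSmoothHump(lower = 250, upper = 400, width = 50)
  ## full score for molecular weights inside the 250-400 Da plateau
  expect_equal(h(325), 1, tolerance = 1e-6)
  expect_lt(h(1e5), 1e-6)
  expect_lt(h(-1e5), 1e-6)
  for (delta in c(10, 40, 120)) {
    expect_equal(h(250 - delta), h(400 + delta), tolerance = 1e-9)
  }
  expect_error(modifierSmoothHump(2, 1, 1), "lower")
  expect_error(modifierSmoothHump(1, 2, 0), "positive")
})

test_that("all modifiers stay inside [0, 1] over a dense grid", {
  grid <- seq(-500, 1500, length.out = 10000)
  for (m in list(modifierClipped(100, 600), modifierClipped(600, 100),
                 modifierGaussian(300, 80),
                 modifierSmoothHump(250, 400, 50),
                 modifierIdentity())) {
    y <- m(grid)
    expect_true(all(y >= 0 & y <= 1))
  }
  ## monotonicity of the clipped ramps
  y <- modifierClipped(100, 600)(grid)
  expect_true(all(diff(y) >= 0))
  y <- modifierClipped(600, 100)(grid)
  expect_true(all(diff(y) <= 0))
})

test_that("built-in scorers produce reference values", {
  expect_equal(scorerMolWeight()$fun("C"), 16.04, tolerance = 0.01)
  expect_equal(scorerTanimoto("CC(=O)Nc1ccc(O)cc1")$fun("CC(=O)Nc1ccc(O)cc1"),
               1)
  ## zero affinity gives zero ligand efficiency
  expect_equal(scorerLigandEfficiency(0)$fun("c1ccccc1"), 0)
  expect_identical(scorerElementPresence("N")$fun(c("CCN", "CCO")), c(1, 0))
  ## invalid SMILES score as missing
  expect_true(is.na(scorerMolWeight()$fun("not_a_smiles")))
  expect_true(is.na(scorerLogP()$fun("xx(")))
})

test_that("batch scoring applies the all-thresholds desirability rule", {
  env <- scoringEnvironment(list(
    objective(scorerElementPresence("N"), modifierIdentity(), 0.5),
    objective(scorerMolWeight(), modifierClipped(0, 100), 0.5)))
  tab <- scoreBatch(env, c("NCCCN", "CCO", "bogus("))
  expect_true(desired(tab)[1])      # both objectives above threshold
  expect_false(desired(tab)[2])     # nitrogen objective below threshold
  expect_false(desired(tab)[3])     # invalid: never desired
  expect_identical(unname(modifiedScores(tab)[3, ]), c(0, 0))
  expect_true(all(modifiedScores(tab) >= 0 & modifiedScores(tab) <= 1))
  expect_identical(dim(rawScores(tab)), c(3L, 2L))
})

test_that("a failing scorer is skipped with a warning, not fatal", {
  env <- scoringEnvironment(list(
    objective(scorerElementPresence("N"), modifierIdentity(), 0.5),
    objective(scorerCustom("broken", function(s) stop("boom")),
              modifierIdentity(), 0.5)))
  expect_warning(tab <- scoreBatch(env, c("NCC", "CCO")), "broken")
  expect_true(all(is.na(rawScores(tab)[, "broken"])))
  ## the failed objective does not veto desirability
  expect_true(desired(tab)[1])
})

test_that("environment configs round-trip through YAML and JSON", {
  tmp <- withr::local_tempdir()
  env <- makeEnvToy(scheme = "PRCD")
  for (ext in c("yml", "json")) {
    p <- file.path(tmp, paste0("env.", ext))
    writeEnvironmentConfig(env, p)
    env2 <- readEnvironmentConfig(p)
    expect_identical(env2@scheme, "PRCD")
    expect_length(env2@objectives, 2)
    ## behaviourally identical on a probe batch
    probe <- c("CCN", fixtureCorpus(3))
    t1 <- scoreBatch(env, probe)
    t2 <- scoreBatch(env2, probe)
    expect_equal(modifiedScores(t2), modifiedScores(t1))
    expect_identical(desired(t2), desired(t1))
  }
})
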