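test_that("mixed sampling follows the mutation-rate contract", {
  prior <- fixturePrior()
  agent <- prior
  b0 <- mixedSample(agent, prior, epsilon = 0, n = 12, seed = 3, maxLen = 40)
  expect_true(all(attr(b0, "provenance") == "agent"))
  b1 <- mixedSample(agent, prior, epsilon = 1, n = 12, seed = 3, maxLen = 40)
  expect_true(all(attr(b1, "provenance") == "prior"))
  ## epsilon = 0.5 with a large batch: prior fraction within 3 binomial
  ## standard deviations of 0.5 (tiny throwaway model keeps this fast)
  sv <- buildSmilesVocab("CCO")
  tiny <- rnnGenerator(sv, nLayers = 1, embeddingSize = 2, hiddenSize = 2,
                       seed = 1)
  bb <- mixedSample(tiny, tiny, epsilon = 0.5, n = 10000, seed = 11,
                    maxLen = 3)
  frac <- mean(attr(bb, "provenance") == "prior")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("policy-gradient loss follows the REINFORCE formula", {
  prior <- fixturePrior()
  smi <- sampleMolecules(prior, 6, seed = 21, maxLen = 60)
  smi <- as.character(smi)
  ## all rewards zero: parameters unchanged, loss zero
  upd0 <- policyGradientUpdate(prior, smi, rep(0, 6))
  expect_identical(upd0$agent@params, prior@params)
  expect_equal(upd0$loss, 0)
  ## single molecule with reward 1: loss equals its sequence NLL sum
  one <- policyGradientUpdate(prior, smi[1], 1, learningRate = 0)
  codes <- matrix(c(2L, deNovoMol:::.svCode(prior@vocab,
                                            tokenizeSmiles(smi[1])), 3L),
                  nrow = 1)
  o <- deNovoMol:::opsPlain(prior@params)
  nll <- deNovoMol:::.rnnLossForward(o, prior, codes,
                                     seqWeights = 1)$loss
  expect_equal(one$loss, nll, tolerance = 1e-9)
  ## doubling rewards doubles the loss (linearity)
  r <- runif(6)
  l1 <- policyGradientUpdate(prior, smi, r, learningRate = 0)$loss
  l2 <- policyGradientUpdate(prior, smi, 2 * r, learningRate = 0)$loss
  expect_equal(l2, 2 * l1, tolerance = 1e-9)
})

test_that("epoch metrics match their definitions on crafted batches", {
  env <- makeEnvToy()
  ## n copies of one valid molecule: unique ratio 1/n
  batch <- rep(fixtureCorpus(1), 4)
  tab <- scoreBatch(env, batch)
  m <- computeMetrics(batch, tab)
  expect_equal(m$unique_ratio, 1 / 4)
  expect_equal(m$valid_ratio, 1)
  ## all invalid: zero ratios and zero means
  bad <- c("xx(", "yy)", ")(")
  m2 <- computeMetrics(bad, scoreBatch(env, bad))
  expect_equal(m2$valid_ratio, 0)
  expect_equal(m2$mean_arithmetic, 0)
  expect_equal(m2$mean_geometric, 0)
  ## hand-built 4-molecule batch with 2 desired
  mols <- c("NCCc1ccc(CC2CCNCC2)cc1",   # ~250 Da, has N -> desired
            "NCCCNCCCCc1ccc(O)cc1O",    # in-hump, has N -> desired
            "CCO",                      # light, no N
            "OCCOCCO")                  # light, no N
  tab3 <- scoreBatch(env, mols)
  m3 <- computeMetrics(mols, tab3)
  expect_equal(m3$desired_ratio, 0.5)
  ## geometric mean never exceeds arithmetic mean
  expect_lte(m3$mean_geometric, m3$mean_arithmetic + 1e-12)
})

test_that("accuracy counts outputs containing all their input fragments", {
  batch <- c("CC(=O)Nc1ccc(O)cc1", "CCO")
  env <- makeEnvToy()
  m <- computeMetrics(batch, scoreBatch(env, batch),
                      fragmentInputs = c("Oc1ccccc1", "Oc1ccccc1"))
  expect_equal(m$accurate_ratio, 0.5)
})

test_that("the explorer improves desirability on the toy objective", {
  prior <- fixturePrior()
  env <- makeEnvToy()
  improved <- vapply(1:5, function(seed) {
    rl <- rlTrain(prior, prior, env,
                  explorerConfig(epochs = 10, batchSize = 32,
                                 epsilon = 0.1, learningRate = 0.01,
                                 syncInterval = 5, seed = seed,
                                 maxLen = 90))
    rl$log$desired[rl$log$epoch == rl$bestEpoch][1] > rl$log$desired[1]
  }, logical(1))
  expect_gte(sum(improved), 4)
})

test_that("the RL loop honors its scheduling and no-op contracts", {
  prior <- fixturePrior()
  env <- makeEnvToy()
  ## zero epochs: agent returned untouched with an empty log
  rl0 <- rlTrain(prior, prior, env, explorerConfig(epochs = 0))
  expect_identical(rl0$agent@params, prior@params)
  expect_identical(nrow(rl0$log), 0L)
  ## auxiliary network refresh epochs for syncInterval 5 over 12 epochs
  rl <- rlTrain(prior, prior, env,
                explorerConfig(epochs = 12, batchSize = 8, epsilon = 0.2,
                               syncInterval = 5, learningRate = 0.005,
                               seed = 2, maxLen = 60,
                               usePeriodicAgent = TRUE))
  expect_identical(rl$syncEpochs, c(5L, 10L))
  ## epsilon 1 with zero learning rate leaves the agent bit-identical
  rlFrozen <- rlTrain(prior, prior, env,
                      explorerConfig(epochs = 2, batchSize = 8, epsilon = 1,
                                     learningRate = 0, seed = 3,
                                     maxLen = 60))
  expect_identical(rlFrozen$agent@params, prior@params)
  ## geometric <= arithmetic on every logged epoch
  expect_true(all(rl$log$mean_geometric <= rl$log$mean_arithmetic + 1e-12))
})

test_that("logged metrics are reproducible from the saved epoch tables", {
  prior <- fixturePrior()
  env <- makeEnvToy()
  tmp <- withr::local_tempdir()
  rl <- rlTrain(prior, prior, env,
                explorerConfig(epochs = 2, batchSize = 16, epsilon = 0.1,
                               learningRate = 0.005, seed = 4, maxLen = 60),
                outDir = tmp)
  for (e in rl$log$epoch) {
    tab <- read.delim(file.path(tmp, sprintf("epoch_%03d.tsv", e)))
    expect_equal(mean(tab$desired), rl$log$desired[rl$log$epoch == e])
  }
  expect_true(file.exists(file.path(tmp, "rl_log.tsv")))
  expect_true(file.exists(file.path(tmp, "agent_best.rds")))
})
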