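test_that("generator constructors expose the declared architecture", {
  sv <- fixtureSmilesVocab()
  gen <- rnnGenerator(sv)
  expect_identical(gen@hyper$nLayers, 3L)      # default recurrent depth
  expect_identical(gen@hyper$cell, "LSTM")
  expect_error(seqTransformer(sv, nHeads = 3, modelDim = 32), "divisible")
  gv <- fixtureGraphVocab()
  gt <- graphTransformer(gv)
  expect_s4_class(gt, "GraphTransformer")
})

test_that("pretraining reduces the held-out loss and stops on patience", {
  corp <- fixtureCorpus(40)
  sv <- fixtureSmilesVocab()
  gen <- rnnGenerator(sv, cell = "GRU", nLayers = 1, embeddingSize = 16,
                      hiddenSize = 24, seed = 3)
  cfg <- trainConfig(epochs = 6, batchSize = 16, learningRate = 0.01,
                     patience = 6, seed = 5)
  fit <- pretrainGenerator(gen, corp, cfg)
  expect_lt(fit$log$testLoss[fit$bestEpoch], fit$log$testLoss[1])
  expect_identical(nrow(fit$log), 6L)
  ## identical seeds give identical logs
  fit2 <- pretrainGenerator(gen, corp, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$generator@params, fit2$generator@params)
  ## zero epochs: weights unchanged
  fit0 <- pretrainGenerator(gen, corp, trainConfig(epochs = 0))
  expect_identical(fit0$generator@params, gen@params)
  ## patience 0 stops at the first non-improving epoch
  fitP <- pretrainGenerator(gen, corp,
                            trainConfig(epochs = 50, patience = 0,
                                        batchSize = 16, seed = 5,
                                        learningRate = 0.3))
  firstFlat <- which(diff(fitP$log$testLoss) >= 0)[1] + 1L
  expect_identical(nrow(fitP$log), firstFlat)
})

test_that("fine-tuning shifts sampling toward the tuning chemistry", {
  prior <- fixturePrior()
  before <- sampleMolecules(prior, 500, seed = 31, maxLen = 90)
  canB <- canonicalSmiles(before)
  fracN <- function(x) mean(grepl("[Nn]", x[nzchar(x)]))
  nRich <- makeCorpus(60, seed = 9, weightRange = c(250, 420),
                      elementBias = c(N = 8))
  fit <- finetuneGenerator(prior, nRich,
                           trainConfig(epochs = 5, batchSize = 16,
                                       learningRate = 0.01, patience = 5,
                                       seed = 13))
  after <- sampleMolecules(fit$generator, 500, seed = 31, maxLen = 90)
  canA <- canonicalSmiles(after)
  expect_gt(fracN(canA), fracN(canB))
  expect_error(finetuneGenerator(prior, character(0), trainConfig()),
               "empty")
})

test_that("fine-tuning rejects corpora outside the model vocabulary", {
  sv <- buildSmilesVocab("CCO")
  gen <- rnnGenerator(sv, nLayers = 1, embeddingSize = 4, hiddenSize = 6)
  expect_error(finetuneGenerator(gen, "CCBr", trainConfig(epochs = 1)),
               "Br")
})

test_that("sampling respects the conditioning contract per architecture", {
  prior <- fixturePrior()
  expect_identical(sampleMolecules(prior, 0), character(0))
  expect_warning(sampleMolecules(prior, 2, inputs = "CCO", seed = 1),
                 "ignored")
  sv <- fixtureSmilesVocab()
  stg <- seqTransformer(sv, nLayers = 1, modelDim = 16, ffDim = 24, seed = 1)
  expect_error(sampleMolecules(stg, 3), "inputs")
  gt <- graphTransformer(fixtureGraphVocab(), modelDim = 16, ffDim = 24,
                         decHidden = 24, seed = 1)
  expect_error(sampleMolecules(gt, 3), "inputs")
  ## same seed, same samples
  s1 <- sampleMolecules(prior, 20, seed = 99, maxLen = 80)
  s2 <- sampleMolecules(prior, 20, seed = 99, maxLen = 80)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("an untrained graph transformer already samples valid molecules", {
  ## validity is enforced by valence masking, not by training
  gt <- graphTransformer(fixtureGraphVocab(), modelDim = 16, ffDim = 24,
                         decHidden = 24, maxAtoms = 60, seed = 8)
  frags <- vapply(fixtureCorpus(10), function(s) {
    paste(stripAttachment(fragmentMolecule(s))[1], collapse = ".")
  }, character(1))
  smi <- sampleMolecules(gt, 30, inputs = frags, seed = 4, maxLen = 25)
  can <- canonicalSmiles(as.character(smi))
  expect_identical(mean(nzchar(can)), 1)
  ## fragment incorporation is measurable and mostly holds by construction
  inc <- vapply(seq_along(can), function(i) {
    fr <- strsplit(attr(smi, "inputs")[i], ".", fixed = TRUE)[[1]]
    all(vapply(fr, function(f) isTRUE(hasSubstructure(can[i], f)),
               logical(1)))
  }, logical(1))
  expect_gt(mean(inc), 0.7)
})

test_that("sequence transformer trains on fragment pairs and samples", {
  corp <- fixtureCorpus(15)
  pairs <- enumerateFragmentPairs(standardizeMolecules(corp),
                                  prepConfig(maxFragments = 2,
                                             maxSubsets = 2))
  sv <- buildSmilesVocab(c(corp, pairs$Frags))
  stg <- seqTransformer(sv, nLayers = 1, modelDim = 16, ffDim = 24, seed = 2)
  fit <- pretrainGenerator(stg, pairs,
                           trainConfig(epochs = 3, batchSize = 8,
                                       patience = 3, seed = 2))
  expect_identical(nrow(fit$log), 3L)
  expect_lt(fit$log$testLoss[3], fit$log$testLoss[1] + 0.5)
  smi <- sampleMolecules(fit$generator, 5, inputs = pairs$Frags[1:5],
                         seed = 3, maxLen = 40)
  expect_length(as.character(smi), 5)
})

test_that("checkpoints round-trip and refuse corrupted vocabularies", {
  tmp <- withr::local_tempdir()
  gen <- rnnGenerator(fixtureSmilesVocab(), nLayers = 1,
                      embeddingSize = 8, hiddenSize = 8, seed = 2)
  p <- file.path(tmp, "gen.rds")
  saveGenerator(gen, p)
  back <- loadGenerator(p)
  expect_identical(back@params, gen@params)
  expect_identical(back@vocab@tokens, gen@vocab@tokens)
  ## tamper with the stored vocabulary: hash check must refuse
  obj <- readRDS(p)
  obj$vocabData$tokens[5] <- "Xx"
  saveRDS(obj, p)
  expect_error(loadGenerator(p), "hash mismatch")
})
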