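test_that("nllLoss matches closed forms", {
  ## a model assigning probability 1 to every target
  p <- diag(4)
  expect_equal(nllLoss(p, 1:4), 0, tolerance = 1e-9)
  ## uniform model over V tokens: loss = ln V, for several V
  for (V in c(2, 7, 31)) {
    p <- matrix(1 / V, 5, V)
    expect_equal(nllLoss(p, rep(1L, 5)), log(V), tolerance = 1e-12)
  }
  ## hand-computed 3-token example
  p <- rbind(c(0.5, 0.5), c(0.25, 0.75), c(0.25, 0.75))
  expect_equal(nllLoss(p, c(1L, 1L, 1L)),
               -(log(0.5) + log(0.25) + log(0.25)) / 3, tolerance = 1e-12)
  expect_error(nllLoss(p, 1:2), "one target per")
})

test_that("reverse-mode gradients match finite differences", {
  ## composite graph: embedding -> linear -> layer norm -> attention-style
  ## softmax -> cross entropy
  set.seed(3)
  params <- list(E = matrix(rnorm(20), 5, 4), W = matrix(rnorm(12), 4, 3),
                 b = matrix(rnorm(3), 1, 3), g = matrix(1, 1, 3),
                 be = matrix(0, 1, 3))
  lossOf <- function(pp) {
    o <- deNovoMol:::opsPlain(pp)
    x <- o$embed(o$p("E"), c(1L, 3L, 5L))
    y <- o$layerNorm(o$add(o$mm(x, o$p("W")), o$p("b")), o$p("g"), o$p("be"))
    pr <- o$softmaxRows(y)
    sum(c(0.5, 1, 2) * (-log(pr[cbind(1:3, c(1L, 2L, 3L))])))
  }
  tp <- deNovoMol:::adTape()
  o <- deNovoMol:::opsTape(tp, params)
  x <- o$embed(o$p("E"), c(1L, 3L, 5L))
  y <- o$layerNorm(o$add(o$mm(x, o$p("W")), o$p("b")), o$p("g"), o$p("be"))
  loss <- deNovoMol:::adCrossEntropy(tp, y, c(1L, 2L, 3L), c(0.5, 1, 2))
  grads <- deNovoMol:::adBackward(tp, loss)
  expect_equal(loss$val[1, 1], lossOf(params), tolerance = 1e-9)
  eps <- 1e-6
  for (nm in names(params)) {
    i <- 1L; j <- min(2L, ncol(params[[nm]]))
    up <- params; up[[nm]][i, j] <- up[[nm]][i, j] + eps
    dn <- params; dn[[nm]][i, j] <- dn[[nm]][i, j] - eps
    fd <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    expect_equal(grads[[nm]][i, j], fd, tolerance = 1e-5)
  }
})

test_that("recurrent and transformer losses are differentiated correctly", {
  corp <- fixtureCorpus(6)
  sv <- fixtureSmilesVocab()
  eps <- 1e-6
  ## GRU RNN
  gen <- rnnGenerator(sv, cell = "GRU", nLayers = 2, embeddingSize = 6,
                      hiddenSize = 8, seed = 3)
  codes <- deNovoMol:::.rnnEncodeCorpus(gen, corp[1:3], 80)
  lg <- deNovoMol:::.rnnLossGrad(gen, codes)
  for (nm in c("E", "l1_Whz", "l2_Wxn", "out_W")) {
    up <- gen; up@params[[nm]][1, 2] <- up@params[[nm]][1, 2] + eps
    dn <- gen; dn@params[[nm]][1, 2] <- dn@params[[nm]][1, 2] - eps
    fd <- (deNovoMol:::.rnnEvalLoss(up, codes) -
             deNovoMol:::.rnnEvalLoss(dn, codes)) / (2 * eps)
    expect_equal(lg$grads[[nm]][1, 2], fd, tolerance = 1e-4)
  }
  ## sequence transformer
  pairs <- enumerateFragmentPairs(standardizeMolecules(corp[1:3]),
                                  prepConfig(maxFragments = 2,
                                             maxSubsets = 2))
  stg <- seqTransformer(sv, nHeads = 2, nLayers = 1, modelDim = 8,
                        ffDim = 12, seed = 5)
  items <- deNovoMol:::.seqTransPrepare(stg, pairs, 120)
  lg2 <- deNovoMol:::.seqTransLoss(stg, items[1:2], wantGrads = TRUE)
  for (nm in c("P", "b1_h1_Wv", "b1_ln2_g", "out_b")) {
    i <- 1L; j <- 2L
    up <- stg; up@params[[nm]][i, j] <- up@params[[nm]][i, j] + eps
    dn <- stg; dn@params[[nm]][i, j] <- dn@params[[nm]][i, j] - eps
    fd <- (deNovoMol:::.seqTransLoss(up, items[1:2])$loss -
             deNovoMol:::.seqTransLoss(dn, items[1:2])$loss) / (2 * eps)
    expect_equal(lg2$grads[[nm]][i, j], fd, tolerance = 1e-4)
  }
})
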