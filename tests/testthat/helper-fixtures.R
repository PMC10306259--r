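## Shared fixtures, built once per test run. Expensive objects (the toy
## corpus and the pretrained RNN prior used by the RL tests) are memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixtureCorpus <- function(n = 60L, seed = 11L) {
  key <- paste0("corpus_", n, "_", seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- makeCorpus(n, seed = seed,
                                       weightRange = c(250, 420))
  }
  .fixtureCache[[key]]
}

fixtureSmilesVocab <- function() {
  if (is.null(.fixtureCache$sv)) {
    .fixtureCache$sv <- buildSmilesVocab(fixtureCorpus())
  }
  .fixtureCache$sv
}

fixtureGraphVocab <- function() {
  if (is.null(.fixtureCache$gv)) {
    .fixtureCache$gv <- buildGraphVocab(c(fixtureCorpus(),
                                          "CC(=O)Nc1ccc(O)cc1"))
  }
  .fixtureCache$gv
}

## A modest pretrained RNN prior shared by the RL tests: 200 fixture
## molecules, LSTM 2x64. Built once (~2 min); every test that needs a
## usable prior reuses it.
fixturePrior <- function() {
  if (is.null(.fixtureCache$prior)) {
    corp <- makeCorpus(200L, seed = 42L, weightRange = c(250, 420))
    sv <- buildSmilesVocab(corp)
    gen <- rnnGenerator(sv, cell = "LSTM", nLayers = 2L,
                        embeddingSize = 32L, hiddenSize = 64L, seed = 7L)
    fit <- pretrainGenerator(gen, corp,
                             trainConfig(epochs = 30L, batchSize = 32L,
                                         learningRate = 0.01,
                                         patience = 30L, seed = 7L))
    .fixtureCache$priorCorpus <- corp
    .fixtureCache$prior <- fit$generator
  }
  .fixtureCache$prior
}

fixturePriorCorpus <- function() {
  invisible(fixturePrior())
  .fixtureCache$priorCorpus
}

## Brute-force Pareto-front oracle: peel off the non-dominated set
## repeatedly, checking domination by definition.
oracleParetoFronts <- function(m) {
  left <- seq_len(nrow(m))
  fronts <- list()
  dominates <- function(i, j) all(m[i, ] >= m[j, ]) && any(m[i, ] > m[j, ])
  while (length(left)) {
    nd <- left[vapply(left, function(j) {
      !any(vapply(left, function(i) i != j && dominates(i, j), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    left <- setdiff(left, nd)
  }
  fronts
}
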