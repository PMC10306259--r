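## Generator base machinery: S4 classes, training configuration, the shared
## pretraining/fine-tuning loop with early stopping, the sequence
## negative-log-likelihood, and checkpoint I/O.

#' TrainConfig: supervised-training settings
#'
#' @slot epochs maximum number of epochs.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam learning rate.
#' @slot patience epochs without monitor improvement before early stop
#'   (must not exceed `epochs`).
#' @slot monitor `"test_loss"` (minimized) or `"smiles_validity"`
#'   (maximized; estimated by sampling `sampleN` molecules per epoch).
#' @slot seed RNG seed; fixed seed makes training bit-reproducible.
#' @slot testFraction held-out fraction for the per-epoch test loss.
#' @slot maxLen maximum encoded sequence length.
#' @slot sampleN molecules sampled per epoch for the validity monitor.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", patience = "integer",
                 monitor = "character", seed = "integer",
                 testFraction = "numeric", maxLen = "integer",
                 sampleN = "integer"),
  validity = function(object) {
    if (object@patience > object@epochs && object@epochs > 0L)
      return("patience must not exceed epochs")
    if (!object@monitor %in% c("test_loss", "smiles_validity"))
      return("monitor must be 'test_loss' or 'smiles_validity'")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param epochs,batchSize,learningRate,patience,monitor,seed,testFraction,maxLen,sampleN
#'   see the class slots.
#' @export
trainConfig <- function(epochs = 10L, batchSize = 32L, learningRate = 5e-3,
                        patience = 3L, monitor = "test_loss", seed = 1L,
                        testFraction = 0.2, maxLen = 110L, sampleN = 200L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      patience = as.integer(min(patience, max(epochs, 1L))),
      monitor = monitor, seed = as.integer(seed),
      testFraction = testFraction, maxLen = as.integer(maxLen),
      sampleN = as.integer(sampleN))
}

#' Virtual parent of the three generator architectures
#'
#' @slot params named list of weight matrices.
#' @slot hyper named list of architecture hyperparameters.
#' @slot optState Adam optimizer state (used by reinforcement learning).
#' @export
setClass("MoleculeGenerator", representation("VIRTUAL",
  params = "list", hyper = "list", optState = "list"))

#' @rdname MoleculeGenerator-class
#' @export
setClass("RnnGenerator",
  contains = "MoleculeGenerator",
  representation(vocab = "SmilesVocabulary"),
  validity = function(object) {
    if (!object@hyper$cell %in% c("LSTM", "GRU"))
      return("cell must be LSTM or GRU")
    if (object@hyper$nLayers < 1L) return("at least one recurrent layer")
    TRUE
  })

#' @rdname MoleculeGenerator-class
#' @export
setClass("SeqTransformer",
  contains = "MoleculeGenerator",
  representation(vocab = "SmilesVocabulary"),
  validity = function(object) {
    if (object@hyper$modelDim %% object@hyper$nHeads != 0L)
      return("modelDim must be divisible by nHeads")
    TRUE
  })

#' @rdname MoleculeGenerator-class
#' @export
setClass("GraphTransformer",
  contains = "MoleculeGenerator",
  representation(vocab = "GraphVocabulary"),
  validity = function(object) {
    if (object@hyper$modelDim %% object@hyper$nHeads != 0L)
      return("modelDim must be divisible by nHeads")
    TRUE
  })

setMethod("show", "MoleculeGenerator", function(object) {
  cat(class(object), "with", length(object@params), "weight tensors (",
      format(sum(vapply(object@params, length, numeric(1))), big.mark = ","),
      "parameters )\n")
})

#' Average sequence negative log-likelihood
#'
#' The training loss of all generators: the mean over non-padding positions
#' of the negative log of the probability assigned to the target token.
#' Distributions are expected row-normalized.
#'
#' @param predicted T x V matrix: one probability distribution per position.
#' @param targets integer vector of T target token codes (1-based).
#' @param mask optional logical/numeric vector: positions that count
#'   (default all).
#' @return non-negative scalar.
#' @export
#' @examples
#' p <- matrix(1 / 4, 3, 4)
#' nllLoss(p, c(1, 2, 3))  # log(4)
nllLoss <- function(predicted, targets, mask = NULL) {
  predicted <- as.matrix(predicted)
  if (nrow(predicted) != length(targets))
    stop("nllLoss: one target per predicted distribution required")
  if (is.null(mask)) mask <- rep(1, length(targets))
  if (length(mask) != length(targets))
    stop("nllLoss: mask length must match targets")
  picked <- predicted[cbind(seq_len(nrow(predicted)), targets)]
  w <- as.numeric(mask)
  if (sum(w) == 0) return(0)
  sum(w * (-log(pmax(picked, 1e-300)))) / sum(w)
}

## ---- shared fit loop -------------------------------------------------------

## Generic supervised loop. `lossGrad(params, idx)` returns list(loss, grads,
## denom); `evalLoss(params, idx)` a scalar; `sampleValidity(params)` a
## fraction or NULL. Returns list(params, log, bestEpoch).
.fitGenerator <- function(params, nData, cfg, lossGrad, evalLoss,
                          sampleValidity = NULL) {
  if (cfg@epochs == 0L || nData == 0L) {
    return(list(params = params, log = data.frame(), bestEpoch = 0L))
  }
  .withSeed(cfg@seed, {
    nTest <- max(1L, round(nData * cfg@testFraction))
    perm <- sample.int(nData)
    testIdx <- perm[seq_len(nTest)]
    trainIdx <- perm[-seq_len(nTest)]
    if (!length(trainIdx)) trainIdx <- testIdx
    state <- adamState(params)
    best <- list(params = params, value = Inf, epoch = 0L)
    sinceBest <- 0L
    rows <- list()
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample(trainIdx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
      epochLoss <- 0; denom <- 0
      for (bidx in batches) {
        lg <- lossGrad(params, bidx)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        upd <- adamStep(params, lg$grads, state, cfg@learningRate)
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + lg$loss * lg$denom
        denom <- denom + lg$denom
      }
      trainLoss <- epochLoss / max(denom, 1)
      testLoss <- evalLoss(params, testIdx)
      monitorValue <- if (cfg@monitor == "smiles_validity") {
        v <- sampleValidity(params)
        -v   # maximize validity == minimize its negative
      } else {
        testLoss
      }
      rows[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                  testLoss = testLoss,
                                  monitor = if (cfg@monitor ==
                                                "smiles_validity")
                                    -monitorValue else monitorValue)
      if (monitorValue < best$value - 1e-12) {
        best <- list(params = params, value = monitorValue, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest > cfg@patience) break
      }
    }
    list(params = best$params, log = do.call(rbind, rows),
         bestEpoch = best$epoch)
  })
}

## ---- generics --------------------------------------------------------------

#' Pretrain a generator on a molecule corpus
#'
#' Splits the corpus into train/test, minimizes the sequence NLL with Adam,
#' logs per-epoch train/test losses, and returns the epoch-best model by
#' the monitor metric with early stopping after `patience` non-improving
#' epochs. Fully reproducible under a fixed seed.
#'
#' @param generator a [MoleculeGenerator-class].
#' @param corpus for the RNN, a character vector of SMILES; for the
#'   transformers, the fragment-pair data.frame from
#'   [enumerateFragmentPairs()].
#' @param config a [TrainConfig-class].
#' @return list with elements `generator` (epoch-best weights), `log`
#'   (data.frame epoch/trainLoss/testLoss/monitor) and `bestEpoch`.
#' @export
setGeneric("pretrainGenerator", function(generator, corpus, config)
  standardGeneric("pretrainGenerator"))

#' Fine-tune a pretrained generator by transfer learning
#'
#' Same contract as [pretrainGenerator()] but initialized from the given
#' weights; the corpus vocabulary must be covered by the generator's
#' vocabulary (missing tokens are reported in the error).
#'
#' @inheritParams pretrainGenerator
#' @return see [pretrainGenerator()].
#' @export
setGeneric("finetuneGenerator", function(generator, corpus, config)
  standardGeneric("finetuneGenerator"))

#' Sample molecules from a generator
#'
#' The RNN samples unconditionally (supplied `inputs` are ignored with a
#' warning); both transformers require `inputs` (fragment SMILES,
#' `"."`-joined combinations allowed, recycled to `n`). Sequence models may
#' emit chemically invalid SMILES, which are returned and flagged
#' downstream, never dropped; the graph transformer's valence-masked
#' decoding emits only valid molecules.
#'
#' @param generator a [MoleculeGenerator-class].
#' @param n number of molecules.
#' @param inputs optional fragment inputs (required for transformers).
#' @param seed RNG seed.
#' @param maxLen sampling budget (tokens or atoms).
#' @return character vector of length `n` (attributes may carry sampling
#'   metadata used by the RL explorer).
#' @export
setGeneric("sampleMolecules",
           function(generator, n, inputs = NULL, seed = 1L, maxLen = 110L)
  standardGeneric("sampleMolecules"))

## Vocabulary-coverage check used by the fine-tuning methods.
.checkVocabCoverage <- function(vocabTokens, corpusSmiles) {
  toks <- unique(unlist(lapply(corpusSmiles, tokenizeSmiles)))
  missing <- setdiff(toks, vocabTokens)
  if (length(missing))
    stop("corpus contains tokens missing from the generator vocabulary: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a generator checkpoint
#'
#' A checkpoint is a single file holding the weights, hyperparameters,
#' vocabulary and a vocabulary hash; loading verifies the hash and refuses
#' a corrupted or mismatched file.
#'
#' @param generator a [MoleculeGenerator-class].
#' @param path checkpoint file path.
#' @return `saveGenerator` returns `path` invisibly; `loadGenerator` the
#'   restored generator.
#' @export
saveGenerator <- function(generator, path) {
  vocabTokens <- if (is(generator@vocab, "SmilesVocabulary")) {
    generator@vocab@tokens
  } else {
    c(generator@vocab@atomTypes, generator@vocab@bondTypes)
  }
  obj <- list(class = class(generator)[1],
              hyper = generator@hyper,
              params = generator@params,
              vocabClass = class(generator@vocab)[1],
              vocabData = if (is(generator@vocab, "SmilesVocabulary"))
                list(tokens = generator@vocab@tokens)
              else list(atomTypes = generator@vocab@atomTypes,
                        bondTypes = generator@vocab@bondTypes),
              vocabHash = .strHash(vocabTokens))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveGenerator
#' @export
loadGenerator <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  vocab <- if (obj$vocabClass == "SmilesVocabulary") {
    new("SmilesVocabulary", tokens = obj$vocabData$tokens)
  } else {
    new("GraphVocabulary", atomTypes = obj$vocabData$atomTypes,
        bondTypes = obj$vocabData$bondTypes)
  }
  tokens <- if (obj$vocabClass == "SmilesVocabulary") vocab@tokens
            else c(vocab@atomTypes, vocab@bondTypes)
  if (!identical(.strHash(tokens), obj$vocabHash))
    stop("checkpoint vocabulary hash mismatch; refusing to load ", path)
  new(obj$class, vocab = vocab, hyper = obj$hyper, params = obj$params,
      optState = list())
}
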