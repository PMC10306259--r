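## Decoder-only sequence transformer: multi-head causal self-attention with
## position-wise feed-forward layers over tokenized SMILES. Fragment
## conditioning is expressed in-band: the training sequence is
## GO fragment-tokens SEP molecule-tokens EOS, with the loss restricted to
## the molecule part; sampling continues a GO+fragments+SEP prefix.

#' Construct a decoder-only sequence transformer
#'
#' @param vocab a [SmilesVocabulary-class].
#' @param nHeads attention heads (must divide `modelDim`).
#' @param nLayers transformer blocks.
#' @param modelDim,ffDim model and feed-forward widths.
#' @param maxLen maximum (fragments + molecule) sequence length.
#' @param seed weight-initialization seed.
#' @return a [SeqTransformer][MoleculeGenerator-class].
#' @export
seqTransformer <- function(vocab, nHeads = 2L, nLayers = 2L, modelDim = 32L,
                           ffDim = 64L, maxLen = 140L, seed = 1L) {
  if (modelDim %% nHeads != 0L)
    stop("seqTransformer: modelDim must be divisible by nHeads")
  V <- vocabSize(vocab)
  shapes <- list(E = c(V, modelDim), P = c(maxLen, modelDim))
  for (l in seq_len(nLayers)) {
    shapes <- c(shapes, nnTransformerShapes(paste0("b", l), nHeads,
                                            modelDim, ffDim))
  }
  shapes <- c(shapes, list(out_W = c(modelDim, V), out_b = c(1, V)))
  params <- nnFixLayerNormInit(adInitParams(shapes, seed))
  new("SeqTransformer", vocab = vocab,
      hyper = list(nHeads = as.integer(nHeads), nLayers = as.integer(nLayers),
                   modelDim = as.integer(modelDim), ffDim = as.integer(ffDim),
                   maxLen = as.integer(maxLen), initSeed = seed),
      params = params, optState = list())
}

## Build the training sequence for one fragment-molecule pair.
.seqTransEncodePair <- function(vocab, frags, molecule, maxLen) {
  go <- 2L; eos <- 3L; sep <- 4L
  fcodes <- .svCode(vocab, tokenizeSmiles(frags))
  mcodes <- .svCode(vocab, tokenizeSmiles(molecule))
  codes <- c(go, fcodes, sep, mcodes, eos)
  if (length(codes) > maxLen) return(NULL)
  ## loss counts positions whose target lies after SEP
  lossFrom <- length(fcodes) + 2L   # predicting from the SEP position on
  list(codes = codes, lossFrom = lossFrom)
}

.seqTransForwardLogits <- function(o, hyper, codes) {
  T <- length(codes)
  x <- o$add(o$embed(o$p("E"), codes), o$embed(o$p("P"), seq_len(T)))
  mask <- matrix(0, T, T)
  mask[upper.tri(mask)] <- -Inf
  for (l in seq_len(hyper$nLayers)) {
    x <- nnTransformerBlock(o, x, paste0("b", l), hyper$nHeads, mask)
  }
  nnLinear(o, x, "out")
}

## Loss over a list of encoded pairs; weights as in the RNN loss.
.seqTransLoss <- function(gen, items, seqWeights = NULL, wantGrads = FALSE) {
  denom <- if (is.null(seqWeights)) {
    sum(vapply(items, function(it) length(it$codes) - it$lossFrom + 1L,
               integer(1)))
  } else {
    length(items)
  }
  total <- 0
  grads <- NULL
  for (i in seq_along(items)) {
    it <- items[[i]]
    T <- length(it$codes)
    idx <- it$lossFrom:(T - 1L)
    w <- rep(0, T - 1L)
    w[idx] <- if (is.null(seqWeights)) 1 / denom else seqWeights[i] / denom
    if (wantGrads) {
      tp <- adTape()
      o <- opsTape(tp, gen@params)
      logits <- .seqTransForwardLogits(o, gen@hyper, it$codes[-T])
      loss <- adCrossEntropy(tp, logits, it$codes[-1L], w)
      g <- adBackward(tp, loss)
      grads <- if (is.null(grads)) g else {
        for (nm in names(g)) {
          grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]]
                         else grads[[nm]] + g[[nm]]
        }
        grads
      }
      total <- total + loss$val[1, 1]
    } else {
      o <- opsPlain(gen@params)
      logits <- .seqTransForwardLogits(o, gen@hyper, it$codes[-T])
      p <- o$softmaxRows(logits)
      picked <- p[cbind(seq_len(T - 1L), it$codes[-1L])]
      total <- total + sum(w * (-log(pmax(picked, 1e-12))))
    }
  }
  list(loss = total, grads = grads, denom = denom)
}

.seqTransPrepare <- function(gen, corpus, maxLen) {
  if (is.character(corpus)) {
    corpus <- data.frame(Frags = vapply(corpus, function(s) {
      paste(stripAttachment(fragmentMolecule(s)), collapse = ".")
    }, character(1)), SMILES = corpus, stringsAsFactors = FALSE)
  }
  items <- list()
  for (i in seq_len(nrow(corpus))) {
    it <- .seqTransEncodePair(gen@vocab, corpus$Frags[i], corpus$SMILES[i],
                              min(maxLen, gen@hyper$maxLen))
    if (!is.null(it)) items[[length(items) + 1L]] <- it
  }
  items
}

.seqTransFit <- function(generator, corpus, config) {
  if (NROW(corpus) == 0L) stop("empty corpus")
  smis <- if (is.character(corpus)) corpus else
    c(corpus$Frags, corpus$SMILES)
  .checkVocabCoverage(generator@vocab@tokens, smis)
  items <- .seqTransPrepare(generator, corpus, config@maxLen)
  gen <- generator
  fit <- .fitGenerator(
    gen@params, length(items), config,
    lossGrad = function(params, idx) {
      gen@params <- params
      .seqTransLoss(gen, items[idx], wantGrads = TRUE)
    },
    evalLoss = function(params, idx) {
      gen@params <- params
      .seqTransLoss(gen, items[idx])$loss
    },
    sampleValidity = function(params) {
      gen@params <- params
      frags <- vapply(items[seq_len(min(20, length(items)))],
                      function(it) decodeSmiles(c(2L, it$codes[
                        2:(it$lossFrom - 1L)]), gen@vocab), character(1))
      smi <- sampleMolecules(gen, config@sampleN, inputs = frags,
                             seed = config@seed + 7919L)
      mean(nzchar(canonicalSmiles(smi)))
    })
  generator@params <- fit$params
  list(generator = generator, log = fit$log, bestEpoch = fit$bestEpoch)
}

#' @rdname pretrainGenerator
setMethod("pretrainGenerator", "SeqTransformer",
          function(generator, corpus, config) {
  .seqTransFit(generator, corpus, config)
})

#' @rdname finetuneGenerator
setMethod("finetuneGenerator", "SeqTransformer",
          function(generator, corpus, config) {
  if (NROW(corpus) == 0L) stop("fine-tuning corpus is empty")
  .seqTransFit(generator, corpus, config)
})

#' @rdname sampleMolecules
setMethod("sampleMolecules", "SeqTransformer",
          function(generator, n, inputs = NULL, seed = 1L, maxLen = 110L) {
  if (n == 0L) return(character(0))
  if (is.null(inputs))
    stop("SeqTransformer requires fragment inputs for sampling")
  inputs <- rep_len(inputs, n)
  o <- opsPlain(generator@params)
  hy <- generator@hyper
  .withSeed(seed, {
    out <- character(n)
    for (b in seq_len(n)) {
      prefix <- c(2L, .svCode(generator@vocab, tokenizeSmiles(inputs[b])), 4L)
      codes <- prefix
      budget <- min(hy$maxLen, length(prefix) + maxLen)
      while (length(codes) < budget) {
        logits <- .seqTransForwardLogits(o, hy, codes)
        p <- o$softmaxRows(logits[length(codes), , drop = FALSE])
        p[, c(1L, 2L, 4L)] <- 0
        nxt <- nnSampleFrom(p[1, ])
        if (nxt == 3L) break
        codes <- c(codes, nxt)
      }
      out[b] <- decodeSmiles(c(codes[-seq_along(prefix)], 3L),
                             generator@vocab)
    }
    attr(out, "inputs") <- inputs
    attr(out, "provenance") <- rep("agent", n)
    out
  })
})
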