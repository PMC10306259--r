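## Recurrent SMILES language model: embedding layer, a stack of LSTM or GRU
## layers (three by default), a linear layer and a softmax over the token
## vocabulary. Trains by next-token NLL; samples unconditionally.

#' Construct a recurrent SMILES generator
#'
#' @param vocab a [SmilesVocabulary-class].
#' @param cell `"LSTM"` (default) or `"GRU"`.
#' @param nLayers number of recurrent layers (default 3).
#' @param embeddingSize,hiddenSize layer widths (desk-scale defaults).
#' @param seed weight-initialization seed.
#' @return an [RnnGenerator][MoleculeGenerator-class].
#' @export
rnnGenerator <- function(vocab, cell = c("LSTM", "GRU"), nLayers = 3L,
                         embeddingSize = 32L, hiddenSize = 64L, seed = 1L) {
  cell <- match.arg(cell)
  V <- vocabSize(vocab)
  shapes <- c(list(E = c(V, embeddingSize)),
              nnRecurrentShapes(cell, nLayers, embeddingSize, hiddenSize),
              list(out_W = c(hiddenSize, V), out_b = c(1, V)))
  new("RnnGenerator", vocab = vocab,
      hyper = list(cell = cell, nLayers = as.integer(nLayers),
                   embeddingSize = as.integer(embeddingSize),
                   hiddenSize = as.integer(hiddenSize), initSeed = seed),
      params = adInitParams(shapes, seed), optState = list())
}

## Encode a SMILES corpus into a codes matrix (n x T).
.rnnEncodeCorpus <- function(gen, corpus, maxLen) {
  lens <- vapply(corpus, function(s) length(tokenizeSmiles(s)), integer(1))
  T <- min(maxLen, max(lens) + 2L)
  keep <- lens + 2L <= T
  if (!all(keep)) {
    warning(sum(!keep), " molecules longer than maxLen dropped")
  }
  mat <- t(vapply(corpus[keep], encodeSmiles, integer(T),
                  vocab = gen@vocab, maxLen = T))
  rownames(mat) <- NULL
  mat
}

## Loss over a codes matrix. weights: per-sequence weights (NULL = token
## averaging). Returns list(loss node-or-number, tape, denom).
.rnnLossForward <- function(o, gen, codes, seqWeights = NULL) {
  hy <- gen@hyper
  B <- nrow(codes); T <- ncol(codes)
  pad <- 1L
  state <- nnRecurrentInit(o, hy$cell, hy$nLayers, B, hy$hiddenSize)
  ceNodes <- list()
  mask <- codes[, -1L, drop = FALSE] != pad
  denom <- if (is.null(seqWeights)) sum(mask) else B
  for (t in seq_len(T - 1L)) {
    x <- o$embed(o$p("E"), codes[, t])
    st <- nnRecurrentStep(o, x, state, hy$cell, hy$nLayers)
    state <- st$state
    logits <- nnLinear(o, st$out, "out")
    w <- if (is.null(seqWeights)) {
      as.numeric(mask[, t]) / denom
    } else {
      as.numeric(mask[, t]) * seqWeights / denom
    }
    if (!is.null(o$tape)) {
      ceNodes[[t]] <- adCrossEntropy(o$tape, logits, codes[, t + 1L], w)
    } else {
      p <- o$softmaxRows(logits)
      picked <- p[cbind(seq_len(B), codes[, t + 1L])]
      ceNodes[[t]] <- matrix(sum(w * (-log(pmax(picked, 1e-12)))), 1, 1)
    }
  }
  if (!is.null(o$tape)) {
    list(loss = adSumScalars(o$tape, ceNodes), denom = denom)
  } else {
    list(loss = sum(vapply(ceNodes, function(m) m[1, 1], numeric(1))),
         denom = denom)
  }
}

.rnnLossGrad <- function(gen, codes, seqWeights = NULL) {
  tp <- adTape()
  o <- opsTape(tp, gen@params)
  fw <- .rnnLossForward(o, gen, codes, seqWeights)
  grads <- adBackward(tp, fw$loss)
  list(loss = fw$loss$val[1, 1], grads = grads, denom = fw$denom)
}

.rnnEvalLoss <- function(gen, codes) {
  o <- opsPlain(gen@params)
  .rnnLossForward(o, gen, codes)$loss
}

.rnnFit <- function(generator, corpus, config) {
  if (!length(corpus)) stop("empty corpus")
  .checkVocabCoverage(generator@vocab@tokens, corpus)
  codes <- .rnnEncodeCorpus(generator, corpus, config@maxLen)
  gen <- generator
  fit <- .fitGenerator(
    gen@params, nrow(codes), config,
    lossGrad = function(params, idx) {
      gen@params <- params
      .rnnLossGrad(gen, codes[idx, , drop = FALSE])
    },
    evalLoss = function(params, idx) {
      gen@params <- params
      .rnnEvalLoss(gen, codes[idx, , drop = FALSE])
    },
    sampleValidity = function(params) {
      gen@params <- params
      smi <- sampleMolecules(gen, config@sampleN,
                             seed = config@seed + 7919L,
                             maxLen = ncol(codes))
      mean(nzchar(canonicalSmiles(smi)))
    })
  generator@params <- fit$params
  list(generator = generator, log = fit$log, bestEpoch = fit$bestEpoch)
}

#' @rdname pretrainGenerator
setMethod("pretrainGenerator", "RnnGenerator", function(generator, corpus,
                                                        config) {
  .rnnFit(generator, corpus, config)
})

#' @rdname finetuneGenerator
setMethod("finetuneGenerator", "RnnGenerator", function(generator, corpus,
                                                        config) {
  if (!length(corpus)) stop("fine-tuning corpus is empty")
  .rnnFit(generator, corpus, config)
})

#' @rdname sampleMolecules
setMethod("sampleMolecules", "RnnGenerator",
          function(generator, n, inputs = NULL, seed = 1L, maxLen = 110L) {
  if (!is.null(inputs))
    warning("RnnGenerator samples unconditionally; fragment inputs ignored")
  if (n == 0L) return(character(0))
  hy <- generator@hyper
  o <- opsPlain(generator@params)
  .withSeed(seed, {
    state <- nnRecurrentInit(o, hy$cell, hy$nLayers, n, hy$hiddenSize)
    last <- rep(2L, n)        # GO
    done <- rep(FALSE, n)
    seqs <- matrix(1L, n, maxLen)
    for (t in seq_len(maxLen)) {
      x <- o$embed(o$p("E"), last)
      st <- nnRecurrentStep(o, x, state, hy$cell, hy$nLayers)
      state <- st$state
      p <- o$softmaxRows(nnLinear(o, st$out, "out"))
      p[, c(1L, 2L, 4L)] <- 0   # never sample PAD, GO or SEP
      nxt <- vapply(seq_len(n), function(b) {
        if (done[b]) 1L else nnSampleFrom(p[b, ])
      }, integer(1))
      seqs[, t] <- nxt
      done <- done | nxt == 3L  # EOS
      last <- nxt
      if (all(done)) break
    }
    out <- vapply(seq_len(n), function(b) {
      decodeSmiles(c(2L, seqs[b, ]), generator@vocab)
    }, character(1))
    attr(out, "provenance") <- rep("agent", n)
    out
  })
})
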