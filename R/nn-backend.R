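## Shared numeric backend for the generators. Forward passes are written
## once against an "ops" interface with two implementations: a tape backend
## (training, gradients) and a plain-matrix backend (evaluation, sampling).

opsTape <- function(tp, params) {
  pnodes <- new.env(parent = emptyenv())
  getp <- function(nm) {
    if (is.null(pnodes[[nm]])) pnodes[[nm]] <- adParam(tp, params[[nm]], nm)
    pnodes[[nm]]
  }
  list(
    tape = tp,
    p = getp,
    c = function(m) adConst(tp, m),
    mm = function(a, b) adMatmul(tp, a, b),
    add = function(a, b) adAdd(tp, a, b),
    mul = function(a, b) adMul(tp, a, b),
    scale = function(a, k) adScale(tp, a, k),
    tanh = function(a) adTanh(tp, a),
    sigmoid = function(a) adSigmoid(tp, a),
    relu = function(a) adRelu(tp, a),
    t = function(a) adTranspose(tp, a),
    embed = function(e, idx) adEmbed(tp, e, idx),
    concat = function(lst) adConcatCols(tp, lst),
    softmaxRows = function(a, mask = NULL) adSoftmaxRows(tp, a, mask),
    layerNorm = function(a, g, b) adLayerNorm(tp, a, g, b),
    val = function(a) a$val
  )
}

opsPlain <- function(params) {
  list(
    tape = NULL,
    p = function(nm) params[[nm]],
    c = identity,
    mm = function(a, b) a %*% b,
    add = function(a, b) {
      if (nrow(b) == 1L && nrow(a) > 1L) sweep(a, 2, b[1, ], "+") else a + b
    },
    mul = function(a, b) a * b,
    scale = function(a, k) a * k,
    tanh = tanh,
    sigmoid = function(a) 1 / (1 + exp(-a)),
    relu = function(a) pmax(a, 0),
    t = t,
    embed = function(e, idx) e[idx, , drop = FALSE],
    concat = function(lst) do.call(cbind, lst),
    softmaxRows = function(a, mask = NULL) {
      if (!is.null(mask)) a <- a + mask
      a <- a - apply(a, 1, max)
      e <- exp(a)
      e / rowSums(e)
    },
    layerNorm = function(a, g, b, eps = 1e-5) {
      mu <- rowMeans(a)
      xc <- a - mu
      inv <- 1 / sqrt(rowMeans(xc^2) + eps)
      sweep(sweep(xc * inv, 2, g[1, ], "*"), 2, b[1, ], "+")
    },
    val = identity
  )
}

## Linear layer y = x W + b  (params named <prefix>_W, <prefix>_b)
nnLinear <- function(o, x, prefix) {
  o$add(o$mm(x, o$p(paste0(prefix, "_W"))), o$p(paste0(prefix, "_b")))
}

## One recurrent step. state is a list of per-layer hidden (and cell)
## matrices (B x H); returns list(state, out).
nnRecurrentStep <- function(o, x, state, cell, nLayers) {
  inp <- x
  for (l in seq_len(nLayers)) {
    pre <- paste0("l", l)
    if (cell == "GRU") {
      h <- state[[l]]$h
      r <- o$sigmoid(o$add(o$add(o$mm(inp, o$p(paste0(pre, "_Wxr"))),
                                 o$mm(h, o$p(paste0(pre, "_Whr")))),
                           o$p(paste0(pre, "_br"))))
      z <- o$sigmoid(o$add(o$add(o$mm(inp, o$p(paste0(pre, "_Wxz"))),
                                 o$mm(h, o$p(paste0(pre, "_Whz")))),
                           o$p(paste0(pre, "_bz"))))
      nn <- o$tanh(o$add(o$add(o$mm(inp, o$p(paste0(pre, "_Wxn"))),
                               o$mul(r, o$mm(h, o$p(paste0(pre, "_Whn"))))),
                         o$p(paste0(pre, "_bn"))))
      one <- o$c(matrix(1, 1, 1))
      ## h' = (1 - z) * n + z * h
      hNew <- o$add(o$mul(o$add(o$scale(z, -1),
                                o$c(matrix(1, nrow(o$val(z)),
                                           ncol(o$val(z))))), nn),
                    o$mul(z, h))
      state[[l]]$h <- hNew
      inp <- hNew
    } else {  # LSTM
      h <- state[[l]]$h; cc <- state[[l]]$c
      gate <- function(sfx, act) {
        act(o$add(o$add(o$mm(inp, o$p(paste0(pre, "_Wx", sfx))),
                        o$mm(h, o$p(paste0(pre, "_Wh", sfx)))),
                  o$p(paste0(pre, "_b", sfx))))
      }
      i <- gate("i", o$sigmoid)
      f <- gate("f", o$sigmoid)
      g <- gate("g", o$tanh)
      u <- gate("o", o$sigmoid)
      cNew <- o$add(o$mul(f, cc), o$mul(i, g))
      hNew <- o$mul(u, o$tanh(cNew))
      state[[l]] <- list(h = hNew, c = cNew)
      inp <- hNew
    }
  }
  list(state = state, out = inp)
}

nnRecurrentInit <- function(o, cell, nLayers, batch, hidden) {
  lapply(seq_len(nLayers), function(l) {
    z <- o$c(matrix(0, batch, hidden))
    if (cell == "GRU") list(h = z) else list(h = z, c = z)
  })
}

nnRecurrentShapes <- function(cell, nLayers, E, H) {
  gates <- if (cell == "GRU") c("r", "z", "n") else c("i", "f", "g", "o")
  shapes <- list()
  for (l in seq_len(nLayers)) {
    din <- if (l == 1L) E else H
    for (gt in gates) {
      shapes[[paste0("l", l, "_Wx", gt)]] <- c(din, H)
      shapes[[paste0("l", l, "_Wh", gt)]] <- c(H, H)
      shapes[[paste0("l", l, "_b", gt)]] <- c(1, H)
    }
  }
  shapes
}

## Multi-head self-attention for a single sequence (T x d), optional
## additive mask (T x T). Head h uses parameter prefixes <prefix>_h<h>_Wq/k/v.
nnSelfAttention <- function(o, x, prefix, nHeads, mask = NULL) {
  dModel <- ncol(o$val(x))
  dk <- dModel / nHeads
  heads <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    pre <- paste0(prefix, "_h", h)
    q <- o$mm(x, o$p(paste0(pre, "_Wq")))
    k <- o$mm(x, o$p(paste0(pre, "_Wk")))
    v <- o$mm(x, o$p(paste0(pre, "_Wv")))
    att <- o$softmaxRows(o$scale(o$mm(q, o$t(k)), 1 / sqrt(dk)), mask)
    heads[[h]] <- o$mm(att, v)
  }
  nnLinear(o, o$concat(heads), paste0(prefix, "_proj"))
}

## Post-norm transformer block: attention + residual + LN, FFN + residual + LN.
nnTransformerBlock <- function(o, x, prefix, nHeads, mask = NULL) {
  a <- nnSelfAttention(o, x, prefix, nHeads, mask)
  x <- o$layerNorm(o$add(x, a), o$p(paste0(prefix, "_ln1_g")),
                   o$p(paste0(prefix, "_ln1_b")))
  f <- nnLinear(o, o$relu(nnLinear(o, x, paste0(prefix, "_ff1"))),
                paste0(prefix, "_ff2"))
  o$layerNorm(o$add(x, f), o$p(paste0(prefix, "_ln2_g")),
              o$p(paste0(prefix, "_ln2_b")))
}

nnTransformerShapes <- function(prefix, nHeads, dModel, dFF) {
  dk <- dModel / nHeads
  shapes <- list()
  for (h in seq_len(nHeads)) {
    pre <- paste0(prefix, "_h", h)
    shapes[[paste0(pre, "_Wq")]] <- c(dModel, dk)
    shapes[[paste0(pre, "_Wk")]] <- c(dModel, dk)
    shapes[[paste0(pre, "_Wv")]] <- c(dModel, dk)
  }
  shapes[[paste0(prefix, "_proj_W")]] <- c(dModel, dModel)
  shapes[[paste0(prefix, "_proj_b")]] <- c(1, dModel)
  shapes[[paste0(prefix, "_ff1_W")]] <- c(dModel, dFF)
  shapes[[paste0(prefix, "_ff1_b")]] <- c(1, dFF)
  shapes[[paste0(prefix, "_ff2_W")]] <- c(dFF, dModel)
  shapes[[paste0(prefix, "_ff2_b")]] <- c(1, dModel)
  shapes[[paste0(prefix, "_ln1_g")]] <- c(1, dModel)
  shapes[[paste0(prefix, "_ln1_b")]] <- c(1, dModel)
  shapes[[paste0(prefix, "_ln2_g")]] <- c(1, dModel)
  shapes[[paste0(prefix, "_ln2_b")]] <- c(1, dModel)
  shapes
}

## LayerNorm gains start at 1, not random.
nnFixLayerNormInit <- function(params) {
  for (nm in grep("_ln[0-9]_g$", names(params), value = TRUE)) {
    params[[nm]][] <- 1
  }
  for (nm in grep("_ln[0-9]_b$", names(params), value = TRUE)) {
    params[[nm]][] <- 0
  }
  params
}

## Multinomial draw from a probability row-vector.
nnSampleFrom <- function(p) {
  sample.int(length(p), 1L, prob = pmax(p, 0))
}
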