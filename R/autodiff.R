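## Minimal reverse-mode automatic differentiation over dense matrices.
## A tape records nodes in creation order; backward() sweeps it in reverse.
## This is deliberately small: just the operations the three generator
## architectures need, in plain R so training is bit-reproducible.

adTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

.adNode <- function(tp, val, parents = integer(0), backfn = NULL,
                    param = NA_character_) {
  ## force arguments BEFORE taking an id: evaluating them may create nodes
  force(val); force(parents); force(backfn); force(param)
  tp$n <- tp$n + 1L
  node <- list(id = tp$n, val = val, parents = parents, backfn = backfn,
               param = param)
  tp$nodes[[tp$n]] <- node
  node
}

## Leaf holding a parameter matrix; gradients are collected under `name`.
adParam <- function(tp, val, name) .adNode(tp, val, param = name)

adConst <- function(tp, val) .adNode(tp, val)

adMatmul <- function(tp, a, b) {
  .adNode(tp, a$val %*% b$val, c(a$id, b$id), function(g, pv) {
    list(g %*% t(pv[[2]]), t(pv[[1]]) %*% g)
  })
}

## a + b with b possibly a single row (bias) broadcast over a's rows.
adAdd <- function(tp, a, b) {
  bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(a$val) > 1L
  val <- if (broadcast) sweep(a$val, 2, bv[1, ], "+") else a$val + bv
  .adNode(tp, val, c(a$id, b$id), function(g, pv) {
    gb <- if (broadcast) matrix(colSums(g), 1) else g
    list(g, gb)
  })
}

adMul <- function(tp, a, b) {
  .adNode(tp, a$val * b$val, c(a$id, b$id), function(g, pv) {
    list(g * pv[[2]], g * pv[[1]])
  })
}

adScale <- function(tp, a, k) {
  .adNode(tp, a$val * k, a$id, function(g, pv) list(g * k))
}

adTanh <- function(tp, a) {
  y <- tanh(a$val)
  .adNode(tp, y, a$id, function(g, pv) list(g * (1 - y^2)))
}

adSigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-a$val))
  .adNode(tp, y, a$id, function(g, pv) list(g * y * (1 - y)))
}

adRelu <- function(tp, a) {
  y <- pmax(a$val, 0)
  .adNode(tp, y, a$id, function(g, pv) list(g * (pv[[1]] > 0)))
}

adTranspose <- function(tp, a) {
  .adNode(tp, t(a$val), a$id, function(g, pv) list(t(g)))
}

## Row-wise gather from an embedding matrix; idx is 1-based.
adEmbed <- function(tp, emb, idx) {
  .adNode(tp, emb$val[idx, , drop = FALSE], emb$id, function(g, pv) {
    ge <- matrix(0, nrow(pv[[1]]), ncol(pv[[1]]))
    for (r in seq_along(idx)) {
      ge[idx[r], ] <- ge[idx[r], ] + g[r, ]
    }
    list(ge)
  })
}

adConcatCols <- function(tp, nodes) {
  vals <- lapply(nodes, `[[`, "val")
  widths <- vapply(vals, ncol, integer(1))
  .adNode(tp, do.call(cbind, vals), vapply(nodes, `[[`, integer(1), "id"),
          function(g, pv) {
    out <- vector("list", length(pv))
    at <- 0L
    for (i in seq_along(pv)) {
      out[[i]] <- g[, at + seq_len(widths[i]), drop = FALSE]
      at <- at + widths[i]
    }
    out
  })
}

## Row-wise softmax with an optional additive mask (-Inf blocks entries).
adSoftmaxRows <- function(tp, a, mask = NULL) {
  z <- a$val
  if (!is.null(mask)) z <- z + mask
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  .adNode(tp, p, a$id, function(g, pv) {
    gs <- rowSums(g * p)
    list((g - gs) * p)
  })
}

## Layer normalization over each row, with per-column gain and bias.
adLayerNorm <- function(tp, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2, gamma$val[1, ], "*"), 2, beta$val[1, ], "+")
  .adNode(tp, val, c(a$id, gamma$id, beta$id), function(g, pv) {
    d <- ncol(x)
    gxhat <- sweep(g, 2, gamma$val[1, ], "*")
    gv <- rowSums(gxhat * xc) * (-0.5) * inv^3
    gmu <- -rowSums(gxhat) * inv + gv * (-2) * rowMeans(xc)
    ga <- gxhat * inv + (2 * xc * gv + gmu) / d
    list(ga,
         matrix(colSums(g * xhat), 1),
         matrix(colSums(g), 1))
  })
}

## Fused softmax + cross-entropy over rows of logits. `targets` are 1-based
## column indices; `weights` scales each row's loss (0 masks it out).
## Returns a scalar node whose value is sum_i weights[i] * (-log p_i[target]).
adCrossEntropy <- function(tp, logits, targets, weights = NULL) {
  z <- logits$val
  if (length(targets) != nrow(z))
    stop("adCrossEntropy: one target per logit row required")
  if (is.null(weights)) weights <- rep(1, nrow(z))
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(nrow(p)), targets)]
  loss <- sum(weights * (-log(pmax(picked, 1e-12))))
  .adNode(tp, matrix(loss, 1, 1), logits$id, function(g, pv) {
    gy <- p
    gy[cbind(seq_len(nrow(p)), targets)] <-
      gy[cbind(seq_len(nrow(p)), targets)] - 1
    list(gy * weights * g[1, 1])
  })
}

adSumScalars <- function(tp, nodes) {
  .adNode(tp, matrix(sum(vapply(nodes, function(n) n$val[1, 1], numeric(1))),
                     1, 1),
          vapply(nodes, `[[`, integer(1), "id"),
          function(g, pv) rep(list(g), length(pv)))
}

## Reverse sweep from scalar node `loss`; returns named list of parameter
## gradients (accumulated by parameter name).
adBackward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- matrix(1, 1, 1)
  paramGrads <- list()
  for (i in rev(seq_len(tp$n))) {
    node <- tp$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (!is.na(node$param)) {
      if (is.null(paramGrads[[node$param]])) {
        paramGrads[[node$param]] <- g
      } else {
        paramGrads[[node$param]] <- paramGrads[[node$param]] + g
      }
      next
    }
    if (is.null(node$backfn)) next
    pv <- lapply(node$parents, function(p) tp$nodes[[p]]$val)
    pg <- node$backfn(g, pv)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      if (is.null(grads[[p]])) grads[[p]] <- pg[[k]]
      else grads[[p]] <- grads[[p]] + pg[[k]]
    }
  }
  paramGrads
}

## ---- parameters and optimizer ---------------------------------------------

## Uniform(-s, s) init with s = 1/sqrt(fan-in), seeded.
adInitParams <- function(shapes, seed) {
  .withSeed(seed, {
    out <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      s <- 1 / sqrt(max(sh[1], 1))
      out[[nm]] <- matrix(stats::runif(sh[1] * sh[2], -s, s), sh[1], sh[2])
    }
    out
  })
}

adamState <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
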