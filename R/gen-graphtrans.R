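## Graph transformer: a transformer encoder reads the columns of the input
## fragments' graph encoding; a GRU decoder emits the molecule column by
## column as events (add-atom, close-ring/link, EOS). During sampling every
## head is masked by a local valence audit of the partial graph, so the
## decoder can only propose chemically admissible bonds: sampled molecules
## are valid by construction. The decoder also records its event trajectory
## so policy-gradient updates can rescore the exact actions taken.

#' Construct a fragment-conditioned graph transformer
#'
#' @param vocab a [GraphVocabulary-class].
#' @param nHeads,nEncLayers,modelDim,ffDim encoder hyperparameters.
#' @param decHidden GRU decoder width.
#' @param maxAtoms atom-index budget per molecule.
#' @param seed weight-initialization seed.
#' @return a [GraphTransformer][MoleculeGenerator-class].
#' @export
graphTransformer <- function(vocab, nHeads = 2L, nEncLayers = 1L,
                             modelDim = 32L, ffDim = 64L, decHidden = 64L,
                             maxAtoms = 80L, seed = 1L) {
  nA <- length(vocab@atomTypes)
  shapes <- list(Ea = c(nA + 3L, modelDim),      # r1 codes 0..nA+2
                 Ei = c(maxAtoms + 1L, modelDim),  # r2 indices
                 En = c(maxAtoms + 1L, modelDim),  # r3 indices
                 Eb = c(5L, modelDim),             # r4 bond codes 0..4
                 Ef = c(17L, modelDim))            # r5 fragment index
  for (l in seq_len(nEncLayers)) {
    shapes <- c(shapes, nnTransformerShapes(paste0("enc", l), nHeads,
                                            modelDim, ffDim))
  }
  shapes <- c(shapes,
              nnRecurrentShapes("GRU", 1L, 2L * modelDim, decHidden),
              list(ev_W = c(decHidden, nA + 2L), ev_b = c(1, nA + 2L),
                   cur_W = c(decHidden, maxAtoms), cur_b = c(1, maxAtoms),
                   nbr_W = c(decHidden, maxAtoms), nbr_b = c(1, maxAtoms),
                   bond_W = c(decHidden, 3L), bond_b = c(1, 3L)))
  params <- nnFixLayerNormInit(adInitParams(shapes, seed))
  new("GraphTransformer", vocab = vocab,
      hyper = list(nHeads = as.integer(nHeads),
                   nEncLayers = as.integer(nEncLayers),
                   modelDim = as.integer(modelDim), ffDim = as.integer(ffDim),
                   decHidden = as.integer(decHidden),
                   maxAtoms = as.integer(maxAtoms), initSeed = seed),
      params = params, optState = list())
}

## Embed a set of 5-row columns (matrix 5 x S) into S x d.
.gtEmbedCols <- function(o, cols, maxAtoms) {
  clip <- function(i) pmin(i, maxAtoms - 1L)
  x <- o$embed(o$p("Ea"), cols[1, ] + 1L)
  x <- o$add(x, o$embed(o$p("Ei"), clip(cols[2, ]) + 1L))
  x <- o$add(x, o$embed(o$p("En"), clip(cols[3, ]) + 1L))
  x <- o$add(x, o$embed(o$p("Eb"), cols[4, ] + 1L))
  o$add(x, o$embed(o$p("Ef"), pmin(cols[5, ], 16L) + 1L))
}

## Encoder: conditioning columns -> mean-pooled context (1 x d).
.gtEncode <- function(o, hyper, condCols) {
  x <- .gtEmbedCols(o, condCols, hyper$maxAtoms)
  for (l in seq_len(hyper$nEncLayers)) {
    x <- nnTransformerBlock(o, x, paste0("enc", l), hyper$nHeads)
  }
  v <- o$val(x)
  o$scale(o$mm(o$c(matrix(1 / nrow(v), 1, nrow(v))), x), 1)
}

## Split an encoded graph matrix into conditioning columns (input fragments
## 1..k) and an event list for the decoder targets.
.gtEventsFromMatrix <- function(mat, k, nAtomTypes) {
  used <- which(mat[1, ] != 0L)
  frag <- used[mat[1, used] > 2L & mat[5, used] > 0L]
  link <- used[mat[1, used] > 2L & mat[5, used] == 0L]
  condIdx <- frag[mat[5, frag] <= k]
  tgtIdx <- c(frag[mat[5, frag] > k], link)
  condCols <- mat[, condIdx, drop = FALSE]
  if (!length(condIdx)) condCols <- matrix(c(1L, 0L, 0L, 0L, 0L), 5, 1)
  maxIdx <- if (length(condIdx)) max(mat[2, condIdx]) else -1L
  events <- list()
  for (ci in tgtIdx) {
    v <- mat[, ci]
    if (v[2] > maxIdx) {          # new atom
      maxIdx <- v[2]
      events[[length(events) + 1L]] <-
        list(ev = v[1] - 2L, cur = NA_integer_, nbr = v[3], bond = v[4],
             hasBond = v[3] != v[2], col = v)
    } else {                      # ring closure / inter-fragment link
      events[[length(events) + 1L]] <-
        list(ev = nAtomTypes + 1L, cur = v[2], nbr = v[3], bond = v[4],
             hasBond = TRUE, col = v)
    }
  }
  events[[length(events) + 1L]] <-
    list(ev = nAtomTypes + 2L, cur = NA_integer_, nbr = NA_integer_,
         bond = NA_integer_, hasBond = FALSE,
         col = c(2L, 0L, 0L, 0L, 0L))
  list(condCols = condCols, events = events)
}

## Teacher-forced decoder loss for one item; returns scalar node (tape) or
## number (plain). weight scales the whole item.
.gtItemLoss <- function(o, gen, item, weight) {
  hy <- gen@hyper
  ctx <- .gtEncode(o, hy, item$condCols)
  nEv <- length(item$events)
  prevCols <- cbind(c(1L, 0L, 0L, 0L, 0L),
                    vapply(item$events[-nEv], function(e) e$col, integer(5)))
  inp <- o$concat(list(.gtEmbedCols(o, prevCols, hy$maxAtoms),
                       o$mm(o$c(matrix(1, nEv, 1)), ctx)))
  hs <- vector("list", nEv)
  st <- nnRecurrentInit(o, "GRU", 1L, 1L, hy$decHidden)
  for (t in seq_len(nEv)) {
    xt <- if (is.null(o$tape)) inp[t, , drop = FALSE] else
      adEmbed(o$tape, inp, t)
    step <- nnRecurrentStep(o, xt, st, "GRU", 1L)
    st <- step$state
    hs[[t]] <- step$out
  }
  ## head losses per step
  lossNodes <- list()
  total <- 0
  for (t in seq_len(nEv)) {
    e <- item$events[[t]]
    ht <- hs[[t]]
    addCE <- function(prefix, target) {
      logits <- nnLinear(o, ht, prefix)
      if (!is.null(o$tape)) {
        lossNodes[[length(lossNodes) + 1L]] <<-
          adCrossEntropy(o$tape, logits, target, weight)
      } else {
        p <- o$softmaxRows(logits)
        total <<- total + weight * (-log(max(p[1, target], 1e-12)))
      }
    }
    addCE("ev", e$ev)
    if (isTRUE(e$hasBond)) {
      addCE("nbr", e$nbr + 1L)
      addCE("bond", e$bond)
    }
    if (!is.na(e$cur)) addCE("cur", e$cur + 1L)
  }
  if (!is.null(o$tape)) adSumScalars(o$tape, lossNodes) else total
}

.gtPrepare <- function(gen, corpus, method = "BRICS") {
  items <- list()
  for (i in seq_len(nrow(corpus))) {
    frags <- strsplit(corpus$Frags[i], ".", fixed = TRUE)[[1]]
    mat <- tryCatch(
      encodeGraph(corpus$SMILES[i], frags, gen@vocab,
                  L = 2L + gen@hyper$maxAtoms * 2L + 38L, nLink = 38L,
                  method = method),
      error = function(e) NULL)
    if (is.null(mat)) next
    it <- .gtEventsFromMatrix(mat, length(frags),
                              length(gen@vocab@atomTypes))
    it$nEvents <- length(it$events)
    items[[length(items) + 1L]] <- it
  }
  items
}

.gtLossGrad <- function(gen, items, seqWeights = NULL) {
  denom <- if (is.null(seqWeights)) {
    sum(vapply(items, `[[`, integer(1), "nEvents"))
  } else {
    length(items)
  }
  grads <- NULL
  total <- 0
  for (i in seq_along(items)) {
    w <- if (is.null(seqWeights)) 1 / denom else seqWeights[i] / denom
    if (!is.null(seqWeights) && seqWeights[i] == 0) next
    tp <- adTape()
    o <- opsTape(tp, gen@params)
    loss <- .gtItemLoss(o, gen, items[[i]], w)
    g <- adBackward(tp, loss)
    grads <- if (is.null(grads)) g else {
      for (nm in names(g)) {
        grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]]
                       else grads[[nm]] + g[[nm]]
      }
      grads
    }
    total <- total + loss$val[1, 1]
  }
  list(loss = total, grads = grads %||% list(), denom = denom)
}

.gtEvalLoss <- function(gen, items) {
  denom <- sum(vapply(items, `[[`, integer(1), "nEvents"))
  total <- 0
  for (it in items) {
    o <- opsPlain(gen@params)
    total <- total + .gtItemLoss(o, gen, it, 1 / denom)
  }
  total
}

.gtFit <- function(generator, corpus, config) {
  if (NROW(corpus) == 0L) stop("empty corpus")
  items <- .gtPrepare(generator, corpus)
  if (!length(items)) stop("no encodable fragment pairs in corpus")
  gen <- generator
  fit <- .fitGenerator(
    gen@params, length(items), config,
    lossGrad = function(params, idx) {
      gen@params <- params
      .gtLossGrad(gen, items[idx])
    },
    evalLoss = function(params, idx) {
      gen@params <- params
      .gtEvalLoss(gen, items[idx])
    },
    sampleValidity = function(params) 1)
  generator@params <- fit$params
  list(generator = generator, log = fit$log, bestEpoch = fit$bestEpoch)
}

#' @rdname pretrainGenerator
setMethod("pretrainGenerator", "GraphTransformer",
          function(generator, corpus, config) {
  .gtFit(generator, corpus, config)
})

#' @rdname finetuneGenerator
setMethod("finetuneGenerator", "GraphTransformer",
          function(generator, corpus, config) {
  if (NROW(corpus) == 0L) stop("fine-tuning corpus is empty")
  .gtFit(generator, corpus, config)
})

## ---- masked sampling -------------------------------------------------------

.gtTypeValence <- function(vocab) {
  vapply(vocab@atomTypes, function(tp) {
    at <- .gvParseAtomType(tp)
    v <- mgValence(at$element, at$charge)
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
}

## Conditioning columns + initial graph state from a fragment combination.
.gtCondFromFragments <- function(fragsString, vocab) {
  g <- mgFromSmiles(fragsString)
  if (is.null(g)) stop("invalid fragment input: ", fragsString)
  comps <- mgComponents(g)
  indexOf <- new.env(); indexOf$map <- list()
  cols <- list()
  for (f in seq_along(comps)) {
    for (cc in .graphTraverseFragment(g, comps[[f]], vocab, indexOf)) {
      cols[[length(cols) + 1L]] <- as.integer(c(cc, f))
    }
  }
  ## atoms reindexed in traversal order
  ord <- order(vapply(names(indexOf$map), function(nm) indexOf$map[[nm]],
                      integer(1)))
  atomIdx <- as.integer(names(indexOf$map))[ord]
  atoms <- g$atoms[atomIdx, c("element", "charge"), drop = FALSE]
  rownames(atoms) <- NULL
  remap <- match(seq_len(nrow(g$atoms)), atomIdx)
  bonds <- data.frame(a1 = remap[g$bonds$a1], a2 = remap[g$bonds$a2],
                      order = g$bonds$order)
  list(condCols = do.call(cbind, cols), atoms = atoms, bonds = bonds)
}

.gtFreeValence <- function(atoms, bondSum) {
  vapply(seq_len(nrow(atoms)), function(i) {
    v <- mgValence(atoms$element[i], atoms$charge[i], bondSum[i])
    if (is.na(v)) 0L else as.integer(max(0L, v - bondSum[i]))
  }, integer(1))
}

#' @rdname sampleMolecules
setMethod("sampleMolecules", "GraphTransformer",
          function(generator, n, inputs = NULL, seed = 1L, maxLen = 110L) {
  if (n == 0L) return(out <- character(0))
  if (is.null(inputs))
    stop("GraphTransformer requires fragment inputs for sampling")
  inputs <- rep_len(inputs, n)
  vocab <- generator@vocab
  hy <- generator@hyper
  nA <- length(vocab@atomTypes)
  typeVal <- .gtTypeValence(vocab)
  o <- opsPlain(generator@params)
  .withSeed(seed, {
    out <- character(n)
    trajectories <- vector("list", n)
    for (b in seq_len(n)) {
      cond <- .gtCondFromFragments(inputs[b], vocab)
      ctx <- .gtEncode(o, hy, cond$condCols)
      atoms <- cond$atoms
      bonds <- cond$bonds
      bondSum <- rep(0L, nrow(atoms))
      for (i in seq_len(nrow(bonds))) {
        bondSum[bonds$a1[i]] <- bondSum[bonds$a1[i]] + bonds$order[i]
        bondSum[bonds$a2[i]] <- bondSum[bonds$a2[i]] + bonds$order[i]
      }
      adjKey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
      st <- nnRecurrentInit(o, "GRU", 1L, 1L, hy$decHidden)
      prevCol <- c(1L, 0L, 0L, 0L, 0L)
      events <- list()
      steps <- 0L
      budget <- max(4L, min(hy$maxAtoms - nrow(atoms) - 1L, maxLen))
      repeat {
        steps <- steps + 1L
        xt <- cbind(o$val(.gtEmbedCols(o, matrix(prevCol, 5, 1),
                                       hy$maxAtoms)), ctx)
        step <- nnRecurrentStep(o, xt, st, "GRU", 1L)
        st <- step$state
        ht <- step$out
        freeVal <- .gtFreeValence(atoms, bondSum)
        canBond <- which(freeVal >= 1L)
        ## event mask
        evMask <- rep(0, nA + 2L)
        if (length(canBond) && nrow(atoms) < hy$maxAtoms - 1L)
          evMask[seq_len(nA)][typeVal >= 1L] <- 1
        closable <- FALSE
        if (length(canBond) >= 2L) {
          for (i in canBond) {
            others <- setdiff(canBond, i)
            others <- others[!(paste(pmin(i, others), pmax(i, others)) %in%
                                 adjKey)]
            if (length(others)) { closable <- TRUE; break }
          }
        }
        if (closable) evMask[nA + 1L] <- 1
        evMask[nA + 2L] <- 1
        if (steps > budget) evMask[seq_len(nA + 1L)] <- 0
        p <- o$softmaxRows(nnLinear(o, ht, "ev"))[1, ] * evMask
        if (sum(p) == 0) { ev <- nA + 2L } else ev <- nnSampleFrom(p)
        if (ev == nA + 2L) {
          events[[length(events) + 1L]] <- list(ev = ev, cur = NA, nbr = NA,
                                                bond = NA,
                                                col = c(2L, 0L, 0L, 0L, 0L))
          break
        }
        sampleIdx <- function(prefix, allowed) {
          mask <- rep(0, hy$maxAtoms)
          mask[allowed] <- 1       # allowed holds 1-based atom ids
          pp <- o$softmaxRows(nnLinear(o, ht, prefix))[1, ] * mask
          if (sum(pp) == 0) allowed[1] else nnSampleFrom(pp)
        }
        if (ev <= nA) {
          ## new atom of type ev, bonded to an existing free-valence atom
          newIdx <- nrow(atoms) + 1L
          at <- .gvParseAtomType(vocab@atomTypes[ev])
          if (length(canBond)) {
            nbr <- sampleIdx("nbr", canBond)
            maxOrd <- min(3L, typeVal[ev], freeVal[nbr])
            bmask <- rep(0, 3L); bmask[seq_len(maxOrd)] <- 1
            pb <- o$softmaxRows(nnLinear(o, ht, "bond"))[1, ] * bmask
            ord <- if (sum(pb) == 0) 1L else nnSampleFrom(pb)
            bonds <- rbind(bonds, data.frame(a1 = newIdx, a2 = nbr,
                                             order = ord))
            adjKey <- c(adjKey, paste(min(newIdx, nbr), max(newIdx, nbr)))
            bondSum <- c(bondSum, ord)
            bondSum[nbr] <- bondSum[nbr] + ord
          } else {
            nbr <- newIdx; ord <- 0L
            bondSum <- c(bondSum, 0L)
          }
          atoms <- rbind(atoms, data.frame(element = at$element,
                                           charge = at$charge,
                                           stringsAsFactors = FALSE))
          prevCol <- c(ev + 2L, newIdx - 1L, nbr - 1L, ord,
                       max(cond$condCols[5, ]) + 1L)
          events[[length(events) + 1L]] <- list(ev = ev, cur = NA,
                                                nbr = nbr - 1L, bond = ord,
                                                col = prevCol)
        } else {
          ## ring closure / link between two existing atoms
          curOk <- integer(0)
          for (i in canBond) {
            others <- setdiff(canBond, i)
            others <- others[!(paste(pmin(i, others), pmax(i, others)) %in%
                                 adjKey)]
            if (length(others)) curOk <- c(curOk, i)
          }
          cur <- sampleIdx("cur", curOk)
          others <- setdiff(canBond, cur)
          others <- others[!(paste(pmin(cur, others), pmax(cur, others)) %in%
                               adjKey)]
          nbr <- sampleIdx("nbr", others)
          maxOrd <- min(3L, freeVal[cur], freeVal[nbr])
          bmask <- rep(0, 3L); bmask[seq_len(maxOrd)] <- 1
          pb <- o$softmaxRows(nnLinear(o, ht, "bond"))[1, ] * bmask
          ord <- if (sum(pb) == 0) 1L else nnSampleFrom(pb)
          bonds <- rbind(bonds, data.frame(a1 = cur, a2 = nbr, order = ord))
          adjKey <- c(adjKey, paste(min(cur, nbr), max(cur, nbr)))
          bondSum[cur] <- bondSum[cur] + ord
          bondSum[nbr] <- bondSum[nbr] + ord
          code <- .gvAtomCode(vocab, .gvAtomTypeOf(atoms$element[cur],
                                                   atoms$charge[cur]))
          prevCol <- c(code, cur - 1L, nbr - 1L, ord, 0L)
          events[[length(events) + 1L]] <- list(ev = ev, cur = cur - 1L,
                                                nbr = nbr - 1L, bond = ord,
                                                col = prevCol)
        }
      }
      ## connect remaining components with single bonds where valence allows
      g <- list(atoms = atoms, bonds = bonds)
      comps <- mgComponents(g)
      if (length(comps) > 1L) {
        freeVal <- .gtFreeValence(atoms, mgBondSums(g))
        base <- comps[[1]]
        for (k in 2L:length(comps)) {
          a <- base[freeVal[base] >= 1L]
          bcand <- comps[[k]][freeVal[comps[[k]]] >= 1L]
          if (length(a) && length(bcand)) {
            g$bonds <- rbind(g$bonds, data.frame(a1 = a[1], a2 = bcand[1],
                                                 order = 1L))
            freeVal[a[1]] <- freeVal[a[1]] - 1L
            freeVal[bcand[1]] <- freeVal[bcand[1]] - 1L
            base <- c(base, comps[[k]])
          }
        }
        comps <- mgComponents(g)
        if (length(comps) > 1L) {
          sizes <- vapply(comps, length, integer(1))
          g <- mgSubgraph(g, comps[[which.max(sizes)]], addDummies = FALSE)
        }
      }
      out[b] <- mgToSmiles(g)
      trajectories[[b]] <- list(condCols = cond$condCols, events = events)
    }
    attr(out, "inputs") <- inputs
    attr(out, "trajectories") <- trajectories
    attr(out, "provenance") <- rep("agent", n)
    out
  })
})
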