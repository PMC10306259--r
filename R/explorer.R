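## The reinforcement-learning loop: sample from an agent/prior mixture,
## score with the environment, update the agent by policy gradient, track
## per-epoch metrics and keep the best epoch by desirability.

#' ExplorerConfig: reinforcement-learning settings
#'
#' `epsilon` is the agent/prior mixing rate: each generated molecule comes
#' from the frozen prior with probability `epsilon` (the analogue of a
#' mutation rate in evolutionary algorithms) and from the trainable agent
#' otherwise. When `usePeriodicAgent` is on (the default for the RNN, off
#' for the transformers), the agent's share is drawn half from the current
#' agent and half from an auxiliary copy refreshed every `syncInterval`
#' epochs (50 by default), which adds exploration.
#'
#' @slot epsilon mixing rate in \[0, 1\] (default 0.1).
#' @slot syncInterval auxiliary-refresh interval in epochs (default 50).
#' @slot usePeriodicAgent logical or `NA` (`NA` = architecture default).
#' @slot batchSize molecules per epoch.
#' @slot epochs RL epochs.
#' @slot monitorMetric epoch-selection metric (default `desired_ratio`).
#' @slot patience epochs without improvement before early stop.
#' @slot learningRate Adam learning rate for policy-gradient steps.
#' @slot seed RNG seed.
#' @slot maxLen sampling budget per molecule.
#' @export
setClass("ExplorerConfig",
  representation(epsilon = "numeric", syncInterval = "integer",
                 usePeriodicAgent = "logical", batchSize = "integer",
                 epochs = "integer", monitorMetric = "character",
                 patience = "integer", learningRate = "numeric",
                 seed = "integer", maxLen = "integer"),
  validity = function(object) {
    if (object@epsilon < 0 || object@epsilon > 1)
      return("epsilon must lie in [0, 1]")
    if (object@syncInterval < 1L) return("syncInterval must be >= 1")
    if (!object@monitorMetric %in%
          c("desired_ratio", "valid_ratio", "unique_ratio", "mean_arithmetic"))
      return("unknown monitorMetric")
    TRUE
  })

#' @rdname ExplorerConfig-class
#' @param epsilon,syncInterval,usePeriodicAgent,batchSize,epochs,monitorMetric,patience,learningRate,seed,maxLen
#'   see the class slots.
#' @export
explorerConfig <- function(epsilon = 0.1, syncInterval = 50L,
                           usePeriodicAgent = NA, batchSize = 32L,
                           epochs = 20L, monitorMetric = "desired_ratio",
                           patience = 100L, learningRate = 5e-3, seed = 1L,
                           maxLen = 110L) {
  new("ExplorerConfig", epsilon = epsilon,
      syncInterval = as.integer(syncInterval),
      usePeriodicAgent = as.logical(usePeriodicAgent),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      monitorMetric = monitorMetric, patience = as.integer(patience),
      learningRate = learningRate, seed = as.integer(seed),
      maxLen = as.integer(maxLen))
}

#' Sample a batch from the agent/prior mixture
#'
#' Each of the `n` outputs is drawn from `prior` with probability `epsilon`
#' and from `agent` otherwise; provenance is recorded in the
#' `"provenance"` attribute. Seeded and reproducible.
#'
#' @param agent,prior generators sharing a vocabulary.
#' @param epsilon prior-mixing rate in \[0, 1\].
#' @param n batch size.
#' @param inputs fragment inputs (transformers only).
#' @param seed RNG seed.
#' @param maxLen sampling budget.
#' @return character vector of SMILES with attributes `provenance` and,
#'   for fragment models, `inputs` / `trajectories`.
#' @export
mixedSample <- function(agent, prior, epsilon, n, inputs = NULL, seed = 1L,
                        maxLen = 110L) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (n == 0L) return(character(0))
  fromPrior <- .withSeed(seed, stats::runif(n) < epsilon)
  out <- character(n)
  prov <- ifelse(fromPrior, "prior", "agent")
  inp <- if (!is.null(inputs)) rep_len(inputs, n) else NULL
  traj <- vector("list", n)
  inpOut <- if (!is.null(inp)) character(n) else NULL
  for (who in c("agent", "prior")) {
    idx <- which(prov == who)
    if (!length(idx)) next
    gen <- if (who == "agent") agent else prior
    smi <- sampleMolecules(gen, length(idx),
                           inputs = if (!is.null(inp)) inp[idx] else NULL,
                           seed = seed + ifelse(who == "agent", 1L, 2L),
                           maxLen = maxLen)
    out[idx] <- as.character(smi)
    tj <- attr(smi, "trajectories")
    if (!is.null(tj)) traj[idx] <- tj
    if (!is.null(inpOut)) inpOut[idx] <- attr(smi, "inputs") %||% inp[idx]
  }
  attr(out, "provenance") <- prov
  if (!is.null(inpOut)) attr(out, "inputs") <- inpOut
  if (any(!vapply(traj, is.null, logical(1)))) {
    attr(out, "trajectories") <- traj
  }
  out
}

#' One policy-gradient step
#'
#' REINFORCE update: the batch loss is the mean over molecules of the
#' reward-weighted sequence negative log-likelihood
#' `-(sum_t log p(token_t)) * reward`, followed by one Adam step on the
#' agent. Molecules with reward 0 (including invalid ones) contribute no
#' gradient. Rewards are expected in \[0, 1\].
#'
#' @param agent the trainable generator.
#' @param batch character vector of sampled molecules (attributes from
#'   [sampleMolecules()] are used where present, e.g. graph trajectories).
#' @param rewards numeric vector, one reward per molecule.
#' @param learningRate Adam step size.
#' @return list with the updated `agent` and the scalar `loss`.
#' @export
policyGradientUpdate <- function(agent, batch, rewards,
                                 learningRate = 5e-3) {
  n <- length(batch)
  stopifnot(length(rewards) == n)
  if (any(!is.finite(rewards))) stop("non-finite rewards")
  if (!length(agent@optState)) agent@optState <- adamState(agent@params)
  if (is(agent, "RnnGenerator")) {
    enc <- lapply(as.character(batch), function(s) {
      tryCatch(c(2L, .svCode(agent@vocab, tokenizeSmiles(s)), 3L),
               error = function(e) NULL)
    })
    ok <- !vapply(enc, is.null, logical(1))
    enc <- enc[ok]; w <- rewards[ok]
    if (!length(enc)) return(list(agent = agent, loss = 0))
    T <- max(vapply(enc, length, integer(1)))
    codes <- t(vapply(enc, function(e) c(e, rep(1L, T - length(e))),
                      integer(T)))
    lg <- .rnnLossGrad(agent, codes, seqWeights = w)
  } else if (is(agent, "SeqTransformer")) {
    inputs <- attr(batch, "inputs")
    if (is.null(inputs)) stop("SeqTransformer policy update needs inputs")
    items <- list(); w <- numeric(0)
    for (i in seq_len(n)) {
      it <- tryCatch(
        .seqTransEncodePair(agent@vocab, inputs[i], as.character(batch)[i],
                            agent@hyper$maxLen),
        error = function(e) NULL)
      if (!is.null(it)) { items[[length(items) + 1L]] <- it
                          w <- c(w, rewards[i]) }
    }
    if (!length(items)) return(list(agent = agent, loss = 0))
    lg <- .seqTransLoss(agent, items, seqWeights = w, wantGrads = TRUE)
  } else {
    traj <- attr(batch, "trajectories")
    if (is.null(traj)) stop("GraphTransformer policy update needs the ",
                            "sampling trajectories")
    items <- lapply(traj, function(tj) {
      ev <- lapply(tj$events, function(e) {
        hasBond <- !is.null(e$bond) && !is.na(e$bond) && isTRUE(e$bond > 0)
        list(ev = e$ev,
             cur = if (is.null(e$cur) || is.na(e$cur)) NA_integer_
                   else as.integer(e$cur),
             nbr = if (is.null(e$nbr) || is.na(e$nbr)) NA_integer_
                   else as.integer(e$nbr),
             bond = e$bond, hasBond = hasBond, col = as.integer(e$col))
      })
      list(condCols = tj$condCols, events = ev, nEvents = length(ev))
    })
    lg <- .gtLossGrad(agent, items, seqWeights = rewards)
  }
  if (!is.finite(lg$loss)) stop("policy gradient produced non-finite loss")
  if (length(lg$grads)) {
    upd <- adamStep(agent@params, lg$grads, agent@optState, learningRate)
    agent@params <- upd$params
    agent@optState <- upd$state
  }
  list(agent = agent, loss = lg$loss)
}

#' Per-epoch generation metrics
#'
#' Computes the fraction of valid (parsable) molecules, the unique ratio
#' (distinct canonical SMILES over batch size), the desired ratio from the
#' score table, for fragment models the accuracy (valid outputs containing
#' all their input fragments as substructures), and the batch averages of
#' the per-molecule arithmetic and geometric mean modified scores (valid
#' molecules only; zero when none). Per-objective mean modified scores are
#' attached as `perObjective`.
#'
#' @param batch character vector of sampled molecules.
#' @param scoreTable the [ScoreTable-class] for the batch.
#' @param fragmentInputs optional character vector of `"."`-joined input
#'   fragments, parallel to `batch`.
#' @return list of metrics.
#' @export
computeMetrics <- function(batch, scoreTable, fragmentInputs = NULL) {
  n <- length(batch)
  can <- canonicalSmiles(as.character(batch))
  valid <- nzchar(can)
  validRatio <- if (n) mean(valid) else 0
  uniqueRatio <- if (n) length(unique(can[valid])) / n else 0
  desiredRatio <- if (n) mean(scoreTable@desired) else 0
  accurate <- NA_real_
  if (!is.null(fragmentInputs)) {
    hits <- vapply(which(valid), function(i) {
      fr <- strsplit(fragmentInputs[i], ".", fixed = TRUE)[[1]]
      all(vapply(fr, function(f) isTRUE(hasSubstructure(can[i], f)),
                 logical(1)))
    }, logical(1))
    accurate <- if (any(valid)) mean(hits) else 0
  }
  mod <- scoreTable@modified
  if (any(valid)) {
    rowsA <- rowMeans(mod[valid, , drop = FALSE])
    rowsG <- exp(rowMeans(log(pmax(mod[valid, , drop = FALSE], 1e-12))))
    meanA <- mean(rowsA); meanG <- mean(rowsG)
  } else {
    meanA <- 0; meanG <- 0
  }
  list(valid_ratio = validRatio, accurate_ratio = accurate,
       unique_ratio = uniqueRatio, desired_ratio = desiredRatio,
       mean_arithmetic = meanA, mean_geometric = meanG,
       perObjective = colMeans(mod[valid, , drop = FALSE]))
}

#' Reinforcement-learning training loop
#'
#' Per epoch: sample a batch from the agent/prior mixture, score it with
#' the environment, convert modified scores to scalar rewards with the
#' environment's ranking scheme (invalid molecules always get reward 0),
#' apply one policy-gradient step, and log metrics. The best epoch by
#' `monitorMetric` (desirability ratio by default) is kept and returned;
#' training stops early after `patience` epochs without improvement. When
#' the periodic auxiliary agent is enabled it is refreshed from the current
#' agent every `syncInterval` epochs. A failing epoch is skipped and
#' logged; training aborts after 5 consecutive failures.
#'
#' @param agent trainable generator (sampled and updated).
#' @param prior frozen exploration generator sharing the agent vocabulary.
#' @param environment a [ScoringEnvironment-class].
#' @param config an [ExplorerConfig-class].
#' @param inputs fragment inputs for transformer agents.
#' @param outDir optional directory for TSV logs, per-epoch molecules and
#'   the best checkpoint.
#' @return list: `agent` (best epoch), `log` (one row per epoch),
#'   `bestEpoch`.
#' @export
rlTrain <- function(agent, prior, environment, config = explorerConfig(),
                    inputs = NULL, outDir = NULL) {
  usePeriodic <- config@usePeriodicAgent
  if (is.na(usePeriodic)) usePeriodic <- is(agent, "RnnGenerator")
  if (config@epochs == 0L) {
    return(list(agent = agent, log = data.frame(), bestEpoch = 0L))
  }
  aux <- agent
  best <- list(agent = agent, value = -Inf, epoch = 0L)
  sinceBest <- 0L
  failures <- 0L
  syncEpochs <- integer(0)
  rows <- list()
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  for (epoch in seq_len(config@epochs)) {
    epochSeed <- config@seed + epoch * 131L
    res <- tryCatch({
      ## agent pool: current agent, optionally alternated with the
      ## periodically synced auxiliary copy
      sampler <- if (usePeriodic && epoch > 1L) {
        half <- .withSeed(epochSeed + 3L,
                          stats::runif(config@batchSize) < 0.5)
        smiA <- mixedSample(agent, prior, config@epsilon, config@batchSize,
                            inputs = inputs, seed = epochSeed,
                            maxLen = config@maxLen)
        smiB <- mixedSample(aux, prior, config@epsilon, config@batchSize,
                            inputs = inputs, seed = epochSeed + 7L,
                            maxLen = config@maxLen)
        out <- ifelse(half, as.character(smiA), as.character(smiB))
        for (at in c("provenance", "inputs")) {
          a1 <- attr(smiA, at); a2 <- attr(smiB, at)
          if (!is.null(a1)) attr(out, at) <- ifelse(half, a1, a2)
        }
        t1 <- attr(smiA, "trajectories"); t2 <- attr(smiB, "trajectories")
        if (!is.null(t1)) {
          tj <- t1; tj[!half] <- t2[!half]
          attr(out, "trajectories") <- tj
        }
        out
      } else {
        mixedSample(agent, prior, config@epsilon, config@batchSize,
                    inputs = inputs, seed = epochSeed,
                    maxLen = config@maxLen)
      }
      batch <- sampler
      tab <- scoreBatch(environment, as.character(batch))
      rewards <- tab@reward
      rewards[!nzchar(canonicalSmiles(as.character(batch)))] <- 0
      upd <- policyGradientUpdate(agent, batch, rewards,
                                  learningRate = config@learningRate)
      metrics <- computeMetrics(batch, tab, attr(batch, "inputs"))
      list(agent = upd$agent, loss = upd$loss, metrics = metrics,
           batch = batch, tab = tab)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning("epoch ", epoch, " failed: ", conditionMessage(res),
              call. = FALSE)
      if (failures >= 5L) stop("rlTrain: too many consecutive failures")
      next
    }
    failures <- 0L
    agent <- res$agent
    m <- res$metrics
    rows[[length(rows) + 1L]] <-
      data.frame(epoch = epoch, loss = res$loss,
                 valid = m$valid_ratio,
                 accurate = m$accurate_ratio %||% NA_real_,
                 unique = m$unique_ratio, desired = m$desired_ratio,
                 mean_arithmetic = m$mean_arithmetic,
                 mean_geometric = m$mean_geometric)
    if (!is.null(outDir)) {
      writeScoreTable(res$tab,
                      file.path(outDir, sprintf("epoch_%03d.tsv", epoch)))
    }
    value <- m[[config@monitorMetric]]
    if (value > best$value + 1e-12) {
      best <- list(agent = agent, value = value, epoch = epoch)
      sinceBest <- 0L
      if (!is.null(outDir)) {
        saveGenerator(agent, file.path(outDir, "agent_best.rds"))
      }
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest > config@patience) break
    }
    if (usePeriodic && epoch %% config@syncInterval == 0L) {
      aux <- agent
      syncEpochs <- c(syncEpochs, epoch)
    }
  }
  log <- do.call(rbind, rows) %||% data.frame()
  if (!is.null(outDir) && nrow(log)) {
    utils::write.table(log, file.path(outDir, "rl_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(agent = best$agent, log = log, bestEpoch = best$epoch,
       syncEpochs = syncEpochs)
}
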