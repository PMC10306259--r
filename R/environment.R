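## The scoring environment: objectives (scorers), desirability modifiers,
## thresholds, and the batch scoring pipeline raw -> modified -> desired.

## ---- modifiers -------------------------------------------------------------

#' Desirability modifiers
#'
#' Modifiers map raw objective scores onto \[0, 1\] desirability values.
#' `modifierClipped` is the monotone piecewise-linear ramp: 0 at/beyond
#' `low`, 1 at/beyond `high`, linear between (reversed when `low > high`).
#' `modifierGaussian` is `exp(-(x - center)^2 / (2 sigma^2))`.
#' `modifierSmoothHump` is a plateau function: (approximately) 1 on
#' `[lower, upper]`, decaying smoothly outside on a scale set by `width`;
#' it is built as a product of two logistic sigmoids shifted outward by
#' `width`, rescaled so its supremum (at the plateau midpoint) is exactly 1.
#' `modifierIdentity` clamps to \[0, 1\] and is intended for scorers that
#' already emit desirability values.
#'
#' @param low,high ramp anchors (must differ).
#' @param center,sigma Gaussian location and positive scale.
#' @param lower,upper plateau bounds (`lower < upper`).
#' @param width positive decay scale outside the plateau.
#' @return a `Modifier` object: a function of a numeric vector, with
#'   attributes `kind` and `parameters`.
#' @name modifiers
NULL

.modifier <- function(fun, kind, parameters) {
  structure(fun, kind = kind, parameters = parameters,
            class = c("Modifier", "function"))
}

#' @rdname modifiers
#' @export
modifierClipped <- function(low, high) {
  if (low == high) stop("modifierClipped: low and high must differ")
  .modifier(function(x) {
    y <- (x - low) / (high - low)
    pmin(1, pmax(0, y))
  }, "ClippedScore", list(low = low, high = high))
}

#' @rdname modifiers
#' @export
modifierGaussian <- function(center, sigma) {
  if (sigma <= 0) stop("modifierGaussian: sigma must be positive")
  .modifier(function(x) exp(-(x - center)^2 / (2 * sigma^2)),
            "Gaussian", list(center = center, sigma = sigma))
}

#' @rdname modifiers
#' @export
modifierSmoothHump <- function(lower, upper, width) {
  if (lower >= upper) stop("modifierSmoothHump: lower must be < upper")
  if (width <= 0) stop("modifierSmoothHump: width must be positive")
  tau <- width / 5
  sig <- function(z) 1 / (1 + exp(-z))
  mid <- (lower + upper) / 2
  peak <- sig((mid - lower + width) / tau) * sig((upper + width - mid) / tau)
  .modifier(function(x) {
    pmin(1, sig((x - lower + width) / tau) *
             sig((upper + width - x) / tau) / peak)
  }, "SmoothHump", list(lower = lower, upper = upper, width = width))
}

#' @rdname modifiers
#' @export
modifierIdentity <- function() {
  .modifier(function(x) pmin(1, pmax(0, x)), "Identity", list())
}

## ---- scorers ---------------------------------------------------------------

#' Built-in objective scorers
#'
#' Scorers map a character vector of SMILES to a numeric vector of raw
#' scores; invalid molecules score `NA`. Custom scorers are created with
#' [scorerCustom()] from any such function, which is also the plug-in point
#' for external QSAR/QSPR predictors.
#'
#' * `scorerMolWeight()`: average molecular weight (Da).
#' * `scorerLogP()`: octanol-water partition estimate (Open Babel logP).
#' * `scorerTanimoto(reference)`: Tanimoto similarity to a reference
#'   structure on 2048-bit circular fingerprints (radius 2); a molecule is
#'   maximally similar to itself.
#' * `scorerSAProxy()`: a simple synthetic-complexity proxy on a 1-10 scale
#'   built from size, ring count and heteroatom fraction. It is a stand-in
#'   descriptor, not a trained synthetic-accessibility model.
#' * `scorerLigandEfficiency(affinity)`: 1.4 x predicted pAffinity / heavy
#'   atom count, with `affinity` a function SMILES -> numeric (or a single
#'   constant).
#' * `scorerElementPresence(element)`: binary 0/1 presence of an element.
#'
#' @param name scorer name (for tables and config files).
#' @param fun function mapping a character vector of SMILES to numerics.
#' @param direction `"maximize"`, `"minimize"`, or `"target-range"` (an
#'   annotation consumed by modifier choice, not by the scorer itself).
#' @param reference reference SMILES for similarity scoring.
#' @param affinity function of SMILES returning predicted pAffinity, or a
#'   single numeric constant.
#' @param element element symbol, e.g. `"N"`.
#' @return a `Scorer` object.
#' @name scorers
NULL

#' @rdname scorers
#' @export
scorerCustom <- function(name, fun, direction = "maximize") {
  structure(list(name = name, fun = fun, direction = direction),
            class = "Scorer")
}

.scorePerMol <- function(smiles, one) {
  vapply(smiles, function(s) {
    g <- mgFromSmiles(s)
    if (is.null(g)) return(NA_real_)
    one(s, g)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname scorers
#' @export
scorerMolWeight <- function() {
  scorerCustom("mol_weight", function(smiles) {
    .scorePerMol(smiles, function(s, g) {
      p <- .obProps(s)
      if (is.null(p)) mgMolWeight(g) else as.numeric(p$MW)
    })
  }, direction = "target-range")
}

#' @rdname scorers
#' @export
scorerLogP <- function() {
  scorerCustom("logp", function(smiles) {
    .scorePerMol(smiles, function(s, g) {
      p <- .obProps(s)
      if (is.null(p)) NA_real_ else as.numeric(p$logP)
    })
  }, direction = "target-range")
}

#' @rdname scorers
#' @export
scorerTanimoto <- function(reference) {
  refGraph <- mgFromSmiles(reference)
  if (is.null(refGraph)) stop("scorerTanimoto: invalid reference SMILES")
  refFp <- mgMorganFingerprint(refGraph)
  sc <- scorerCustom(paste0("tanimoto_", substr(reference, 1, 12)),
               function(smiles) {
    .scorePerMol(smiles, function(s, g) {
      fp <- mgMorganFingerprint(g)
      u <- sum(fp | refFp)
      if (u == 0) 0 else sum(fp & refFp) / u
    })
  })
  attr(sc, "params") <- list(reference = reference)
  sc
}

#' @rdname scorers
#' @export
scorerSAProxy <- function() {
  scorerCustom("sa_proxy", function(smiles) {
    .scorePerMol(smiles, function(s, g) {
      nHeavy <- sum(g$atoms$element != "H")
      nRings <- length(mgRings(g))
      hetFrac <- mean(!g$atoms$element %in% c("C", "H"))
      min(10, 1 + nHeavy / 12 + nRings + 3 * hetFrac)
    })
  }, direction = "minimize")
}

#' @rdname scorers
#' @export
scorerLigandEfficiency <- function(affinity) {
  affFun <- if (is.function(affinity)) affinity else function(s) {
    rep(as.numeric(affinity), length(s))
  }
  sc <- scorerCustom("ligand_efficiency", function(smiles) {
    aff <- affFun(smiles)
    ha <- .scorePerMol(smiles, function(s, g) sum(g$atoms$element != "H"))
    ifelse(is.na(ha) | ha == 0, NA_real_, 1.4 * aff / ha)
  })
  if (!is.function(affinity)) attr(sc, "params") <- list(affinity = affinity)
  sc
}

#' @rdname scorers
#' @export
scorerElementPresence <- function(element) {
  scorerCustom(paste0("contains_", element), function(smiles) {
    .scorePerMol(smiles, function(s, g) {
      as.numeric(any(g$atoms$element == element))
    })
  })
}

## ---- objectives and environment -------------------------------------------

#' Bundle a scorer, a modifier and a desirability threshold
#'
#' @param scorer a `Scorer` (see [scorers]).
#' @param modifier a `Modifier` (see [modifiers]).
#' @param threshold desirability threshold in \[0, 1\] (default 0.5). A
#'   compound is desired when its modified score meets or exceeds the
#'   threshold on every objective.
#' @param name optional objective name; defaults to the scorer name.
#' @return an `Objective` object.
#' @export
objective <- function(scorer, modifier, threshold = 0.5, name = NULL) {
  stopifnot(inherits(scorer, "Scorer"), inherits(modifier, "Modifier"))
  if (threshold < 0 || threshold > 1)
    stop("objective: threshold must lie in [0, 1]")
  structure(list(scorer = scorer, modifier = modifier, threshold = threshold,
                 name = name %||% scorer$name),
            class = "Objective")
}

#' ScoringEnvironment: objectives plus a ranking scheme
#'
#' An ordered list of (scorer, modifier, threshold) objectives together with
#' the multiobjective ranking scheme that turns modified scores into scalar
#' rewards: `"WS"` (dynamic weighted sum), `"PRCD"` (Pareto fronts ranked by
#' crowding distance), or `"PRTD"` (Pareto fronts ranked by mean Tanimoto
#' distance within the front).
#'
#' @slot objectives list of `Objective` objects.
#' @slot scheme ranking scheme name.
#' @export
setClass("ScoringEnvironment",
  representation(objectives = "list", scheme = "character"),
  validity = function(object) {
    if (!length(object@objectives)) return("at least one objective required")
    if (!all(vapply(object@objectives, inherits, logical(1), "Objective")))
      return("objectives must be Objective objects")
    if (!object@scheme %in% c("WS", "PRCD", "PRTD"))
      return("scheme must be one of WS, PRCD, PRTD")
    TRUE
  })

#' @rdname ScoringEnvironment-class
#' @param objectives list of [objective()] bundles.
#' @param scheme ranking scheme, one of `"WS"`, `"PRCD"`, `"PRTD"`.
#' @export
scoringEnvironment <- function(objectives, scheme = c("WS", "PRCD", "PRTD")) {
  new("ScoringEnvironment", objectives = objectives,
      scheme = match.arg(scheme))
}

setMethod("show", "ScoringEnvironment", function(object) {
  cat("ScoringEnvironment:", length(object@objectives), "objectives,",
      object@scheme, "ranking\n")
  for (ob in object@objectives) {
    cat(sprintf("  - %s | %s | threshold %.2f\n", ob$name,
                attr(ob$modifier, "kind"), ob$threshold))
  }
})

#' Score a batch of molecules
#'
#' Runs the three scoring stages: raw per-objective scores, modifier
#' scaling to \[0, 1\], and the desirability verdict (all modified scores at
#' or above their thresholds). Invalid molecules receive modified score 0 on
#' every objective and are never desired. A scorer that raises leaves its
#' column `NA` (logged as a warning) and the batch continues; the failed
#' column does not count against desirability. Scalar rewards are then
#' assigned by the environment's ranking scheme (see [assignRewards()]).
#'
#' @param env a [ScoringEnvironment-class].
#' @param smiles character vector of molecules.
#' @param computeRewards if `TRUE` (default) fill the reward column.
#' @return a [ScoreTable-class].
#' @export
scoreBatch <- function(env, smiles, computeRewards = TRUE) {
  n <- length(smiles)
  k <- length(env@objectives)
  valid <- nzchar(canonicalSmiles(smiles))
  raw <- matrix(NA_real_, n, k)
  mod <- matrix(0, n, k)
  failed <- logical(k)
  names <- vapply(env@objectives, `[[`, character(1), "name")
  colnames(raw) <- colnames(mod) <- names
  for (j in seq_len(k)) {
    ob <- env@objectives[[j]]
    r <- tryCatch(ob$scorer$fun(smiles), error = function(e) {
      warning("scorer '", ob$name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      failed[j] <<- TRUE
      rep(NA_real_, n)
    })
    if (length(r) != n)
      stop("scorer '", ob$name, "' returned ", length(r),
           " scores for ", n, " molecules")
    raw[, j] <- r
    m <- ob$modifier(r)
    m[!valid | is.na(r)] <- 0
    mod[, j] <- m
  }
  thr <- vapply(env@objectives, `[[`, numeric(1), "threshold")
  consider <- !failed
  des <- valid & apply(mod[, consider, drop = FALSE] >=
                         rep(thr[consider], each = n), 1, all)
  tab <- new("ScoreTable", smiles = as.character(smiles), raw = raw,
             modified = mod, desired = des, reward = rep(0, n),
             thresholds = thr)
  if (computeRewards) tab <- assignRewards(env, tab)
  tab
}

#' Serialize / restore a scoring-environment configuration
#'
#' The configuration file (YAML or JSON, chosen by extension) records each
#' objective's scorer name and parameters, modifier kind and parameters, and
#' threshold, plus the ranking scheme. Only built-in scorers can be
#' round-tripped; custom function scorers must be re-registered in code.
#'
#' @param env a [ScoringEnvironment-class].
#' @param path output/input path ending in `.yml`, `.yaml` or `.json`.
#' @return `writeEnvironmentConfig` returns `path` invisibly;
#'   `readEnvironmentConfig` returns a [ScoringEnvironment-class].
#' @export
writeEnvironmentConfig <- function(env, path) {
  cfg <- list(
    scheme = env@scheme,
    objectives = lapply(env@objectives, function(ob) {
      sc <- ob$scorer
      list(name = ob$name,
           scorer = sc$name,
           scorer_params = attr(sc, "params") %||% list(),
           modifier = attr(ob$modifier, "kind"),
           modifier_params = attr(ob$modifier, "parameters"),
           threshold = ob$threshold)
    }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

.scorerFromName <- function(name, params) {
  if (name == "mol_weight") return(scorerMolWeight())
  if (name == "logp") return(scorerLogP())
  if (name == "sa_proxy") return(scorerSAProxy())
  if (startsWith(name, "contains_"))
    return(scorerElementPresence(sub("^contains_", "", name)))
  if (startsWith(name, "tanimoto_") && !is.null(params$reference))
    return(scorerTanimoto(params$reference))
  if (name == "ligand_efficiency" && !is.null(params$affinity))
    return(scorerLigandEfficiency(params$affinity))
  stop("unknown scorer in environment config: ", name)
}

.modifierFromConfig <- function(kind, p) {
  switch(kind,
    ClippedScore = modifierClipped(p$low, p$high),
    Gaussian = modifierGaussian(p$center, p$sigma),
    SmoothHump = modifierSmoothHump(p$lower, p$upper, p$width),
    Identity = modifierIdentity(),
    stop("unknown modifier kind: ", kind))
}

#' @rdname writeEnvironmentConfig
#' @export
readEnvironmentConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  objs <- lapply(cfg$objectives, function(o) {
    objective(.scorerFromName(o$scorer, o$scorer_params),
              .modifierFromConfig(o$modifier, o$modifier_params),
              threshold = o$threshold, name = o$name)
  })
  scoringEnvironment(objs, scheme = cfg$scheme)
}

#' Write a ScoreTable as TSV
#'
#' One row per molecule with raw and modified columns per objective plus the
#' desired flag and reward.
#'
#' @param tab a [ScoreTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(tab, path) {
  df <- data.frame(SMILES = tab@smiles, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(tab@raw))) {
    df[[paste0(colnames(tab@raw)[j], "_raw")]] <- tab@raw[, j]
    df[[paste0(colnames(tab@raw)[j], "_mod")]] <- tab@modified[, j]
  }
  df$desired <- tab@desired
  df$reward <- tab@reward
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
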