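## Cross-validation orchestrator, performance metrics, permutation nulls and
## group-difference tests.
##
## The modeling protocol, per drug: (0) discard cell lines without a measured
## AUC; (1) split lines into nFolds folds; (2') transform expression and
## filter features on training lines only; (3) standardize with training
## parameters; (4-5) select hyperparameters (e.g. the number of PLS
## components) by nested CV inside the training fold; (6) transform the test
## fold with the training parameters and predict; (7) iterate folds so every
## line is predicted exactly once; (8) score predictions against measured
## AUC; (9) repeat with fresh fold assignments and average the scores.

#' Cross-validation configuration
#'
#' @slot nFolds outer folds (default 10).
#' @slot nRepeats outer repeats (default 100).
#' @slot nestedNFolds folds of the inner hyperparameter CV (default 10).
#' @slot pcMin,pcMax PLS component search range (defaults 1, 10).
#' @slot seed master seed; all fold assignments and shuffles derive from it.
#' @slot metric "spearman" or "r2" (primary metric for permutation tests).
#' @export
setClass("CVConfig", representation(
  nFolds = "integer", nRepeats = "integer", nestedNFolds = "integer",
  pcMin = "integer", pcMax = "integer", seed = "integer", metric = "character"))

setValidity("CVConfig", function(object) {
  msgs <- character()
  if (object@nFolds < 2L) msgs <- c(msgs, "nFolds must be at least 2")
  if (object@pcMin > object@pcMax) msgs <- c(msgs, "pcMin must not exceed pcMax")
  if (!object@metric %in% c("spearman", "r2"))
    msgs <- c(msgs, "metric must be 'spearman' or 'r2'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CVConfig-class
#' @param nFolds,nRepeats,nestedNFolds,pcMin,pcMax,seed,metric see slots.
#' @export
cvConfig <- function(nFolds = 10L, nRepeats = 100L, nestedNFolds = 10L,
                     pcMin = 1L, pcMax = 10L, seed = 1L,
                     metric = c("spearman", "r2")) {
  cfg <- new("CVConfig", nFolds = as.integer(nFolds),
             nRepeats = as.integer(nRepeats),
             nestedNFolds = as.integer(nestedNFolds),
             pcMin = as.integer(pcMin), pcMax = as.integer(pcMax),
             seed = as.integer(seed), metric = match.arg(metric))
  validObject(cfg)
  cfg
}

#' Specify a learner for the cross-validation pipeline
#'
#' @param name one of "pls", "tree", "enet", "lasso", "maxcorr" or "mean"
#'   (training-mean baseline).
#' @param ... learner-specific settings (e.g. `minBucket` for "tree",
#'   `alpha`/`lambda` to pin elastic-net hyperparameters instead of nested
#'   selection).
#' @return a learner specification for [repeatedNestedCV()].
#' @export
learnerSpec <- function(name = c("pls", "tree", "enet", "lasso", "maxcorr",
                                 "mean"), ...) {
  structure(list(name = match.arg(name), params = list(...)),
            class = "learnerSpec")
}

## ---- metrics ---------------------------------------------------------------

#' Fraction of variance explained
#'
#' R^2 = 1 - <(ahat_i - a_i)^2> / <(a_i - abar)^2>, with abar the mean
#' measured AUC. May be negative (worse than the mean predictor); equals 1
#' iff the prediction is perfect.
#'
#' @param a measured values (non-constant, length >= 2).
#' @param ahat predicted values.
#' @return scalar R^2.
#' @export
r2Explained <- function(a, ahat) {
  stopifnot(length(a) == length(ahat), length(a) >= 2L)
  denom <- mean((a - mean(a))^2)
  if (denom == 0) stop("measured values are constant; R^2 undefined")
  1 - mean((ahat - a)^2) / denom
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged). Returns NA with a
#' warning when either vector is constant.
#'
#' @param a,ahat numeric vectors (length >= 3).
#' @return scalar rho.
#' @export
spearmanRho <- function(a, ahat) {
  stopifnot(length(a) == length(ahat), length(a) >= 3L)
  if (sd(a) == 0 || sd(ahat) == 0) {
    warning("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(a, ahat, method = "spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted vector.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Welch's two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided. The
#' degenerate case of zero variance in both groups with equal means returns
#' t = 0, p = 1.
#'
#' @param values numeric vector (e.g. one drug's AUCs).
#' @param groups binary labels, both groups with >= 2 members.
#' @return named vector c(t, df, p).
#' @export
welchGroupTest <- function(values, groups) {
  g <- split(values, groups)
  if (length(g) != 2L || any(lengths(g) < 2L))
    stop("need exactly two groups with at least 2 members each")
  if (sd(g[[1]]) == 0 && sd(g[[2]]) == 0 && mean(g[[1]]) == mean(g[[2]]))
    return(c(t = 0, df = sum(lengths(g)) - 2, p = 1))
  ht <- t.test(g[[1]], g[[2]], var.equal = FALSE)
  c(t = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value))
}

#' Select the number of PLS components from a nested-CV RMS curve
#'
#' The smallest component count PC where moving to PC + 1 increases the RMS;
#' if the RMS never increases, the largest count tried.
#'
#' @param nestedRms RMS values indexed by component count pcMin..pcMax.
#' @param pcMin component count of the first entry.
#' @return the selected component count.
#' @export
selectNcomp <- function(nestedRms, pcMin = 1L) {
  stopifnot(length(nestedRms) >= 1L)
  up <- which(diff(nestedRms) > 0)
  pcMin + (if (length(up)) up[1L] - 1L else length(nestedRms) - 1L)
}

## ---- fold-wise preparation -------------------------------------------------

## Normalize the x argument to a list of pre-transformed blocks.
.asBlocks <- function(x) {
  if (is(x, "OmicMatrix")) x <- list(x)
  if (is.matrix(x)) x <- list(OmicMatrix(x, "protein", transformed = TRUE))
  lapply(x, function(b) {
    if (is.matrix(b)) b <- OmicMatrix(b, "protein", transformed = TRUE)
    stopifnot(is(b, "OmicMatrix"))
    if (!b@transformed && b@dataType != "mutation") transformExpression(b)
    else b
  })
}

## Fold-wise filter (training statistics only) for one block's value matrix.
.foldFilterCols <- function(v, dataType, trIdx) {
  tr <- v[trIdx, , drop = FALSE]
  if (dataType == "mutation") {
    s <- colSums(tr)
    keep <- s >= 3 & s <= nrow(tr) - 3
  } else {
    th <- .filterThresholds[[dataType]]
    keep <- colMeans(tr) >= th$minMean & colSds(tr) >= th$minSd
    keep[is.na(keep)] <- FALSE
  }
  if (!any(keep))
    stop("no ", dataType, " features survive the training-fold filters")
  which(keep)
}

## Prepare one outer fold: per block filter + standardize on training lines,
## apply to all lines; returns combined standardized matrices.
.prepareFold <- function(blocks, trIdx, teIdx) {
  trList <- list(); teList <- list()
  for (b in blocks) {
    v <- b@values
    keep <- .foldFilterCols(v, b@dataType, trIdx)
    v <- v[, keep, drop = FALSE]
    st <- .fitScaleState(v[trIdx, , drop = FALSE])
    trList[[length(trList) + 1L]] <-
      applyStandardizer(v[trIdx, , drop = FALSE], st)
    teList[[length(teList) + 1L]] <-
      applyStandardizer(v[teIdx, , drop = FALSE], st)
  }
  list(train = do.call(cbind, trList), test = do.call(cbind, teList))
}

## ---- learner training with nested hyperparameter selection -----------------

## Nested-CV RMS curve over component counts for PLS, then final fit.
.fitPLSNested <- function(Xtr, ytr, cv, seed) {
  n <- nrow(Xtr)
  innerK <- min(cv@nestedNFolds, n)
  folds <- foldAssignment(n, innerK, seed)
  pcMax <- min(cv@pcMax, n - ceiling(n / innerK) - 1L, ncol(Xtr))
  pcMax <- max(pcMax, cv@pcMin)
  rms <- .cppPls1InnerRms(Xtr, ytr, as.integer(folds), pcMax)
  idx <- seq(cv@pcMin, pcMax)
  ncomp <- selectNcomp(rms[idx], pcMin = cv@pcMin)
  suppressWarnings(plsFit(Xtr, ytr, ncomp = ncomp))
}

## Lasso lambda by inner CV (alpha fixed at 1).
.fitLassoNested <- function(Xtr, ytr, cv, seed) {
  path <- glmnet::glmnet(Xtr, ytr, alpha = 1, nlambda = 30,
                         standardize = FALSE)$lambda
  folds <- foldAssignment(nrow(Xtr), min(cv@nestedNFolds, nrow(Xtr)), seed)
  sse <- rep(0, length(path))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    fitk <- glmnet::glmnet(Xtr[tr, , drop = FALSE], ytr[tr], alpha = 1,
                           lambda = path, standardize = FALSE)
    pr <- predict(fitk, Xtr[!tr, , drop = FALSE], s = path)
    sse <- sse + colSums((pr - ytr[!tr])^2)
  }
  best <- path[order(sqrt(sse), -path)[1L]]
  elasticNetFit(Xtr, ytr, alpha = 1, lambda = best)
}

.trainLearner <- function(learner, Xtr, ytr, cv, seed) {
  p <- learner$params
  switch(learner$name,
    pls = .fitPLSNested(Xtr, ytr, cv, seed),
    tree = treeFit(Xtr, ytr, minBucket = p$minBucket %||% 5L,
                   nestedNFolds = cv@nestedNFolds, seed = seed),
    enet = {
      if (!is.null(p$alpha) && !is.null(p$lambda))
        elasticNetFit(Xtr, ytr, alpha = p$alpha, lambda = p$lambda)
      else {
        sel <- selectAlphaLambda(Xtr, ytr, nestedNFolds = cv@nestedNFolds,
                                 seed = seed)
        elasticNetFit(Xtr, ytr, alpha = sel$alpha, lambda = sel$lambda)
      }
    },
    lasso = .fitLassoNested(Xtr, ytr, cv, seed),
    maxcorr = maxCorrFit(Xtr, ytr),
    mean = structure(list(mean = mean(ytr)), class = "meanModel"),
    stop("unknown learner: ", learner$name))
}

.predictLearner <- function(model, Xte) {
  if (inherits(model, "meanModel"))
    return(setNames(rep(model$mean, nrow(Xte)), rownames(Xte)))
  predictAUC(model, Xte)
}

## ---- the orchestrator ------------------------------------------------------

#' Repeated nested cross-validation of one drug's sensitivity model
#'
#' Runs the full leakage-free protocol (see file header): per repeat, a
#' seeded random partition into folds; within each training fold the
#' expression transform, feature filters and standardization are fitted on
#' training lines only, hyperparameters are selected by nested CV, and the
#' held-out fold is transformed with the training parameters and predicted.
#' Per-repeat Spearman rho, R^2 and RMS are averaged over repeats; per-cell-
#' line predictions are reported as the across-repeat mean.
#'
#' @param x an [OmicMatrix-class], plain matrix (treated as pre-transformed),
#'   or a list of blocks for early integration.
#' @param y named numeric AUC vector over the cell lines (NAs dropped).
#' @param learner a [learnerSpec()].
#' @param cv a [cvConfig()].
#' @return a [PredictionResult-class].
#' @export
repeatedNestedCV <- function(x, y, learner = learnerSpec("pls"),
                             cv = cvConfig()) {
  blocks <- .asBlocks(x)
  lines <- rownames(blocks[[1L]]@values)
  for (b in blocks)
    if (!identical(rownames(b@values), lines))
      stop("blocks must share the same cell lines in the same order")
  if (!is.null(names(y))) y <- y[lines]
  ok <- !is.na(y)
  y <- y[ok]
  blocks <- lapply(blocks, function(b)
    initialize(b, values = b@values[ok, , drop = FALSE]))
  n <- length(y)
  nFolds <- cv@nFolds
  if (n < 2L * nFolds) {
    nFolds <- max(2L, n %/% 2L)
    warning("too few cell lines for ", cv@nFolds, " folds; using ", nFolds)
  }
  predSum <- rep(0, n)
  perRepeat <- data.frame(rho = numeric(cv@nRepeats),
                          r2 = numeric(cv@nRepeats),
                          rms = numeric(cv@nRepeats))
  for (r in seq_len(cv@nRepeats)) {
    folds <- foldAssignment(n, nFolds,
                            streamSeed(cv@seed, paste0("repeat_", r)))
    pred <- rep(NA_real_, n)
    for (k in sort(unique(folds))) {
      te <- folds == k
      prep <- .prepareFold(blocks, which(!te), which(te))
      model <- .trainLearner(learner, prep$train, y[!te], cv,
                             streamSeed(cv@seed,
                                        paste0("inner_", r, "_", k)))
      pred[te] <- .predictLearner(model, prep$test)
    }
    perRepeat$rho[r] <- suppressWarnings(spearmanRho(y, pred))
    perRepeat$r2[r] <- r2Explained(y, pred)
    perRepeat$rms[r] <- sqrt(mean((pred - y)^2))
    predSum <- predSum + pred
  }
  new("PredictionResult",
      measured = setNames(as.vector(y), names(y) %||% lines[ok]),
      predicted = setNames(predSum / cv@nRepeats, names(y) %||% lines[ok]),
      perRepeat = perRepeat,
      metrics = list(rho = mean(perRepeat$rho), r2 = mean(perRepeat$r2),
                     rms = mean(perRepeat$rms)),
      learner = learner$name)
}

.metricOf <- function(result, metric) {
  if (metric == "spearman") result@metrics$rho else result@metrics$r2
}

#' Permutation null distribution for a drug's prediction performance
#'
#' Shuffles the response across cell lines `nShuffles` times; each shuffle
#' reruns the full pipeline (fold-wise filtering, standardization and nested
#' hyperparameter selection included) as a single CV run and records the
#' metric. One-sided empirical p = (1 + #\{null >= observed\}) / (1 + N),
#' which is bounded below by 1 / (1 + N) and never exactly zero.
#'
#' @inheritParams repeatedNestedCV
#' @param nShuffles number of response permutations N.
#' @param observed optionally a precomputed [PredictionResult-class] for the
#'   unshuffled data (with `cv` as given); computed if missing.
#' @return a [PermutationNull-class].
#' @export
permutationBackground <- function(x, y, learner = learnerSpec("pls"),
                                  cv = cvConfig(), nShuffles = 200L,
                                  observed = NULL) {
  if (is.null(observed))
    observed <- repeatedNestedCV(x, y, learner, cv)
  obs <- .metricOf(observed, cv@metric)
  nullCv <- initialize(cv, nRepeats = 1L)
  blocks <- .asBlocks(x)
  lines <- rownames(blocks[[1L]]@values)
  if (!is.null(names(y))) y <- y[lines]
  nullVals <- vapply(seq_len(nShuffles), function(s) {
    yperm <- withSeed(streamSeed(cv@seed, paste0("shuffle_", s)),
                      setNames(sample(y), names(y)))
    res <- repeatedNestedCV(blocks, yperm, learner,
                            initialize(nullCv,
                                       seed = streamSeed(cv@seed,
                                                paste0("shuffle_cv_", s))))
    .metricOf(res, cv@metric)
  }, numeric(1))
  k <- sum(nullVals >= obs, na.rm = TRUE) + sum(is.na(nullVals))
  new("PermutationNull", nShuffles = as.integer(nShuffles),
      nullValues = nullVals, observed = obs,
      pValue = (1 + k) / (1 + nShuffles), pAdjusted = NA_real_,
      metric = cv@metric)
}
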