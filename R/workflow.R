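## End-to-end benchmark orchestration over drugs x data types x learners.

#' Fit one model on the full panel (no outer CV)
#'
#' Applies the same preparation as one training fold spanning all measured
#' lines - transform, filter, standardize - selects hyperparameters by
#' nested CV, and fits the final model. The returned model carries the
#' standardization state, so [predictAUC()] on raw transformed data works.
#'
#' @inheritParams repeatedNestedCV
#' @return a fitted model object.
#' @export
fitPanelModel <- function(x, y, learner = learnerSpec("pls"),
                          cv = cvConfig()) {
  blocks <- .asBlocks(x)
  ok <- !is.na(y)
  blocks <- lapply(blocks, function(b)
    initialize(b, values = b@values[ok, , drop = FALSE]))
  y <- y[ok]
  idx <- seq_along(y)
  prep <- .prepareFold(blocks, idx, idx)
  model <- .trainLearner(learner, prep$train, y, cv,
                         streamSeed(cv@seed, "full_fit"))
  model
}

#' Run the full drug x data type x learner benchmark
#'
#' For every combination, repeated nested cross-validation (and, when
#' `nPermutations > 0`, a permutation background with empirical p-values);
#' Benjamini-Hochberg adjustment is applied across drugs within each
#' (data type, learner) family.
#'
#' @param panel a [CellLinePanel-class].
#' @param dataTypes molecular blocks to benchmark.
#' @param learners list of [learnerSpec()]s; every learner is run on every
#'   data type.
#' @param cv a [cvConfig()].
#' @param nPermutations response shuffles per combination (0 = no
#'   significance testing).
#' @param drugs drugs to benchmark (default: all drugs in the panel).
#' @param auc optionally a precomputed AUC matrix; by default recomputed
#'   from the panel's dose-response table via [meanViabilityAUC()].
#' @return data.frame with one row per (drug, dataType, learner): rho, r2,
#'   rms, pPerm, pAdj, nCellLines, nFeaturesUsed; seed and timestamp as
#'   attributes.
#' @export
runFullBenchmark <- function(panel,
                             dataTypes = c("mutation", "transcript",
                                           "protein"),
                             learners = list(learnerSpec("pls")),
                             cv = cvConfig(), nPermutations = 0L,
                             drugs = NULL, auc = NULL) {
  stopifnot(is(panel, "CellLinePanel"))
  if (is.null(auc)) auc <- meanViabilityAUC(doseResponse(panel))
  auc <- auc[cellLines(panel), , drop = FALSE]
  drugs <- drugs %||% colnames(auc)
  rows <- list()
  for (type in dataTypes) {
    block <- omicBlock(panel, type)
    nFeat <- tryCatch(
      length(.foldFilterCols(values(.asBlocks(block)[[1L]]), type,
                             seq_len(nrow(values(block))))),
      error = function(e) 0L)
    for (learner in learners) {
      for (d in drugs) {
        y <- auc[, d]
        res <- repeatedNestedCV(block, y, learner, cv)
        p <- NA_real_
        if (nPermutations > 0L) {
          bg <- permutationBackground(block, y, learner, cv,
                                      nShuffles = nPermutations,
                                      observed = res)
          p <- bg@pValue
        }
        rows[[length(rows) + 1L]] <- data.frame(
          drug = d, dataType = type, learner = learner$name,
          rho = res@metrics$rho, r2 = res@metrics$r2, rms = res@metrics$rms,
          pPerm = p, pAdj = NA_real_,
          nCellLines = length(res@measured), nFeaturesUsed = nFeat)
      }
    }
  }
  out <- do.call(rbind, rows)
  for (key in unique(paste(out$dataType, out$learner))) {
    sel <- paste(out$dataType, out$learner) == key & !is.na(out$pPerm)
    if (any(sel)) out$pAdj[sel] <- bhAdjust(out$pPerm[sel])
  }
  attr(out, "seed") <- cv@seed
  attr(out, "timestamp") <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  out
}

#' Per-drug model coefficient table for one data type
#'
#' Fits a full-panel model per drug (nested-CV hyperparameters, fold
#' spanning all measured lines) and collects the standardized-input linear
#' coefficients - the per-marker importance report. Only linear learners
#' (pls, enet, lasso) have coefficients.
#'
#' @inheritParams runFullBenchmark
#' @param dataType one molecular block.
#' @param learner a linear [learnerSpec()].
#' @return feature x drug coefficient matrix (features absent from a drug's
#'   filtered model get 0).
#' @export
coefficientTable <- function(panel, dataType = "protein",
                             learner = learnerSpec("pls"), cv = cvConfig(),
                             drugs = NULL, auc = NULL) {
  if (is.null(auc)) auc <- meanViabilityAUC(doseResponse(panel))
  auc <- auc[cellLines(panel), , drop = FALSE]
  drugs <- drugs %||% colnames(auc)
  block <- omicBlock(panel, dataType)
  cols <- lapply(drugs, function(d) {
    fit <- fitPanelModel(block, auc[, d], learner, cv)
    if (is(fit, "PLSModel")) setNames(fit@coefficients[, 1],
                                      fit@featureNames)
    else if (is(fit, "ElasticNetModel")) fit@coefficients
    else stop("coefficientTable needs a linear learner")
  })
  feats <- sort(unique(unlist(lapply(cols, names))))
  out <- matrix(0, length(feats), length(drugs),
                dimnames = list(feats, drugs))
  for (j in seq_along(cols)) out[names(cols[[j]]), j] <- cols[[j]]
  out
}

#' Rank data types by predictive performance
#'
#' Per data type: number of significantly predicted drugs (adjusted p below
#' `alpha`; 0 when no permutations were run) and mean Spearman rho across
#' drugs, in descending order; ties are broken by mean rho, then by name.
#'
#' @param result a [runFullBenchmark()] table.
#' @param alpha adjusted-p significance cut (default 0.05).
#' @return data.frame with columns dataType, nSignificant, meanRho, ordered
#'   best first.
#' @export
rankDataTypes <- function(result, alpha = 0.05) {
  types <- unique(result$dataType)
  tab <- do.call(rbind, lapply(types, function(tp) {
    sel <- result$dataType == tp
    data.frame(dataType = tp,
               nSignificant = sum(result$pAdj[sel] < alpha, na.rm = TRUE),
               meanRho = mean(result$rho[sel], na.rm = TRUE))
  }))
  tab[order(-tab$nSignificant, -tab$meanRho, tab$dataType), , drop = FALSE]
}
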