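## Multi-omic integration and cross-tissue transfer benchmarking.

#' Early integration: one model on concatenated omic blocks
#'
#' Each block is transformed, filtered and standardized fold-wise on its own,
#' then the standardized blocks are concatenated and a single model is fitted
#' on the combined matrix. With a single block this is identical to
#' [repeatedNestedCV()].
#'
#' @param blocks list of [OmicMatrix-class] blocks sharing cell lines.
#' @inheritParams repeatedNestedCV
#' @return a [PredictionResult-class].
#' @export
earlyIntegrationFit <- function(blocks, y, learner = learnerSpec("pls"),
                                cv = cvConfig()) {
  repeatedNestedCV(blocks, y, learner, cv)
}

#' Late integration: inverse-RMS weighting of per-block predictions
#'
#' Combines per-block predicted AUC vectors as a convex combination with
#' weights proportional to each block's inverse RMS:
#' ahat = sum_m (1/RMS_m) ahat_m / sum_m (1/RMS_m). A zero RMS gives that
#' block all the weight (limit case).
#'
#' @param predictions list of equal-length predicted AUC vectors.
#' @param blockRms per-block RMS values (typically each block's nested-CV
#'   RMS on the training data, so no test information enters the weights).
#' @return combined prediction vector.
#' @export
lateIntegrationPredict <- function(predictions, blockRms) {
  stopifnot(length(predictions) == length(blockRms), length(blockRms) >= 1L)
  if (any(blockRms < 0)) stop("RMS values must be non-negative")
  if (any(blockRms == 0)) {
    message("zero RMS block takes all the weight (limit case)")
    w <- as.numeric(blockRms == 0)
  } else {
    w <- 1 / blockRms
  }
  w <- w / sum(w)
  out <- 0
  for (m in seq_along(predictions)) out <- out + w[m] * predictions[[m]]
  out
}

#' Leave-one-out tissue-mean predictor
#'
#' Predicts each cell line's AUC as the mean AUC of the other lines of its
#' tissue. Lines whose tissue has no other measured line get NA.
#'
#' @param y named AUC vector.
#' @param tissueLabels tissue label per cell line (same order as `y`).
#' @return prediction vector aligned with `y`.
#' @export
tissueMeanPredictor <- function(y, tissueLabels) {
  stopifnot(length(y) == length(tissueLabels))
  out <- rep(NA_real_, length(y))
  for (i in seq_along(y)) {
    peers <- which(tissueLabels == tissueLabels[i] & seq_along(y) != i &
                     !is.na(y))
    if (length(peers)) out[i] <- mean(y[peers])
  }
  names(out) <- names(y)
  out
}

#' Coefficient-of-variation drug filter for transfer benchmarks
#'
#' Drugs with low AUC variability (sigma/mu below the threshold) either
#' across the target-tissue lines or across the remaining lines are dropped.
#'
#' @param auc cell line x drug AUC matrix.
#' @param tissueLabels tissue per cell line (rows of `auc`).
#' @param targetTissue the held-out tissue.
#' @param threshold CV threshold (default 0.2).
#' @return character vector of retained drug ids.
#' @export
filterTransferDrugs <- function(auc, tissueLabels, targetTissue,
                                threshold = 0.2) {
  inT <- tissueLabels == targetTissue
  cvT <- drugCoefficientOfVariation(auc[inT, , drop = FALSE])
  cvC <- drugCoefficientOfVariation(auc[!inT, , drop = FALSE])
  colnames(auc)[cvT >= threshold & cvC >= threshold]
}

## Single train/test evaluation with nested hyperparameter selection inside
## the training set; shared by cross-tissue and cross-fair runs.
.transferOnce <- function(blocks, y, trIdx, teIdx, learner, cv, seed) {
  prep <- .prepareFold(blocks, trIdx, teIdx)
  model <- .trainLearner(learner, prep$train, y[trIdx], cv, seed)
  pred <- .predictLearner(model, prep$test)
  meas <- y[teIdx]
  list(measured = meas, predicted = pred,
       rho = suppressWarnings(spearmanRho(meas, pred)),
       r2 = r2Explained(meas, pred),
       rms = sqrt(mean((pred - meas)^2)))
}

#' Cross-tissue transfer evaluation
#'
#' Excludes all cell lines of the target tissue, trains a single model on the
#' remaining lines (hyperparameters by nested CV within the training set),
#' and evaluates once on the held-out tissue.
#'
#' @inheritParams repeatedNestedCV
#' @param tissueLabels tissue per cell line (same order as the block rows).
#' @param targetTissue tissue to hold out (>= 3 lines required; holding out
#'   every line is an error).
#' @return a [PredictionResult-class] over the target-tissue lines.
#' @export
crossTissueTransfer <- function(x, y, tissueLabels, targetTissue,
                                learner = learnerSpec("pls"),
                                cv = cvConfig()) {
  blocks <- .asBlocks(x)
  ok <- !is.na(y)
  blocks <- lapply(blocks, function(b)
    initialize(b, values = b@values[ok, , drop = FALSE]))
  y <- y[ok]; tissueLabels <- tissueLabels[ok]
  te <- which(tissueLabels == targetTissue)
  tr <- which(tissueLabels != targetTissue)
  if (length(te) < 3L) stop("target tissue has fewer than 3 cell lines")
  if (!length(tr)) stop("holding out every tissue leaves no training lines")
  res <- .transferOnce(blocks, y, tr, te, learner, cv,
                       streamSeed(cv@seed, "transfer_fit"))
  new("PredictionResult", measured = res$measured, predicted = res$predicted,
      perRepeat = data.frame(rho = res$rho, r2 = res$r2, rms = res$rms),
      metrics = list(rho = res$rho, r2 = res$r2, rms = res$rms),
      learner = learner$name)
}

#' "Cross fair" transfer: equal-n resampled cross-tissue models
#'
#' Like [crossTissueTransfer()], but each model is trained on a random subset
#' of non-target lines of the same size as the target tissue (sampled without
#' replacement), removing the sample-size advantage of the full cross-tissue
#' training set; repeated `nResamples` times.
#'
#' @inheritParams crossTissueTransfer
#' @param nResamples number of training-set resamples (default 1024).
#' @return list with `perResample` (data.frame rho/r2/rms per resample),
#'   `mean` and `se` of the rho values.
#' @export
crossFairBenchmark <- function(x, y, tissueLabels, targetTissue,
                               learner = learnerSpec("pls"), cv = cvConfig(),
                               nResamples = 1024L) {
  blocks <- .asBlocks(x)
  ok <- !is.na(y)
  blocks <- lapply(blocks, function(b)
    initialize(b, values = b@values[ok, , drop = FALSE]))
  y <- y[ok]; tissueLabels <- tissueLabels[ok]
  te <- which(tissueLabels == targetTissue)
  comp <- which(tissueLabels != targetTissue)
  if (length(te) < 3L) stop("target tissue has fewer than 3 cell lines")
  if (length(comp) < length(te))
    stop("complement smaller than the target tissue; cannot match n")
  per <- data.frame(rho = numeric(nResamples), r2 = numeric(nResamples),
                    rms = numeric(nResamples))
  for (s in seq_len(nResamples)) {
    tr <- sort(withSeed(streamSeed(cv@seed, paste0("crossfair_", s)),
                        sample(comp, length(te))))
    res <- .transferOnce(blocks, y, tr, te, learner, cv,
                         streamSeed(cv@seed, "transfer_fit"))
    per$rho[s] <- res$rho; per$r2[s] <- res$r2; per$rms[s] <- res$rms
  }
  list(perResample = per, mean = mean(per$rho, na.rm = TRUE),
       se = sd(per$rho, na.rm = TRUE) / sqrt(sum(!is.na(per$rho))))
}

#' Subset a panel to a set of cell lines
#'
#' @param panel a [CellLinePanel-class].
#' @param lines cell-line ids to keep.
#' @return the subset panel (ground-truth true AUC and patient ids follow).
#' @export
subsetPanel <- function(panel, lines) {
  stopifnot(all(lines %in% cellLines(panel)))
  gt <- panel@groundTruth
  if (!is.null(gt))
    gt <- initialize(gt, trueAuc = gt@trueAuc[lines, , drop = FALSE],
                     patientIds = gt@patientIds[lines])
  dr <- panel@doseResponse
  new("CellLinePanel",
      mutationMatrix = panel@mutationMatrix[lines, , drop = FALSE],
      transcriptMatrix = panel@transcriptMatrix[lines, , drop = FALSE],
      proteinMatrix = panel@proteinMatrix[lines, , drop = FALSE],
      doseResponse = dr[dr$cell_line %in% lines, , drop = FALSE],
      tissues = panel@tissues[lines], patients = panel@patients[lines],
      groundTruth = gt)
}

#' Drop duplicate cell lines sharing a patient
#'
#' Retains the first cell line (in the panel's stable ordering) of every
#' patient.
#'
#' @param panel a [CellLinePanel-class] with patient annotation.
#' @return the de-duplicated panel.
#' @export
excludeDuplicatePatients <- function(panel) {
  keep <- cellLines(panel)[!duplicated(patients(panel))]
  subsetPanel(panel, keep)
}
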