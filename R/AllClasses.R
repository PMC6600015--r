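## Central S4 containers.

#' Configuration of a synthetic cell-line panel
#'
#' Parameters controlling the size and signal structure of a generated panel.
#' Defaults emulate a melanoma-type screen: 49 cell lines, 88 (phospho)proteins,
#' thousands of transcripts, a binary mutation block with one high-prevalence
#' driver, drugs grouped into classes with correlated sensitivities, a handful
#' of null drugs, and nine-dose 1:3 serial-dilution viability curves.
#'
#' @slot nCellLines,nTissues,nTranscripts,nProteins,nMutations panel dimensions.
#' @slot driverPrevalence fraction of cell lines carrying the driver mutation,
#'   strictly inside (0, 1).
#' @slot nDrugs total number of drugs, including null drugs.
#' @slot drugClasses data.frame with columns `size` (drugs per class) and
#'   `shared` (logical; class members share planted molecular effects). The
#'   first class with `shared = TRUE` is the driver-dependent class: its drugs'
#'   sensitivity is controlled by the driver mutation.
#' @slot nNullDrugs number of drugs with no molecular association at all.
#' @slot effectSize per-drug planted signal SD expressed as a multiple of the
#'   AUC measurement noise SD (`viabilityNoiseSd / sqrt(nDoses)`); the
#'   noiseless panel R^2 for such a drug is `effectSize^2 / (1 + effectSize^2)`.
#' @slot tissueEffectSd SD of tissue-by-drug AUC offsets (AUC units).
#' @slot nDoses,doseDilutionFactor dose grid: `nDoses` doses in an evenly
#'   log-spaced `1:doseDilutionFactor` serial dilution.
#' @slot viabilityNoiseSd additive noise SD on each viability measurement.
#' @slot nDuplicatePatients number of cell lines that are near-copies of
#'   another line from the same patient.
#' @slot seed master seed; all generation substreams derive from it.
#' @seealso [panelConfig()], [generatePanel()]
#' @export
setClass("PanelConfig", representation(
  nCellLines = "integer", nTissues = "integer", nTranscripts = "integer",
  nProteins = "integer", nMutations = "integer", driverPrevalence = "numeric",
  nDrugs = "integer", drugClasses = "data.frame", nNullDrugs = "integer",
  effectSize = "numeric", tissueEffectSd = "numeric", nDoses = "integer",
  doseDilutionFactor = "numeric", viabilityNoiseSd = "numeric",
  nDuplicatePatients = "integer", seed = "integer"))

setValidity("PanelConfig", function(object) {
  msgs <- character()
  counts <- c(nCellLines = object@nCellLines, nTissues = object@nTissues,
              nTranscripts = object@nTranscripts, nProteins = object@nProteins,
              nMutations = object@nMutations, nDrugs = object@nDrugs,
              nDoses = object@nDoses)
  if (any(counts < 1L))
    msgs <- c(msgs, paste0("counts must be positive: ",
                           paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@driverPrevalence <= 0 || object@driverPrevalence >= 1)
    msgs <- c(msgs, "driverPrevalence must be strictly between 0 and 1")
  if (object@nNullDrugs > object@nDrugs)
    msgs <- c(msgs, "nNullDrugs must not exceed nDrugs")
  if (object@nNullDrugs < 0L || object@nDuplicatePatients < 0L)
    msgs <- c(msgs, "nNullDrugs and nDuplicatePatients must be non-negative")
  if (!all(c("size", "shared") %in% names(object@drugClasses)))
    msgs <- c(msgs, "drugClasses needs columns 'size' and 'shared'")
  else if (sum(object@drugClasses$size) + object@nNullDrugs > object@nDrugs)
    msgs <- c(msgs, "class drugs plus null drugs exceed nDrugs")
  if (object@doseDilutionFactor <= 1)
    msgs <- c(msgs, "doseDilutionFactor must exceed 1")
  if (object@viabilityNoiseSd < 0 || object@tissueEffectSd < 0 ||
      object@effectSize < 0)
    msgs <- c(msgs, "noise/effect parameters must be non-negative")
  if (object@nDuplicatePatients >= object@nCellLines)
    msgs <- c(msgs, "nDuplicatePatients must be smaller than nCellLines")
  if (length(msgs)) msgs else TRUE
})

#' Planted ground truth of a synthetic panel
#'
#' @slot plantedCoefficients named list, one numeric coefficient vector per
#'   drug (names are feature ids); empty vector for drugs with no planted
#'   molecular effect.
#' @slot driverMutationId id of the planted driver mutation column.
#' @slot driverDependentDrugs drugs whose AUC is controlled by the driver.
#' @slot nullDrugs drugs with no molecular association.
#' @slot tissueOffsets tissue x drug matrix of AUC shifts.
#' @slot trueAuc cell line x drug noiseless AUC matrix, values in [0, 1.2].
#' @slot patientIds named character, cell line -> patient label.
#' @slot switchPair the two anti-correlated "switch" protein ids.
#' @export
setClass("GroundTruth", representation(
  plantedCoefficients = "list", driverMutationId = "character",
  driverDependentDrugs = "character", nullDrugs = "character",
  tissueOffsets = "matrix", trueAuc = "matrix", patientIds = "character",
  switchPair = "character"))

setValidity("GroundTruth", function(object) {
  msgs <- character()
  if (any(object@trueAuc < 0 | object@trueAuc > 1.2))
    msgs <- c(msgs, "trueAuc must lie within [0, 1.2]")
  for (d in object@nullDrugs) {
    b <- object@plantedCoefficients[[d]]
    if (length(b) && any(b != 0))
      msgs <- c(msgs, paste0("null drug ", d, " has nonzero planted coefficients"))
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("GroundTruthOrNULL", c("GroundTruth", "NULL"))

#' A multi-omic cell-line drug-screen panel
#'
#' Container tying together the molecular blocks (binary mutations,
#' non-negative transcript expression, positive protein intensities), the
#' long-format dose-response table, and per-cell-line tissue and patient
#' annotation. Generated panels additionally carry their [GroundTruth].
#'
#' @slot mutationMatrix binary cell line x mutation matrix.
#' @slot transcriptMatrix non-negative cell line x transcript matrix.
#' @slot proteinMatrix positive cell line x protein intensity matrix.
#' @slot doseResponse data.frame with columns cell_line, drug, dose, viability.
#' @slot tissues,patients named character vectors over cell lines.
#' @slot groundTruth a [GroundTruth] or NULL for real data.
#' @export
setClass("CellLinePanel", representation(
  mutationMatrix = "matrix", transcriptMatrix = "matrix",
  proteinMatrix = "matrix", doseResponse = "data.frame",
  tissues = "character", patients = "character",
  groundTruth = "GroundTruthOrNULL"))

setValidity("CellLinePanel", function(object) {
  msgs <- character()
  lines <- rownames(object@transcriptMatrix)
  if (!all(object@mutationMatrix %in% c(0, 1)))
    msgs <- c(msgs, "mutationMatrix entries must be 0/1")
  if (any(object@transcriptMatrix < 0))
    msgs <- c(msgs, "transcript values must be non-negative")
  for (s in c("mutationMatrix", "proteinMatrix"))
    if (!identical(rownames(slot(object, s)), lines))
      msgs <- c(msgs, paste0(s, " rownames disagree with transcriptMatrix"))
  if (!identical(names(object@tissues), lines) ||
      !identical(names(object@patients), lines))
    msgs <- c(msgs, "tissues/patients must be named by the cell lines")
  if (length(msgs)) msgs else TRUE
})

#' A typed cell line x feature matrix
#'
#' Wraps a numeric matrix with its data-type tag (which controls the
#' expression transform and filter thresholds applied during modeling) and,
#' once fitted, the centering/scaling state used to transform test data.
#'
#' @slot values cell line x feature matrix.
#' @slot dataType one of "mutation", "transcript", "protein".
#' @slot transformed has the data-type log transform been applied?
#' @slot transformState list with `center`, `scale`, `keep` once a
#'   standardizer has been fitted; empty before.
#' @export
setClass("OmicMatrix", representation(
  values = "matrix", dataType = "character", transformed = "logical",
  transformState = "list"))

setValidity("OmicMatrix", function(object) {
  msgs <- character()
  if (!object@dataType %in% c("mutation", "transcript", "protein"))
    msgs <- c(msgs, "dataType must be mutation, transcript or protein")
  if (object@dataType == "mutation" && !all(object@values %in% c(0, 1)))
    msgs <- c(msgs, "mutation matrices must be binary")
  if (object@dataType == "transcript" && !object@transformed &&
      any(object@values < 0))
    msgs <- c(msgs, "raw transcript values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Fitted partial least squares model
#'
#' Single- or multi-response PLS fitted by NIPALS. Slots store per-component
#' weights/loadings/scores plus the collapsed linear form: prediction =
#' intercept + X %*% coefficients, which exactly reproduces the
#' component-wise prediction.
#'
#' @slot ncomp number of components retained.
#' @slot weights,loadings p x ncomp weight and X-loading matrices.
#' @slot yloadings ncomp x m response loadings.
#' @slot scores n x ncomp training score matrix.
#' @slot coefficients p x m regression coefficients on the model's input scale.
#' @slot intercept length-m intercept.
#' @slot tt,ssy per-component score norms and explained response variance
#'   (used by [vipScores()]).
#' @slot featureNames training feature ids.
#' @slot transformState training-fold standardization state used to transform
#'   test data (may be empty when the caller standardizes externally).
#' @export
setClass("PLSModel", representation(
  ncomp = "integer", weights = "matrix", loadings = "matrix",
  yloadings = "matrix", scores = "matrix", coefficients = "matrix",
  intercept = "numeric", tt = "numeric", ssy = "numeric",
  featureNames = "character", transformState = "list"))

#' Regression-tree drug sensitivity model
#'
#' A cost-complexity pruned CART regression tree (backed by rpart) with the
#' pruning level chosen by nested 10-fold cross-validation and a minimum
#' bucket size, plus the standardization state of its training fold.
#'
#' @slot fit the pruned rpart object.
#' @slot cp the selected complexity parameter.
#' @slot minBucket minimum number of training lines per leaf.
#' @slot featureNames,transformState as for [PLSModel-class].
#' @export
setClass("TreeModel", representation(
  fit = "ANY", cp = "numeric", minBucket = "integer",
  featureNames = "character", transformState = "list"))

#' Elastic-net / lasso drug sensitivity model
#'
#' Minimizes (1/2n) RSS + lambda * ((1 - alpha) * ||beta||_2^2 +
#' alpha * ||beta||_1) with an unpenalized intercept; alpha = 1 is the lasso,
#' alpha = 0 pure ridge.
#'
#' @slot coefficients named coefficient vector.
#' @slot intercept intercept.
#' @slot lambda,alpha penalty weight and mixing parameter.
#' @slot featureNames,transformState as for [PLSModel-class].
#' @export
setClass("ElasticNetModel", representation(
  coefficients = "numeric", intercept = "numeric", lambda = "numeric",
  alpha = "numeric", featureNames = "character", transformState = "list"))

#' Maximum-correlation baseline model
#'
#' Simple linear regression on the single feature with the largest absolute
#' Pearson correlation with the response in the training data.
#'
#' @slot feature the selected feature id.
#' @slot slope,intercept the regression line.
#' @slot featureNames,transformState as for [PLSModel-class].
#' @export
setClass("MaxCorrModel", representation(
  feature = "character", slope = "numeric", intercept = "numeric",
  featureNames = "character", transformState = "list"))

#' Cross-validated prediction result
#'
#' @slot measured named measured AUC per cell line (missing AUCs dropped).
#' @slot predicted per-cell-line prediction averaged over repeats.
#' @slot perRepeat data.frame with one row per repeat: rho, r2, rms.
#' @slot metrics list with summary `rho`, `r2`, `rms` (means over repeats).
#' @slot learner learner name.
#' @export
setClass("PredictionResult", representation(
  measured = "numeric", predicted = "numeric", perRepeat = "data.frame",
  metrics = "list", learner = "character"))

#' Permutation null distribution of a performance metric
#'
#' @slot nShuffles number of response shuffles N.
#' @slot nullValues metric values under shuffled responses (length N).
#' @slot observed observed metric.
#' @slot pValue one-sided empirical p = (1 + #\{null >= observed\}) / (1 + N).
#' @slot pAdjusted BH-adjusted p (NA until adjusted across a drug family).
#' @slot metric metric name ("spearman" or "r2").
#' @export
setClass("PermutationNull", representation(
  nShuffles = "integer", nullValues = "numeric", observed = "numeric",
  pValue = "numeric", pAdjusted = "numeric", metric = "character"))

setValidity("PermutationNull", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  if (!is.na(object@pAdjusted) && object@pAdjusted < object@pValue)
    return("adjusted p cannot be smaller than p")
  TRUE
})
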