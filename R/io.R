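## Plain-text readers and writers: TSV matrices (rows = cell lines, header =
## feature ids), CSV dose-response tables, two-column annotation TSVs,
## structured JSON for ground truth and fitted models.

#' @rdname panelIO
#' @param m numeric matrix with cell-line rownames.
#' @param file path.
#' @export
writeMatrixTSV <- function(m, file) {
  df <- data.frame(cell_line = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname panelIO
#' @export
readMatrixTSV <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write panel components
#'
#' `writePanel` lays a panel out as a directory of plain-text files:
#' `mutations.tsv`, `transcripts.tsv`, `proteins.tsv` (TSV, rows = cell
#' lines), `dose_response.csv` (long format), `annotations.tsv` (cell line,
#' tissue, patient) and, when present, `ground_truth.json`. `readPanel`
#' reconstructs the [CellLinePanel-class] from such a directory.
#'
#' @param panel a [CellLinePanel-class].
#' @param dir directory path (created if needed).
#' @name panelIO
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTSV(mutationMatrix(panel), file.path(dir, "mutations.tsv"))
  writeMatrixTSV(transcriptMatrix(panel), file.path(dir, "transcripts.tsv"))
  writeMatrixTSV(proteinMatrix(panel), file.path(dir, "proteins.tsv"))
  write.csv(doseResponse(panel), file.path(dir, "dose_response.csv"),
            row.names = FALSE, quote = FALSE)
  write.table(data.frame(cell_line = cellLines(panel),
                         tissue = unname(tissues(panel)),
                         patient = unname(patients(panel))),
              file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- groundTruth(panel)
  if (!is.null(gt)) writeGroundTruthJSON(gt, file.path(dir,
                                                       "ground_truth.json"))
  invisible(dir)
}

#' @rdname panelIO
#' @export
readPanel <- function(dir) {
  ann <- read.delim(file.path(dir, "annotations.tsv"),
                    stringsAsFactors = FALSE)
  gtFile <- file.path(dir, "ground_truth.json")
  new("CellLinePanel",
      mutationMatrix = readMatrixTSV(file.path(dir, "mutations.tsv")),
      transcriptMatrix = readMatrixTSV(file.path(dir, "transcripts.tsv")),
      proteinMatrix = readMatrixTSV(file.path(dir, "proteins.tsv")),
      doseResponse = read.csv(file.path(dir, "dose_response.csv"),
                              stringsAsFactors = FALSE),
      tissues = setNames(ann$tissue, ann$cell_line),
      patients = setNames(ann$patient, ann$cell_line),
      groundTruth = if (file.exists(gtFile)) readGroundTruthJSON(gtFile)
      else NULL)
}

#' @rdname panelIO
#' @param gt a [GroundTruth-class].
#' @export
writeGroundTruthJSON <- function(gt, file) {
  jsonlite::write_json(list(
    plantedCoefficients = lapply(gt@plantedCoefficients, as.list),
    driverMutationId = gt@driverMutationId,
    driverDependentDrugs = gt@driverDependentDrugs,
    nullDrugs = gt@nullDrugs,
    tissueOffsets = list(values = gt@tissueOffsets,
                         tissues = rownames(gt@tissueOffsets),
                         drugs = colnames(gt@tissueOffsets)),
    trueAuc = list(values = gt@trueAuc, cellLines = rownames(gt@trueAuc),
                   drugs = colnames(gt@trueAuc)),
    patientIds = as.list(gt@patientIds),
    switchPair = gt@switchPair), file, auto_unbox = TRUE, digits = NA)
}

#' @rdname panelIO
#' @export
readGroundTruthJSON <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  toMat <- function(x) {
    m <- matrix(unlist(x$values), length(x[[2]]), length(x$drugs),
                dimnames = list(x[[2]], x$drugs))
    m
  }
  new("GroundTruth",
      plantedCoefficients = lapply(j$plantedCoefficients, unlist),
      driverMutationId = j$driverMutationId,
      driverDependentDrugs = as.character(j$driverDependentDrugs),
      nullDrugs = as.character(j$nullDrugs),
      tissueOffsets = toMat(j$tissueOffsets),
      trueAuc = toMat(j$trueAuc),
      patientIds = unlist(j$patientIds),
      switchPair = as.character(j$switchPair))
}

#' Serialize a fitted linear model to JSON
#'
#' Stores coefficients, intercept, component count and the training
#' standardization state for [PLSModel-class], [ElasticNetModel-class] and
#' [MaxCorrModel-class]; tree models are written as their split/leaf frame
#' for inspection but cannot be read back.
#'
#' @param model a fitted model.
#' @param file output path.
#' @export
writeModelJSON <- function(model, file) {
  st <- model@transformState
  stOut <- if (length(st)) list(center = as.list(st$center),
                                scale = as.list(st$scale),
                                keep = st$keep) else NULL
  payload <- if (is(model, "PLSModel")) {
    list(type = "pls", nComponents = model@ncomp,
         coefficients = as.list(setNames(model@coefficients[, 1],
                                         model@featureNames)),
         intercept = model@intercept[1], transformState = stOut)
  } else if (is(model, "ElasticNetModel")) {
    list(type = "enet", alpha = model@alpha, lambda = model@lambda,
         coefficients = as.list(model@coefficients),
         intercept = model@intercept, transformState = stOut)
  } else if (is(model, "MaxCorrModel")) {
    list(type = "maxcorr", feature = model@feature, slope = model@slope,
         intercept = model@intercept, transformState = stOut)
  } else if (is(model, "TreeModel")) {
    fr <- model@fit$frame
    list(type = "tree", cp = model@cp, minBucket = model@minBucket,
         frame = data.frame(var = as.character(fr$var), n = fr$n,
                            yval = fr$yval))
  } else stop("unsupported model class: ", class(model))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
}

#' Read a JSON-serialized linear model
#'
#' @param file path written by [writeModelJSON()].
#' @return the reconstructed model (PLS models come back as the collapsed
#'   linear form with the stored component count).
#' @export
readModelJSON <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  st <- if (!is.null(j$transformState))
    list(center = unlist(j$transformState$center),
         scale = unlist(j$transformState$scale),
         keep = j$transformState$keep) else list()
  if (j$type == "pls") {
    cf <- unlist(j$coefficients)
    p <- length(cf)
    new("PLSModel", ncomp = as.integer(j$nComponents),
        weights = matrix(0, p, 0), loadings = matrix(0, p, 0),
        yloadings = matrix(0, 0, 1), scores = matrix(0, 0, 0),
        coefficients = matrix(cf, ncol = 1,
                              dimnames = list(names(cf), "y")),
        intercept = j$intercept, tt = numeric(0), ssy = numeric(0),
        featureNames = names(cf), transformState = st)
  } else if (j$type == "enet") {
    new("ElasticNetModel", coefficients = unlist(j$coefficients),
        intercept = j$intercept, lambda = j$lambda, alpha = j$alpha,
        featureNames = names(unlist(j$coefficients)), transformState = st)
  } else if (j$type == "maxcorr") {
    new("MaxCorrModel", feature = j$feature, slope = j$slope,
        intercept = j$intercept, featureNames = j$feature,
        transformState = st)
  } else stop("cannot reconstruct model of type ", j$type)
}

#' Write a benchmark result table as tidy TSV
#'
#' @param result a [runFullBenchmark()] data.frame.
#' @param file output path.
#' @export
writeBenchmarkTSV <- function(result, file) {
  write.table(result, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
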