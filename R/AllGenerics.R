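## Generics and accessors.

#' Predict drug sensitivity from a fitted model
#'
#' Common prediction contract for all learners. `newdata` is a cell line x
#' feature matrix on the same (transformed) scale as the training input; if
#' the model carries a fitted standardization state, it is applied to
#' `newdata` with the *training* parameters before prediction.
#'
#' @param object a fitted model ([PLSModel-class], [TreeModel-class],
#'   [ElasticNetModel-class] or [MaxCorrModel-class]).
#' @param newdata numeric matrix with the model's training features.
#' @param ... passed to methods; for PLS2 models, `response` selects columns.
#' @return numeric vector (or matrix for multi-response PLS2) of predicted AUC.
#' @export
setGeneric("predictAUC", function(object, newdata, ...)
  standardGeneric("predictAUC"))

#' @rdname CellLinePanel-class
#' @param object,x a `CellLinePanel` (or `GroundTruth` for its accessors).
#' @export
setGeneric("mutationMatrix", function(x) standardGeneric("mutationMatrix"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("transcriptMatrix", function(x) standardGeneric("transcriptMatrix"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("proteinMatrix", function(x) standardGeneric("proteinMatrix"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("doseResponse", function(x) standardGeneric("doseResponse"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("tissues", function(x) standardGeneric("tissues"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname GroundTruth-class
#' @param x a `GroundTruth`.
#' @export
setGeneric("trueAuc", function(x) standardGeneric("trueAuc"))
#' @rdname CellLinePanel-class
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname OmicMatrix-class
#' @param x an `OmicMatrix`.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname OmicMatrix-class
#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))

setMethod("mutationMatrix", "CellLinePanel", function(x) x@mutationMatrix)
setMethod("transcriptMatrix", "CellLinePanel", function(x) x@transcriptMatrix)
setMethod("proteinMatrix", "CellLinePanel", function(x) x@proteinMatrix)
setMethod("doseResponse", "CellLinePanel", function(x) x@doseResponse)
setMethod("tissues", "CellLinePanel", function(x) x@tissues)
setMethod("patients", "CellLinePanel", function(x) x@patients)
setMethod("groundTruth", "CellLinePanel", function(x) x@groundTruth)
setMethod("cellLines", "CellLinePanel", function(x) rownames(x@transcriptMatrix))
setMethod("trueAuc", "GroundTruth", function(x) x@trueAuc)
setMethod("values", "OmicMatrix", function(x) x@values)
setMethod("dataType", "OmicMatrix", function(x) x@dataType)

#' Retrieve a molecular block from a panel as a typed matrix
#'
#' @param panel a [CellLinePanel-class].
#' @param type "mutation", "transcript" or "protein".
#' @return an [OmicMatrix-class] wrapping the raw (untransformed) block.
#' @export
omicBlock <- function(panel, type = c("mutation", "transcript", "protein")) {
  type <- match.arg(type)
  m <- switch(type, mutation = mutationMatrix(panel),
              transcript = transcriptMatrix(panel),
              protein = proteinMatrix(panel))
  OmicMatrix(m, type)
}

setMethod("show", "CellLinePanel", function(object) {
  gt <- if (is.null(object@groundTruth)) "no" else "yes"
  cat("CellLinePanel:", length(cellLines(object)), "cell lines,",
      ncol(object@mutationMatrix), "mutations,",
      ncol(object@transcriptMatrix), "transcripts,",
      ncol(object@proteinMatrix), "proteins\n")
  cat("  drugs:", length(unique(object@doseResponse$drug)),
      "| tissues:", length(unique(object@tissues)),
      "| ground truth:", gt, "\n")
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@ncomp, "component(s),",
      nrow(object@coefficients), "features,",
      ncol(object@coefficients), "response(s)\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult (", object@learner, "): ",
      length(object@measured), " cell lines, ",
      nrow(object@perRepeat), " repeat(s)\n", sep = "")
  cat(sprintf("  mean Spearman rho = %.3f | mean R2 = %.3f | mean RMS = %.4f\n",
              object@metrics$rho, object@metrics$r2, object@metrics$rms))
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf(
    "PermutationNull (%s): observed = %.3f, N = %d, p = %.4g, adj. p = %.4g\n",
    object@metric, object@observed, object@nShuffles, object@pValue,
    object@pAdjusted))
})

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", object@nCellLines, "lines x",
      object@nDrugs, "drugs |", object@nTranscripts, "transcripts,",
      object@nProteins, "proteins,", object@nMutations, "mutations | seed",
      object@seed, "\n")
})
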