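## Data-type-specific transforms, filters and mutation-matrix construction.
## All statistics used by filters and standardizers are computed on training
## lines only, so that fold-wise application leaks nothing from test lines.

#' @rdname OmicMatrix-class
#' @param valuesMatrix numeric cell line x feature matrix.
#' @param type "mutation", "transcript" or "protein".
#' @param transformed has the data-type log transform already been applied?
#' @export
OmicMatrix <- function(valuesMatrix, type, transformed = FALSE) {
  stopifnot(is.matrix(valuesMatrix))
  if (is.null(rownames(valuesMatrix)))
    rownames(valuesMatrix) <- paste0("line_", seq_len(nrow(valuesMatrix)))
  if (is.null(colnames(valuesMatrix)) && ncol(valuesMatrix) > 0L)
    colnames(valuesMatrix) <- paste0("f", seq_len(ncol(valuesMatrix)))
  new("OmicMatrix", values = valuesMatrix, dataType = type,
      transformed = transformed, transformState = list())
}

#' Apply the data-type expression transform
#'
#' Transcript values x become log2(1 + x); protein intensities x become
#' log2(x); binary mutation matrices pass through unchanged. Applying the
#' transform twice is an error.
#'
#' @param x an [OmicMatrix-class].
#' @return the transformed `OmicMatrix` (marked `transformed`).
#' @examples
#' m <- OmicMatrix(matrix(c(0, 3, 7, 15), 2, 2), "transcript")
#' values(transformExpression(m))  # log2(1 + x)
#' @export
transformExpression <- function(x) {
  stopifnot(is(x, "OmicMatrix"))
  if (x@transformed) stop("expression values are already transformed")
  v <- x@values
  if (x@dataType == "transcript") {
    if (any(v < 0)) stop("transcript values must be non-negative")
    v <- log2(1 + v)
  } else if (x@dataType == "protein") {
    if (any(v <= 0))
      stop("protein values must be strictly positive for the log2 transform")
    v <- log2(v)
  }
  initialize(x, values = v, transformed = TRUE)
}

## Data-type filter thresholds (on transformed scale).
.filterThresholds <- list(
  transcript = list(minMean = 2.0, minSd = 0.5),
  protein    = list(minMean = -Inf, minSd = 0.1))

#' Filter features by training-fold mean and variability
#'
#' Transcripts: discard genes with mean expression below 2.0 or sample SD
#' below 0.5 (log2(1 + x) scale) across the training lines. Proteins: discard
#' antibodies with SD below 0.1 (log2 scale). Mutations pass through (their
#' frequency filter is [filterMutationsByFrequency()]). Statistics use only
#' `trainingLines`, and the surviving feature set is what must be applied to
#' test lines.
#'
#' @param x a transformed [OmicMatrix-class].
#' @param trainingLines cell-line ids (or indices) defining the training fold;
#'   default all lines.
#' @return `OmicMatrix` restricted to surviving features.
#' @export
filterFeatures <- function(x, trainingLines = rownames(values(x))) {
  stopifnot(is(x, "OmicMatrix"))
  if (x@dataType == "mutation") return(x)
  if (!x@transformed)
    stop("filterFeatures expects transformed expression values")
  tr <- x@values[trainingLines, , drop = FALSE]
  th <- .filterThresholds[[x@dataType]]
  keep <- colMeans(tr) >= th$minMean & colSds(tr) >= th$minSd
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no features survive the ", x@dataType, " filters")
  initialize(x, values = x@values[, keep, drop = FALSE])
}

.impactLevels <- c("LOW" = 1L, "MODERATE" = 2L, "HIGH" = 3L)

#' Build a binary gene-level mutation matrix from a variant table
#'
#' A cell line is called mutated in a gene iff it carries at least one variant
#' passing all filters: read depth >= `minDepth`, supporting-read fraction >=
#' `minFraction`, predicted impact at least `minImpact` (unknown impact fails,
#' conservatively), and the gene not matching any excluded prefix (HLA- and
#' MUC- genes are recurrent false-positive cancer genes).
#'
#' @param variants data.frame with columns cell_line, gene, position,
#'   read_depth, supporting_reads, impact.
#' @param minDepth minimum read depth (default 30).
#' @param minFraction minimum fraction of reads supporting the variant (0.2).
#' @param minImpact minimum impact category, "LOW" < "MODERATE" < "HIGH".
#' @param excludedGenePrefixes gene-name prefixes to drop.
#' @param cellLines optional full cell-line universe (lines without any
#'   qualifying variant get all-zero rows).
#' @return an [OmicMatrix-class] with `dataType = "mutation"`.
#' @export
buildMutationMatrix <- function(variants, minDepth = 30L, minFraction = 0.2,
                                minImpact = "MODERATE",
                                excludedGenePrefixes = c("HLA-", "MUC-"),
                                cellLines = NULL) {
  req <- c("cell_line", "gene", "read_depth", "supporting_reads", "impact")
  if (!all(req %in% names(variants)))
    stop("variant table must have columns: ", paste(req, collapse = ", "))
  if (any(variants$supporting_reads > variants$read_depth))
    stop("supporting_reads cannot exceed read_depth")
  impOk <- .impactLevels[as.character(variants$impact)] >=
    .impactLevels[[minImpact]]
  impOk[is.na(impOk)] <- FALSE
  pass <- variants$read_depth >= minDepth &
    variants$supporting_reads >= minFraction * variants$read_depth & impOk
  for (pre in excludedGenePrefixes)
    pass <- pass & !startsWith(as.character(variants$gene), pre)
  v <- variants[pass, , drop = FALSE]
  lines <- cellLines %||% sort(unique(as.character(variants$cell_line)))
  genes <- sort(unique(as.character(v$gene)))
  m <- matrix(0, length(lines), max(length(genes), 1L),
              dimnames = list(lines, if (length(genes)) genes else "none"))
  if (!length(genes)) {
    message("no variants pass the filters; returning an empty mutation matrix")
    m <- m[, 0, drop = FALSE]
  } else {
    idx <- cbind(match(as.character(v$cell_line), lines),
                 match(as.character(v$gene), genes))
    m[idx] <- 1
  }
  OmicMatrix(m, "mutation")
}

#' Filter mutations by panel frequency
#'
#' Keep mutation columns carried by at least `minCount` and at most `maxCount`
#' of the cell lines (defaults 3 and n - 3).
#'
#' @param x a binary mutation [OmicMatrix-class].
#' @param minCount,maxCount inclusive bounds on the column sum.
#' @return filtered `OmicMatrix`.
#' @export
filterMutationsByFrequency <- function(x, minCount = 3L,
                                       maxCount = nrow(values(x)) - 3L) {
  stopifnot(is(x, "OmicMatrix"), x@dataType == "mutation")
  if (minCount > maxCount) stop("minCount must not exceed maxCount")
  s <- colSums(x@values)
  initialize(x, values = x@values[, s >= minCount & s <= maxCount,
                                  drop = FALSE])
}

#' Subset features to a gene list or a seeded random selection
#'
#' @param x an [OmicMatrix-class].
#' @param geneList character vector of feature ids to keep (order preserved).
#' @param randomK alternatively, keep `randomK` randomly selected features.
#' @param seed seed for the random selection.
#' @return subset `OmicMatrix`.
#' @export
subsetGenes <- function(x, geneList = NULL, randomK = NULL, seed = 1L) {
  stopifnot(is(x, "OmicMatrix"), is.null(geneList) != is.null(randomK))
  if (!is.null(geneList)) {
    hit <- geneList[geneList %in% colnames(x@values)]
    if (!length(hit)) stop("gene list has no overlap with the feature ids")
    return(initialize(x, values = x@values[, hit, drop = FALSE]))
  }
  if (randomK > ncol(x@values))
    stop("randomK exceeds the number of features")
  pick <- withSeed(streamSeed(seed, "subset_genes"),
                   sample(ncol(x@values), randomK))
  initialize(x, values = x@values[, pick, drop = FALSE])
}

#' Fit / apply a training-fold standardizer
#'
#' `fitStandardizer` computes per-feature centering and scaling parameters on
#' the training lines (columns with zero training SD are dropped with a
#' warning, as fold-wise subsets can create them) and returns the matrix with
#' those parameters applied and recorded. `applyStandardizer` transforms any
#' matrix (typically test lines) with a previously fitted state - never with
#' the test lines' own statistics.
#'
#' @param x an [OmicMatrix-class] (or plain matrix for `applyStandardizer`).
#' @param trainingLines training cell-line ids or indices.
#' @return `fitStandardizer`: `OmicMatrix` with `transformState` set;
#'   `applyStandardizer`: transformed numeric matrix.
#' @export
fitStandardizer <- function(x, trainingLines = rownames(values(x))) {
  stopifnot(is(x, "OmicMatrix"))
  tr <- x@values[trainingLines, , drop = FALSE]
  st <- .fitScaleState(tr)
  if (length(st$dropped))
    warning("dropping ", length(st$dropped),
            " zero-variance training column(s): ",
            paste(head(st$dropped, 5), collapse = ", "))
  initialize(x, values = applyStandardizer(x@values, st),
             transformState = st)
}

.fitScaleState <- function(tr) {
  ctr <- colMeans(tr)
  scl <- colSds(tr)
  keep <- !is.na(scl) & scl > 0
  list(center = ctr[keep], scale = scl[keep], keep = colnames(tr)[keep],
       dropped = colnames(tr)[!keep])
}

#' @rdname fitStandardizer
#' @param state a `transformState` list from `fitStandardizer`.
#' @export
applyStandardizer <- function(x, state) {
  v <- if (is(x, "OmicMatrix")) x@values else x
  missing <- setdiff(state$keep, colnames(v))
  if (length(missing))
    stop("matrix lacks features of the fitted state: ",
         paste(head(missing, 5), collapse = ", "))
  v <- v[, state$keep, drop = FALSE]
  centerScaleCols(v, state$center, state$scale)
}
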