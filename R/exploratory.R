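## Unsupervised structure analysis: complete-linkage hierarchical clustering,
## PCA, and two-cluster drug-response group tests.

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering over a Euclidean metric with complete linkage
#' (inter-cluster distance = maximum pairwise distance, so merge heights are
#' monotone non-decreasing). Rows containing missing values are dropped with
#' a warning.
#'
#' @param x numeric matrix.
#' @param axis cluster "rows" or "columns".
#' @return an object of class `hclust` (merge sequence + heights + order).
#' @export
hierarchicalCluster <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (axis == "columns") x <- t(x)
  bad <- rowSums(is.na(x)) > 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with missing values")
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into its two top-level clusters
#'
#' Labels from cutting just below the final merge.
#'
#' @param dendrogram an `hclust` object.
#' @return integer cluster labels (1/2) named by item.
#' @export
cutTwoClusters <- function(dendrogram) {
  stats::cutree(dendrogram, k = 2L)
}

#' Principal component analysis
#'
#' Column-centered PCA. Variance fractions are non-increasing, and with all
#' components the scores-loadings product reconstructs the centered matrix.
#'
#' @param x numeric matrix (centering applied internally; no scaling).
#' @param nComponents components to keep (truncated to the rank).
#' @return list with `scores`, `loadings`, `varianceFraction`.
#' @export
pcaPanel <- function(x, nComponents = 2L) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$rotation))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       varianceFraction = vf[seq_len(k)])
}

#' Per-drug response test between two cell-line clusters
#'
#' Welch's t test of each drug's AUC distribution between the two clusters,
#' with Benjamini-Hochberg adjustment across drugs. Drugs with fewer than 2
#' measured lines in either cluster are skipped (NA row, with a message).
#'
#' @param auc cell line x drug AUC matrix.
#' @param clusterLabels two-level labels over the rows of `auc`.
#' @return data.frame with columns drug, t, df, p, pAdj.
#' @export
clusterDrugResponseTest <- function(auc, clusterLabels) {
  stopifnot(length(clusterLabels) == nrow(auc))
  lv <- unique(clusterLabels)
  if (length(lv) != 2L) stop("clusterLabels must have exactly two levels")
  out <- data.frame(drug = colnames(auc), t = NA_real_, df = NA_real_,
                    p = NA_real_)
  for (j in seq_len(ncol(auc))) {
    v <- auc[, j]; ok <- !is.na(v)
    if (min(table(clusterLabels[ok])) < 2L ||
        length(unique(clusterLabels[ok])) < 2L) {
      message("skipping drug ", colnames(auc)[j],
              ": a cluster has fewer than 2 measured lines")
      next
    }
    w <- welchGroupTest(v[ok], clusterLabels[ok])
    out$t[j] <- w["t"]; out$df[j] <- w["df"]; out$p[j] <- w["p"]
  }
  out$pAdj <- NA_real_
  ok <- !is.na(out$p)
  out$pAdj[ok] <- bhAdjust(out$p[ok])
  out
}

#' Export a dendrogram as Newick text
#'
#' Writes the merge structure of an `hclust` object in Newick format, with
#' merge heights converted to branch lengths.
#'
#' @param dendrogram an `hclust` object.
#' @param file output path; with `file = ""` the string is returned invisibly
#'   without writing.
#' @return the Newick string, invisibly.
#' @export
exportNewick <- function(dendrogram, file = "") {
  n <- length(dendrogram$order)
  lab <- dendrogram$labels %||% as.character(seq_len(n))
  rec <- function(i, parentH) {
    if (i < 0) return(paste0(lab[-i], ":", format(parentH, digits = 10)))
    h <- dendrogram$height[i]
    kids <- vapply(dendrogram$merge[i, ], rec, character(1), parentH = h)
    paste0("(", paste(kids, collapse = ","), "):",
           format(max(parentH - h, 0), digits = 10))
  }
  top <- nrow(dendrogram$merge)
  nwk <- paste0(sub(":[^:]*$", "", rec(top, dendrogram$height[top])), ";")
  if (nzchar(file)) writeLines(nwk, file)
  invisible(nwk)
}
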