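## Dose-response summaries: mean-viability AUC, variable-drug selection,
## per-drug normalization.

.checkGeometricDoses <- function(doses, label, tol = 1e-6) {
  doses <- sort(doses)
  if (length(doses) < 2L)
    stop("dose series for ", label, " has fewer than 2 doses")
  if (any(doses <= 0)) stop("non-positive dose in series for ", label)
  r <- diff(log(doses))
  if (diff(range(r)) > tol * max(abs(r), 1))
    stop("dose series for ", label,
         " is not a geometric (evenly log-spaced) grid")
}

#' Summarise dose-response curves as mean-viability AUC
#'
#' The drug-sensitivity summary used throughout the package: for each
#' (cell line, drug) pair, the arithmetic mean of the measured viabilities
#' over the evenly log-spaced dose grid - equivalently the normalized area
#' under the dose-response curve. Lower AUC means more sensitive.
#' (Cell line, drug) pairs absent from the input are flagged missing (NA),
#' never imputed.
#'
#' @param curves data.frame with columns cell_line, drug, dose, viability;
#'   doses of each series must form a geometric grid.
#' @param summaries also attach per-pair IC50 (lowest dose with fitted
#'   viability below 0.5, by log-linear interpolation; NA if never reached)
#'   and maximum-inhibition matrices as attributes "ic50" and
#'   "max_inhibition". These are reported for inspection only and are not
#'   used by any downstream model.
#' @return numeric cell line x drug AUC matrix with NA for missing pairs.
#' @examples
#' tab <- data.frame(cell_line = "L1", drug = "d1", dose = 3^(0:8),
#'                   viability = seq(1, 0.2, length.out = 9))
#' meanViabilityAUC(tab)  # 0.6
#' @export
meanViabilityAUC <- function(curves, summaries = FALSE) {
  req <- c("cell_line", "drug", "dose", "viability")
  if (!all(req %in% names(curves)))
    stop("dose-response table must have columns: ", paste(req, collapse = ", "))
  if (any(curves$viability < 0)) stop("viability must be non-negative")
  key <- interaction(curves$cell_line, curves$drug, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    .checkGeometricDoses(curves$dose[sel], sub("\\.", " / ", k))
  }
  lines <- sort(unique(as.character(curves$cell_line)))
  drugs <- sort(unique(as.character(curves$drug)))
  auc <- matrix(NA_real_, length(lines), length(drugs),
                dimnames = list(lines, drugs))
  agg <- tapply(curves$viability, list(as.character(curves$cell_line),
                                       as.character(curves$drug)), mean)
  auc[rownames(agg), colnames(agg)] <- agg
  if (summaries) {
    ic50 <- maxinh <- auc * NA
    for (k in levels(key)) {
      sel <- key == k
      d <- curves$dose[sel]; v <- curves$viability[sel]
      o <- order(d); d <- d[o]; v <- v[o]
      cl <- as.character(curves$cell_line[sel][1])
      dr <- as.character(curves$drug[sel][1])
      maxinh[cl, dr] <- 1 - min(v)
      below <- which(v <= 0.5)
      if (length(below)) {
        i <- below[1]
        ic50[cl, dr] <- if (i == 1L) d[1] else
          exp(approx(v[c(i - 1L, i)], log(d[c(i - 1L, i)]), xout = 0.5)$y)
      }
    }
    attr(auc, "ic50") <- ic50
    attr(auc, "max_inhibition") <- maxinh
  }
  auc
}

#' Per-drug coefficient of variation of AUC
#'
#' @param auc cell line x drug AUC matrix (NAs allowed).
#' @return named vector sigma/mu per drug (sample SD over non-missing AUCs).
#' @export
drugCoefficientOfVariation <- function(auc) {
  mu <- colMeans(auc, na.rm = TRUE)
  sig <- apply(auc, 2, sd, na.rm = TRUE)
  if (any(mu <= 0, na.rm = TRUE))
    stop("coefficient of variation requires positive mean AUC")
  sig / mu
}

#' Select variable drugs by coefficient of variation
#'
#' Drugs with near-identical response across the panel carry no signal to
#' model; keep either the `k` drugs with the largest sigma/mu ("top_k") or all
#' drugs with sigma/mu at or above a threshold ("cv_threshold").
#'
#' @param auc cell line x drug AUC matrix.
#' @param mode "top_k" or "cv_threshold".
#' @param kOrThreshold k (count) or the CV threshold.
#' @return character vector of selected drug ids.
#' @export
selectVariableDrugs <- function(auc, mode = c("top_k", "cv_threshold"),
                                kOrThreshold) {
  mode <- match.arg(mode)
  nOk <- colSums(!is.na(auc))
  if (any(nOk < 3L))
    stop("each drug needs at least 3 non-missing AUCs: ",
         paste(colnames(auc)[nOk < 3L], collapse = ", "))
  cv <- drugCoefficientOfVariation(auc)
  if (mode == "top_k") {
    k <- as.integer(kOrThreshold)
    if (k > ncol(auc)) stop("k exceeds the number of drugs")
    names(sort(cv, decreasing = TRUE))[seq_len(k)]
  } else {
    colnames(auc)[cv >= kOrThreshold]
  }
}

#' Z-score AUC within each drug
#'
#' Per-drug z-score over the non-missing entries (mean 0, sample SD 1);
#' missing entries stay missing.
#'
#' @param auc cell line x drug AUC matrix.
#' @return normalized matrix of the same shape.
#' @export
normalizeAUCPerDrug <- function(auc) {
  nOk <- colSums(!is.na(auc))
  if (any(nOk < 2L))
    stop("need at least 2 non-missing values per drug")
  mu <- colMeans(auc, na.rm = TRUE)
  sig <- apply(auc, 2, sd, na.rm = TRUE)
  if (any(sig == 0))
    stop("zero-SD drug cannot be normalized: ",
         paste(colnames(auc)[sig == 0], collapse = ", "))
  sweep(sweep(auc, 2, mu), 2, sig, `/`)
}
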