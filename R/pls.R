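## Partial least squares by NIPALS, single- and multi-response.
##
## For a single response the NIPALS inner loop converges in one step
## (w is proportional to X'y), so components are computed directly; for
## multi-response PLS2 the classical iterative loop is used (tolerance 1e-12,
## at most 500 inner iterations). Deflation of X after each component makes
## successive components orthogonal.

.plsCore <- function(X, Y, ncomp, tol = 1e-12, maxit = 500L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  rmax <- min(n - 1L, p)
  if (ncomp > rmax) {
    warning("ncomp reduced from ", ncomp, " to ", rmax, " (rank limit)")
    ncomp <- rmax
  }
  xc <- colMeans(X); yc <- colMeans(Y)
  Xd <- centerCols(X, xc); Yd <- centerCols(Y, yc)
  W <- P <- matrix(0, p, ncomp)
  C <- matrix(0, ncomp, m)
  TT <- numeric(ncomp)
  S <- matrix(0, n, ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    if (m == 1L) {
      w <- crossprod(Xd, Yd)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tvec <- as.vector(Xd %*% w)
    } else {
      u <- Yd[, which.max(colSums(Yd^2))]
      tvec <- rep(0, n)
      for (it in seq_len(maxit)) {
        w <- crossprod(Xd, u)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14) break
        w <- w / nw
        tnew <- as.vector(Xd %*% w)
        q <- crossprod(Yd, tnew)[, 1]
        q <- q / sqrt(sum(q^2))
        u <- as.vector(Yd %*% q)
        if (sum((tnew - tvec)^2) < tol^2 * max(sum(tnew^2), 1)) {
          tvec <- tnew; break
        }
        tvec <- tnew
      }
      if (nw < 1e-14) break
    }
    tt <- sum(tvec^2)
    if (tt < 1e-28) break
    pl <- crossprod(Xd, tvec)[, 1] / tt
    cv <- crossprod(Yd, tvec)[, 1] / tt
    Xd <- Xd - tcrossprod(tvec, pl)
    Yd <- Yd - tcrossprod(tvec, cv)
    a <- k
    W[, k] <- w; P[, k] <- pl; C[k, ] <- cv; TT[k] <- tt; S[, k] <- tvec
  }
  if (a == 0L) {
    # degenerate (constant y or X): intercept-only model
    return(list(ncomp = 0L, W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
                C = C[0, , drop = FALSE], TT = numeric(0),
                S = S[, 0, drop = FALSE],
                B = matrix(0, p, m, dimnames = list(colnames(X), colnames(Y))),
                intercept = yc, xCenter = xc, yMean = yc))
  }
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  C <- C[seq_len(a), , drop = FALSE]; TT <- TT[seq_len(a)]
  S <- S[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))        # X-rotations
  B <- R %*% C
  dimnames(B) <- list(colnames(X), colnames(Y))
  list(ncomp = a, W = W, P = P, C = C, TT = TT, S = S, B = B,
       intercept = as.vector(yc - crossprod(xc, B)), xCenter = xc, yMean = yc)
}

.asPLSModel <- function(core, transformState = list()) {
  new("PLSModel", ncomp = core$ncomp, weights = core$W, loadings = core$P,
      yloadings = core$C, scores = core$S, coefficients = core$B,
      intercept = core$intercept,
      tt = core$TT, ssy = as.vector(core$TT * rowSums(core$C^2)),
      featureNames = rownames(core$B), transformState = transformState)
}

#' Fit a PLS regression model
#'
#' Fits single-response partial least squares by NIPALS: each component's
#' weight vector maximizes covariance between the X-projection and the
#' response, and X is deflated between components. The fit is deterministic
#' (no random initialization). The input is expected column-standardized and
#' is additionally centered internally, so predictions collapse exactly to
#' intercept + X %*% coefficients.
#'
#' @param X numeric cell line x feature matrix (no missing values),
#'   standardized by the caller (see [fitStandardizer()]).
#' @param y numeric response vector (AUC); centered internally.
#' @param ncomp number of PLS components; truncated with a warning when it
#'   exceeds the data rank limit min(n - 1, p).
#' @param transformState optional training standardization state stored in
#'   the model and applied to test data by [predictAUC()].
#' @return a [PLSModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3); y <- X[, 1] - X[, 2] + rnorm(20, sd = .1)
#' fit <- plsFit(X, y, ncomp = 2)
#' cor(predictAUC(fit, X), y)
#' @export
plsFit <- function(X, y, ncomp, transformState = list()) {
  stopifnot(is.matrix(X), length(y) == nrow(X), ncomp >= 1)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed in plsFit")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  .asPLSModel(.plsCore(X, matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                       as.integer(ncomp)), transformState)
}

#' Fit a multi-response (PLS2) model
#'
#' One shared component set predicts all responses at once; per-response
#' coefficient vectors are recovered from the shared rotations. With a single
#' response column this reduces exactly to [plsFit()].
#'
#' @param X as in [plsFit()].
#' @param Y numeric cell line x drug response matrix (no missing values; cell
#'   lines must be complete for all modeled drugs).
#' @inheritParams plsFit
#' @return a [PLSModel-class] with one coefficient column per response.
#' @export
pls2Fit <- function(X, Y, ncomp, transformState = list()) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(Y) == nrow(X), ncomp >= 1)
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed in pls2Fit")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  .asPLSModel(.plsCore(X, Y, as.integer(ncomp)), transformState)
}

#' @describeIn plsFit predict from a fitted PLS model; applies the stored
#'   training standardization state if present, checks feature agreement,
#'   and returns intercept + X %*% coefficients (a vector for one response).
#' @export
setMethod("predictAUC", "PLSModel", function(object, newdata, ...) {
  newdata <- .prepareNewdata(newdata, object)
  out <- sweep(newdata %*% object@coefficients, 2, object@intercept, `+`)
  if (ncol(out) == 1L) setNames(out[, 1], rownames(newdata)) else out
})

.prepareNewdata <- function(newdata, model) {
  if (is(newdata, "OmicMatrix")) newdata <- newdata@values
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(model@featureNames))
    colnames(newdata) <- model@featureNames
  if (length(model@transformState))
    newdata <- applyStandardizer(newdata, model@transformState)
  missing <- setdiff(model@featureNames, colnames(newdata))
  if (length(missing))
    stop("newdata lacks training features: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  newdata[, model@featureNames, drop = FALSE]
}

## Predictions of the first response for every component count 1..ncomp at
## once (n x ncomp), via sequential score computation on the deflated test
## matrix; used by nested-CV component selection. Column a equals the
## prediction of an a-component model.
.plsPredictAllComps <- function(core, Xtest) {
  n <- nrow(Xtest); A <- core$ncomp
  pred <- matrix(core$yMean[1], n, max(A, 1L))
  if (A == 0L) return(pred)
  Xd <- centerCols(Xtest, core$xCenter)
  acc <- rep(core$yMean[1], n)
  for (a in seq_len(A)) {
    tvec <- as.vector(Xd %*% core$W[, a])
    acc <- acc + tvec * core$C[a, 1]
    Xd <- Xd - tcrossprod(tvec, core$P[, a])
    pred[, a] <- acc
  }
  pred
}

#' Select a shared PLS2 component count by summed nested-CV RMS
#'
#' For a multi-response model the component count must be shared by all
#' drugs; it is chosen as the count minimizing the *sum* over responses of
#' the nested cross-validated RMS between predicted and measured
#' sensitivities.
#'
#' @param X standardized feature matrix.
#' @param Y response matrix (cell lines complete for all drugs).
#' @param nestedNFolds inner folds (default 10).
#' @param pcMin,pcMax component search range (defaults 1, 10).
#' @param seed fold-assignment seed.
#' @return list with `ncomp` (the argmin) and `rms` (the summed per-count
#'   RMS curve, named by component count).
#' @export
pls2SelectNcomp <- function(X, Y, nestedNFolds = 10L, pcMin = 1L,
                            pcMax = 10L, seed = 1L) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(Y) == nrow(X))
  n <- nrow(X)
  innerK <- min(nestedNFolds, n)
  folds <- foldAssignment(n, innerK, streamSeed(seed, "pls2_inner"))
  A <- max(min(pcMax, n - ceiling(n / innerK) - 1L, ncol(X)), pcMin)
  sse <- matrix(0, A, ncol(Y))   # per component count x response
  for (k in sort(unique(folds))) {
    tr <- folds != k
    st <- .fitScaleState(X[tr, , drop = FALSE])
    Xin <- applyStandardizer(X[tr, , drop = FALSE], st)
    Xte <- applyStandardizer(X[!tr, , drop = FALSE], st)
    core <- .plsCore(Xin, Y[tr, , drop = FALSE], A)
    Xd <- centerCols(Xte, core$xCenter)
    pred <- matrix(rep(core$yMean, each = nrow(Xte)), nrow(Xte))
    for (a in seq_len(A)) {
      if (a <= core$ncomp) {
        tvec <- as.vector(Xd %*% core$W[, a])
        pred <- pred + tcrossprod(tvec, core$C[a, ])
        Xd <- Xd - tcrossprod(tvec, core$P[, a])
      }
      sse[a, ] <- sse[a, ] + colSums((pred - Y[!tr, , drop = FALSE])^2)
    }
  }
  rms <- rowSums(sqrt(sse / n))
  idx <- seq(pcMin, A)
  curve <- setNames(rms[idx], idx)
  list(ncomp = as.integer(names(curve)[which.min(curve)]), rms = curve)
}

#' Variable Importance in Projection scores
#'
#' Standard VIP over the fitted components: for feature j,
#' VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a), where ssy_a is the
#' response variance explained by component a. Squared VIPs average to 1 by
#' construction.
#'
#' @param model a fitted [PLSModel-class].
#' @return named numeric vector of VIP scores.
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "PLSModel"))
  if (model@ncomp == 0L)
    return(setNames(rep(NA_real_, length(model@featureNames)),
                    model@featureNames))
  p <- nrow(model@weights)
  num <- model@weights^2 %*% model@ssy
  setNames(sqrt(p * num[, 1] / sum(model@ssy)), model@featureNames)
}
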