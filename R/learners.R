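## Comparison learners under the common fit/predict contract.
## The regression tree is backed by rpart (greedy variance-reduction CART
## with cost-complexity pruning over the tree's own cp sequence, pruning
## level picked by nested 10-fold CV at the plain minimum); the elastic net
## is backed by glmnet with the penalty reparameterized so that the package's
## (alpha, lambda) correspond to the objective
##   (1/2n) RSS + lambda * ((1 - alpha) ||beta||_2^2 + alpha ||beta||_1).

## Our (alpha, lambda) -> glmnet's (alpha', lambda'). glmnet's effective
## gaussian objective is (1/2n) RSS + lambda' alpha' ||b||_1 +
## (lambda' (1 - alpha') / (2 s_y)) ||b||_2^2, where s_y is the population SD
## of the response (its internal response standardization rescales only the
## quadratic penalty term). Matching our lambda ((1-alpha)||b||^2 +
## alpha||b||_1) exactly gives lambda' = lambda (alpha + 2 s_y (1 - alpha)),
## alpha' = lambda alpha / lambda'. Verified against the ridge closed form
## and an L1 optimizer oracle in the tests.
.glmnetParams <- function(alpha, lambda, y) {
  sy <- sqrt(mean((y - mean(y))^2))
  if (sy == 0) sy <- 1
  scale <- alpha + 2 * sy * (1 - alpha)
  list(alpha = if (lambda > 0) alpha / scale else alpha,
       lambda = lambda * scale)
}

#' Fit a cost-complexity pruned regression tree
#'
#' Greedy variance-reduction splits with a minimum bucket size; the pruning
#' level is selected by nested `nestedNFolds`-fold cross-validation over the
#' full tree's own cp sequence (plain minimum of the CV error).
#'
#' @param X numeric (or binary) cell line x feature matrix.
#' @param y response vector; a constant response yields a root-only tree
#'   predicting the mean.
#' @param minBucket minimum training lines per leaf (default 5).
#' @param nestedNFolds folds of the internal pruning CV.
#' @param seed seed for the pruning CV fold assignment.
#' @param transformState optional standardization state stored in the model.
#' @return a [TreeModel-class].
#' @export
treeFit <- function(X, y, minBucket = 5L, nestedNFolds = 10L, seed = 1L,
                    transformState = list()) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  df <- data.frame(.y = y, X, check.names = FALSE)
  ctl <- rpart::rpart.control(minbucket = minBucket,
                              minsplit = 2L * minBucket, cp = 0,
                              xval = min(nestedNFolds, nrow(X)),
                              maxsurrogate = 0, usesurrogate = 0)
  fit <- withSeed(seed,
    rpart::rpart(.y ~ ., data = df, method = "anova", control = ctl))
  cpt <- fit$cptable
  best <- cpt[which.min(cpt[, "xerror"]), "CP"]
  new("TreeModel", fit = rpart::prune(fit, cp = best), cp = unname(best),
      minBucket = as.integer(minBucket), featureNames = colnames(X),
      transformState = transformState)
}

#' @describeIn treeFit predict from a pruned tree.
#' @inheritParams predictAUC
#' @export
setMethod("predictAUC", "TreeModel", function(object, newdata, ...) {
  newdata <- .prepareNewdataFlexible(newdata, object)
  setNames(predict(object@fit,
                   data.frame(newdata, check.names = FALSE)),
           rownames(newdata))
})

## Like .prepareNewdata but tolerant of models without transformState.
.prepareNewdataFlexible <- function(newdata, model) {
  if (is(newdata, "OmicMatrix")) newdata <- newdata@values
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(model@featureNames))
    colnames(newdata) <- model@featureNames
  if (length(model@transformState))
    newdata <- applyStandardizer(newdata, model@transformState)
  missing <- setdiff(model@featureNames, colnames(newdata))
  if (length(missing))
    stop("newdata lacks training features: ",
         paste(head(missing, 5), collapse = ", "))
  newdata[, model@featureNames, drop = FALSE]
}

#' Fit an elastic-net (or lasso) linear model
#'
#' Minimizes (1/2n) RSS + lambda * ((1 - alpha) ||beta||_2^2 +
#' alpha ||beta||_1) with an unpenalized intercept. `alpha = 1` is the lasso,
#' `alpha = 0` pure ridge. Optimization is delegated to glmnet after an exact
#' reparameterization of the penalty.
#'
#' @param X standardized feature matrix.
#' @param y response vector.
#' @param alpha mixing parameter in [0, 1].
#' @param lambda penalty weight (>= 0).
#' @param transformState optional standardization state stored in the model.
#' @return an [ElasticNetModel-class].
#' @export
elasticNetFit <- function(X, y, alpha, lambda, transformState = list()) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  y <- as.vector(y)
  g <- .glmnetParams(alpha, lambda, y)
  ## a short warm-start path ending above the target; coef(exact = TRUE)
  ## refits at the target lambda itself
  path <- if (g$lambda > 0) g$lambda * c(10, 4, 2) else NULL
  fit <- glmnet::glmnet(X, y, alpha = g$alpha, lambda = path,
                        standardize = FALSE, thresh = 1e-12)
  cf <- as.vector(coef(fit, s = g$lambda, exact = TRUE, x = X, y = y,
                       alpha = g$alpha, standardize = FALSE, thresh = 1e-12))
  new("ElasticNetModel", coefficients = setNames(cf[-1], colnames(X)),
      intercept = cf[1], lambda = lambda, alpha = alpha,
      featureNames = colnames(X), transformState = transformState)
}

#' @describeIn elasticNetFit predict from a fitted elastic net.
#' @inheritParams predictAUC
#' @export
setMethod("predictAUC", "ElasticNetModel", function(object, newdata, ...) {
  newdata <- .prepareNewdataFlexible(newdata, object)
  setNames(as.vector(newdata %*% object@coefficients) + object@intercept,
           rownames(newdata))
})

#' Select elastic-net hyperparameters by nested cross-validation
#'
#' Grid search over alpha in 0, 0.1, ..., 1.0 and a data-driven log-spaced
#' lambda path; the winner minimizes the nested `nestedNFolds`-fold CV RMS.
#' Ties are broken toward the smallest alpha, then the largest lambda
#' (the sparser/smoother model).
#'
#' @param X standardized feature matrix (>= 20 training lines recommended).
#' @param y response vector.
#' @param nestedNFolds folds of the selection CV.
#' @param nLambda path length per alpha.
#' @param seed fold-assignment seed.
#' @return list with elements `alpha`, `lambda` (package parametrization) and
#'   the full CV table (`grid`).
#' @export
selectAlphaLambda <- function(X, y, nestedNFolds = 10L, nLambda = 30L,
                              seed = 1L) {
  y <- as.vector(y)
  n <- nrow(X)
  folds <- foldAssignment(n, nestedNFolds, streamSeed(seed, "enet_inner"))
  alphas <- seq(0, 1, by = 0.1)
  rows <- list()
  for (a in alphas) {
    gp <- .glmnetParams(a, 1, y)
    ga <- gp$alpha
    path <- glmnet::glmnet(X, y, alpha = max(ga, 1e-3), nlambda = nLambda,
                           standardize = FALSE)$lambda
    sse <- rep(0, length(path))
    for (k in sort(unique(folds))) {
      tr <- folds != k
      fitk <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = ga,
                             lambda = path, standardize = FALSE)
      pr <- predict(fitk, X[!tr, , drop = FALSE], s = path)
      sse <- sse + colSums((pr - y[!tr])^2)
    }
    rms <- sqrt(sse / n)
    rows[[length(rows) + 1L]] <-
      data.frame(alpha = a, lambda = path / gp$lambda, rms = rms)
  }
  grid <- do.call(rbind, rows)
  ## tie rule: min rms, then smallest alpha, then largest lambda
  o <- order(grid$rms, grid$alpha, -grid$lambda)
  win <- grid[o[1L], ]
  list(alpha = win$alpha, lambda = win$lambda, grid = grid)
}

#' Lasso sparsity-versus-performance sweep
#'
#' Along the lasso path (alpha = 1), reports cross-validated prediction
#' performance as a function of the number of nonzero coefficients - how
#' few features still give near-optimal predictions.
#'
#' @param X standardized feature matrix.
#' @param y response vector.
#' @param nFolds CV folds for the per-lambda performance estimate.
#' @param nLambda path length.
#' @param seed fold-assignment seed.
#' @return data.frame with columns lambda, nNonzero, rho, rms (per path
#'   point, CV estimates; nNonzero from the full-data fit).
#' @export
lassoSparsitySweep <- function(X, y, nFolds = 10L, nLambda = 40L, seed = 1L) {
  y <- as.vector(y)
  n <- nrow(X)
  full <- glmnet::glmnet(X, y, alpha = 1, nlambda = nLambda,
                         standardize = FALSE, lambda.min.ratio = 1e-3)
  path <- full$lambda
  folds <- foldAssignment(n, nFolds, streamSeed(seed, "lasso_sweep"))
  pred <- matrix(NA_real_, n, length(path))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    fitk <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1,
                           lambda = path, standardize = FALSE)
    pred[!tr, ] <- predict(fitk, X[!tr, , drop = FALSE], s = path)
  }
  nnz <- colSums(as.matrix(full$beta) != 0)
  rho <- apply(pred, 2, function(p)
    if (sd(p) == 0) 0 else cor(p, y, method = "spearman"))
  rms <- sqrt(colMeans((pred - y)^2))
  data.frame(lambda = path, nNonzero = nnz, rho = rho, rms = rms)
}

#' Fit the maximum-correlation baseline
#'
#' Simple linear regression on the single feature with the largest absolute
#' Pearson correlation with the response on the training data; ties go to
#' the lowest column index.
#'
#' @param X feature matrix (>= 3 training lines; at least one feature with
#'   nonzero variance).
#' @param y response vector.
#' @param transformState optional standardization state stored in the model.
#' @return a [MaxCorrModel-class].
#' @export
maxCorrFit <- function(X, y, transformState = list()) {
  stopifnot(nrow(X) >= 3L)
  sds <- colSds(X)
  if (all(sds == 0 | is.na(sds))) stop("all features are constant")
  r <- suppressWarnings(as.vector(cor(X, y)))
  r[is.na(r)] <- -Inf
  j <- which.max(abs(r))   # which.max takes the first (lowest index) on ties
  xj <- X[, j]
  slope <- cov(xj, y) / var(xj)
  new("MaxCorrModel", feature = colnames(X)[j], slope = slope,
      intercept = mean(y) - slope * mean(xj), featureNames = colnames(X),
      transformState = transformState)
}

#' @describeIn maxCorrFit predict from the selected single-feature line.
#' @inheritParams predictAUC
#' @export
setMethod("predictAUC", "MaxCorrModel", function(object, newdata, ...) {
  newdata <- .prepareNewdataFlexible(newdata, object)
  setNames(object@intercept + object@slope * newdata[, object@feature],
           rownames(newdata))
})
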