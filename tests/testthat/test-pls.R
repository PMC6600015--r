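# PLS core: oracle equivalences, algebraic identities, VIP.

test_that("univariate PLS with one component equals simple least squares", {
  set.seed(1)
  x <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "x"))
  y <- 0.4 + 2 * x[, 1] + rnorm(25, sd = 0.3)
  fit <- plsFit(x, y, 1)
  expect_lt(max(abs(predictAUC(fit, x) - fitted(lm(y ~ x)))), 1e-10)
})

test_that("with orthonormal columns full-component PLS equals OLS", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(25 * 5), 25, 5)))
  colnames(Q) <- paste0("q", 1:5)
  y <- rnorm(25)
  fit <- plsFit(Q, y, 5)
  ols <- lm(y ~ Q)
  expect_lt(max(abs(unname(fit@coefficients[, 1]) - unname(coef(ols)[-1]))),
            1e-10)
})

test_that("identical feature columns receive identical coefficients", {
  set.seed(3)
  x <- rnorm(20)
  X <- cbind(a = x, b = x, c = rnorm(20))
  y <- x + rnorm(20, sd = 0.2)
  fit <- plsFit(X, y, 2)
  expect_equal(fit@coefficients["a", 1], fit@coefficients["b", 1],
               tolerance = 1e-12)
})

test_that("predictions reproduce in-sample fitted values and the intercept", {
  set.seed(4)
  X <- scale(matrix(rnorm(120), 20, 6))
  colnames(X) <- paste0("f", 1:6)
  y <- rnorm(20)
  fit <- plsFit(X, y, 3)
  # training means row predicts the training mean of y
  expect_equal(unname(predictAUC(fit, matrix(colMeans(X), 1, 6,
    dimnames = list("m", colnames(X))))[1]), mean(y), tolerance = 1e-12)
  # collapsed linear form equals component-wise prediction on new data
  Xnew <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, colnames(X)))
  manual <- rep(mean(y), 5)
  Xd <- sweep(Xnew, 2, colMeans(X))
  Xt <- sweep(X, 2, colMeans(X))
  yd <- y - mean(y)
  for (a in seq_len(fit@ncomp)) {
    tv <- Xd %*% fit@weights[, a]
    manual <- manual + tv * fit@yloadings[a, 1]
    Xd <- Xd - tv %*% t(fit@loadings[, a])
  }
  expect_lt(max(abs(predictAUC(fit, Xnew) - manual)), 1e-10)
})

test_that("NIPALS matches an eigen-decomposition PLS reference", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rnorm(30)
    ref <- eigenPLSReference(X, y, 4)
    fit <- plsFit(X, y, 4)
    expect_lt(max(abs(abs(fit@weights) - abs(ref$W))), 1e-6)
    expect_lt(max(abs(predictAUC(fit, X) - ref$predict(X))), 1e-6)
  }
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(40)
  m <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  pm <- predict(m, X)$predict[, 1, 4]
  expect_lt(max(abs(predictAUC(plsFit(X, y, 4), X) - pm)), 1e-8)
})

test_that("training RMS is non-increasing in the number of components", {
  set.seed(7)
  X <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- rnorm(30)
  rms <- vapply(1:8, function(a) {
    f <- plsFit(X, y, a)
    sqrt(mean((predictAUC(f, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("coefficients are equivariant under feature permutation", {
  set.seed(8)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rnorm(25)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- plsFit(X, y, 3)
  f2 <- plsFit(X[, perm], y, 3)
  expect_equal(f2@coefficients[colnames(X), 1], f1@coefficients[, 1],
               tolerance = 1e-12)
})

test_that("requesting more components than the rank truncates with warning", {
  set.seed(9)
  X <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(6)
  expect_warning(fit <- plsFit(X, y, 10), "rank")
  expect_lte(fit@ncomp, 5L)
})

test_that("PLS2 reduces to PLS1 and respects duplicated-response symmetry", {
  set.seed(10)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rnorm(30)
  f1 <- plsFit(X, y, 3)
  f2 <- pls2Fit(X, cbind(y = y), 3)
  expect_lt(max(abs(predictAUC(f2, X) - predictAUC(f1, X))), 1e-10)
  fdup <- pls2Fit(X, cbind(a = y, b = y), 3)
  expect_equal(fdup@coefficients[, "a"], fdup@coefficients[, "b"],
               tolerance = 1e-10)
})

test_that("PLS2 agrees with an independent implementation on two responses", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("f", 1:6)))
  Y <- cbind(a = rnorm(30), b = rnorm(30))
  m <- mixOmics::pls(X, Y, ncomp = 3, mode = "regression", scale = FALSE)
  pm <- predict(m, X)$predict[, , 3]
  expect_lt(max(abs(predictAUC(pls2Fit(X, Y, 3), X) - pm)), 1e-8)
})

test_that("VIP scores satisfy their normalization and a hand computation", {
  set.seed(12)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "only"))
  y <- rnorm(20)
  expect_equal(unname(vipScores(plsFit(x, y, 1))), 1)
  X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fit <- plsFit(X, y, 3)
  v <- vipScores(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  # hand formula from the stored weights and per-component explained variance
  ssy <- fit@ssy
  hand <- sqrt(5 * (fit@weights^2 %*% ssy) / sum(ssy))[, 1]
  expect_equal(unname(v), unname(hand), tolerance = 1e-12)
})

test_that("prediction on mismatched features fails informatively", {
  set.seed(13)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  fit <- plsFit(X, rnorm(10), 2)
  bad <- X[, 1:2]
  expect_error(predictAUC(fit, bad), "f3")
})

test_that("compiled inner-CV RMS curve matches a plain-R recomputation", {
  set.seed(14)
  X <- matrix(rnorm(35 * 12), 35, 12)
  y <- rnorm(35)
  folds <- sample(rep(1:5, length.out = 35))
  rmsC <- drugOmics:::.cppPls1InnerRms(X, y, as.integer(folds), 6L)
  sse <- rep(0, 6)
  for (k in 1:5) {
    tr <- folds != k
    ctr <- colMeans(X[tr, ]); scl <- apply(X[tr, ], 2, sd)
    Xin <- scale(X[tr, ], ctr, scl)
    Xte <- scale(X[!tr, , drop = FALSE], ctr, scl)
    colnames(Xin) <- colnames(Xte) <- paste0("f", 1:12)
    for (a in 1:6) {
      f <- plsFit(Xin, y[tr], a)
      sse[a] <- sse[a] + sum((predictAUC(f, Xte) - y[!tr])^2)
    }
  }
  expect_equal(as.vector(rmsC), sqrt(sse / 35), tolerance = 1e-10)
})

test_that("PLS2 shared component count is the argmin of the summed RMS curve", {
  set.seed(25)
  X <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(NULL, paste0("f", 1:12)))
  Y <- cbind(a = X[, 1] + rnorm(40, sd = 0.6),
             b = X[, 2] - X[, 3] + rnorm(40, sd = 0.6))
  sel <- pls2SelectNcomp(X, Y, nestedNFolds = 5, pcMax = 6, seed = 4)
  # brute force: per fold, per component count, refit PLS2 and accumulate
  # squared errors per response; sum the per-response RMS curves
  folds <- drugOmics:::foldAssignment(40, 5, drugOmics:::streamSeed(4, "pls2_inner"))
  sse <- matrix(0, 6, 2)
  for (k in 1:5) {
    tr <- folds != k
    ctr <- colMeans(X[tr, ]); scl <- apply(X[tr, ], 2, sd)
    Xin <- scale(X[tr, ], ctr, scl); Xte <- scale(X[!tr, ], ctr, scl)
    colnames(Xin) <- colnames(Xte) <- colnames(X)
    for (a in 1:6) {
      fit <- pls2Fit(Xin, Y[tr, ], a)
      pr <- predictAUC(fit, Xte)
      sse[a, ] <- sse[a, ] + colSums((pr - Y[!tr, ])^2)
    }
  }
  curve <- rowSums(sqrt(sse / 40))
  expect_equal(unname(sel$rms), curve, tolerance = 1e-10)
  expect_equal(sel$ncomp, which.min(curve))
})
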