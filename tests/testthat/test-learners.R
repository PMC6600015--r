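# Comparison learners: regression tree, elastic net / lasso, max-correlation.

test_that("a perfectly separating binary feature yields a single-split tree", {
  X <- cbind(split = rep(c(0, 1), each = 6), noise = rnorm(12))
  y <- rep(c(1, 5), each = 6)
  fit <- treeFit(X, y, minBucket = 5, seed = 1)
  fr <- fit@fit$frame
  expect_identical(as.character(fr$var[1]), "split")
  expect_equal(sum(fr$var == "<leaf>"), 2L)
  pred <- predictAUC(fit, X)
  expect_equal(unname(pred), y)         # training R^2 = 1
})

test_that("constant response gives a root-only tree predicting the mean", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(2.5, 20)
  fit <- treeFit(X, y, seed = 1)
  expect_equal(nrow(fit@fit$frame), 1L)
  expect_equal(unname(predictAUC(fit, X)), rep(2.5, 20))
})

test_that("near-XOR structure is recovered as a depth-2 tree", {
  set.seed(15)
  x1 <- rep(c(0, 0, 1, 1), each = 6)
  x2 <- rep(c(0, 1, 0, 1), each = 6)
  y <- as.numeric(xor(x1, x2)) + rnorm(24, sd = 0.05)
  X <- cbind(f1 = x1, f2 = x2)
  fit <- treeFit(X, y, minBucket = 5, seed = 2)
  used <- setdiff(as.character(fit@fit$frame$var), "<leaf>")
  expect_setequal(used, c("f1", "f2"))
  # brute-force oracle: best depth-2 tree on the 4 cells predicts cell means
  cellMean <- tapply(y, interaction(x1, x2), mean)
  pred <- predictAUC(fit, X)
  expect_equal(unname(pred),
               as.numeric(cellMean[as.character(interaction(x1, x2))]),
               tolerance = 1e-10)
})

test_that("tree predictions are invariant to monotone feature transforms", {
  set.seed(16)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- (X[, 1] > 0) * 2 + rnorm(30, sd = 0.3)
  f1 <- treeFit(X, y, seed = 3)
  X2 <- X; X2[, 1] <- exp(X2[, 1])   # strictly monotone transform
  f2 <- treeFit(X2, y, seed = 3)
  expect_equal(unname(predictAUC(f1, X)), unname(predictAUC(f2, X2)),
               tolerance = 1e-10)
})

test_that("elastic net limits: full shrinkage and the unpenalized OLS case", {
  set.seed(17)
  X <- scale(matrix(rnorm(40 * 3), 40, 3))
  colnames(X) <- paste0("f", 1:3)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(40, sd = 0.2)
  big <- elasticNetFit(X, y, alpha = 0.5, lambda = 1e4)
  expect_true(all(big@coefficients == 0))
  expect_equal(big@intercept, mean(y), tolerance = 1e-8)
  none <- elasticNetFit(X, y, alpha = 0.5, lambda = 0)
  ols <- lm(y ~ X)
  expect_equal(unname(none@coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-4)
  expect_error(elasticNetFit(X, y, alpha = 2, lambda = 1), "alpha")
  expect_error(elasticNetFit(X, y, alpha = 1, lambda = -1), "lambda")
})

test_that("lasso solution minimizes the stated objective (optimizer oracle)", {
  set.seed(18)
  n <- 30
  X <- scale(matrix(rnorm(n * 4), n, 4)); colnames(X) <- paste0("f", 1:4)
  y <- X[, 1] + rnorm(n, sd = 0.5)
  lam <- 0.05
  obj <- function(b0b) {
    r <- y - b0b[1] - X %*% b0b[-1]
    sum(r^2) / (2 * n) + lam * sum(abs(b0b[-1]))
  }
  fit <- elasticNetFit(X, y, alpha = 1, lambda = lam)
  ours <- c(fit@intercept, fit@coefficients)
  oracle <- optim(rep(0, 5), obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-14))
  expect_lte(obj(ours), obj(oracle$par) + 1e-8)
  expect_lt(max(abs(ours - oracle$par)), 1e-3)
  # objective at the solution never exceeds the zero-coefficient objective
  expect_lte(obj(ours), obj(c(mean(y), 0, 0, 0, 0)) + 1e-12)
})

test_that("elastic-net objective matches across the alpha mixing range", {
  set.seed(19)
  n <- 25
  X <- scale(matrix(rnorm(n * 3), n, 3)); colnames(X) <- paste0("f", 1:3)
  y <- X %*% c(1, 0, -0.5) + rnorm(n, sd = 0.3)
  for (alpha in c(0, 0.3, 0.7)) {
    lam <- 0.08
    obj <- function(b0b) {
      r <- y - b0b[1] - X %*% b0b[-1]
      sum(r^2) / (2 * n) +
        lam * ((1 - alpha) * sum(b0b[-1]^2) + alpha * sum(abs(b0b[-1])))
    }
    fit <- elasticNetFit(X, y, alpha = alpha, lambda = lam)
    ours <- c(fit@intercept, fit@coefficients)
    oracle <- optim(rep(0, 4), obj, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
    expect_lte(obj(ours), obj(oracle$par) + 1e-8)
  }
})

test_that("hyperparameter search recovers strong features, shrinks pure noise", {
  set.seed(20)
  n <- 40
  X <- scale(matrix(rnorm(n * 10), n, 10)); colnames(X) <- paste0("f", 1:10)
  y <- 2 * X[, 1] - 2 * X[, 2] + rnorm(n, sd = 0.4)
  sel <- selectAlphaLambda(X, y, seed = 1)
  fit <- elasticNetFit(X, y, alpha = sel$alpha, lambda = sel$lambda)
  expect_true(all(fit@coefficients[c("f1", "f2")] != 0))
  ynoise <- rnorm(n)
  seln <- selectAlphaLambda(X, ynoise, seed = 1)
  fitn <- elasticNetFit(X, ynoise, alpha = seln$alpha, lambda = seln$lambda)
  # heavy shrinkage under pure noise: predictions nearly flat
  expect_lt(sd(predictAUC(fitn, X)), 0.4 * sd(ynoise))
})

test_that("selection tie rule prefers smallest alpha then largest lambda", {
  grid <- data.frame(alpha = c(0.2, 0.1, 0.1), lambda = c(1, 0.5, 2),
                     rms = c(1, 1, 1))
  o <- order(grid$rms, grid$alpha, -grid$lambda)
  expect_equal(grid[o[1], "alpha"], 0.1)
  expect_equal(grid[o[1], "lambda"], 2)
})

test_that("lasso sparsity sweep: monotone support, baseline at empty support", {
  set.seed(21)
  n <- 45
  X <- scale(matrix(rnorm(n * 20), n, 20)); colnames(X) <- paste0("f", 1:20)
  y <- X[, 1:5] %*% runif(5, 0.8, 1.2) + rnorm(n, sd = 0.8)
  sweep <- lassoSparsitySweep(X, y, seed = 2)
  # lambda path is decreasing, support sizes non-decreasing along it
  expect_true(all(diff(sweep$lambda) <= 0))
  expect_true(all(diff(sweep$nNonzero) >= 0))
  # empty-support entries behave like the mean predictor (rho ~ 0)
  if (any(sweep$nNonzero == 0))
    expect_lt(max(abs(sweep$rho[sweep$nNonzero == 0])), 0.5)
  # near-optimal performance reached by support size 10
  best <- min(sweep$rms)
  at10 <- min(sweep$rms[sweep$nNonzero <= 10])
  expect_lte(at10, best * 1.15)
})

test_that("max-correlation model selects the right feature and tie-breaks low", {
  set.seed(22)
  y <- rnorm(20)
  X <- cbind(a = rnorm(20), exact = y, b = rnorm(20))
  fit <- maxCorrFit(X, y)
  expect_identical(fit@feature, "exact")
  expect_lt(max(abs(predictAUC(fit, X) - y)), 1e-12)
  # duplicated feature: the lower column index wins
  X2 <- cbind(first = y + rnorm(20, sd = 0.5))
  X2 <- cbind(X2, second = X2[, "first"])
  expect_identical(maxCorrFit(X2, y)@feature, "first")
  expect_error(maxCorrFit(cbind(k = rep(1, 20)), y), "constant")
})

test_that("max-correlation succeeds against many noise features", {
  set.seed(23)
  hits <- 0L
  for (i in 1:100) {
    n <- 30
    X <- matrix(rnorm(n * 51), n, 51,
                dimnames = list(NULL, c(paste0("noise", 1:50), "signal")))
    y <- 0.9 * scale(X[, "signal"])[, 1] + rnorm(n, sd = sqrt(1 - 0.81))
    if (maxCorrFit(X, y)@feature == "signal") hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
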