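# Metrics, component selection, the CV orchestrator and permutation nulls.

test_that("R^2 fraction-of-variance-explained matches hand computations", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(r2Explained(a, a), 1)
  expect_equal(r2Explained(a, rep(mean(a), 4)), 0)
  expect_equal(r2Explained(c(0, 1), c(1, 0)), -3)  # 1 - (2*1)/(2*0.25)
  expect_error(r2Explained(c(1, 1), c(1, 2)), "constant")
})

test_that("Spearman rho averages tied ranks", {
  a <- c(1, 2, 3)
  expect_equal(spearmanRho(a, 2 * a), 1)
  expect_equal(spearmanRho(a, -a), -1)
  # ties in the prediction: ranks 1.5, 1.5, 3 against 1, 2, 3
  expect_equal(spearmanRho(a, c(1, 1, 2)), 0.866, tolerance = 1e-3)
  expect_warning(r <- spearmanRho(a, c(1, 1, 1)), "constant")
  expect_true(is.na(r))
})

test_that("Benjamini-Hochberg step-up matches hand computations", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  p <- runif(20)
  expect_true(all(bhAdjust(p) >= p))
  expect_true(all(bhAdjust(p) <= 1))
})

test_that("Welch test matches the textbook example and its symmetries", {
  w <- welchGroupTest(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(w["t"]), -3.674, tolerance = 1e-3)
  expect_equal(unname(w["df"]), 4, tolerance = 1e-6)
  expect_equal(unname(w["p"]), 0.0213, tolerance = 1e-3)
  wFlip <- welchGroupTest(c(1, 2, 3, 4, 5, 6), rep(c("b", "a"), each = 3))
  expect_equal(unname(wFlip["t"]), -unname(w["t"]))
  expect_equal(unname(wFlip["p"]), unname(w["p"]))
  same <- welchGroupTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(unname(same["t"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_error(welchGroupTest(1:3, c("a", "b", "b")), "at least 2")
})

test_that("component count selection stops at the first RMS increase", {
  expect_equal(selectNcomp(c(5, 4, 3, 3.5, 2)), 3)
  expect_equal(selectNcomp(10:1), 10)        # never increases: take the max
  expect_equal(selectNcomp(c(2, 3, 1)), 1)
  expect_equal(selectNcomp(c(4)), 1)
  expect_equal(selectNcomp(c(5, 4, 4.5), pcMin = 2), 3)
})

test_that("fold assignment partitions 49 lines into 9 fives and a four", {
  f <- drugOmics:::foldAssignment(49, 10, seed = 3)
  expect_equal(sort(as.vector(table(f))), c(4, rep(5, 9)))
  expect_length(f, 49)
})

test_that("the training-mean baseline cannot beat the mean (R^2 <= 0)", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  res <- repeatedNestedCV(omicBlock(panel, "protein"), auc[, 1],
                          learnerSpec("mean"),
                          cvConfig(nRepeats = 3, seed = 4))
  expect_lte(res@metrics$r2, 0)
})

test_that("repeated nested CV is deterministic and predicts each line once", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  cv <- cvConfig(nFolds = 5, nRepeats = 2, nestedNFolds = 5, pcMax = 4,
                 seed = 11)
  r1 <- repeatedNestedCV(omicBlock(panel, "protein"), auc[, 2],
                         learnerSpec("pls"), cv)
  r2 <- repeatedNestedCV(omicBlock(panel, "protein"), auc[, 2],
                         learnerSpec("pls"), cv)
  expect_identical(r1, r2)
  expect_length(r1@predicted, nrow(auc))
  expect_false(anyNA(r1@predicted))
  r3 <- repeatedNestedCV(omicBlock(panel, "protein"), auc[, 2],
                         learnerSpec("pls"), initialize(cv, seed = 12L))
  expect_false(identical(r1@perRepeat, r3@perRepeat))
})

test_that("cell lines with missing AUC are discarded before modeling", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  y <- auc[, 1]
  y[c(2, 5)] <- NA
  res <- repeatedNestedCV(omicBlock(panel, "protein"), y,
                          learnerSpec("maxcorr"),
                          cvConfig(nFolds = 5, nRepeats = 1, seed = 1))
  expect_length(res@measured, length(y) - 2)
  expect_false(any(names(res@measured) %in% names(y)[c(2, 5)]))
})

test_that("planted signal is recovered while shuffled responses are not", {
  panel <- defaultPanel(seed = 1, effectSize = 2)
  auc <- meanViabilityAUC(doseResponse(panel))
  prot <- omicBlock(panel, "protein")
  d <- "drug_08"  # an informative protein-signature drug in this layout
  cv <- cvConfig(nRepeats = 3, seed = 5)
  res <- repeatedNestedCV(prot, auc[, d], learnerSpec("pls"), cv)
  expect_gt(res@metrics$rho, 0.3)
  yshuf <- withSeed(99, sample(auc[, d]))
  names(yshuf) <- rownames(auc)
  resShuf <- repeatedNestedCV(prot, yshuf, learnerSpec("pls"), cv)
  expect_lt(resShuf@metrics$rho, res@metrics$rho)
})

test_that("permutation p-values follow the add-one empirical formula", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  prot <- omicBlock(panel, "protein")
  cv <- cvConfig(nFolds = 5, nRepeats = 1, nestedNFolds = 5, pcMax = 3,
                 seed = 7)
  bg <- permutationBackground(prot, auc[, 1], learnerSpec("maxcorr"), cv,
                              nShuffles = 19)
  k <- sum(bg@nullValues >= bg@observed, na.rm = TRUE) +
    sum(is.na(bg@nullValues))
  expect_equal(bg@pValue, (1 + k) / 20)
  expect_gte(bg@pValue, 1 / 20)
  expect_lte(bg@pValue, 1)
  # formula edge cases, computed directly
  expect_equal((1 + 0) / (1 + 999), 0.001)       # observed beats all nulls
  expect_equal((1 + 999) / (1 + 999), 1.0)       # observed below all nulls
})

test_that("null responses give centred Spearman distribution over shuffles", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  gt <- groundTruth(panel)
  prot <- omicBlock(panel, "protein")
  cv <- cvConfig(nFolds = 5, nRepeats = 1, nestedNFolds = 5, pcMax = 3,
                 seed = 13)
  bg <- permutationBackground(prot, auc[, gt@nullDrugs[1]],
                              learnerSpec("pls"), cv, nShuffles = 40)
  vals <- bg@nullValues[!is.na(bg@nullValues)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2.5 * se + 0.05)
})

test_that("test-fold values never influence training-fold preparation", {
  panel <- smallPanel()
  auc <- meanViabilityAUC(doseResponse(panel))
  blocks <- drugOmics:::.asBlocks(omicBlock(panel, "transcript"))
  n <- length(cellLines(panel))
  trIdx <- 1:16; teIdx <- 17:n
  p1 <- drugOmics:::.prepareFold(blocks, trIdx, teIdx)
  # corrupt the test rows: training matrix and chosen features must not move
  b2 <- blocks
  v <- b2[[1]]@values
  v[teIdx, ] <- v[teIdx, ] * 7 + 3
  b2[[1]] <- methods::initialize(b2[[1]], values = v)
  p2 <- drugOmics:::.prepareFold(b2, trIdx, teIdx)
  expect_identical(p1$train, p2$train)
  expect_identical(colnames(p1$test), colnames(p2$test))
})
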