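# Transforms, filters, mutation-matrix construction, standardizers.

test_that("expression transforms follow the data type", {
  tr <- OmicMatrix(matrix(c(0, 3, 1, 7), 2, 2), "transcript")
  expect_equal(unname(values(transformExpression(tr))),
               matrix(c(0, 2, 1, 3), 2, 2))
  pr <- OmicMatrix(matrix(c(8, 2, 4, 1), 2, 2), "protein")
  expect_equal(unname(values(transformExpression(pr))),
               matrix(c(3, 1, 2, 0), 2, 2))
  mu <- OmicMatrix(matrix(c(0, 1, 1, 0), 2, 2), "mutation")
  expect_identical(values(transformExpression(mu)), values(mu))
  bad <- OmicMatrix(matrix(c(0, 2, 4, 1), 2, 2), "protein")
  expect_error(transformExpression(bad), "positive")
})

test_that("mean/SD filters drop the stated transcript and protein features", {
  raw <- cbind(allzero = rep(0, 6),
               constant = rep(15, 6),            # log2(16) = 4, SD 0
               good = 2^c(2, 3, 4, 2.5, 3.5, 4.5) - 1,
               lowmean = 2^c(0.5, 1, 0.2, 0.8, 1.2, 0.3) - 1)
  x <- transformExpression(OmicMatrix(raw, "transcript"))
  kept <- colnames(values(filterFeatures(x)))
  expect_identical(kept, "good")
  prot <- cbind(flat = 2^rnorm(6, 3, 0.01), varying = 2^rnorm(6, 3, 1))
  xp <- transformExpression(OmicMatrix(prot, "protein"))
  expect_identical(colnames(values(filterFeatures(xp))), "varying")
})

test_that("feature filtering is monotone in its thresholds", {
  set.seed(2)
  raw <- matrix(2^rnorm(200, 3, 1.2) - 1, 20, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
  x <- transformExpression(OmicMatrix(raw, "transcript"))
  kept <- colnames(values(filterFeatures(x)))
  # relaxing thresholds == recomputing membership by hand with lower cuts
  v <- values(x)
  relaxed <- colnames(v)[colMeans(v) >= 1 & apply(v, 2, sd) >= 0.2]
  expect_true(all(kept %in% relaxed))
})

test_that("variant filters implement the depth/support/impact/prefix rules", {
  variants <- data.frame(
    cell_line = c("A", "A", "B", "B", "A", "B"),
    gene = c("BRAF", "KRAS", "BRAF", "HLA-A", "NRAS", "NRAS"),
    position = 1:6,
    read_depth = c(40, 25, 50, 60, 40, 40),
    supporting_reads = c(20, 10, 6, 30, 10, 20),
    impact = c("HIGH", "HIGH", "MODERATE", "HIGH", "LOW", "MODERATE"))
  m <- values(buildMutationMatrix(variants))
  # KRAS variant fails depth (25 < 30); BRAF in B fails support (6/50 = 12%);
  # HLA-A excluded by prefix; NRAS in A fails impact (LOW)
  expect_identical(sort(colnames(m)), c("BRAF", "NRAS"))
  expect_equal(m["A", "BRAF"], 1)
  expect_equal(m["B", "BRAF"], 0)
  expect_equal(m["A", "NRAS"], 0)
  expect_equal(m["B", "NRAS"], 1)
  # boundary: exactly 30 reads and exactly 20% support pass
  edge <- data.frame(cell_line = "A", gene = "TP53", position = 1,
                     read_depth = 30, supporting_reads = 6,
                     impact = "MODERATE")
  expect_equal(values(buildMutationMatrix(edge))["A", "TP53"], 1)
  # unknown impact fails conservatively
  unk <- transform(edge, impact = "MODIFIER")
  expect_message(m2 <- buildMutationMatrix(unk), "no variants")
  expect_equal(ncol(values(m2)), 0L)
})

test_that("mutation-matrix construction is idempotent on its own semantics", {
  set.seed(3)
  variants <- data.frame(
    cell_line = sample(paste0("L", 1:8), 40, TRUE),
    gene = sample(c("G1", "G2", "G3"), 40, TRUE),
    position = 1:40,
    read_depth = sample(20:60, 40, TRUE),
    supporting_reads = sample(1:20, 40, TRUE),
    impact = sample(c("LOW", "MODERATE", "HIGH"), 40, TRUE))
  variants$supporting_reads <- pmin(variants$supporting_reads,
                                    variants$read_depth)
  m1 <- buildMutationMatrix(variants)
  # refilter the already-passing variants: same matrix
  pass <- variants$read_depth >= 30 &
    variants$supporting_reads >= 0.2 * variants$read_depth &
    variants$impact %in% c("MODERATE", "HIGH")
  m2 <- buildMutationMatrix(variants[pass, ],
                            cellLines = rownames(values(m1)))
  expect_identical(values(m1), values(m2))
})

test_that("frequency filter keeps column sums within [min, max]", {
  m <- matrix(0, 45, 3, dimnames = list(paste0("L", 1:45), c("a", "b", "c")))
  m[1:2, "a"] <- 1   # sum 2: dropped
  m[1:3, "b"] <- 1   # sum 3: kept
  m[1:43, "c"] <- 1  # sum 43 > 42: dropped
  kept <- colnames(values(filterMutationsByFrequency(OmicMatrix(m, "mutation"))))
  expect_identical(kept, "b")
  expect_error(filterMutationsByFrequency(OmicMatrix(m, "mutation"),
                                          minCount = 5, maxCount = 2),
               "exceed")
})

test_that("gene subsetting honors lists and seeded random selection", {
  x <- OmicMatrix(matrix(rnorm(40), 4, 10,
                         dimnames = list(NULL, paste0("g", 1:10))),
                  "protein")
  expect_identical(colnames(values(subsetGenes(x, geneList = paste0("g", 10:1)))),
                   paste0("g", 10:1))
  expect_identical(values(subsetGenes(x, geneList = colnames(values(x)))),
                   values(x))
  r1 <- subsetGenes(x, randomK = 10L, seed = 5)
  expect_setequal(colnames(values(r1)), colnames(values(x)))
  r2 <- subsetGenes(x, randomK = 3L, seed = 5)
  expect_identical(values(r2), values(subsetGenes(x, randomK = 3L, seed = 5)))
  expect_error(subsetGenes(x, geneList = c("nope")), "overlap")
})

test_that("standardizer fits on training lines and transfers to test lines", {
  m <- matrix(c(1, 3, 2, 10, 20, 15), 3, 2,
              dimnames = list(c("tr1", "tr2", "te"), c("f1", "f2")))
  x <- OmicMatrix(m, "protein", transformed = TRUE)
  fitted <- fitStandardizer(x, trainingLines = c("tr1", "tr2"))
  st <- fitted@transformState
  expect_equal(unname(st$center), c(2, 15))
  expect_equal(unname(st$scale), c(sqrt(2), sqrt(50)))
  # two-point columns standardize to +/- 1/sqrt(2) under the sample SD
  expect_equal(unname(values(fitted)["tr1", ]), c(-1 / sqrt(2), -1 / sqrt(2)))
  # test value at the training mean maps to 0
  expect_equal(unname(applyStandardizer(matrix(c(2, 15), 1, 2,
    dimnames = list("z", c("f1", "f2"))), st)[1, ]), c(0, 0))
  # identity check on a random matrix
  set.seed(8)
  mm <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ss <- fitStandardizer(OmicMatrix(mm, "protein", transformed = TRUE))
  expect_lt(max(abs(colMeans(values(ss)))), 1e-12)
  expect_lt(max(abs(apply(values(ss), 2, sd) - 1)), 1e-12)
})

test_that("zero-variance training columns are dropped with a warning", {
  m <- cbind(const = rep(1, 4), ok = c(1, 2, 3, 4))
  x <- OmicMatrix(m, "protein", transformed = TRUE)
  expect_warning(out <- fitStandardizer(x), "zero-variance")
  expect_identical(colnames(values(out)), "ok")
})

test_that("filters and standardizers never look at test lines", {
  set.seed(10)
  raw <- matrix(2^rnorm(300, 3, 1) - 1, 30, 10,
                dimnames = list(paste0("L", 1:30), paste0("g", 1:10)))
  x <- transformExpression(OmicMatrix(raw, "transcript"))
  trainLines <- paste0("L", 1:20)
  f1 <- filterFeatures(x, trainLines)
  s1 <- fitStandardizer(f1, trainLines)
  # corrupt the test rows wildly; training-derived state must not move
  raw2 <- raw
  raw2[21:30, ] <- raw2[21:30, ] * 100 + 5
  x2 <- transformExpression(OmicMatrix(raw2, "transcript"))
  f2 <- filterFeatures(x2, trainLines)
  s2 <- fitStandardizer(f2, trainLines)
  expect_identical(colnames(values(f1)), colnames(values(f2)))
  expect_identical(s1@transformState, s2@transformState)
})
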