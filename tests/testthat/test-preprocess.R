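test_that("session selection keeps exactly n per subject, without replacement", {
  pe <- smallCohort(sessions = 5L)
  sel <- selectSessionsPerSubject(pe, 3L, seed = 4L)
  expect_true(all(table(subjectIds(sel)) == 3L))
  # no duplicated sample within a subject: session indices unique
  bySub <- split(sessionIndex(sel), subjectIds(sel))
  expect_true(all(vapply(bySub, anyDuplicated, integer(1)) == 0L))
  # a subject with exactly n sessions keeps them all
  pe3 <- smallCohort(sessions = 3L)
  sel3 <- selectSessionsPerSubject(pe3, 3L, seed = 4L)
  expect_equal(ncol(sel3), ncol(pe3))
  # n = 1 gives one distinct row per subject
  sel1 <- selectSessionsPerSubject(pe, 1L, seed = 4L)
  expect_equal(ncol(sel1), length(unique(subjectIds(pe))))
  expect_equal(anyDuplicated(subjectIds(sel1)), 0L)
  # seeded determinism
  expect_identical(postureMatrix(selectSessionsPerSubject(pe, 3L, seed = 9L)),
                   postureMatrix(selectSessionsPerSubject(pe, 3L, seed = 9L)))
  # subject with too few sessions is named in the error
  expect_error(selectSessionsPerSubject(pe, 6L), "S0001")
})

test_that("isolation forest flags planted gross outliers", {
  set.seed(21)
  sch <- buildSchema()
  inliers <- matrix(rnorm(100 * 54, sd = 1), 100)
  outliers <- matrix(rnorm(5 * 54, mean = 10, sd = 1), 5)  # 10 SD away
  X <- rbind(inliers, outliers)
  colnames(X) <- featureNames(sch)
  pe <- PostureExperiment(X, subjectId = sprintf("S%03d", 1:105),
                          classLabel = rep("h", 105), sessionIdx = rep(1L, 105))
  res <- removeOutliers(pe, contamination = 5 / 105, seed = 22L)
  expect_equal(res$removed, 5L)
  # independent oracle: Mahalanobis distance ranks the same 5 rows highest
  md <- mahalanobis(X, colMeans(X), diag(diag(cov(X))))
  worst <- order(md, decreasing = TRUE)[1:5]
  kept <- subjectIds(res$dataset)
  expect_true(all(!sprintf("S%03d", worst) %in% kept))
})

test_that("numeric contamination removes round(contamination * n) rows", {
  pe <- smallCohort(sessions = 5L)  # 50 samples
  for (ct in c(0.1, 0.06, 0.5)) {
    res <- removeOutliers(pe, nTrees = 50L, contamination = ct, seed = 1L)
    expect_equal(res$removed, round(ct * ncol(pe)))
    expect_equal(ncol(res$dataset), ncol(pe) - res$removed)
  }
  expect_error(removeOutliers(pe, contamination = 0.6), "contamination")
  expect_error(removeOutliers(pe, contamination = -0.1), "contamination")
})

test_that("grouped folds are subject-disjoint and cover everyone exactly once", {
  pe <- smallCohort(nSub = c(healthy_1 = 13, back_pain = 8), sessions = 3L)
  folds <- makeGroupedFolds(pe, k = 5L, seed = 17L)
  allSub <- unique(subjectIds(pe))
  testedOnce <- unlist(lapply(folds$folds, `[[`, "test"))
  expect_setequal(testedOnce, allSub)
  expect_equal(anyDuplicated(testedOnce), 0L)
  for (f in folds$folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_setequal(c(f$train, f$val, f$test), allSub)
  }
})

test_that("test-set sizes are near-equal and the split approximates 70/10/20", {
  sch <- buildSchema()
  n <- 338L
  m <- matrix(rnorm(n * 54), n, dimnames = list(NULL, featureNames(sch)))
  pe <- PostureExperiment(m, subjectId = sprintf("P%03d", 1:n),
                          classLabel = rep("h", n), sessionIdx = rep(1L, n))
  folds <- makeGroupedFolds(pe, k = 5L, seed = 3L)
  sizes <- vapply(folds$folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes %in% c(67L, 68L)))   # ceil/floor of 338/5
  fr <- vapply(folds$folds, function(f)
    c(length(f$train), length(f$val), length(f$test)) / n, numeric(3))
  expect_equal(rowMeans(fr), c(0.70, 0.10, 0.20), tolerance = 0.02)
  # 5 subjects, k = 5: singleton test sets
  pe5 <- pe[, 1:5]
  f5 <- makeGroupedFolds(pe5, k = 5L, seed = 1L)
  expect_true(all(vapply(f5$folds, function(f) length(f$test), integer(1)) == 1L))
  expect_error(makeGroupedFolds(pe5, k = 6L), "k")
})

test_that("fold assignments survive a JSON round trip", {
  pe <- smallCohort()
  folds <- makeGroupedFolds(pe, k = 3L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  writeFoldsJson(folds, path)
  back <- readFoldsJson(path)
  expect_equal(back$k, folds$k)
  for (i in 1:3) expect_equal(back$folds[[i]], folds$folds[[i]])
})

test_that("standardizer matches the closed form and inverts exactly", {
  std <- fitStandardizer(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(std$center, 2, ignore_attr = TRUE)
  expect_equal(std$scale, sqrt(2 / 3), ignore_attr = TRUE)  # population SD
  z <- applyStandardizer(std, matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(z)[1], -1.224745, tolerance = 1e-6)
  # degenerate constant feature transforms to 0
  std2 <- fitStandardizer(cbind(c(5, 5, 5), c(1, 2, 3)))
  z2 <- applyStandardizer(std2, cbind(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(z2[, 1], rep(0, 3))
  # round trip on random data
  set.seed(6)
  X <- matrix(rnorm(200), 20)
  stdX <- fitStandardizer(X)
  expect_equal(invertStandardizer(stdX, applyStandardizer(stdX, X)), X,
               tolerance = 1e-10, ignore_attr = TRUE)
  # standardized fit rows have mean 0 and population SD 1
  Z <- applyStandardizer(stdX, X)
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1)), 1e-8)
  expect_error(applyStandardizer(list(), X), "fitted")
})
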