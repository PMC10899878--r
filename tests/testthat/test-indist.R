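test_that("kNN discriminability is at chance for identical distributions", {
  set.seed(61)
  real <- matrix(rnorm(500 * 54), 500)
  synth <- matrix(rnorm(500 * 54), 500)
  res <- knnDiscriminability(real, synth, seed = 62L)
  expect_gte(res$accuracyMean, 0.45)
  expect_lte(res$accuracyMean, 0.55)
  expect_equal(sum(res$confusion), 1000)     # conservation
})

test_that("kNN discriminability separates shifted clouds and is monotone in shift", {
  set.seed(63)
  base <- matrix(rnorm(200 * 54), 200)
  accs <- vapply(c(0, 1, 3, 10), function(shift) {
    knnDiscriminability(base, matrix(rnorm(200 * 54), 200) + shift,
                        seed = 64L)$accuracyMean
  }, numeric(1))
  expect_gte(accs[4], 0.99)
  expect_true(all(diff(accs) >= -0.02))      # non-decreasing up to CV noise
})

test_that("kNN guards: imbalance warns, oversized k errors", {
  set.seed(65)
  a <- matrix(rnorm(60 * 54), 60)
  b <- matrix(rnorm(30 * 54), 30)
  expect_warning(knnDiscriminability(a, b, seed = 1L), "imbalance")
  expect_error(suppressWarnings(
    knnDiscriminability(a[1:12, ], b[1:12, ], k = 30L, seed = 1L)), "k")
})

test_that("accuracy from a 2x2 confusion matrix is the diagonal fraction", {
  expect_equal(accuracyFromConfusion(matrix(c(160, 140, 147, 153), 2)),
               313 / 600)
  expect_equal(accuracyFromConfusion(matrix(c(562, 431, 234, 759), 2)),
               1321 / 1986)
  expect_equal(accuracyFromConfusion(matrix(c(50, 0, 0, 50), 2)), 1)
  # symmetric under transpose in this 2-class layout
  m <- matrix(c(10, 3, 7, 20), 2)
  expect_equal(accuracyFromConfusion(m), accuracyFromConfusion(t(m)))
  expect_error(accuracyFromConfusion(matrix(0, 2, 2)), "empty")
  expect_error(accuracyFromConfusion(matrix(1, 3, 3)), "2 x 2")
})

test_that("loose majority vote favours 'real' at exact ties", {
  r3 <- rbind(c("real", "real", "synthetic"),
              c("synthetic", "synthetic", "real"),
              c("synthetic", "synthetic", "synthetic"))
  v <- looseMajorityVote(r3)
  expect_equal(unname(v$labels), c("real", "synthetic", "synthetic"))
  expect_equal(sum(v$counts), 3L)
  # two raters, split vote, threshold 0.5 -> real (the loose rule)
  v2 <- looseMajorityVote(rbind(c("real", "synthetic")))
  expect_equal(unname(v2$labels), "real")
  # strict threshold above 0.5 flips the tie
  v3 <- looseMajorityVote(rbind(c("real", "synthetic")), threshold = 0.51)
  expect_equal(unname(v3$labels), "synthetic")
  expect_error(looseMajorityVote(rbind(c("real", "fake"))), "unknown")
})

test_that("Fleiss' kappa matches direct formula evaluation and its invariances", {
  # perfect agreement
  allAgree <- matrix("real", 10, 3)
  allAgree[6:10, ] <- "synthetic"
  expect_equal(fleissKappa(allAgree), 1)
  # hand-computable 4 items x 3 raters table, brute-force oracle
  tab <- rbind(c("a", "a", "b"),
               c("a", "b", "b"),
               c("b", "b", "b"),
               c("a", "a", "a"))
  counts <- cbind(a = rowSums(tab == "a"), b = rowSums(tab == "b"))
  Pi <- (rowSums(counts^2) - 3) / (3 * 2)
  p <- colSums(counts) / 12
  oracle <- (mean(Pi) - sum(p^2)) / (1 - sum(p^2))
  expect_equal(fleissKappa(tab), oracle)
  # invariance under category relabeling and item/rater permutation
  relab <- matrix(c(x = "x", y = "y")[match(tab, c("a", "b"))], 4)
  expect_equal(fleissKappa(relab), fleissKappa(tab))
  expect_equal(fleissKappa(tab[sample(4), ]), fleissKappa(tab))
  expect_equal(fleissKappa(tab[, c(2, 3, 1)]), fleissKappa(tab))
  # iid uniform votes give kappa near 0
  set.seed(66)
  ks <- replicate(20, fleissKappa(matrix(sample(c("real", "synthetic"),
                                                600 * 3, TRUE), 600)))
  expect_lt(abs(mean(ks)), 0.05)
  # degenerate: single category -> informative error, not NaN
  expect_error(fleissKappa(matrix("real", 5, 3)), "undefined")
})

test_that("node-wise SPM t equals the textbook pooled two-sample t", {
  set.seed(67)
  A <- matrix(rnorm(5 * 17), 5)
  B <- matrix(rnorm(4 * 17, mean = 0.5), 4)
  res <- spmUnpairedT1d(A, B, nPermutations = 200L, seed = 68L)
  oracle <- vapply(1:17, function(q) {
    unname(t.test(A[, q], B[, q], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(res$t, oracle, tolerance = 1e-10)
})

test_that("SPM handles identical groups, degenerate nodes and extreme effects", {
  set.seed(69)
  A <- matrix(rnorm(10 * 17), 10)
  same <- spmUnpairedT1d(A, A, nPermutations = 500L, seed = 70L)
  expect_equal(same$t, rep(0, 17))
  expect_false(same$significant)
  expect_equal(nrow(same$clusters), 0L)
  # constant identical node in both groups -> t = 0 there
  B <- matrix(rnorm(10 * 17), 10)
  A2 <- A; B2 <- B; A2[, 5] <- 1; B2[, 5] <- 1
  r2 <- spmUnpairedT1d(A2, B2, nPermutations = 500L, seed = 71L)
  expect_equal(r2$t[5], 0)
  # +50 shift at every node: all 17 nodes suprathreshold in one cluster
  C <- matrix(rnorm(20 * 17), 20)
  D <- matrix(rnorm(20 * 17), 20) + 50
  r3 <- spmUnpairedT1d(C, D, nPermutations = 1000L, seed = 72L)
  expect_true(r3$significant)
  expect_equal(r3$clusters$start, 1L)
  expect_equal(r3$clusters$end, 17L)
  expect_true(all(abs(r3$t) > r3$tstar))
})

test_that("critical threshold is non-increasing in alpha and above the pointwise one", {
  set.seed(73)
  A <- matrix(rnorm(15 * 17), 15)
  B <- matrix(rnorm(15 * 17), 15)
  ts <- vapply(c(0.01, 0.05, 0.2), function(a)
    spmUnpairedT1d(A, B, alpha = a, nPermutations = 1000L, seed = 74L)$tstar,
    numeric(1))
  expect_true(all(diff(ts) <= 0))
  # pointwise (single-node) permutation threshold at node 1 is not above t*
  r <- spmUnpairedT1d(A, B, alpha = 0.05, nPermutations = 1000L, seed = 74L)
  r1 <- spmUnpairedT1d(A[, 1, drop = FALSE], B[, 1, drop = FALSE],
                       alpha = 0.05, nPermutations = 1000L, seed = 74L)
  expect_gte(r$tstar, r1$tstar - 1e-9)
})

test_that("small groups trigger exhaustive enumeration of label assignments", {
  A <- matrix(rnorm(4 * 17), 4)
  B <- matrix(rnorm(4 * 17), 4)
  r <- spmUnpairedT1d(A, B, nPermutations = 1000L, seed = 1L)
  expect_true(r$exhaustive)
  expect_equal(r$nPermutations, choose(8, 4))
  # exhaustive null is seed-independent
  r2 <- spmUnpairedT1d(A, B, nPermutations = 1000L, seed = 999L)
  expect_identical(r$tstar, r2$tstar)
})

test_that("per-plane SPM uses one sample per subject and equal group sizes", {
  pe <- smallCohort(nSub = c(healthy_1 = 10), sessions = 3L)
  nSubj <- 10L
  synth <- postureMatrix(smallCohort(seed = 555, nSub = c(healthy_1 = 12),
                                     sessions = 3L))
  synthPe <- PostureExperiment(synth,
                               subjectId = sprintf("Y%03d", seq_len(nrow(synth))),
                               classLabel = rep("synthetic", nrow(synth)),
                               sessionIdx = rep(1L, nrow(synth)))
  res <- spmAllPlanes(pe, synthPe, nPermutations = 300L, seed = 5L)
  expect_named(res, c("sagittal", "coronal", "transverse"))
  for (r in res) {
    expect_equal(r$nA, nSubj)
    expect_equal(r$nB, nSubj)
  }
})

test_that("resampled real rows are not declared different from the real cohort", {
  ds <- processedCohort()
  hits <- vapply(1:6, function(i) {
    resampled <- withr::with_seed(300 + i, {
      pick <- sample.int(ncol(ds), 338L)
      PostureExperiment(postureMatrix(ds)[pick, ],
                        subjectId = sprintf("R%04d", seq_along(pick)),
                        classLabel = rep("synthetic", length(pick)),
                        sessionIdx = rep(1L, length(pick)))
    })
    res <- spmAllPlanes(ds, resampled, nPermutations = 300L, seed = 400 + i)
    any(vapply(res, `[[`, logical(1), "significant"))
  }, logical(1))
  # family-wise alpha 0.05 over 3 planes: more than half the seeds null
  expect_lte(sum(hits), 2L)
})

test_that("blinded rating sheet export withholds truth and the key recovers it", {
  pe <- smallCohort()
  synth <- postureMatrix(pe) + rnorm(length(postureMatrix(pe)))
  sheet <- withr::local_tempfile(fileext = ".csv")
  key <- withr::local_tempfile(fileext = ".csv")
  exportBlindedRatingSheet(pe, synth, nPerGroup = 8L, sheet, key, seed = 12L)
  blind <- read.csv(sheet, check.names = FALSE)
  expect_equal(nrow(blind), 16L)
  expect_false("truth" %in% names(blind))
  k <- read.csv(key)
  expect_equal(sort(table(k$truth), decreasing = TRUE),
               sort(table(c(rep("real", 8), rep("synthetic", 8))),
                    decreasing = TRUE), ignore_attr = TRUE)
  # rating table reader round trip
  ratings <- data.frame(item_id = k$item_id, truth = k$truth,
                        rater_1 = sample(c("real", "synthetic"), 16, TRUE),
                        rater_2 = sample(c("real", "synthetic"), 16, TRUE))
  rt <- withr::local_tempfile(fileext = ".csv")
  write.csv(ratings, rt, row.names = FALSE)
  tab <- readRatingTable(rt)
  expect_equal(dim(tab$ratings), c(16L, 2L))
  expect_equal(tab$truth, k$truth)
})
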