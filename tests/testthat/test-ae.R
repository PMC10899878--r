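test_that("scheme multipliers and training mixtures have the specified sizes", {
  expect_equal(schemeMultiplier("RTD"), 0L)
  expect_equal(schemeMultiplier("RTSD"), 1L)
  expect_equal(schemeMultiplier("RT3SD"), 3L)
  expect_error(schemeMultiplier("RT9SD"), "unknown scheme")
  set.seed(81)
  real <- matrix(rnorm(70 * 54), 70)
  vae <- trainVAE(real, NULL, tinyVaeConfig(epochs = 2L, seed = 1L))
  expect_equal(nrow(mixTrainingData(real, vae, "RTSD", seed = 2L)), 140L)
  m3 <- mixTrainingData(real, vae, "RT3SD", seed = 2L)
  expect_equal(nrow(m3), 280L)
  # RTD is the real rows up to order
  m0 <- mixTrainingData(real, vae, "RTD", seed = 2L)
  expect_equal(dim(m0), dim(real))
  expect_equal(m0[order(m0[, 1]), ], real[order(real[, 1]), ],
               ignore_attr = TRUE)
  # RT3SD contains every real row exactly once (25% of the mixture)
  inReal <- m3[, 1] %in% real[, 1]
  expect_equal(sum(inReal), 70L)
})

test_that("early stopping restores the best-validation weights", {
  set.seed(82)
  X <- matrix(rnorm(120 * 54), 120)
  val <- matrix(rnorm(30 * 54), 30)
  ae <- trainAutoencoder(X, val, tinyAeConfig(maxEpochs = 60L, seed = 3L))
  h <- ae$history
  expect_equal(ae$valMse, min(h$valMse))                 # exact contract
  expect_equal(ae$bestEpoch, which.min(h$valMse))
  expect_equal(reconstruct(ae, val)$mse, ae$valMse, tolerance = 1e-12)
  # stopping happened patience epochs after the best, or at the cap
  expect_true(nrow(h) == ae$bestEpoch + ae$config$earlyStoppingPatience ||
                nrow(h) == ae$config$maxEpochs)
})

test_that("early stopping halts quickly when validation can only worsen", {
  # validation from a different distribution + aggressive learning rate:
  # the first epochs overshoot and valMse deteriorates monotonically
  set.seed(83)
  X <- matrix(rnorm(40 * 54), 40)
  val <- matrix(rnorm(20 * 54, mean = 30), 20)
  ae <- trainAutoencoder(X, val, tinyAeConfig(maxEpochs = 500L,
                                              learningRate = 0.1, seed = 4L))
  expect_lt(nrow(ae$history), 500L)
  expect_equal(ae$valMse, min(ae$history$valMse))
})

test_that("the autoencoder drives noiseless low-rank data to near-zero error", {
  set.seed(84)
  n <- 700
  L <- matrix(rnorm(54 * 5), 54, 5)
  X <- matrix(rnorm(n * 5), n, 5) %*% t(L)
  X <- scale(X)[, ]
  tr <- X[1:500, ]; va <- X[501:600, ]; te <- X[601:700, ]
  ae <- trainAutoencoder(tr, va, aeConfig(latentDim = 15L, seed = 5L,
                                          learningRate = 0.002,
                                          earlyStoppingPatience = 20L))
  expect_lte(reconstruct(ae, te)$mse, 0.01)  # PCA at rank 5 would be exact
})

test_that("latent embedding export is deterministic with correct shape and rank", {
  set.seed(85)
  n <- 150
  L <- matrix(rnorm(54 * 4), 54, 4)
  X <- scale(matrix(rnorm(n * 4), n, 4) %*% t(L))[, ]
  ae <- trainAutoencoder(X, X, tinyAeConfig(latentDim = 8L, maxEpochs = 80L,
                                            seed = 6L))
  meta <- data.frame(class_label = rep(c("a", "b"), length.out = n))
  emb <- exportLatentEmbedding(ae, X, meta)
  expect_equal(nrow(emb), n)
  expect_named(emb, c(paste0("z", 1:8), "class_label"))
  expect_identical(emb, exportLatentEmbedding(ae, X, meta))
  # rank-4 data with latent 8: at least 4 substantial singular values
  sv <- svd(scale(as.matrix(emb[, 1:8]), scale = FALSE))$d
  expect_gte(sum(sv > 0.01 * sv[1]), 4L)
})

test_that("benchmark bookkeeping: rows per cell and recomputable summaries", {
  pe <- smallCohort(nSub = c(healthy_1 = 12), sessions = 4L)
  folds <- makeGroupedFolds(pe, k = 2L, seed = 7L)
  rep <- runAugmentationBenchmark(folds, pe, schemes = "RTD",
                                  latentDims = 3L,
                                  vaeCfg = tinyVaeConfig(),
                                  aeCfg = tinyAeConfig(), seed = 8L)
  res <- rep$results
  expect_equal(nrow(res), 2L * 1L * 1L * 2L)  # folds x schemes x dims x splits
  expect_true(all(res$mse >= 0))
  # mean row equals the arithmetic mean of the fold rows
  for (sp in c("train", "test")) {
    m <- rep$summary$mean[rep$summary$split == sp]
    expect_equal(m, mean(res$mse[res$split == sp]), tolerance = 1e-12)
  }
})

test_that("the dim x scheme sweep produces a full grid", {
  pe <- smallCohort(nSub = c(healthy_1 = 12), sessions = 4L)
  folds <- makeGroupedFolds(pe, k = 2L, seed = 9L)
  rep <- latentDimSweep(folds, pe, dims = c(5L, 3L),
                        schemes = c("RTD", "RTSD", "RT3SD"),
                        vaeCfg = tinyVaeConfig(), aeCfg = tinyAeConfig(),
                        foldIndices = 1L, seed = 10L)
  cells <- unique(rep$results[, c("scheme", "latent_dim")])
  expect_equal(nrow(cells), 6L)               # 3 schemes x 2 dims
  path <- withr::local_tempfile(fileext = ".csv")
  writeReport(rep, csvPath = path)
  expect_equal(nrow(read.csv(path)), nrow(rep$results))
})

test_that("subject leakage between train and test aborts the benchmark", {
  pe <- smallCohort(nSub = c(healthy_1 = 6), sessions = 3L)
  folds <- makeGroupedFolds(pe, k = 2L, seed = 11L)
  folds$folds[[1]]$train <- c(folds$folds[[1]]$train, folds$folds[[1]]$test[1])
  expect_error(runAugmentationBenchmark(folds, pe, schemes = "RTD",
                                        latentDims = 3L,
                                        vaeCfg = tinyVaeConfig(),
                                        aeCfg = tinyAeConfig()),
               "leakage")
})
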