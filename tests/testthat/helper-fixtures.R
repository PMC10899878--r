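# Shared fixtures, built in code. The small cohort keeps module tests fast;
# the processed study-scale cohort is built once and reused by the heavier
# acceptance checks.

smallCohort <- function(seed = 101L, nSub = c(healthy_1 = 6, back_pain = 4),
                        sessions = 4L) {
  simulateCohort(cohortConfig(classSizes = nSub, sessionsPerSubject = sessions,
                              seed = seed))
}

# memoised default-scale cohort after session selection + outlier removal
processedCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pe <- simulateCohort()
      sel <- selectSessionsPerSubject(pe, 3L, seed = 1L)
      cache <<- removeOutliers(sel, contamination = 66 / ncol(sel),
                               seed = 2L)$dataset
    }
    cache
  }
})

# memoised fold-1 matrices and VAE on the processed cohort (shared between
# the generative-quality and indistinguishability checks)
trainedFoldVAE <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- processedCohort()
      folds <- makeGroupedFolds(ds, seed = 3L)
      fm <- postureVAE:::foldMatrices(ds, folds$folds[[1]])
      vae <- trainVAE(fm$train, fm$val, vaeConfig(seed = 42L))
      cache <<- list(dataset = ds, folds = folds, fm = fm, vae = vae)
    }
    cache
  }
})

# memoised 10-replicate data-scarce benchmark (RTD/RTSD x dims 15/7),
# shared by the augmentation-benefit and latent-compression checks
augmentationReplicatesCached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- augmentationReplicates(processedCohort(), nReplicates = 10L,
                                       nTrainRows = 150L,
                                       schemes = c("RTD", "RTSD"),
                                       dims = c(15L, 7L), seed = 1L)
    cache
  }
})

# tiny VAE/AE configs for contract tests where model quality is irrelevant
tinyVaeConfig <- function(...) {
  args <- utils::modifyList(list(hiddenDims = c(16L, 8L), latentDim = 3L,
                                 epochs = 5L, batchSize = 16L), list(...))
  do.call(vaeConfig, args)
}
tinyAeConfig <- function(...) {
  args <- utils::modifyList(list(encoderHidden = c(16L, 8L), latentDim = 3L,
                                 maxEpochs = 30L, batchSize = 16L), list(...))
  do.call(aeConfig, args)
}
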