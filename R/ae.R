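#' Deep autoencoder configuration
#'
#' Defaults give the benchmark architecture: a 54-input encoder with three
#' ReLU hidden layers (500, 250, 50) and a linear bottleneck, mirrored by a
#' symmetric decoder with a linear output layer, trained with Adam
#' (learning rate 0.001, batch size 64) under early stopping (patience 10,
#' at most 1000 epochs, best-validation weights restored).
#'
#' @param inputDim input feature count (54).
#' @param encoderHidden encoder hidden widths; decoder mirrors them.
#' @param latentDim bottleneck dimension (default 15; 7 in the compression
#'   sweep).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param earlyStoppingPatience epochs without validation improvement
#'   before stopping.
#' @param seed integer seed.
#' @return a list of class \code{aeConfig}.
#' @export
aeConfig <- function(inputDim = 54L, encoderHidden = c(500L, 250L, 50L),
                     latentDim = 15L, learningRate = 0.001, batchSize = 64L,
                     maxEpochs = 1000L, earlyStoppingPatience = 10L,
                     seed = 1L) {
  if (latentDim < 1L) fail("'latentDim' must be >= 1")
  if (any(c(inputDim, encoderHidden, batchSize, maxEpochs) <= 0))
    fail("all sizes must be positive")
  structure(list(inputDim = as.integer(inputDim),
                 encoderHidden = as.integer(encoderHidden),
                 latentDim = as.integer(latentDim),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 earlyStoppingPatience = as.integer(earlyStoppingPatience),
                 seed = as.integer(seed)),
            class = "aeConfig")
}

#' Augmentation schemes: real / synthetic training mixtures
#'
#' \code{RTD} trains on real data only; \code{RTSD} adds synthetic rows
#' equal in number to the real rows (50/50); \code{RT3SD} adds three times
#' as many (25/75).
#'
#' @param scheme one of \code{"RTD"}, \code{"RTSD"}, \code{"RT3SD"}.
#' @return the synthetic-to-real multiplier (0, 1 or 3).
#' @export
schemeMultiplier <- function(scheme) {
  mult <- c(RTD = 0L, RTSD = 1L, RT3SD = 3L)
  if (!scheme %in% names(mult)) fail("unknown scheme: ", scheme)
  mult[[scheme]]
}

#' Build an augmented training matrix for one scheme
#'
#' Generates \code{multiplier * nrow(realTrain)} synthetic rows from the
#' VAE (in the same scaled space as the real rows), appends them to the
#' real rows and shuffles the order.
#'
#' @param realTrain standardized real training rows.
#' @param vae a \code{trainedVAE} fitted on the same scaled space.
#' @param scheme \code{"RTD"}, \code{"RTSD"} or \code{"RT3SD"}.
#' @param seed integer seed (sampling and shuffling).
#' @return the mixed training matrix.
#' @export
mixTrainingData <- function(realTrain, vae, scheme, seed = NULL) {
  realTrain <- as.matrix(realTrain)
  if (nrow(realTrain) < 1L) fail("'realTrain' must be non-empty")
  m <- schemeMultiplier(scheme)
  withSeed(seed, {
    out <- if (m == 0L) realTrain else {
      syn <- sampleSynthetic(vae, m * nrow(realTrain),
                             seed = sample.int(.Machine$integer.max, 1L))
      rbind(realTrain, syn)
    }
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Train a deep autoencoder with early stopping
#'
#' Minimizes the mean squared reconstruction error with minibatch Adam.
#' Validation MSE is evaluated after every epoch; training stops once it
#' has not improved for \code{earlyStoppingPatience} consecutive epochs (or
#' at \code{maxEpochs}) and the weights of the best-validation epoch are
#' restored.
#'
#' @param train standardized training matrix (possibly an augmented
#'   mixture).
#' @param val standardized validation matrix (real rows only).
#' @param config an \code{\link{aeConfig}}.
#' @return an object of class \code{trainedAE} with the encoder/decoder
#'   weights of the best epoch, \code{history} (per-epoch train/val MSE),
#'   \code{valMse} (the restored minimum) and \code{bestEpoch}.
#' @export
trainAutoencoder <- function(train, val, config = aeConfig()) {
  train <- as.matrix(train); val <- as.matrix(val)
  d <- config$inputDim
  if (ncol(train) != d || ncol(val) != d) fail("column count must be ", d)
  if (nrow(val) == 0L) fail("early stopping needs a non-empty validation set")
  hid <- config$encoderHidden; L <- config$latentDim
  withSeed(config$seed, {
    # linear activations at the bottleneck and the output, ReLU elsewhere
    enc <- nnInit(c(d, hid, L), c(rep("relu", length(hid)), "linear"))
    dec <- nnInit(c(L, rev(hid), d), c(rep("relu", length(hid)), "linear"))
    states <- list(adamInit(enc), adamInit(dec))
    step <- 0L
    best <- list(val = Inf, enc = enc, dec = dec, epoch = 0L)
    sinceBest <- 0L
    hist <- list()
    for (epoch in seq_len(config$maxEpochs)) {
      batches <- miniBatches(nrow(train), config$batchSize)
      eLoss <- 0
      for (bi in seq_along(batches)) {
        X <- train[batches[[bi]], , drop = FALSE]
        B <- nrow(X)
        ef <- nnForward(enc, X)
        df <- nnForward(dec, ef$out)
        Xhat <- df$out
        loss <- mean((X - Xhat)^2)
        if (!is.finite(loss)) fail("non-finite AE loss at epoch ", epoch)
        eLoss <- eLoss + loss * B
        dXhat <- 2 * (Xhat - X) / (B * d)
        db <- nnBackward(dec, df$caches, dXhat)
        eb <- nnBackward(enc, ef$caches, db$dInput)
        step <- step + 1L
        upd <- adamStep(list(enc, dec), states, list(eb$grads, db$grads),
                        step, config$learningRate)
        enc <- upd$stacks[[1]]; dec <- upd$stacks[[2]]
        states <- upd$states
      }
      valMse <- mean((val - nnForward(dec, nnForward(enc, val)$out)$out)^2)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainMse = eLoss / nrow(train),
                                  valMse = valMse)
      if (valMse < best$val) {
        best <- list(val = valMse, enc = enc, dec = dec, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$earlyStoppingPatience) break
      }
    }
    structure(list(enc = best$enc, dec = best$dec, config = config,
                   history = do.call(rbind, hist), valMse = best$val,
                   bestEpoch = best$epoch),
              class = "trainedAE")
  })
}

#' @export
print.trainedAE <- function(x, ...) {
  cfg <- x$config
  cat("trainedAE:", cfg$inputDim, "->",
      paste(cfg$encoderHidden, collapse = " -> "), "-> latent",
      cfg$latentDim, "\n")
  cat(sprintf("  stopped after %d epochs (best epoch %d, val MSE %.4f)\n",
              nrow(x$history), x$bestEpoch, x$valMse))
  invisible(x)
}

#' @export
reconstruct.trainedAE <- function(model, rows) {
  rows <- as.matrix(rows)
  if (ncol(rows) != model$config$inputDim) fail("column count mismatch")
  xhat <- nnForward(model$dec, nnForward(model$enc, rows)$out)$out
  list(xhat = xhat, mse = mean((rows - xhat)^2))
}

#' Encode rows into the bottleneck space, with metadata
#'
#' Deterministic encoder pass used for latent-space exports (e.g. for a
#' downstream UMAP projection, which is deliberately left to external
#' tools).
#'
#' @param model a \code{trainedAE} or \code{trainedVAE} (the VAE uses its
#'   posterior mean).
#' @param rows standardized matrix.
#' @param metadata optional data frame (one row per sample) to bind.
#' @return data frame with latent coordinate columns \code{z1...zL} plus
#'   the metadata columns.
#' @export
exportLatentEmbedding <- function(model, rows, metadata = NULL) {
  rows <- as.matrix(rows)
  Z <- if (inherits(model, "trainedVAE")) vaeEncode(model, rows)$mu
       else nnForward(model$enc, rows)$out
  out <- as.data.frame(Z)
  names(out) <- paste0("z", seq_len(ncol(Z)))
  if (!is.null(metadata)) {
    if (nrow(metadata) != nrow(out)) fail("metadata row count mismatch")
    out <- cbind(out, metadata)
  }
  out
}

## ---- benchmark orchestration ------------------------------------------

#' Cross-validated augmentation benchmark for the autoencoder
#'
#' For each fold: fits the standardizer on the fold's real training rows,
#' trains a fold-specific VAE on them, builds each scheme's training
#' mixture, trains the autoencoder per scheme x latent dimension, and
#' records MSE on the real training rows (a common reference across
#' schemes) and on the real test rows. Aborts if any test subject leaks
#' into a training partition.
#'
#' @param folds a \code{foldAssignment}.
#' @param dataset a \linkS4class{PostureExperiment}.
#' @param schemes character vector of schemes (default all three).
#' @param latentDims autoencoder bottleneck sizes to cross (default 15).
#' @param vaeCfg \code{\link{vaeConfig}} for the per-fold VAEs.
#' @param aeCfg \code{\link{aeConfig}} template (latent dim overridden per
#'   cell).
#' @param nTrainRows optional subsample size of real training rows (the
#'   data-scarce regime); \code{NULL} uses all.
#' @param foldIndices folds to run (default all).
#' @param seed integer seed.
#' @return an object of class \code{experimentReport}: a long data frame
#'   \code{results} with columns \code{fold}, \code{scheme},
#'   \code{latent_dim}, \code{split} (\code{train}/\code{test}) and
#'   \code{mse}, plus a \code{summary} of means/SDs across folds.
#' @export
runAugmentationBenchmark <- function(folds, dataset,
                                     schemes = c("RTD", "RTSD", "RT3SD"),
                                     latentDims = 15L,
                                     vaeCfg = vaeConfig(),
                                     aeCfg = aeConfig(),
                                     nTrainRows = NULL,
                                     foldIndices = seq_len(folds$k),
                                     seed = 1L) {
  invisible(vapply(schemes, schemeMultiplier, integer(1)))
  rows <- list()
  for (f in foldIndices) {
    fold <- folds$folds[[f]]
    if (length(intersect(fold$test, c(fold$train, fold$val))))
      fail("subject leakage detected in fold ", f)
    fm <- foldMatrices(dataset, fold)
    tr <- fm$train
    if (!is.null(nTrainRows) && nTrainRows < nrow(tr)) {
      pick <- withSeed(deriveSeed(seed, paste0("subsample_f", f)),
                       sample.int(nrow(tr), nTrainRows))
      tr <- tr[pick, , drop = FALSE]
      # refit scaling on the rows the models actually see
      std <- fitStandardizer(invertStandardizer(fm$std, tr))
      tr <- applyStandardizer(std, invertStandardizer(fm$std, tr))
      fm$val <- applyStandardizer(std, invertStandardizer(fm$std, fm$val))
      fm$test <- applyStandardizer(std, invertStandardizer(fm$std, fm$test))
    }
    vCfg <- vaeCfg; vCfg$seed <- deriveSeed(seed, paste0("vae_f", f))
    vae <- trainVAE(tr, fm$val, vCfg)
    for (dim in latentDims) {
      for (scheme in schemes) {
        mix <- mixTrainingData(tr, vae, scheme,
                               seed = deriveSeed(seed, paste0("mix_f", f, "_",
                                                              scheme, "_", dim)))
        cfg <- aeCfg
        cfg$latentDim <- as.integer(dim)
        cfg$seed <- deriveSeed(seed, paste0("ae_f", f, "_", scheme, "_", dim))
        ae <- trainAutoencoder(mix, fm$val, cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, scheme = scheme, latent_dim = dim,
          split = c("train", "test"),
          mse = c(reconstruct(ae, tr)$mse, reconstruct(ae, fm$test)$mse))
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarizeReport(results)),
            class = "experimentReport")
}

# mean/SD across folds per scheme x latent_dim x split
summarizeReport <- function(results) {
  agg <- stats::aggregate(mse ~ scheme + latent_dim + split, results,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(agg[, c("scheme", "latent_dim", "split")],
                    mean = agg$mse[, "mean"], sd = agg$mse[, "sd"])
  out[order(out$latent_dim, out$scheme, out$split), ]
}

#' @export
print.experimentReport <- function(x, ...) {
  cat("experimentReport:", length(unique(x$results$fold)), "fold(s)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross schemes with a set of bottleneck dimensions
#'
#' Convenience wrapper for the latent-compression question: run the
#' augmentation benchmark over every combination of scheme and latent
#' dimension (e.g. 15 vs 7).
#'
#' @inheritParams runAugmentationBenchmark
#' @param dims latent dimensions (default \code{c(15, 7)}).
#' @return an \code{experimentReport}.
#' @export
latentDimSweep <- function(folds, dataset, dims = c(15L, 7L),
                           schemes = c("RTD", "RTSD", "RT3SD"), ...) {
  runAugmentationBenchmark(folds, dataset, schemes = schemes,
                           latentDims = dims, ...)
}

#' Write an experiment report to CSV / JSON
#'
#' @param report an \code{experimentReport}.
#' @param csvPath,jsonPath output paths (\code{NULL} skips).
#' @return invisibly, the report.
#' @export
writeReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report$results, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(results = report$results,
                              summary = report$summary),
                         jsonPath, dataframe = "rows", digits = NA)
  invisible(report)
}

#' Replicated data-scarce augmentation comparison
#'
#' The package's replicated test of the augmentation-benefit and
#' latent-compression claims: each replicate draws its own subject-grouped
#' 5-fold split of the cohort, subsamples the first fold's real training
#' rows to \code{nTrainRows}, trains the fold's VAE and one autoencoder per
#' scheme x latent dimension, and records real-test-set MSE. Replicates
#' differ in every random ingredient (split, subsample, weights,
#' synthetic draws) through seeds derived from \code{seed}.
#'
#' @param dataset a \linkS4class{PostureExperiment} (default cohort scale).
#' @param nReplicates number of replicates (default 10).
#' @param nTrainRows real training rows per replicate (default 150, the
#'   data-scarce regime).
#' @param schemes schemes to compare.
#' @param dims latent dimensions to compare.
#' @param vaeCfg,aeCfg model configurations.
#' @param seed integer seed.
#' @return data frame with one row per replicate x scheme x dim:
#'   \code{replicate}, \code{scheme}, \code{latent_dim}, \code{testMse}.
#' @export
augmentationReplicates <- function(dataset, nReplicates = 10L,
                                   nTrainRows = 150L,
                                   schemes = c("RTD", "RTSD"),
                                   dims = 15L,
                                   vaeCfg = vaeConfig(),
                                   aeCfg = aeConfig(),
                                   seed = 1L) {
  out <- list()
  for (r in seq_len(nReplicates)) {
    rSeed <- deriveSeed(seed, paste0("replicate_", r))
    folds <- makeGroupedFolds(dataset, k = 5L,
                              seed = deriveSeed(rSeed, "folds"))
    rep <- runAugmentationBenchmark(folds, dataset, schemes = schemes,
                                    latentDims = dims, vaeCfg = vaeCfg,
                                    aeCfg = aeCfg, nTrainRows = nTrainRows,
                                    foldIndices = 1L, seed = rSeed)
    res <- rep$results
    res <- res[res$split == "test", c("scheme", "latent_dim", "mse")]
    res$replicate <- r
    out[[r]] <- data.frame(replicate = res$replicate, scheme = res$scheme,
                           latent_dim = res$latent_dim, testMse = res$mse)
  }
  do.call(rbind, out)
}
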