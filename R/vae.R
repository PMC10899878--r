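#' Variational autoencoder configuration
#'
#' Defaults reproduce the generative architecture used throughout the
#' package's analyses: a 54-input encoder with two ReLU hidden layers (256,
#' 108) feeding a 15-dimensional Gaussian latent space, a symmetric decoder
#' with a linear output layer, and Adam optimization (learning rate 0.001,
#' batch size 128, 400 epochs, no early stopping).
#'
#' @param inputDim input feature count (54).
#' @param hiddenDims encoder hidden layer widths; decoder mirrors them.
#' @param latentDim latent dimension (must be below \code{inputDim}).
#' @param epochs training epochs (fixed; the VAE does not early-stop).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param klWeight weight on the KL term; 1 gives the plain ELBO.
#' @param lvBiasInit initial bias of the log-variance head. A negative
#'   value starts the posterior tight so early epochs are dominated by
#'   reconstruction learning; the KL term then widens the posterior to its
#'   equilibrium.
#' @param seed integer seed for weight init, shuffling and sampling.
#' @return a list of class \code{vaeConfig}.
#' @export
vaeConfig <- function(inputDim = 54L, hiddenDims = c(256L, 108L),
                      latentDim = 15L, epochs = 400L, learningRate = 0.001,
                      batchSize = 128L, klWeight = 1.0, lvBiasInit = 0,
                      seed = 1L) {
  if (latentDim >= inputDim) fail("'latentDim' must be below 'inputDim'")
  if (any(c(inputDim, hiddenDims, latentDim, epochs, batchSize) <= 0))
    fail("all sizes must be positive")
  structure(list(inputDim = as.integer(inputDim),
                 hiddenDims = as.integer(hiddenDims),
                 latentDim = as.integer(latentDim),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 klWeight = klWeight, lvBiasInit = lvBiasInit,
                 seed = as.integer(seed)),
            class = "vaeConfig")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form for \eqn{KL(N(\mu, diag(\sigma^2)) \| N(0, I)) =
#' \frac{1}{2}\sum_i (\mu_i^2 + \sigma_i^2 - 1 - \log\sigma_i^2)}, the
#' regularizer that keeps the encoder's posterior close to the latent
#' prior.
#'
#' @param mu numeric vector of posterior means.
#' @param logVar numeric vector of posterior log-variances (same length).
#' @return a non-negative scalar.
#' @export
#' @examples
#' klDivergenceDiagGaussian(0, 0)          # 0: posterior equals prior
#' klDivergenceDiagGaussian(1, 0)          # 0.5
#' klDivergenceDiagGaussian(0, log(2))     # 0.5 * (2 - 1 - log 2)
klDivergenceDiagGaussian <- function(mu, logVar) {
  if (length(mu) != length(logVar)) fail("'mu' and 'logVar' lengths differ")
  if (!all(is.finite(mu)) || !all(is.finite(logVar)))
    fail("non-finite input to KL divergence")
  0.5 * sum(mu^2 + exp(logVar) - 1 - logVar)
}

# encoder forward to (mu, logVar); logVar soft-clamped for stability
vaeEncode <- function(model, X) {
  h <- nnForward(model$enc, X)
  mu <- h$out %*% model$muW + matrix(model$mub, nrow(X), length(model$mub),
                                     byrow = TRUE)
  lv <- h$out %*% model$lvW + matrix(model$lvb, nrow(X), length(model$lvb),
                                     byrow = TRUE)
  lv <- pmin(pmax(lv, -10), 10)
  list(mu = mu, logVar = lv, encCache = h)
}

vaeDecode <- function(model, Z) nnForward(model$dec, Z)$out

# per-batch loss pieces. The optimized objective is the negative ELBO of a
# unit-variance Gaussian likelihood: squared error summed over features
# (averaged over the batch) plus klWeight times the KL term (averaged over
# the batch, summed over latent dims). `recon` is reported as per-entry MSE;
# `total` is the optimized objective. Averaging the reconstruction over
# features as well would rescale the effective KL weight by the feature
# count and collapse the posterior.
vaeBatchLoss <- function(X, Xhat, mu, lv, klWeight) {
  recon <- mean((X - Xhat)^2)
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
  list(recon = recon, kl = kl,
       total = ncol(X) * recon + klWeight * kl)
}

#' Train a variational autoencoder on standardized posture rows
#'
#' Maximizes the evidence lower bound of a unit-variance Gaussian
#' observation model: the squared reconstruction error summed over the 54
#' features plus \code{klWeight} times the KL divergence of the
#' diagonal-Gaussian posterior from the standard-normal prior, minimized by
#' minibatch Adam with the reparameterization trick
#' \eqn{z = \mu + \sigma \odot \epsilon}. Reported reconstruction errors
#' are always per-entry MSE (scaled units). Runs the
#' configured number of epochs; the per-epoch loss breakdown on the
#' training stream and a deterministic (posterior-mean) evaluation on the
#' validation rows are recorded in \code{history}.
#'
#' @param train numeric matrix of standardized training rows (n x 54).
#' @param val numeric matrix of standardized validation rows.
#' @param config a \code{\link{vaeConfig}}.
#' @return an object of class \code{trainedVAE}: encoder/decoder weights,
#'   the config, and a per-epoch \code{history} data frame with columns
#'   \code{trainRecon}, \code{trainKl}, \code{trainTotal}, \code{valRecon},
#'   \code{valKl}, \code{valTotal}.
#' @export
trainVAE <- function(train, val = NULL, config = vaeConfig()) {
  train <- as.matrix(train)
  if (ncol(train) != config$inputDim)
    fail("'train' must have ", config$inputDim, " columns")
  if (!is.null(val)) {
    val <- as.matrix(val)
    if (ncol(val) != config$inputDim) fail("'val' column count mismatch")
  }
  d <- config$inputDim; L <- config$latentDim; hid <- config$hiddenDims
  withSeed(config$seed, {
    lastHid <- hid[length(hid)]
    enc <- nnInit(c(d, hid), rep("relu", length(hid)))
    lim <- sqrt(6 / lastHid)
    model <- list(enc = enc,
                  muW = matrix(stats::runif(lastHid * L, -lim, lim), lastHid, L),
                  mub = numeric(L),
                  lvW = matrix(stats::runif(lastHid * L, -lim, lim), lastHid, L),
                  lvb = rep(config$lvBiasInit, L),
                  dec = nnInit(c(L, rev(hid), d),
                               c(rep("relu", length(hid)), "linear")),
                  config = config)
    # Adam state: encoder stack, decoder stack, and the two heads (as 1-layer stacks)
    heads <- list(list(W = model$muW, b = model$mub, act = "linear"),
                  list(W = model$lvW, b = model$lvb, act = "linear"))
    states <- list(adamInit(model$enc), adamInit(model$dec), adamInit(heads))
    step <- 0L
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      batches <- miniBatches(nrow(train), config$batchSize)
      eR <- eK <- 0
      for (bi in seq_along(batches)) {
        X <- train[batches[[bi]], , drop = FALSE]
        B <- nrow(X)
        e <- vaeEncode(model, X)
        eps <- matrix(stats::rnorm(B * L), B, L)
        sigma <- exp(0.5 * e$logVar)
        Z <- e$mu + sigma * eps
        decFwd <- nnForward(model$dec, Z)
        Xhat <- decFwd$out
        ls <- vaeBatchLoss(X, Xhat, e$mu, e$logVar, config$klWeight)
        if (!is.finite(ls$total))
          fail("non-finite VAE loss at epoch ", epoch)
        eR <- eR + ls$recon * B; eK <- eK + ls$kl * B

        # gradients: reconstruction into the decoder, then through z into
        # both posterior heads; KL adds its closed-form terms directly
        dXhat <- 2 * (Xhat - X) / B
        decBack <- nnBackward(model$dec, decFwd$caches, dXhat)
        dZ <- decBack$dInput
        kw <- config$klWeight
        dMu <- dZ + kw * e$mu / B
        dLv <- dZ * (0.5 * sigma * eps) + kw * 0.5 * (exp(e$logVar) - 1) / B
        H <- e$encCache$out
        headGrads <- list(list(W = crossprod(H, dMu), b = colSums(dMu)),
                          list(W = crossprod(H, dLv), b = colSums(dLv)))
        dH <- dMu %*% t(model$muW) + dLv %*% t(model$lvW)
        encBack <- nnBackward(model$enc, e$encCache$caches, dH)
        step <- step + 1L
        heads <- list(list(W = model$muW, b = model$mub, act = "linear"),
                      list(W = model$lvW, b = model$lvb, act = "linear"))
        upd <- adamStep(list(model$enc, model$dec, heads), states,
                        list(encBack$grads, decBack$grads, headGrads),
                        step, config$learningRate)
        model$enc <- upd$stacks[[1]]
        model$dec <- upd$stacks[[2]]
        model$muW <- upd$stacks[[3]][[1]]$W; model$mub <- upd$stacks[[3]][[1]]$b
        model$lvW <- upd$stacks[[3]][[2]]$W; model$lvb <- upd$stacks[[3]][[2]]$b
        states <- upd$states
      }
      n <- nrow(train)
      row <- data.frame(epoch = epoch, trainRecon = eR / n, trainKl = eK / n,
                        trainTotal = d * eR / n + config$klWeight * eK / n,
                        valRecon = NA_real_, valKl = NA_real_,
                        valTotal = NA_real_)
      if (!is.null(val) && nrow(val) > 0) {
        ev <- vaeEncode(model, val)
        vhat <- vaeDecode(model, ev$mu)          # deterministic evaluation
        vl <- vaeBatchLoss(val, vhat, ev$mu, ev$logVar, config$klWeight)
        row$valRecon <- vl$recon; row$valKl <- vl$kl; row$valTotal <- vl$total
      }
      hist[[epoch]] <- row
    }
    model$history <- do.call(rbind, hist)
    class(model) <- "trainedVAE"
    model
  })
}

#' @export
print.trainedVAE <- function(x, ...) {
  cfg <- x$config
  cat("trainedVAE:", cfg$inputDim, "->",
      paste(cfg$hiddenDims, collapse = " -> "), "-> latent", cfg$latentDim, "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs; final train recon %.4f, KL %.4f\n",
              nrow(x$history), last$trainRecon, last$trainKl))
  invisible(x)
}

#' Deterministic reconstruction and its mean squared error
#'
#' Passes rows through the encoder and decodes the posterior mean (no
#' latent sampling), so repeated calls give identical results — the
#' evaluation path used for all reported reconstruction errors.
#'
#' @param model a \code{trainedVAE}.
#' @param rows standardized matrix to reconstruct.
#' @return a list with \code{xhat} (matrix) and \code{mse} (mean over all
#'   entries of the squared error, scaled units).
#' @export
reconstruct <- function(model, rows) {
  UseMethod("reconstruct")
}

#' @export
reconstruct.trainedVAE <- function(model, rows) {
  rows <- as.matrix(rows)
  if (ncol(rows) != model$config$inputDim) fail("column count mismatch")
  e <- vaeEncode(model, rows)
  xhat <- vaeDecode(model, e$mu)
  list(xhat = xhat, mse = mean((rows - xhat)^2))
}

#' Generate synthetic posture samples from the latent prior
#'
#' Draws \code{n} latent vectors from the standard normal prior and decodes
#' them. Without a standardizer the rows are in the scaled training space;
#' with one they are inverted back to degrees so synthetic samples are
#' directly comparable with (and presentable alongside) real measurements.
#'
#' @param model a \code{trainedVAE}.
#' @param n number of samples (>= 0).
#' @param seed integer seed.
#' @param standardizer optional \code{postureStandardizer} used to invert
#'   the scaling.
#' @return an \code{n x inputDim} numeric matrix.
#' @export
sampleSynthetic <- function(model, n, seed = NULL, standardizer = NULL) {
  if (n < 0) fail("'n' must be non-negative")
  L <- model$config$latentDim
  d <- model$config$inputDim
  if (n == 0) return(matrix(numeric(0), 0L, d))
  Z <- withSeed(seed, matrix(stats::rnorm(n * L), n, L))
  out <- vaeDecode(model, Z)
  if (!is.null(standardizer)) out <- invertStandardizer(standardizer, out)
  out
}

#' Save / load a trained VAE as portable JSON
#'
#' Weights, biases and the config are written as one JSON document (plain
#' text, full double precision), so models survive across sessions and
#' platforms without binary artifacts.
#'
#' @param model a \code{trainedVAE}.
#' @param path file path.
#' @return \code{loadVAE}: the restored \code{trainedVAE} (without training
#'   history).
#' @export
saveVAE <- function(model, path) {
  ser <- list(config = unclass(model$config),
              enc = lapply(model$enc, function(l)
                list(W = l$W, b = l$b, act = l$act)),
              dec = lapply(model$dec, function(l)
                list(W = l$W, b = l$b, act = l$act)),
              muW = model$muW, mub = model$mub,
              lvW = model$lvW, lvb = model$lvb)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveVAE
#' @export
loadVAE <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(c("inputDim", "hiddenDims", "latentDim", "epochs",
                      "learningRate", "batchSize", "klWeight", "lvBiasInit",
                      "seed"), names(ser$config))
  cfg <- do.call(vaeConfig, ser$config[keep])
  fixStack <- function(st) lapply(seq_len(nrow(st)), function(i)
    list(W = st$W[[i]], b = as.numeric(st$b[[i]]), act = st$act[[i]]))
  # jsonlite may simplify the stack to a data frame or keep it a list
  enc <- if (is.data.frame(ser$enc)) fixStack(ser$enc) else
    lapply(ser$enc, function(l) list(W = as.matrix(l$W), b = as.numeric(l$b),
                                     act = l$act))
  dec <- if (is.data.frame(ser$dec)) fixStack(ser$dec) else
    lapply(ser$dec, function(l) list(W = as.matrix(l$W), b = as.numeric(l$b),
                                     act = l$act))
  model <- list(enc = enc, dec = dec,
                muW = as.matrix(ser$muW), mub = as.numeric(ser$mub),
                lvW = as.matrix(ser$lvW), lvb = as.numeric(ser$lvb),
                config = cfg, history = NULL)
  class(model) <- "trainedVAE"
  model
}
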