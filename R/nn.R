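## Minimal dense-network engine: stacks of fully connected layers with ReLU
## or linear activations, reverse-mode gradients, and an Adam optimizer.
## Sized for 54-feature posture tables; all heavy lifting is BLAS matmuls.

# He-uniform initialization; weights drawn from the current RNG stream
nnInit <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1L)
  lapply(seq_along(acts), function(i) {
    fanIn <- sizes[i]
    lim <- sqrt(6 / fanIn)
    list(W = matrix(stats::runif(fanIn * sizes[i + 1L], -lim, lim),
                    fanIn, sizes[i + 1L]),
         b = numeric(sizes[i + 1L]),
         act = acts[i])
  })
}

# forward pass; returns output and per-layer caches for backprop
nnForward <- function(layers, X) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    Z <- H %*% ly$W + matrix(ly$b, nrow(H), length(ly$b), byrow = TRUE)
    A <- if (ly$act == "relu") pmax(Z, 0) else Z
    caches[[i]] <- list(input = H, Z = Z)
    H <- A
  }
  list(out = H, caches = caches)
}

# backward pass from gradient dOut at the stack output;
# returns per-layer W/b gradients plus the gradient at the stack input
nnBackward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    dZ <- if (ly$act == "relu") dA * (caches[[i]]$Z > 0) else dA
    grads[[i]] <- list(W = crossprod(caches[[i]]$input, dZ),
                       b = colSums(dZ))
    dA <- dZ %*% t(ly$W)
  }
  list(grads = grads, dInput = dA)
}

adamInit <- function(layers) {
  lapply(layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

# one Adam update over a list of layer stacks (modified in place by value);
# `states` parallels `stacks`, `gradsList` parallels both. t is the step.
adamStep <- function(stacks, states, gradsList, t, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (s in seq_along(stacks)) {
    for (i in seq_along(stacks[[s]])) {
      g <- gradsList[[s]][[i]]
      st <- states[[s]][[i]]
      st$mW <- beta1 * st$mW + (1 - beta1) * g$W
      st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
      st$mb <- beta1 * st$mb + (1 - beta1) * g$b
      st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
      stacks[[s]][[i]]$W <- stacks[[s]][[i]]$W -
        lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
      stacks[[s]][[i]]$b <- stacks[[s]][[i]]$b -
        lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
      states[[s]][[i]] <- st
    }
  }
  list(stacks = stacks, states = states)
}

# minibatch index list for one epoch (seeded shuffling by the caller's RNG)
miniBatches <- function(n, batchSize) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batchSize))
}
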