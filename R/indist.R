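#' k-nearest-neighbour discriminability of synthetic from real samples
#'
#' Labels real rows 0 and synthetic rows 1, then estimates how well a
#' k-nearest-neighbour classifier (Euclidean distance, uniform vote,
#' k = 10 by default) separates the two via stratified shuffled n-fold
#' cross-validation. Accuracy near 0.5 means the synthetic data are
#' statistically indistinguishable from the real data to this classifier;
#' accuracy near 1 means they are trivially separable.
#'
#' @param real numeric matrix of real rows.
#' @param synthetic numeric matrix of synthetic rows (same columns).
#' @param k neighbour count (default 10).
#' @param nFolds cross-validation folds (default 5).
#' @param seed integer seed (fold shuffling and kNN tie-breaks).
#' @return a list with \code{accuracyMean}, \code{accuracySd} (over folds)
#'   and \code{confusion}, a 2 x 2 matrix with predicted class in rows and
#'   actual class in columns, pooled over the out-of-fold predictions.
#' @export
knnDiscriminability <- function(real, synthetic, k = 10L, nFolds = 5L,
                                seed = NULL) {
  real <- as.matrix(real); synthetic <- as.matrix(synthetic)
  if (nrow(real) < 1L || nrow(synthetic) < 1L) fail("both groups must be non-empty")
  if (ncol(real) != ncol(synthetic)) fail("column count mismatch")
  if (nrow(real) != nrow(synthetic))
    warning("group sizes differ (", nrow(real), " real vs ", nrow(synthetic),
            " synthetic); accuracy is sensitive to imbalance", call. = FALSE)
  X <- rbind(real, synthetic)
  y <- factor(c(rep("real", nrow(real)), rep("synthetic", nrow(synthetic))),
              levels = c("real", "synthetic"))
  withSeed(seed, {
    foldOf <- integer(length(y))
    for (lv in levels(y)) {                 # stratified shuffled folds
      idx <- sample(which(y == lv))
      foldOf[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    acc <- numeric(nFolds)
    confusion <- matrix(0L, 2L, 2L,
                        dimnames = list(predicted = c("real", "synthetic"),
                                        actual = c("real", "synthetic")))
    for (f in seq_len(nFolds)) {
      tr <- foldOf != f; te <- !tr
      if (k >= sum(tr)) fail("k = ", k, " >= fold training size ", sum(tr))
      pred <- class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                         y[tr], k = k)
      acc[f] <- mean(pred == y[te])
      confusion <- confusion + table(factor(pred, levels(y)),
                                     factor(y[te], levels(y)))
    }
    list(accuracyMean = mean(acc), accuracySd = stats::sd(acc),
         confusion = confusion, foldAccuracies = acc)
  })
}

#' Classification accuracy from a 2 x 2 confusion matrix
#'
#' @param cm 2 x 2 numeric matrix, predicted class in rows and actual class
#'   in columns (same class order on both axes); or the four counts
#'   as a vector in column-major order.
#' @return fraction of correctly classified items (the diagonal over the
#'   total).
#' @export
#' @examples
#' accuracyFromConfusion(matrix(c(160, 140, 147, 153), 2))  # 0.5217
accuracyFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == 2L)) fail("'cm' must be 2 x 2")
  if (any(cm < 0) || any(cm != round(cm))) fail("counts must be non-negative integers")
  tot <- sum(cm)
  if (tot == 0) fail("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Loose majority vote over a table of binary ratings
#'
#' Labels an item \code{"real"} when the fraction of its \code{"real"}
#' votes is at least \code{threshold}; ties at exactly the threshold
#' resolve permissively toward \code{"real"} (the loose rule). With an odd
#' rater count and the default 0.5 threshold this reduces to the plain
#' majority.
#'
#' @param ratings character matrix (items x raters) with entries
#'   \code{"real"} / \code{"synthetic"}.
#' @param threshold vote fraction required for a \code{"real"} label.
#' @return a list with \code{labels} (per item) and \code{counts} (total
#'   items labelled real / synthetic).
#' @export
looseMajorityVote <- function(ratings, threshold = 0.5) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 1L || nrow(ratings) < 1L) fail("empty rating table")
  bad <- setdiff(unique(as.vector(ratings)), c("real", "synthetic"))
  if (length(bad)) fail("unknown rating values: ", paste(bad, collapse = ", "))
  frac <- rowMeans(ratings == "real")
  labels <- ifelse(frac >= threshold, "real", "synthetic")
  list(labels = labels,
       counts = c(real = sum(labels == "real"),
                  synthetic = sum(labels == "synthetic")))
}

#' Fleiss' kappa for fixed-panel categorical ratings
#'
#' Chance-corrected agreement \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar
#' P_e)} for n items each rated by the same number of raters: \eqn{\bar P}
#' is the mean per-item pairwise agreement and \eqn{\bar P_e} the agreement
#' expected from the pooled category proportions.
#'
#' @param ratings matrix (items x raters) of categorical labels.
#' @return kappa in [-1, 1].
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); r <- ncol(ratings)
  if (n < 2L || r < 2L) fail("need >= 2 items and >= 2 raters")
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(cc) rowSums(ratings == cc),
                   numeric(n))                       # n x categories
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = n)
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  p <- colSums(counts) / (n * r)
  Pe <- sum(p^2)
  if (1 - Pe < .Machine$double.eps^0.5)
    fail("all votes in one category: chance agreement is 1, kappa undefined")
  (mean(Pi) - Pe) / (1 - Pe)
}

## ---- nonparametric 1-D SPM --------------------------------------------

# node-wise pooled-variance two-sample t for subsets coded by an indicator
# matrix P (B x n, rows select group A); returns B x Q matrix of t values
permTstats <- function(X, X2, P, nA, nB, colTot, colTot2) {
  SA1 <- P %*% X
  SA2 <- P %*% X2
  SB1 <- matrix(colTot, nrow(P), ncol(X), byrow = TRUE) - SA1
  SB2 <- matrix(colTot2, nrow(P), ncol(X), byrow = TRUE) - SA2
  mA <- SA1 / nA; mB <- SB1 / nB
  ssA <- SA2 - SA1^2 / nA
  ssB <- SB2 - SB1^2 / nB
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  denom <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / denom
  t[!is.finite(t)] <- 0      # identical values at a node -> t defined as 0
  t
}

#' Nonparametric 1-D unpaired t-test over the vertebral domain
#'
#' Computes the pooled-variance two-sample t statistic at each node of a
#' one-dimensional domain (here the 17 vertebral levels) and controls the
#' family-wise error across nodes nonparametrically: group labels are
#' permuted, the maximum of |t| over nodes is collected for each
#' permutation, and the critical threshold t* is the (1 - alpha) quantile
#' of that max-statistic null distribution. The test is two-tailed by
#' construction. When the number of distinct label assignments is at most
#' \code{nPermutations} the null is enumerated exhaustively.
#'
#' @param groupA nA x Q matrix of curves.
#' @param groupB nB x Q matrix of curves (same Q).
#' @param alpha family-wise significance level (default 0.05).
#' @param nPermutations label permutations for the null (default 10000).
#' @param seed integer seed.
#' @return an object of class \code{spmResult}: node \code{t} values,
#'   critical threshold \code{tstar}, \code{clusters} (data frame of
#'   suprathreshold runs with 1-based \code{start}, \code{end},
#'   \code{maxAbsT}), \code{significant}, \code{alpha},
#'   \code{nPermutations} actually used, and the group sizes.
#' @export
spmUnpairedT1d <- function(groupA, groupB, alpha = 0.05,
                           nPermutations = 10000L, seed = NULL) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (ncol(A) != ncol(B)) fail("node count mismatch")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2L || nB < 2L) fail("need at least 2 curves per group")
  if (alpha <= 0 || alpha >= 1) fail("'alpha' must be in (0, 1)")
  X <- rbind(A, B); n <- nA + nB
  X2 <- X^2
  colTot <- colSums(X); colTot2 <- colSums(X2)

  obsP <- matrix(0, 1L, n); obsP[1, seq_len(nA)] <- 1
  tObs <- drop(permTstats(X, X2, obsP, nA, nB, colTot, colTot2))

  nDistinct <- suppressWarnings(choose(n, nA))
  exhaustive <- is.finite(nDistinct) && nDistinct <= nPermutations
  P <- if (exhaustive) {
    combos <- utils::combn(n, nA)
    M <- matrix(0, ncol(combos), n)
    M[cbind(rep(seq_len(ncol(combos)), each = nA), as.vector(combos))] <- 1
    M
  } else withSeed(seed, {
    M <- matrix(0, nPermutations, n)
    pick <- vapply(seq_len(nPermutations), function(i) sample.int(n, nA),
                   integer(nA))
    M[cbind(rep(seq_len(nPermutations), each = nA), as.vector(pick))] <- 1
    M
  })
  maxT <- apply(abs(permTstats(X, X2, P, nA, nB, colTot, colTot2)), 1L, max)
  bUsed <- length(maxT)
  tstar <- sort(maxT)[ceiling((1 - alpha) * bUsed)]

  above <- abs(tObs) > tstar
  clusters <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               maxAbsT = vapply(keep, function(i)
                 max(abs(tObs[starts[i]:ends[i]])), numeric(1)))
  } else data.frame(start = integer(0), end = integer(0), maxAbsT = numeric(0))

  structure(list(t = tObs, tstar = tstar, clusters = clusters,
                 significant = any(above), alpha = alpha,
                 nPermutations = bUsed, exhaustive = exhaustive,
                 nA = nA, nB = nB),
            class = "spmResult")
}

#' @export
print.spmResult <- function(x, ...) {
  cat(sprintf("spmResult: %d nodes, nA=%d nB=%d, alpha=%.3g (%s, %d perms)\n",
              length(x$t), x$nA, x$nB, x$alpha,
              if (x$exhaustive) "exhaustive" else "sampled", x$nPermutations))
  cat(sprintf("  max |t| = %.3f, t* = %.3f -> %s\n", max(abs(x$t)), x$tstar,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  if (nrow(x$clusters))
    cat("  clusters:", paste(sprintf("[%d,%d]", x$clusters$start,
                                     x$clusters$end), collapse = " "), "\n")
  invisible(x)
}

#' Per-plane SPM comparison of real and synthetic cohorts
#'
#' For each anatomical plane, extracts the 17-level vertebral curves from
#' both datasets and runs \code{\link{spmUnpairedT1d}}. With
#' \code{onePerSubject} (the default) a single sample is drawn per real
#' subject and an equal number of synthetic rows is drawn, so each plane's
#' test compares independent subjects against a same-sized synthetic group.
#'
#' @param real a \linkS4class{PostureExperiment} of real samples.
#' @param synthetic a \linkS4class{PostureExperiment} of synthetic samples.
#' @param onePerSubject draw one sample per real subject (default TRUE).
#' @param alpha family-wise level per plane.
#' @param nPermutations permutations per plane.
#' @param seed integer seed.
#' @return named list of \code{spmResult}, one per plane.
#' @export
spmAllPlanes <- function(real, synthetic, onePerSubject = TRUE, alpha = 0.05,
                         nPermutations = 10000L, seed = NULL) {
  schR <- postureSchema(real)
  if (!identical(featureNames(schR), featureNames(postureSchema(synthetic))))
    fail("real and synthetic datasets must share one schema")
  withSeed(seed, {
    if (onePerSubject) {
      subj <- subjectIds(real)
      pickR <- vapply(split(seq_along(subj), subj), function(idx)
        if (length(idx) == 1L) idx else sample(idx, 1L), integer(1))
      real <- real[, sort(pickR)]
      nS <- ncol(synthetic)
      if (nS < ncol(real)) fail("fewer synthetic samples than real subjects")
      if (nS > ncol(real))
        synthetic <- synthetic[, sort(sample.int(nS, ncol(real)))]
    }
    res <- lapply(schR@planeOrder, function(p)
      spmUnpairedT1d(planeCurves(real, p), planeCurves(synthetic, p),
                     alpha = alpha, nPermutations = nPermutations,
                     seed = sample.int(.Machine$integer.max, 1L)))
    names(res) <- schR@planeOrder
    res
  })
}

#' Empirical family-wise false-positive rate of the 1-D permutation test
#'
#' Calibration check for \code{\link{spmUnpairedT1d}}: repeatedly draws two
#' groups of smooth 17-node curves from one distribution (the cohort
#' generator's curve model — smooth subject variation plus session noise,
#' identical parameters for both groups), runs the test, and reports the
#' fraction of replicates declaring any node significant. For a calibrated
#' test this fraction should match the nominal level \code{alpha} up to
#' Monte-Carlo error.
#'
#' @param nReplicates null replicates (default 500).
#' @param nPerGroup curves per group (default 50).
#' @param nPermutations permutations per replicate (default 1000).
#' @param alpha nominal family-wise level (default 0.05).
#' @param seed integer seed governing the whole replicate schedule.
#' @return a list with \code{rate} (empirical family-wise error),
#'   \code{nReplicates}, \code{alpha} and the binomial \code{mcInterval}
#'   (95\% Monte-Carlo interval around \code{alpha}).
#' @export
spmFalsePositiveRate <- function(nReplicates = 500L, nPerGroup = 50L,
                                 nPermutations = 1000L, alpha = 0.05,
                                 seed = 1L) {
  Phi <- cosineBasis(4L)
  hits <- withSeed(seed, {
    repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    vapply(seq_len(nReplicates), function(r) {
      withSeed(repSeeds[r], {
        n <- 2L * nPerGroup
        # smooth per-curve variation on the cosine basis + i.i.d. node noise,
        # one common distribution for all curves
        coef <- matrix(stats::rnorm(n * ncol(Phi), sd = 3), n)
        X <- coef %*% t(Phi) +
          matrix(stats::rnorm(n * nrow(Phi)), n, nrow(Phi))
        sA <- sample.int(.Machine$integer.max, 1L)
        res <- spmUnpairedT1d(X[seq_len(nPerGroup), ],
                              X[nPerGroup + seq_len(nPerGroup), ],
                              alpha = alpha, nPermutations = nPermutations,
                              seed = sA)
        res$significant
      })
    }, logical(1))
  })
  rate <- mean(hits)
  mc <- alpha + c(-1.96, 1.96) * sqrt(alpha * (1 - alpha) / nReplicates)
  list(rate = rate, nReplicates = nReplicates, alpha = alpha,
       mcInterval = mc)
}

#' Export a blinded rating sheet for human raters
#'
#' Draws equal numbers of real and synthetic samples, shuffles them, and
#' writes a CSV without the truth column (plus a separate key file) so
#' domain experts can classify samples as real or synthetic without cues.
#'
#' @param real a \linkS4class{PostureExperiment} of real samples.
#' @param synthetic matrix or \linkS4class{PostureExperiment} of synthetic
#'   samples in degrees.
#' @param nPerGroup samples per group to include.
#' @param path output CSV path for the blinded sheet.
#' @param keyPath output CSV path for the truth key.
#' @param seed integer seed.
#' @return invisibly, a data frame with \code{item_id} and \code{truth}.
#' @export
exportBlindedRatingSheet <- function(real, synthetic, nPerGroup, path,
                                     keyPath, seed = NULL) {
  Xr <- postureMatrix(real)
  Xs <- if (is(synthetic, "PostureExperiment")) postureMatrix(synthetic)
        else as.matrix(synthetic)
  if (nrow(Xr) < nPerGroup || nrow(Xs) < nPerGroup)
    fail("not enough samples for nPerGroup = ", nPerGroup)
  withSeed(seed, {
    pickR <- sample.int(nrow(Xr), nPerGroup)
    pickS <- sample.int(nrow(Xs), nPerGroup)
    M <- rbind(Xr[pickR, , drop = FALSE], Xs[pickS, , drop = FALSE])
    truth <- c(rep("real", nPerGroup), rep("synthetic", nPerGroup))
    ord <- sample.int(nrow(M))
    ids <- sprintf("item_%03d", seq_len(nrow(M)))
    blind <- data.frame(item_id = ids, M[ord, , drop = FALSE],
                        check.names = FALSE)
    utils::write.csv(blind, path, row.names = FALSE)
    key <- data.frame(item_id = ids, truth = truth[ord])
    utils::write.csv(key, keyPath, row.names = FALSE)
    invisible(key)
  })
}

#' Read a rating table from CSV
#'
#' Expected columns: \code{item_id}, \code{truth}, then one column per
#' rater (\code{rater_1}, ...), each entry \code{"real"} or
#' \code{"synthetic"}.
#'
#' @param path CSV path.
#' @return a list with \code{ratings} (items x raters character matrix,
#'   item IDs as row names) and \code{truth} (character vector).
#' @export
readRatingTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("item_id", "truth") %in% names(df)))
    fail("rating CSV needs 'item_id' and 'truth' columns")
  raters <- setdiff(names(df), c("item_id", "truth"))
  if (!length(raters)) fail("no rater columns found")
  m <- as.matrix(df[, raters, drop = FALSE])
  rownames(m) <- df$item_id
  list(ratings = m, truth = df$truth)
}
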