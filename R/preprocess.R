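#' Randomly retain a fixed number of sessions per subject
#'
#' Draws \code{nPerSubject} samples without replacement from each subject's
#' sessions, mirroring the study design in which three repeated measurements
#' per participant are carried forward.
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param nPerSubject samples to keep per subject (default 3).
#' @param seed integer seed.
#' @return a \linkS4class{PostureExperiment} with exactly
#'   \code{nPerSubject} samples per subject, in original sample order.
#' @export
selectSessionsPerSubject <- function(x, nPerSubject = 3L, seed = NULL) {
  subj <- subjectIds(x)
  cnt <- table(subj)
  short <- names(cnt)[cnt < nPerSubject]
  if (length(short))
    fail("subject(s) with fewer than ", nPerSubject, " sessions: ",
         paste(utils::head(short, 5L), collapse = ", "))
  keep <- withSeed(seed, {
    unlist(lapply(split(seq_along(subj), subj), function(idx)
      if (length(idx) == nPerSubject) idx else sample(idx, nPerSubject)),
      use.names = FALSE)
  })
  x[, sort(keep)]
}

## ---- isolation forest -------------------------------------------------
## Standard isolation forest: trees grown on subsamples of size psi with
## uniform random feature/split-point choices down to depth ceil(log2(psi));
## anomaly score s(x) = 2^(-E[h(x)]/c(psi)) from the average path length.

harmonicC <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

growITree <- function(X, idx, depth, maxDepth) {
  n <- length(idx)
  if (depth >= maxDepth || n <= 1L) return(list(size = n))
  f <- sample.int(ncol(X), 1L)
  v <- X[idx, f]
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(list(size = n))
  sp <- stats::runif(1L, lo, hi)
  left <- idx[v < sp]
  right <- idx[v >= sp]
  list(f = f, sp = sp,
       left = growITree(X, left, depth + 1L, maxDepth),
       right = growITree(X, right, depth + 1L, maxDepth))
}

# accumulate path lengths of all rows in `idx` under one tree
iTreeDepths <- function(tree, X, idx, depth, out) {
  if (is.null(tree$f)) {
    out[idx] <- depth + harmonicC(tree$size)
    return(out)
  }
  v <- X[idx, tree$f]
  l <- idx[v < tree$sp]
  r <- idx[v >= tree$sp]
  if (length(l)) out <- iTreeDepths(tree$left, X, l, depth + 1L, out)
  if (length(r)) out <- iTreeDepths(tree$right, X, r, depth + 1L, out)
  out
}

#' Isolation-forest anomaly scores
#'
#' @param X numeric matrix, samples in rows.
#' @param nTrees ensemble size (default 500).
#' @param subsampleSize per-tree subsample (default \code{min(256, n)}).
#' @param seed integer seed.
#' @return numeric vector of anomaly scores in (0, 1); larger is more
#'   anomalous, with 0.5 the score of an average point.
#' @export
isolationForestScores <- function(X, nTrees = 500L,
                                  subsampleSize = min(256L, nrow(X)),
                                  seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) fail("need at least 2 rows")
  psi <- min(subsampleSize, n)
  maxDepth <- ceiling(log2(psi))
  withSeed(seed, {
    total <- numeric(n)
    for (b in seq_len(nTrees)) {
      idx <- sample.int(n, psi)
      tree <- growITree(X, idx, 0L, maxDepth)
      total <- total + iTreeDepths(tree, X, seq_len(n), 0L, numeric(n))
    }
    2^(-(total / nTrees) / harmonicC(psi))
  })
}

#' Remove multivariate outliers with an isolation forest
#'
#' Scores every sample on the 54 posture features with a 500-tree isolation
#' forest and drops the most anomalous ones. With a numeric
#' \code{contamination} fraction, exactly \code{round(contamination * n)}
#' samples (the highest scores) are removed; with \code{"auto"}, samples
#' scoring above 0.5 — more easily isolated than an average point — are
#' removed.
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param nTrees ensemble size (default 500).
#' @param contamination \code{"auto"} or a fraction in (0, 0.5].
#' @param seed integer seed.
#' @return a list with \code{dataset} (filtered
#'   \linkS4class{PostureExperiment}) and \code{removed} (count).
#' @export
removeOutliers <- function(x, nTrees = 500L, contamination = "auto",
                           seed = NULL) {
  n <- ncol(x)
  if (n < 2L) fail("need at least 2 samples")
  if (is.numeric(contamination) &&
      (contamination <= 0 || contamination > 0.5))
    fail("'contamination' must be in (0, 0.5]")
  sc <- isolationForestScores(postureMatrix(x), nTrees = nTrees, seed = seed)
  if (is.numeric(contamination)) {
    kOut <- round(contamination * n)
    drop <- if (kOut > 0) order(sc, decreasing = TRUE)[seq_len(kOut)] else integer(0)
  } else {
    drop <- which(sc > 0.5)
  }
  keep <- setdiff(seq_len(n), drop)
  list(dataset = x[, keep], removed = length(drop))
}

## ---- grouped k-fold construction --------------------------------------

#' Subject-disjoint grouped k-fold assignment
#'
#' Partitions subjects (never samples) into k near-equal test groups, then
#' splits each fold's remaining subjects into train and validation sets.
#' With the defaults (k = 5, \code{valFraction} = 0.125 of the non-test
#' subjects) the overall proportions approximate 70/10/20. Subjects are
#' shuffled under the seed and dealt round-robin, so test-set sizes differ
#' by at most one.
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param k number of folds (default 5).
#' @param valFraction fraction of each fold's non-test subjects assigned to
#'   validation (default 0.125).
#' @param seed integer seed.
#' @return an object of class \code{foldAssignment}: a list with \code{k},
#'   \code{valFraction} and \code{folds}, where each fold holds character
#'   vectors \code{train}, \code{val} and \code{test} of subject IDs.
#' @export
makeGroupedFolds <- function(x, k = 5L, valFraction = 0.125, seed = NULL) {
  subjects <- unique(subjectIds(x))
  nSub <- length(subjects)
  if (k < 2L || k > nSub) fail("'k' must be in [2, number of subjects]")
  withSeed(seed, {
    shuffled <- sample(subjects)
    testGroups <- split(shuffled, rep_len(seq_len(k), nSub))
    folds <- lapply(seq_len(k), function(i) {
      test <- testGroups[[i]]
      rest <- sample(setdiff(shuffled, test))
      nVal <- round(valFraction * length(rest))
      val <- utils::head(rest, nVal)
      list(train = sort(setdiff(rest, val)), val = sort(val),
           test = sort(test))
    })
    structure(list(k = as.integer(k), valFraction = valFraction,
                   folds = folds, subjects = sort(subjects)),
              class = "foldAssignment")
  })
}

#' @export
print.foldAssignment <- function(x, ...) {
  cat("foldAssignment: k =", x$k, "over", length(x$subjects), "subjects\n")
  for (i in seq_len(x$k))
    cat(sprintf("  fold %d: train %d / val %d / test %d subjects\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$val),
                length(x$folds[[i]]$test)))
  invisible(x)
}

#' Serialize / read a fold assignment as JSON
#'
#' @param folds a \code{foldAssignment}.
#' @param path file path.
#' @return \code{readFoldsJson}: a \code{foldAssignment}.
#' @export
writeFoldsJson <- function(folds, path) {
  jsonlite::write_json(unclass(folds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFoldsJson
#' @export
readFoldsJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) unname(vapply(x, identity, character(1)))
  folds <- lapply(obj$folds, function(f)
    list(train = chr(f$train), val = chr(f$val), test = chr(f$test)))
  structure(list(k = as.integer(obj$k), valFraction = obj$valFraction[[1]],
                 folds = folds, subjects = chr(obj$subjects)),
            class = "foldAssignment")
}

## ---- feature standardization ------------------------------------------

#' Per-feature z-scoring fitted on a training set
#'
#' \code{fitStandardizer} learns per-feature means and population (divide
#' by n) standard deviations from the fit rows; \code{applyStandardizer}
#' z-scores new rows and \code{invertStandardizer} maps scaled rows back to
#' degrees. Zero-variance features are guarded: they transform to 0 and
#' invert to the training mean.
#'
#' @param X numeric matrix of fit rows (samples x features).
#' @return \code{fitStandardizer}: an object of class
#'   \code{postureStandardizer} with \code{center}, \code{scale} and a
#'   \code{degenerate} flag per feature.
#' @export
#' @examples
#' std <- fitStandardizer(matrix(c(1, 2, 3), ncol = 1))
#' applyStandardizer(std, matrix(c(1, 2, 3), ncol = 1))  # +-1.2247, 0
fitStandardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) fail("'X' must be non-empty")
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2L, center)^2))   # population SD
  degenerate <- scale <= 0
  scale[degenerate] <- 1
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "postureStandardizer")
}

#' @rdname fitStandardizer
#' @param std a fitted \code{postureStandardizer}.
#' @param rows numeric matrix to transform.
#' @export
applyStandardizer <- function(std, rows) {
  checkStandardizer(std, rows)
  out <- sweep(sweep(as.matrix(rows), 2L, std$center), 2L, std$scale, "/")
  out[, std$degenerate] <- 0
  out
}

#' @rdname fitStandardizer
#' @export
invertStandardizer <- function(std, rows) {
  checkStandardizer(std, rows)
  out <- sweep(sweep(as.matrix(rows), 2L, std$scale, "*"), 2L, std$center, "+")
  if (any(std$degenerate))
    out[, std$degenerate] <- matrix(std$center[std$degenerate],
                                    nrow(out), sum(std$degenerate), byrow = TRUE)
  out
}

checkStandardizer <- function(std, rows) {
  if (!inherits(std, "postureStandardizer"))
    fail("standardizer not fitted: call fitStandardizer() first")
  if (ncol(as.matrix(rows)) != length(std$center))
    fail("column count does not match the fitted standardizer")
  invisible(TRUE)
}

# samples x features matrices for one fold, scaled on the real training rows
foldMatrices <- function(x, fold, std = NULL) {
  tr <- subsetSamples(x, subjects = fold$train)
  va <- subsetSamples(x, subjects = fold$val)
  te <- subsetSamples(x, subjects = fold$test)
  if (is.null(std)) std <- fitStandardizer(postureMatrix(tr))
  list(train = applyStandardizer(std, postureMatrix(tr)),
       val = applyStandardizer(std, postureMatrix(va)),
       test = applyStandardizer(std, postureMatrix(te)),
       std = std)
}
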