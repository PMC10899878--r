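#' Configuration for the synthetic posture cohort generator
#'
#' The generator emulates the statistical structure of a multi-study
#' surface-topography cohort: five diagnostic groups of unequal size, a few
#' repeated measurement sessions per subject, smooth per-plane vertebral
#' curves, strong subject-level clustering and only weak class separation.
#' Defaults mirror the study conditions the package's analyses assume:
#' 201/25/32/34/60 subjects in the classes healthy_1, healthy_2, back_pain,
#' spinal_fusion and osteoarthritis, 12 sessions per subject, and a
#' low-dimensional latent factor structure.
#'
#' @param classSizes named integer vector: subjects per class.
#' @param sessionsPerSubject sessions recorded per subject (>= 3).
#' @param nFactors latent factor count of the generative model; gives the
#'   data a true low-rank structure that latent dimensions of 7--15 can
#'   capture.
#' @param classShiftScale SD (degrees) of the smooth class mean shifts; kept
#'   below \code{subjectSd} so classes overlap heavily.
#' @param subjectSd SD (degrees) of the smooth between-subject variation.
#' @param sessionSd SD (degrees) of i.i.d. within-subject session noise;
#'   must be below \code{subjectSd} so repeated measures cluster by subject.
#' @param smoothnessBasisOrder number of low-frequency cosine basis
#'   functions used for class means and factor loadings.
#' @param factorSdDecay geometric decay of the per-factor loading scale
#'   (factor f is weighted \code{factorSdDecay^(f-1)}). Values below 1 give
#'   the scree-like decaying eigenvalue spectrum real posture data show, so
#'   a bottleneck smaller than \code{nFactors} can still capture most of
#'   the between-subject variance.
#' @param seed integer seed.
#' @return a list of class \code{cohortConfig}.
#' @export
#' @examples
#' cfg <- cohortConfig(classSizes = c(healthy_1 = 4), sessionsPerSubject = 3)
#' pe <- simulateCohort(cfg)
#' ncol(pe)  # 12 samples
cohortConfig <- function(classSizes = c(healthy_1 = 201, healthy_2 = 25,
                                        back_pain = 32, spinal_fusion = 34,
                                        osteoarthritis = 60),
                         sessionsPerSubject = 12L,
                         nFactors = 10L,
                         classShiftScale = 0.5,
                         subjectSd = 3.0,
                         sessionSd = 1.0,
                         smoothnessBasisOrder = 4L,
                         factorSdDecay = 0.75,
                         seed = 20240214L) {
  if (is.null(names(classSizes)) || any(!nzchar(names(classSizes))))
    fail("'classSizes' must be a named vector")
  if (any(classSizes <= 0) || any(classSizes != round(classSizes)))
    fail("class sizes must be positive integers")
  if (sessionsPerSubject < 3) fail("'sessionsPerSubject' must be >= 3")
  if (nFactors < 1) fail("'nFactors' must be positive")
  if (sessionSd >= subjectSd)
    fail("'sessionSd' must be below 'subjectSd' (repeated measures cluster by subject)")
  if (classShiftScale >= subjectSd)
    fail("'classShiftScale' must be below 'subjectSd' (weak class separation)")
  if (smoothnessBasisOrder < 1) fail("'smoothnessBasisOrder' must be positive")
  if (factorSdDecay <= 0 || factorSdDecay > 1)
    fail("'factorSdDecay' must be in (0, 1]")
  structure(list(classSizes = classSizes,
                 sessionsPerSubject = as.integer(sessionsPerSubject),
                 nFactors = as.integer(nFactors),
                 classShiftScale = classShiftScale,
                 subjectSd = subjectSd,
                 sessionSd = sessionSd,
                 smoothnessBasisOrder = as.integer(smoothnessBasisOrder),
                 factorSdDecay = factorSdDecay,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

# low-frequency cosine basis over the 17 vertebral levels (includes constant)
cosineBasis <- function(order, q = 17L) {
  t <- seq(0, 1, length.out = q)
  vapply(seq_len(order) - 1L, function(j) cos(pi * j * t), numeric(q))
}

# fixed population baseline: a kyphosis/lordosis-like sagittal profile,
# near-neutral coronal/transverse alignment, typical sacral inclination
populationBaseline <- function(schema) {
  t <- seq(0, 1, length.out = 17L)
  base <- numeric(54L)
  names(base) <- schema@featureNames
  base[1:3] <- c(0, 18, 0)                      # obliquity, inclination, rotation
  base[planeColumns(schema, "sagittal")] <- 12 * cos(2 * pi * t) - 2
  base
}

#' Simulate a subject-grouped synthetic posture cohort
#'
#' Generative model, per anatomical plane: the class mean curve over the 17
#' vertebral levels is a smooth expansion in the first
#' \code{smoothnessBasisOrder} cosine basis functions with class-specific
#' coefficients (scale \code{classShiftScale}), added to a fixed population
#' baseline. Each subject draws an \code{nFactors}-dimensional standard
#' normal factor score; smooth loading curves (built on the same basis and
#' scaled so the implied per-feature SD equals \code{subjectSd}) map it to
#' the vertebral features, and a linear map of the same score drives the
#' three pelvic parameters. Each session adds i.i.d. Gaussian noise with SD
#' \code{sessionSd}. All draws are governed by \code{config$seed}, so equal
#' configs give bit-identical cohorts.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{PostureExperiment} with
#'   \code{sum(classSizes) * sessionsPerSubject} samples; subject IDs are
#'   \code{"S0001"}, \code{"S0002"}, ...
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "cohortConfig")) fail("'config' must come from cohortConfig()")
  sch <- buildSchema()
  nSub <- sum(config$classSizes)
  nSes <- config$sessionsPerSubject
  nf <- config$nFactors
  Phi <- cosineBasis(config$smoothnessBasisOrder)          # 17 x order

  withSeed(config$seed, {
    classes <- names(config$classSizes)
    # smooth class mean shifts, one 51-vector per class (+ pelvic shift)
    classShift <- lapply(classes, function(cl) {
      vert <- as.vector(vapply(sch@planeOrder, function(p)
        as.numeric(Phi %*% stats::rnorm(ncol(Phi))), numeric(17L)))
      c(stats::rnorm(3L), vert) * config$classShiftScale
    })
    names(classShift) <- classes

    # smooth factor loadings for the vertebral block, linear map for pelvic
    Lraw <- matrix(0, 51L, nf)
    for (f in seq_len(nf)) {
      Lraw[, f] <- as.vector(vapply(sch@planeOrder, function(p)
        as.numeric(Phi %*% stats::rnorm(ncol(Phi))), numeric(17L)))
    }
    decay <- config$factorSdDecay^(seq_len(nf) - 1L)
    Lraw <- sweep(Lraw, 2L, decay, "*")
    Lvert <- Lraw * (config$subjectSd / sqrt(mean(rowSums(Lraw^2))))
    Apel <- sweep(matrix(stats::rnorm(3L * nf), 3L, nf), 2L, decay, "*")
    Apel <- Apel * (config$subjectSd / sqrt(mean(rowSums(Apel^2))))
    L <- rbind(Apel, Lvert)                                # 54 x nf

    base <- populationBaseline(sch)
    subjectClass <- rep(classes, times = config$classSizes)
    subjectIdv <- sprintf("S%04d", seq_len(nSub))
    U <- matrix(stats::rnorm(nSub * nf), nSub, nf)         # factor scores

    n <- nSub * nSes
    X <- matrix(0, n, 54L)
    rowSubj <- rep(subjectIdv, each = nSes)
    rowClass <- rep(subjectClass, each = nSes)
    rowSess <- rep(seq_len(nSes), times = nSub)
    subjMeans <- U %*% t(L)                                # nSub x 54
    for (s in seq_len(nSub)) {
      mu <- base + classShift[[subjectClass[s]]] + subjMeans[s, ]
      rows <- (s - 1L) * nSes + seq_len(nSes)
      X[rows, ] <- matrix(mu, nSes, 54L, byrow = TRUE) +
        matrix(stats::rnorm(nSes * 54L, sd = config$sessionSd), nSes, 54L)
    }
    colnames(X) <- sch@featureNames
    PostureExperiment(X, subjectId = rowSubj, classLabel = rowClass,
                      sessionIdx = rowSess, schema = sch)
  })
}
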