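#' Full-study experiment configuration
#'
#' Bundles the per-stage configurations of the end-to-end workflow:
#' cohort simulation, preprocessing, VAE training, synthetic-data
#' evaluation and the autoencoder benchmark. Stage seeds are derived
#' deterministically from the single global seed with
#' \code{\link{deriveSeed}}, so one integer reproduces the whole run.
#'
#' @param cohort a \code{\link{cohortConfig}}.
#' @param nPerSubject sessions retained per subject.
#' @param contamination isolation-forest contamination (\code{"auto"} or a
#'   fraction).
#' @param k grouped-CV fold count.
#' @param valFraction validation fraction of non-test subjects.
#' @param vae a \code{\link{vaeConfig}}.
#' @param ae an \code{\link{aeConfig}}.
#' @param schemes augmentation schemes for the benchmark.
#' @param latentDims autoencoder bottleneck sizes.
#' @param kNeighbors kNN discriminability neighbour count.
#' @param spmAlpha family-wise level for the per-plane SPM tests.
#' @param spmPermutations permutations per SPM test.
#' @param seed global integer seed.
#' @return a list of class \code{experimentConfig}.
#' @export
experimentConfig <- function(cohort = cohortConfig(),
                             nPerSubject = 3L, contamination = "auto",
                             k = 5L, valFraction = 0.125,
                             vae = vaeConfig(), ae = aeConfig(),
                             schemes = c("RTD", "RTSD", "RT3SD"),
                             latentDims = 15L,
                             kNeighbors = 10L, spmAlpha = 0.05,
                             spmPermutations = 10000L, seed = 1L) {
  structure(list(cohort = cohort, nPerSubject = as.integer(nPerSubject),
                 contamination = contamination, k = as.integer(k),
                 valFraction = valFraction, vae = vae, ae = ae,
                 schemes = schemes, latentDims = as.integer(latentDims),
                 kNeighbors = as.integer(kNeighbors), spmAlpha = spmAlpha,
                 spmPermutations = as.integer(spmPermutations),
                 seed = as.integer(seed)),
            class = "experimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the \code{\link{experimentConfig}} arguments;
#' \code{cohort}, \code{vae} and \code{ae} are nested maps whose keys are
#' the corresponding constructor arguments. Absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return an \code{experimentConfig}.
#' @export
readExperimentYaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) {
    cArgs <- y$cohort
    if (!is.null(cArgs$classSizes)) cArgs$classSizes <- unlist(cArgs$classSizes)
    args$cohort <- do.call(cohortConfig, cArgs)
  }
  if (!is.null(y$vae)) args$vae <- do.call(vaeConfig, y$vae)
  if (!is.null(y$ae)) args$ae <- do.call(aeConfig, y$ae)
  for (nm in c("nPerSubject", "contamination", "k", "valFraction", "schemes",
               "latentDims", "kNeighbors", "spmAlpha", "spmPermutations",
               "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(experimentConfig, args)
}

#' Run the full augmentation study end to end
#'
#' Executes the complete workflow from one configuration: simulate the
#' cohort, retain sessions, remove outliers, build subject-grouped folds,
#' train a VAE per fold, generate synthetic data, evaluate
#' indistinguishability (kNN discriminability and per-plane SPM), and run
#' the autoencoder benchmark. Every artifact is written under
#' \code{outDir}, together with a manifest recording the configuration and
#' all derived stage seeds; rerunning with the same configuration
#' reproduces the artifacts exactly.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param outDir writable output directory (created if missing).
#' @param verbose print stage progress to stderr (default TRUE).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{cohort}, \code{folds}, \code{vaes}, \code{knn}, \code{spm},
#'   \code{report}, \code{manifest}).
#' @export
runFullStudy <- function(config, outDir, verbose = TRUE) {
  if (!inherits(config, "experimentConfig"))
    fail("'config' must come from experimentConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[postureVAE] ", ...)
  gseed <- config$seed
  stageSeeds <- c(select = deriveSeed(gseed, "select"),
                  outliers = deriveSeed(gseed, "outliers"),
                  folds = deriveSeed(gseed, "folds"),
                  synth = deriveSeed(gseed, "synth"),
                  knn = deriveSeed(gseed, "knn"),
                  spm = deriveSeed(gseed, "spm"),
                  bench = deriveSeed(gseed, "bench"))

  say("simulating cohort")
  cohort <- simulateCohort(config$cohort)
  writePostureCsv(cohort, file.path(outDir, "cohort.csv"))

  say("selecting sessions and removing outliers")
  sel <- selectSessionsPerSubject(cohort, config$nPerSubject,
                                  seed = stageSeeds[["select"]])
  filt <- removeOutliers(sel, contamination = config$contamination,
                         seed = stageSeeds[["outliers"]])
  dataset <- filt$dataset
  writePostureCsv(dataset, file.path(outDir, "dataset_clean.csv"))

  say("building grouped folds (k = ", config$k, ")")
  folds <- makeGroupedFolds(dataset, k = config$k,
                            valFraction = config$valFraction,
                            seed = stageSeeds[["folds"]])
  writeFoldsJson(folds, file.path(outDir, "folds.json"))

  say("training per-fold VAEs")
  vaes <- vector("list", config$k)
  knnRes <- vector("list", config$k)
  vaeMse <- data.frame()
  for (f in seq_len(config$k)) {
    fm <- foldMatrices(dataset, folds$folds[[f]])
    vCfg <- config$vae
    vCfg$seed <- deriveSeed(gseed, paste0("vae_f", f))
    vaes[[f]] <- trainVAE(fm$train, fm$val, vCfg)
    saveVAE(vaes[[f]], file.path(outDir, sprintf("vae_fold%d.json", f)))
    vaeMse <- rbind(vaeMse, data.frame(
      fold = f,
      trainMse = reconstruct(vaes[[f]], fm$train)$mse,
      valMse = reconstruct(vaes[[f]], fm$val)$mse,
      testMse = reconstruct(vaes[[f]], fm$test)$mse))
    syn <- sampleSynthetic(vaes[[f]], nrow(fm$test),
                           seed = deriveSeed(gseed, paste0("synth_f", f)))
    synDeg <- invertStandardizer(fm$std, syn)
    colnames(synDeg) <- featureNames(postureSchema(dataset))
    synPe <- PostureExperiment(synDeg,
                               subjectId = sprintf("SYN_f%d_%04d", f,
                                                   seq_len(nrow(synDeg))),
                               classLabel = rep("synthetic", nrow(synDeg)),
                               sessionIdx = rep(1L, nrow(synDeg)))
    writePostureCsv(synPe, file.path(outDir, sprintf("synthetic_fold%d.csv", f)))
    knnRes[[f]] <- knnDiscriminability(fm$test, syn, k = config$kNeighbors,
                                       seed = deriveSeed(gseed,
                                                         paste0("knn_f", f)))
  }
  utils::write.csv(vaeMse, file.path(outDir, "vae_mse.csv"), row.names = FALSE)
  knnSummary <- list(
    perFold = lapply(knnRes, function(r)
      list(accuracyMean = r$accuracyMean, accuracySd = r$accuracySd)),
    accuracyMean = mean(vapply(knnRes, `[[`, numeric(1), "accuracyMean")))
  jsonlite::write_json(knnSummary, file.path(outDir, "knn.json"),
                       auto_unbox = TRUE, digits = NA)

  say("SPM comparison, one sample per subject")
  # pool synthetic samples across folds (in degrees), as one synthetic cohort
  synAll <- do.call(rbind, lapply(seq_len(config$k), function(f)
    postureMatrix(readPostureCsv(file.path(outDir,
                                           sprintf("synthetic_fold%d.csv", f))))))
  synPe <- PostureExperiment(synAll,
                             subjectId = sprintf("SYN%05d", seq_len(nrow(synAll))),
                             classLabel = rep("synthetic", nrow(synAll)),
                             sessionIdx = rep(1L, nrow(synAll)))
  spm <- spmAllPlanes(dataset, synPe, alpha = config$spmAlpha,
                      nPermutations = config$spmPermutations,
                      seed = stageSeeds[["spm"]])
  jsonlite::write_json(
    lapply(spm, function(r) list(t = r$t, tstar = r$tstar,
                                 significant = r$significant,
                                 clusters = r$clusters)),
    file.path(outDir, "spm.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  say("autoencoder augmentation benchmark")
  report <- runAugmentationBenchmark(folds, dataset, schemes = config$schemes,
                                     latentDims = config$latentDims,
                                     vaeCfg = config$vae, aeCfg = config$ae,
                                     seed = stageSeeds[["bench"]])
  writeReport(report, csvPath = file.path(outDir, "ae_report.csv"),
              jsonPath = file.path(outDir, "ae_report.json"))

  manifest <- list(
    package = "postureVAE",
    version = as.character(utils::packageVersion("postureVAE")),
    rVersion = R.version.string,
    seed = gseed, stageSeeds = as.list(stageSeeds),
    k = config$k, schemes = config$schemes, latentDims = config$latentDims,
    nSamples = ncol(dataset), nSubjects = length(unique(subjectIds(dataset))),
    outliersRemoved = filt$removed,
    artifacts = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outDir)
  invisible(list(cohort = cohort, dataset = dataset, folds = folds,
                 vaes = vaes, vaeMse = vaeMse, knn = knnRes, spm = spm,
                 report = report, manifest = manifest))
}
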