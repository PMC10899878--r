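#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' PostureExperiment: subject-grouped posture samples
#'
#' The central data container of the package: a
#' \linkS4class{SummarizedExperiment} whose single assay \code{"posture"}
#' holds the 54 posture parameters (rows, in canonical
#' \linkS4class{PostureSchema} order, degrees) for every sample (columns).
#' Per-sample metadata in \code{colData} records \code{subject_id},
#' \code{class_label} and \code{session_idx}; repeated measurements of one
#' subject are separate columns sharing a \code{subject_id}. All grouped
#' cross-validation machinery in the package keys on \code{subject_id} so a
#' subject's samples never straddle a train/test boundary.
#'
#' @exportClass PostureExperiment
setClass("PostureExperiment", contains = "SummarizedExperiment")

setValidity("PostureExperiment", function(object) {
  msg <- NULL
  if (!"posture" %in% SummarizedExperiment::assayNames(object))
    return("assay 'posture' is required")
  a <- assay(object, "posture")
  if (nrow(a) != 54L) msg <- c(msg, "assay must have 54 feature rows")
  if (ncol(a) > 0 && !all(is.finite(a)))
    msg <- c(msg, "posture values must all be finite")
  need <- c("subject_id", "class_label", "session_idx")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && ncol(a) > 0) {
    tab <- unique(data.frame(s = as.character(colData(object)$subject_id),
                             c = as.character(colData(object)$class_label)))
    if (anyDuplicated(tab$s))
      msg <- c(msg, "each subject must carry exactly one class_label")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a PostureExperiment
#'
#' @param values numeric matrix of posture parameters, samples in rows and
#'   the 54 schema features in columns (degrees).
#' @param subjectId character/factor, one entry per sample.
#' @param classLabel character/factor, one entry per sample; all samples of
#'   one subject must share a label.
#' @param sessionIdx integer session index per sample.
#' @param schema a \linkS4class{PostureSchema}; columns of \code{values} are
#'   checked (and reordered if named) against it.
#' @return a \linkS4class{PostureExperiment}.
#' @export
#' @examples
#' sch <- buildSchema()
#' m <- matrix(stats::rnorm(2 * 54), 2, dimnames = list(NULL, featureNames(sch)))
#' pe <- PostureExperiment(m, subjectId = c("S1", "S1"),
#'                         classLabel = c("healthy_1", "healthy_1"),
#'                         sessionIdx = 1:2)
#' pe
PostureExperiment <- function(values, subjectId, classLabel, sessionIdx,
                              schema = buildSchema()) {
  values <- as.matrix(values)
  if (ncol(values) != 54L)
    fail("'values' must have 54 columns, got ", ncol(values))
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), schema@featureNames))
      fail("column names of 'values' do not match the posture schema")
    values <- values[, schema@featureNames, drop = FALSE]
  } else colnames(values) <- schema@featureNames
  n <- nrow(values)
  if (length(subjectId) != n || length(classLabel) != n || length(sessionIdx) != n)
    fail("metadata vectors must match the number of samples (", n, ")")
  block <- c(rep("pelvic", 3L), rep("vertebral", 51L))
  level <- c(rep(NA_character_, 3L), rep(schema@levelOrder, times = 3L))
  plane <- c(rep(NA_character_, 3L), rep(schema@planeOrder, each = 17L))
  se <- SummarizedExperiment(
    assays = list(posture = t(values)),
    colData = DataFrame(subject_id = as.character(subjectId),
                        class_label = as.character(classLabel),
                        session_idx = as.integer(sessionIdx),
                        row.names = if (is.null(rownames(values)))
                          sprintf("sample_%04d", seq_len(n)) else rownames(values)),
    rowData = DataFrame(block = block, level = level, plane = plane))
  out <- new("PostureExperiment", se)
  S4Vectors::metadata(out)$schema <- schema
  validObject(out)
  out
}

#' Accessors for PostureExperiment
#'
#' \code{postureMatrix} returns the samples x 54 numeric matrix (the
#' transpose of the assay); \code{subjectIds}, \code{classLabels} and
#' \code{sessionIndex} return the per-sample metadata; \code{postureSchema}
#' returns the stored \linkS4class{PostureSchema}.
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @return see individual descriptions.
#' @export
postureMatrix <- function(x) t(assay(x, "posture"))

#' @rdname postureMatrix
#' @export
subjectIds <- function(x) as.character(colData(x)$subject_id)

#' @rdname postureMatrix
#' @export
classLabels <- function(x) as.character(colData(x)$class_label)

#' @rdname postureMatrix
#' @export
sessionIndex <- function(x) as.integer(colData(x)$session_idx)

#' @rdname postureMatrix
#' @export
postureSchema <- function(x) {
  s <- S4Vectors::metadata(x)$schema
  if (is.null(s)) buildSchema() else s
}

setMethod("show", "PostureExperiment", function(object) {
  n <- ncol(object)
  subj <- unique(subjectIds(object))
  cat("PostureExperiment:", n, "samples,", length(subj), "subjects, 54 features\n")
  if (n > 0) {
    tab <- table(classLabels(object)[!duplicated(subjectIds(object))])
    cat("  subjects per class:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
    cat("  sessions per subject:",
        paste(range(table(subjectIds(object))), collapse = "-"), "\n")
  }
})

#' Subset a PostureExperiment to a set of samples or subjects
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param samples integer or logical index over samples (columns).
#' @param subjects character vector of subject IDs to keep.
#' @return the subsetted \linkS4class{PostureExperiment}.
#' @export
subsetSamples <- function(x, samples = NULL, subjects = NULL) {
  if (!is.null(subjects)) {
    keep <- subjectIds(x) %in% subjects
    x <- x[, keep]
  }
  if (!is.null(samples)) x <- x[, samples]
  x
}

#' Read / write a posture dataset as CSV
#'
#' The on-disk interchange format: one row per sample with columns
#' \code{subject_id}, \code{class_label}, \code{session_idx} followed by the
#' 54 schema-named feature columns (UTF-8, header row, \code{.} decimal).
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param path file path.
#' @param schema schema used to validate columns on read.
#' @return \code{writePostureCsv}: \code{path}, invisibly.
#'   \code{readPostureCsv}: a \linkS4class{PostureExperiment}.
#' @export
writePostureCsv <- function(x, path) {
  df <- data.frame(subject_id = subjectIds(x),
                   class_label = classLabels(x),
                   session_idx = sessionIndex(x),
                   postureMatrix(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writePostureCsv
#' @export
readPostureCsv <- function(path, schema = buildSchema()) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "class_label", "session_idx")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("CSV missing columns: ", paste(miss, collapse = ", "))
  feat <- setdiff(names(df), need)
  if (!setequal(feat, schema@featureNames))
    fail("CSV feature columns do not match the 54-feature posture schema")
  PostureExperiment(as.matrix(df[, schema@featureNames]),
                    subjectId = df$subject_id,
                    classLabel = df$class_label,
                    sessionIdx = df$session_idx,
                    schema = schema)
}

#' Extract per-plane vertebral curves for all samples
#'
#' @param x a \linkS4class{PostureExperiment}.
#' @param plane one of \code{"sagittal"}, \code{"coronal"},
#'   \code{"transverse"}.
#' @return an n x 17 matrix of orientation curves (degrees), columns in
#'   level order.
#' @export
planeCurves <- function(x, plane) {
  sch <- postureSchema(x)
  postureMatrix(x)[, planeColumns(sch, plane), drop = FALSE]
}
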