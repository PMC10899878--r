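#' @import methods
NULL

#' PostureSchema: the canonical 54-parameter feature layout
#'
#' Surface-topography posture records carry 54 static parameters in degrees:
#' three pelvic angles (obliquity, inclination at the lumbar dimples,
#' rotation) followed by the orientation of 17 vertebral levels — the
#' vertebra prominens (VP), the twelve thoracic vertebrae T1--T12 and the
#' four lumbar vertebrae L1--L4 — in each of the three anatomical planes
#' (sagittal, coronal, transverse). The schema fixes the feature order used
#' by every matrix in the package: the pelvic block first, then the
#' vertebral block grouped by plane with levels running cranially to
#' caudally (VP, T1, ..., T12, L1, ..., L4) within each plane.
#'
#' @slot featureNames ordered character vector of all 54 feature names.
#' @slot pelvicNames the 3 pelvic feature names.
#' @slot levelOrder the 17 vertebral levels, cranial to caudal.
#' @slot planeOrder the 3 anatomical planes.
#' @exportClass PostureSchema
setClass("PostureSchema", representation(
  featureNames = "character",
  pelvicNames  = "character",
  levelOrder   = "character",
  planeOrder   = "character"
))

setValidity("PostureSchema", function(object) {
  msg <- NULL
  if (length(object@pelvicNames) != 3L) msg <- c(msg, "need exactly 3 pelvic names")
  if (length(object@levelOrder) != 17L) msg <- c(msg, "need exactly 17 vertebral levels")
  if (length(object@planeOrder) != 3L) msg <- c(msg, "need exactly 3 planes")
  if (length(object@featureNames) != 54L) msg <- c(msg, "need exactly 54 feature names")
  if (anyDuplicated(object@featureNames)) msg <- c(msg, "feature names must be unique")
  expected <- c(object@pelvicNames,
                as.vector(vapply(object@planeOrder, function(p)
                  paste(object@levelOrder, p, "deg", sep = "_"), character(17L))))
  if (!identical(object@featureNames, expected))
    msg <- c(msg, "featureNames must be pelvic block then plane-major vertebral block")
  if (is.null(msg)) TRUE else msg
})

#' Build the canonical posture schema
#'
#' @return a \linkS4class{PostureSchema} with the 54 features in canonical
#'   order: \code{pelvic_obliquity_deg}, \code{pelvic_inclination_deg},
#'   \code{pelvic_rotation_deg}, then \code{<level>_<plane>_deg} for the 17
#'   levels within each of the sagittal, coronal and transverse planes.
#' @export
#' @examples
#' sch <- buildSchema()
#' length(featureNames(sch))   # 54
#' head(featureNames(sch), 4)
buildSchema <- function() {
  pelvic <- c("pelvic_obliquity_deg", "pelvic_inclination_deg",
              "pelvic_rotation_deg")
  levels <- c("VP", paste0("T", 1:12), paste0("L", 1:4))
  planes <- c("sagittal", "coronal", "transverse")
  feats <- c(pelvic,
             as.vector(vapply(planes, function(p)
               paste(levels, p, "deg", sep = "_"), character(17L))))
  new("PostureSchema", featureNames = feats, pelvicNames = pelvic,
      levelOrder = levels, planeOrder = planes)
}

#' @describeIn buildSchema ordered feature names of a schema
#' @param schema a \linkS4class{PostureSchema}.
#' @export
featureNames <- function(schema) schema@featureNames

#' @describeIn buildSchema vertebral levels, cranial to caudal
#' @export
levelOrder <- function(schema) schema@levelOrder

#' @describeIn buildSchema anatomical planes in storage order
#' @export
planeOrder <- function(schema) schema@planeOrder

#' @describeIn buildSchema pelvic feature names
#' @export
pelvicNames <- function(schema) schema@pelvicNames

setMethod("show", "PostureSchema", function(object) {
  cat("PostureSchema: 54 features\n")
  cat("  pelvic block :", paste(object@pelvicNames, collapse = ", "), "\n")
  cat("  vertebral    : 17 levels (", object@levelOrder[1], "...",
      object@levelOrder[17], ") x 3 planes (",
      paste(object@planeOrder, collapse = ", "), ")\n")
})

#' Reshape one posture sample into per-plane vertebral curves
#'
#' Splits a 54-vector into its pelvic block and a 3 x 17 matrix of vertebral
#' orientation curves (one row per anatomical plane, columns in level order).
#' The reshape is a pure permutation; \code{curveUnview} is its exact
#' inverse.
#'
#' @param sample numeric vector of length 54 in schema order.
#' @param schema a \linkS4class{PostureSchema} (default \code{buildSchema()}).
#' @return \code{curveView}: a list with \code{curves} (3 x 17 matrix, row
#'   and column names from the schema) and \code{pelvic} (named length-3
#'   vector). \code{curveUnview}: the 54-vector.
#' @export
#' @examples
#' sch <- buildSchema()
#' x <- stats::rnorm(54)
#' cv <- curveView(x, sch)
#' dim(cv$curves)                       # 3 17
#' all.equal(curveUnview(cv, sch), x)   # lossless round trip
curveView <- function(sample, schema = buildSchema()) {
  if (length(sample) != 54L)
    fail("'sample' must have length 54, got ", length(sample))
  x <- as.numeric(sample)
  curves <- matrix(x[-(1:3)], nrow = 3L, ncol = 17L, byrow = TRUE,
                   dimnames = list(schema@planeOrder, schema@levelOrder))
  pelvic <- x[1:3]
  names(pelvic) <- schema@pelvicNames
  list(curves = curves, pelvic = pelvic)
}

#' @rdname curveView
#' @param view a list as returned by \code{curveView}.
#' @export
curveUnview <- function(view, schema = buildSchema()) {
  if (!all(c("curves", "pelvic") %in% names(view)))
    fail("'view' must have elements 'curves' and 'pelvic'")
  if (!all(dim(view$curves) == c(3L, 17L)))
    fail("'curves' must be a 3 x 17 matrix")
  out <- c(as.numeric(view$pelvic), as.vector(t(view$curves)))
  names(out) <- schema@featureNames
  out
}

# column indices of one plane's 17 levels within the 54-feature layout
planeColumns <- function(schema, plane) {
  i <- match(plane, schema@planeOrder)
  if (is.na(i)) fail("unknown plane: ", plane)
  3L + (i - 1L) * 17L + seq_len(17L)
}
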