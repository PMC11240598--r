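#' Shape parameters for a synthetic cell-cluster boundary
#'
#' Parametrizes a star-shaped cluster boundary in polar form
#' \deqn{r(\theta) = R_e(\theta)\,\big(1 + a \sum_{k=1}^{K} k^{-\beta}
#'   (u_k \cos k\theta + v_k \sin k\theta)\big)}
#' where \eqn{R_e(\theta)} is an ellipse with semi-major axis `baseRadius`
#' and eccentricity `eccentricity`, \eqn{a} is `roughnessAmplitude`,
#' \eqn{\beta} is `roughnessExponent` (spectral decay of the boundary
#' harmonics; smaller values give rougher, more fractal-looking outlines),
#' and \eqn{u_k, v_k} are standard-normal draws fixed by `seed`.
#' `roughnessAmplitude = 0` gives an exact ellipse.
#'
#' @slot baseRadius semi-major axis of the unperturbed ellipse, pixels (> 0).
#' @slot eccentricity ellipse eccentricity in \[0, 1).
#' @slot roughnessAmplitude scale of the radial perturbation (>= 0).
#' @slot roughnessExponent spectral decay exponent (> 0).
#' @slot nHarmonics number of Fourier harmonics (>= 0).
#' @slot seed integer seed fixing the harmonic coefficients.
#' @seealso [shapeParams()], [generateClusterMask()]
#' @export
setClass("ClusterShapeParams",
  representation(
    baseRadius = "numeric",
    eccentricity = "numeric",
    roughnessAmplitude = "numeric",
    roughnessExponent = "numeric",
    nHarmonics = "integer",
    seed = "integer"
  )
)

setValidity("ClusterShapeParams", function(object) {
  msg <- character()
  if (length(object@baseRadius) != 1 || !is.finite(object@baseRadius) ||
      object@baseRadius <= 0) {
    msg <- c(msg, "baseRadius must be a single positive number")
  }
  if (object@eccentricity < 0 || object@eccentricity >= 1) {
    msg <- c(msg, "eccentricity must lie in [0, 1)")
  }
  if (object@roughnessAmplitude < 0) {
    msg <- c(msg, "roughnessAmplitude must be >= 0")
  }
  if (object@roughnessExponent <= 0) {
    msg <- c(msg, "roughnessExponent must be > 0")
  }
  if (object@nHarmonics < 0L) msg <- c(msg, "nHarmonics must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct cluster shape parameters
#'
#' @param baseRadius semi-major axis in pixels.
#' @param eccentricity ellipse eccentricity in \[0, 1); 0 gives a circle.
#' @param roughnessAmplitude scale of the radial boundary perturbation;
#'   0 gives an exact ellipse.
#' @param roughnessExponent spectral decay of the perturbation harmonics.
#' @param nHarmonics number of harmonics in the perturbation series.
#' @param seed integer seed fixing the harmonic coefficients.
#' @return A [ClusterShapeParams-class] object.
#' @examples
#' shapeParams(baseRadius = 50, roughnessAmplitude = 0.2, seed = 1)
#' @export
shapeParams <- function(baseRadius, eccentricity = 0,
                        roughnessAmplitude = 0, roughnessExponent = 1.5,
                        nHarmonics = 24L, seed = 1L) {
  new("ClusterShapeParams",
    baseRadius = as.numeric(baseRadius),
    eccentricity = as.numeric(eccentricity),
    roughnessAmplitude = as.numeric(roughnessAmplitude),
    roughnessExponent = as.numeric(roughnessExponent),
    nHarmonics = as.integer(nHarmonics),
    seed = as.integer(seed)
  )
}

setMethod("show", "ClusterShapeParams", function(object) {
  cat("ClusterShapeParams: R =", object@baseRadius,
      "px, e =", object@eccentricity,
      ", a =", object@roughnessAmplitude,
      ", beta =", object@roughnessExponent,
      ", K =", object@nHarmonics,
      ", seed =", object@seed, "\n")
})

#' One microscope field of a liquid-based cytology slide
#'
#' Holds the 8-bit grayscale pixel grid of one field (rows are image rows,
#' values 0-255), the binary mask derived from it (TRUE = cluster
#' foreground), the labeled components, and provenance. Five fields (top,
#' bottom, left, right, center) are captured per specimen; `fieldIndex`
#' records which one this is.
#'
#' @slot gray numeric matrix of 8-bit gray levels in \[0, 255\].
#' @slot mask logical matrix, same dimensions as `gray`; 0x0 when unset.
#' @slot labels integer matrix of component labels (0 = background);
#'   0x0 when unset.
#' @slot fieldIndex integer in 1..5.
#' @slot specimenId character scalar.
#' @slot info list of provenance: threshold method/value, degenerate flag,
#'   and (for synthetic fields) ground-truth cluster masks.
#' @seealso [generateField()], [binarize()], [labelClusters()]
#' @export
setClass("CytoField",
  representation(
    gray = "matrix",
    mask = "matrix",
    labels = "matrix",
    fieldIndex = "integer",
    specimenId = "character",
    info = "list"
  ),
  prototype(
    mask = matrix(logical(0), 0, 0),
    labels = matrix(integer(0), 0, 0),
    fieldIndex = 1L,
    specimenId = "specimen",
    info = list()
  )
)

setValidity("CytoField", function(object) {
  msg <- character()
  g <- object@gray
  if (!length(g)) msg <- c(msg, "gray must be a non-empty matrix")
  if (length(g) && (min(g) < 0 || max(g) > 255)) {
    msg <- c(msg, "gray values must lie in [0, 255]")
  }
  if (length(object@mask) && !identical(dim(object@mask), dim(g))) {
    msg <- c(msg, "mask dimensions must match gray")
  }
  if (length(object@labels) && !identical(dim(object@labels), dim(g))) {
    msg <- c(msg, "labels dimensions must match gray")
  }
  if (!(object@fieldIndex %in% 1:5)) {
    msg <- c(msg, "fieldIndex must be in 1..5")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CytoField
#'
#' @param gray numeric matrix of gray levels in \[0, 255\].
#' @param fieldIndex position of the field on the slide (1..5).
#' @param specimenId specimen identifier.
#' @param mask optional logical foreground mask.
#' @param info optional provenance list.
#' @return A [CytoField-class] object.
#' @export
CytoField <- function(gray, fieldIndex = 1L, specimenId = "specimen",
                      mask = NULL, info = list()) {
  storage.mode(gray) <- "double"
  new("CytoField",
    gray = gray,
    mask = if (is.null(mask)) matrix(logical(0), 0, 0) else mask,
    fieldIndex = as.integer(fieldIndex),
    specimenId = as.character(specimenId),
    info = info
  )
}

setMethod("show", "CytoField", function(object) {
  d <- dim(object@gray)
  cat("CytoField", object@specimenId, "field", object@fieldIndex,
      sprintf("(%d x %d px)", d[1], d[2]), "\n")
  if (length(object@mask)) {
    cat("  mask: ", sum(object@mask), " foreground px", sep = "")
    if (!is.null(object@info$threshold)) {
      cat(sprintf(" [%s threshold = %.1f]",
                  object@info$method, object@info$threshold))
    }
    cat("\n")
  }
  if (length(object@labels)) {
    cat("  labels:", max(object@labels), "components\n")
  }
})

#' Cohort container: specimen morphometry plus clinical metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `morphometry` assay
#' is the feature x patient matrix of specimen-level descriptors (five-field
#' averages) and whose `colData` carries the clinical variables: `age`
#' (years), `cytology` (negative / suspicious_positive / positive),
#' `histology` (Normal, EH, AEH, EM_G1, EM_G2, EM_G3, Others),
#' `time_months` and `event` for overall survival.
#'
#' @seealso [CytometryExperiment()], [generateCohort()]
#' @export
setClass("CytometryExperiment", contains = "SummarizedExperiment")

.HISTOLOGY_LEVELS <- c("Normal", "EH", "AEH", "EM_G1", "EM_G2", "EM_G3", "Others")
.CYTOLOGY_LEVELS <- c("negative", "suspicious_positive", "positive")
.FEATURE_NAMES <- c(
  "area", "perimeter", "circularity", "fit_ellipse_major",
  "fit_ellipse_minor", "angle", "solidity", "feret_max", "feret_min",
  "cluster_count", "fractal_dimension"
)

setValidity("CytometryExperiment", function(object) {
  msg <- character()
  if (!"morphometry" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'morphometry' is required")
  }
  cd <- colData(object)
  need <- c("age", "cytology", "histology", "time_months", "event")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  }
  if ("histology" %in% colnames(cd) &&
      !all(as.character(cd$histology) %in% .HISTOLOGY_LEVELS)) {
    msg <- c(msg, "histology outside the seven recognized classes")
  }
  if ("cytology" %in% colnames(cd) &&
      !all(as.character(cd$cytology) %in% .CYTOLOGY_LEVELS)) {
    msg <- c(msg, "cytology outside the three-tier reporting categories")
  }
  if ("time_months" %in% colnames(cd) && any(cd$time_months < 0)) {
    msg <- c(msg, "time_months must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CytometryExperiment
#'
#' @param features numeric matrix, features x patients (rows named by
#'   descriptor, columns by patient id).
#' @param meta data.frame of clinical metadata, one row per patient, with
#'   columns `age`, `cytology`, `histology`, `time_months`, `event`.
#' @param metadata optional list stored in the object metadata (e.g. the
#'   generating configuration).
#' @return A [CytometryExperiment-class].
#' @export
CytometryExperiment <- function(features, meta, metadata = list()) {
  meta$cytology <- factor(as.character(meta$cytology), levels = .CYTOLOGY_LEVELS)
  meta$histology <- factor(as.character(meta$histology), levels = .HISTOLOGY_LEVELS)
  se <- SummarizedExperiment(
    assays = list(morphometry = as.matrix(features)),
    colData = DataFrame(meta, row.names = colnames(features)),
    metadata = metadata
  )
  new("CytometryExperiment", se)
}

#' @describeIn CytometryExperiment the feature x patient morphometry matrix.
#' @param x a `CytometryExperiment`.
#' @export
morphometry <- function(x) assay(x, "morphometry")

#' @describeIn CytometryExperiment histology class per patient.
#' @export
histologyClass <- function(x) colData(x)$histology

setMethod("show", "CytometryExperiment", function(object) {
  callNextMethod()
  tab <- table(histologyClass(object))
  cat("histology:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("events:", sum(colData(object)$event), "of", ncol(object), "\n")
})
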