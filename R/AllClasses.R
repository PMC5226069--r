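#' @import methods
#' @importFrom stats sd var rnorm runif qf pf pt pchisq shapiro.test t.test chisq.test aov anova setNames quantile cor complete.cases
#' @importFrom grDevices contourLines
#' @importFrom utils head tail write.csv read.csv
NULL

#' Labelled short-axis segmentation stack
#'
#' Voxelised label volume of a short-axis cine stack at end-diastole.
#' Labels follow the package convention: 0 background, 1 RV myocardium
#' (septum included, LV free wall excluded), 2 RV cavity (trabeculations
#' excluded), 3 LV landmark marked on the most basal slice.  Slices are
#' stored base-to-apex along the third array dimension.
#'
#' @slot labels integer 3D array (nx, ny, nslices).
#' @slot voxelSize numeric length-2, in-plane voxel size in mm.
#' @slot sliceSpacing numeric, effective slice spacing (thickness + gap) in mm.
#' @slot legend named integer vector mapping label names to codes.
#'
#' @exportClass SegmentationStack
setClass("SegmentationStack",
  representation(
    labels = "array",
    voxelSize = "numeric",
    sliceSpacing = "numeric",
    legend = "integer"
  )
)

setValidity("SegmentationStack", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (length(object@voxelSize) != 2L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be two positive numbers (mm)")
  if (length(object@sliceSpacing) != 1L || object@sliceSpacing <= 0)
    msg <- c(msg, "sliceSpacing must be a single positive number (mm)")
  if (is.null(msg)) TRUE else msg
})

#' Corresponded endo/epicardial surface mesh
#'
#' Fixed-topology right-ventricular surface pair with point correspondence
#' across subjects.  Vertices are stored as ring grids: \code{nTheta}
#' circumferential positions times \code{nRings} long-axis rings, base first,
#' for the endocardial and epicardial surfaces separately.  The flattened
#' shape vector is the concatenation endo-then-epi of per-vertex (x, y, z),
#' giving 3456 entries at the default 24 x 24 resolution.
#'
#' @slot endo numeric matrix (nTheta*nRings, 3), endocardial vertices in mm.
#' @slot epi numeric matrix, same shape, epicardial vertices.
#' @slot nTheta integer, circumferential samples per ring.
#' @slot nRings integer, number of rings base to apex.
#' @slot septalMask logical vector over ring-grid vertices; TRUE for septal
#'   vertices (facing the LV remnant).
#' @slot lvLandmark numeric length-3, LV landmark anchor point in mm.
#' @slot fittingError numeric, mean point-to-surface fitting error in mm
#'   (NA for template/synthetic meshes).
#'
#' @exportClass CorrespondedMesh
setClass("CorrespondedMesh",
  representation(
    endo = "matrix",
    epi = "matrix",
    nTheta = "integer",
    nRings = "integer",
    septalMask = "logical",
    lvLandmark = "numeric",
    fittingError = "numeric"
  )
)

setValidity("CorrespondedMesh", function(object) {
  msg <- NULL
  nv <- object@nTheta * object@nRings
  if (nrow(object@endo) != nv || ncol(object@endo) != 3L)
    msg <- c(msg, "endo must be an (nTheta*nRings) x 3 matrix")
  if (nrow(object@epi) != nv || ncol(object@epi) != 3L)
    msg <- c(msg, "epi must be an (nTheta*nRings) x 3 matrix")
  if (length(object@septalMask) != nv)
    msg <- c(msg, "septalMask must have one entry per vertex")
  if (length(object@lvLandmark) != 3L)
    msg <- c(msg, "lvLandmark must be a length-3 point")
  if (any(!is.finite(object@endo)) || any(!is.finite(object@epi)))
    msg <- c(msg, "vertex coordinates must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Tracked boundary contour sequence
#'
#' Ordered boundary points over the cardiac cycle at one imaging level.
#' Frame 0 (the first frame) is the Lagrangian reference (end-diastole for
#' generator output).  Short-axis contours are closed; the four-chamber
#' contour is an open base-apex-base polyline.
#'
#' @slot points numeric 3D array (frames, points, 2), in-plane mm.
#' @slot frameInterval numeric, seconds between frames.
#' @slot level character, one of "4ch", "basal", "mid", "apical".
#' @slot surface character, "endo" or "epi".
#' @slot closed logical, TRUE for short-axis contours.
#'
#' @exportClass ContourSequence
setClass("ContourSequence",
  representation(
    points = "array",
    frameInterval = "numeric",
    level = "character",
    surface = "character",
    closed = "logical"
  )
)

setValidity("ContourSequence", function(object) {
  msg <- NULL
  d <- dim(object@points)
  if (length(d) != 3L || d[3] != 2L)
    msg <- c(msg, "points must be a (frames, points, 2) array")
  if (!object@level %in% c("4ch", "basal", "mid", "apical"))
    msg <- c(msg, "level must be one of 4ch/basal/mid/apical")
  if (!object@surface %in% c("endo", "epi"))
    msg <- c(msg, "surface must be endo or epi")
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Statistical shape atlas
#'
#' Principal-component atlas of a population of shape vectors: the mean
#' shape, orthonormal anatomical modes, per-mode variances (eigenvalues of
#' the sample covariance) and per-subject mode scores.
#'
#' @slot mean numeric vector (3456 at default resolution).
#' @slot modes numeric matrix (length(mean) x K), orthonormal columns.
#' @slot eigenvalues numeric length-K, non-increasing, per-mode variance.
#' @slot allEigenvalues numeric, the full positive spectrum (for explained
#'   variance denominators).
#' @slot scores numeric matrix (N x K), column means zero.
#' @slot K integer, number of retained modes.
#'
#' @exportClass ShapeAtlas
setClass("ShapeAtlas",
  representation(
    mean = "numeric",
    modes = "matrix",
    eigenvalues = "numeric",
    allEigenvalues = "numeric",
    scores = "matrix",
    K = "integer"
  )
)

setValidity("ShapeAtlas", function(object) {
  msg <- NULL
  K <- object@K
  if (ncol(object@modes) != K || length(object@eigenvalues) != K)
    msg <- c(msg, "modes/eigenvalues must match K")
  G <- crossprod(object@modes)
  if (max(abs(G - diag(K))) > 1e-8)
    msg <- c(msg, "modes must be orthonormal (Gram matrix != identity)")
  if (any(object@eigenvalues < -1e-12))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (K > 1 && any(diff(object@eigenvalues) > 1e-8 * object@eigenvalues[1]))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (nrow(object@scores) > 0 &&
      max(abs(colMeans(object@scores))) > 1e-8 * (1 + max(abs(object@scores))))
    msg <- c(msg, "score columns must be mean-centred")
  if (is.null(msg)) TRUE else msg
})

#' Strain and strain-rate analysis result
#'
#' Per-segment and global Lagrangian strain curves (percent, relative to
#' frame 0) with strain-rate curves (1/s) and systolic/diastolic peaks, for
#' one direction at one level.
#'
#' @slot direction character, "circumferential", "longitudinal" or "radial".
#' @slot level character.
#' @slot time numeric, frame times in seconds.
#' @slot segmentStrain matrix (frames x segments), percent.
#' @slot globalStrain numeric, percent; the arithmetic mean of segments.
#' @slot segmentRate matrix (frames x segments), 1/s.
#' @slot globalRate numeric, 1/s.
#' @slot peaks named numeric: systolic_strain_pct, systolic_rate_per_s,
#'   diastolic_rate_per_s.
#' @slot radialMethod character, "centroid", "thickness" or NA.
#'
#' @exportClass StrainResult
setClass("StrainResult",
  representation(
    direction = "character",
    level = "character",
    time = "numeric",
    segmentStrain = "matrix",
    globalStrain = "numeric",
    segmentRate = "matrix",
    globalRate = "numeric",
    peaks = "numeric",
    radialMethod = "character"
  )
)

setValidity("StrainResult", function(object) {
  msg <- NULL
  if (abs(object@globalStrain[1]) > 1e-9)
    msg <- c(msg, "strain at frame 0 must be 0")
  if (max(abs(object@globalStrain - rowMeans(object@segmentStrain))) > 1e-9)
    msg <- c(msg, "global strain must equal the mean of segments")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SegmentationStack", function(object) {
  d <- dim(object@labels)
  cat("SegmentationStack:", d[1], "x", d[2], "x", d[3], "voxels\n")
  cat("  in-plane", paste(object@voxelSize, collapse = " x "),
      "mm, slice spacing", object@sliceSpacing, "mm\n")
  tab <- table(factor(object@labels, levels = sort(unique(object@legend))))
  names(tab) <- names(object@legend)[match(names(tab), as.character(object@legend))]
  cat("  label voxels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CorrespondedMesh", function(object) {
  cat("CorrespondedMesh:", object@nTheta, "x", object@nRings,
      "ring grid per surface (", 2L * object@nTheta * object@nRings,
      "vertices )\n")
  cat("  shape vector length:", 6L * object@nTheta * object@nRings, "\n")
  if (!is.na(object@fittingError))
    cat("  fitting error:", signif(object@fittingError, 4), "mm\n")
})

setMethod("show", "ShapeAtlas", function(object) {
  cat("ShapeAtlas:", nrow(object@scores), "subjects,",
      length(object@mean), "variables reduced to", object@K, "modes\n")
  ev <- cumsum(object@eigenvalues) / sum(object@allEigenvalues)
  cat("  explained variance at K:", sprintf("%.1f%%", 100 * ev[object@K]), "\n")
})

setMethod("show", "ContourSequence", function(object) {
  d <- dim(object@points)
  cat("ContourSequence:", object@level, object@surface, "-", d[1], "frames x",
      d[2], "points,", if (object@closed) "closed" else "open", "\n")
})

setMethod("show", "StrainResult", function(object) {
  cat("StrainResult:", object@direction, "strain at", object@level, "level\n")
  cat("  peaks: systolic strain", sprintf("%.2f%%", object@peaks["systolic_strain_pct"]),
      ", systolic rate", sprintf("%.3f 1/s", object@peaks["systolic_rate_per_s"]),
      ", diastolic rate", sprintf("%.3f 1/s", object@peaks["diastolic_rate_per_s"]), "\n")
})

# ---- accessors ----

#' Accessors for rvatlas objects
#'
#' Small read-only accessors for the S4 containers.
#'
#' @param x an rvatlas object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
stackLabels <- function(x) x@labels

#' @rdname accessors
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname accessors
#' @export
sliceSpacing <- function(x) x@sliceSpacing

#' @rdname accessors
#' @export
endoVertices <- function(x) x@endo

#' @rdname accessors
#' @export
epiVertices <- function(x) x@epi

#' @rdname accessors
#' @export
septalMask <- function(x) x@septalMask

#' @rdname accessors
#' @export
fittingError <- function(x) x@fittingError

#' @rdname accessors
#' @export
atlasMean <- function(x) x@mean

#' @rdname accessors
#' @export
atlasModes <- function(x) x@modes

#' @rdname accessors
#' @export
atlasEigenvalues <- function(x) x@eigenvalues

#' @rdname accessors
#' @export
atlasScores <- function(x) x@scores

#' @rdname accessors
#' @export
contourPoints <- function(x) x@points

#' @rdname accessors
#' @export
strainPeaks <- function(x) x@peaks

#' @rdname accessors
#' @export
globalStrain <- function(x) x@globalStrain

#' @rdname accessors
#' @export
globalStrainRate <- function(x) x@globalRate
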