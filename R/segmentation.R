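# Loading label stacks, extracting half-voxel iso-contours and rigid pose
# standardization.  The pose convention matches the template: base cavity
# centre at the origin, long axis along z with the apex at negative z, and
# the LV landmark direction along +x.  Alignment is rigid only (rotation +
# translation, no scaling): ventricular size must survive into the atlas.

#' Load a segmentation stack from NIfTI
#'
#' Reads a label volume, validates the label content and normalises the
#' slice order so the landmark-bearing (most basal) slice is index 1.
#'
#' @param path NIfTI file (\code{.nii} / \code{.nii.gz}).
#' @param legend named integer label legend; defaults to the package
#'   convention.
#' @return A [SegmentationStack-class].
#' @export
loadSegmentation <- function(path, legend = .LABELS) {
  nii <- readNifti(path)
  lab <- nii$data
  storage.mode(lab) <- "integer"
  stack <- new("SegmentationStack", labels = lab,
               voxelSize = nii$pixdim[1:2], sliceSpacing = nii$pixdim[3],
               legend = legend)
  .normalizeSliceOrder(.checkStack(stack))
}

.checkStack <- function(stack) {
  lab <- stack@labels
  lg <- stack@legend
  rvSlices <- apply(lab, 3, function(m)
    any(m == lg[["myocardium"]] | m == lg[["cavity"]]))
  if (!any(rvSlices)) stop("empty segmentation: no RV labels present")
  if (sum(rvSlices) < 3L)
    stop("empty segmentation: RV labels on fewer than 3 slices")
  lmSlices <- which(apply(lab, 3, function(m) any(m == lg[["lv_landmark"]])))
  if (length(lmSlices) == 0L) stop("missing landmark: no LV landmark label")
  if (length(lmSlices) > 1L)
    stop("ambiguous landmark: LV landmark label on ", length(lmSlices),
         " slices")
  stack
}

.normalizeSliceOrder <- function(stack) {
  lg <- stack@legend
  lm <- which(apply(stack@labels, 3, function(m) any(m == lg[["lv_landmark"]])))
  nS <- dim(stack@labels)[3]
  if (lm == 1L) return(stack)
  if (lm == nS) {
    stack@labels <- stack@labels[, , rev(seq_len(nS)), drop = FALSE]
    return(stack)
  }
  stop("landmark slice is neither first nor last; cannot normalise order")
}

#' Write a segmentation stack to NIfTI
#'
#' @param stack a [SegmentationStack-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSegmentation <- function(stack, path) {
  writeNifti(stack@labels, path,
             pixdim = c(stack@voxelSize, stack@sliceSpacing))
}

# half-voxel iso-contours of a binary mask on one slice, in mm coordinates
.sliceContours <- function(mask, voxelSize) {
  nx <- nrow(mask); ny <- ncol(mask)
  xs <- (seq_len(nx) - 0.5) * voxelSize[1]
  ys <- (seq_len(ny) - 0.5) * voxelSize[2]
  cl <- contourLines(xs, ys, mask + 0, levels = 0.5)
  lapply(cl, function(co) cbind(co$x, co$y))
}

#' Extract boundary point clouds from a stack
#'
#' Half-voxel iso-contours of the cavity (endocardial) and cavity-plus-
#' myocardium (epicardial) masks on every slice, in mm, with slice z
#' coordinates decreasing from the base (slice 1, z = 0).
#'
#' @param stack a [SegmentationStack-class].
#' @return List with \code{endo}, \code{epi} (matrices x, y, z),
#'   \code{landmark} (length-3 centroid) and \code{sliceZ}.
#' @export
boundaryPoints <- function(stack) {
  lg <- stack@legend
  lab <- stack@labels
  nS <- dim(lab)[3]
  zs <- -(seq_len(nS) - 1) * stack@sliceSpacing
  endo <- list(); epi <- list()
  for (s in seq_len(nS)) {
    sl <- lab[, , s]
    cavity <- sl == lg[["cavity"]]
    muscle <- cavity | sl == lg[["myocardium"]]
    if (any(cavity))
      endo[[length(endo) + 1L]] <- do.call(rbind, lapply(
        .sliceContours(cavity, stack@voxelSize),
        function(p) cbind(p, zs[s], s)))
    if (any(muscle))
      epi[[length(epi) + 1L]] <- do.call(rbind, lapply(
        .sliceContours(muscle, stack@voxelSize),
        function(p) cbind(p, zs[s], s)))
  }
  lmIdx <- which(lab == lg[["lv_landmark"]], arr.ind = TRUE)
  landmark <- if (nrow(lmIdx) > 0) {
    c((mean(lmIdx[, 1]) - 0.5) * stack@voxelSize[1],
      (mean(lmIdx[, 2]) - 0.5) * stack@voxelSize[2],
      zs[round(mean(lmIdx[, 3]))])
  } else rep(NA_real_, 3)
  list(endo = do.call(rbind, endo), epi = do.call(rbind, epi),
       landmark = landmark, sliceZ = zs)
}

# rigid frame from per-slice (or per-ring) centroids + landmark: the long
# axis is the principal direction of the centroid line, which is robust even
# when the ventricular diameter exceeds its length; rows of R are the
# standard axes
.poseFrame <- function(centers, landmark) {
  cen <- colMeans(centers)
  pc <- eigen(cov(centers), symmetric = TRUE)
  e3 <- pc$vectors[, 1]                       # centroid-line direction
  # orient towards the base: the landmark sits beside the basal slice
  if (sum((landmark - cen) * e3) < 0) e3 <- -e3
  w <- landmark - cen
  w <- w - sum(w * e3) * e3
  if (sqrt(sum(w^2)) < 1e-9)
    stop("degenerate landmark direction: landmark lies on the long axis")
  e1 <- w / sqrt(sum(w^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  R <- rbind(e1, e2, e3, deparse.level = 0)
  list(R = R, center = cen)
}

#' Standardize the pose of a segmentation stack
#'
#' Rigid-only (rotation + translation, no scaling) alignment of the boundary
#' point clouds into the template frame: long axis to z (apex negative), LV
#' landmark direction to +x, basal cavity centre at the origin.  Volumes are
#' preserved exactly (rigid isometry).
#'
#' @param stack a [SegmentationStack-class] (or the output of
#'   [boundaryPoints()]).
#' @return List with transformed \code{endo}, \code{epi}, \code{landmark},
#'   and the rigid \code{transform} (rotation \code{R}, translation
#'   \code{t}; applied as \code{R \%*\% (p - t)}).
#' @export
standardizePose <- function(stack) {
  bnd <- if (is(stack, "SegmentationStack")) boundaryPoints(stack) else stack
  sliceId <- if (ncol(bnd$epi) >= 4L) bnd$epi[, 4] else round(bnd$epi[, 3], 6)
  centers <- do.call(rbind, lapply(split(seq_len(nrow(bnd$epi)), sliceId),
    function(ix) colMeans(bnd$epi[ix, 1:3, drop = FALSE])))
  if (nrow(centers) < 2L)
    stop("degenerate long axis: all boundary mass in one slice")
  frame <- .poseFrame(centers, bnd$landmark)
  apply3 <- function(P) {
    out <- t(frame$R %*% (t(P[, 1:3, drop = FALSE]) - frame$center))
    if (ncol(P) > 3L) out <- cbind(out, P[, 4])
    out
  }
  endo <- apply3(bnd$endo); epi <- apply3(bnd$epi)
  lm <- as.numeric(frame$R %*% (bnd$landmark - frame$center))
  # origin at the basal cavity contour centre (slice-group based so that
  # re-standardization is exactly idempotent)
  sliceIdE <- if (ncol(endo) >= 4L) endo[, 4] else round(endo[, 3], 6)
  gE <- split(seq_len(nrow(endo)), sliceIdE)
  zOfE <- vapply(gE, function(ix) mean(endo[ix, 3]), numeric(1))
  basal <- endo[gE[[which.max(zOfE)]], , drop = FALSE]
  shift <- c(mean(basal[, 1]), mean(basal[, 2]), max(zOfE))
  shiftP <- if (ncol(endo) > 3L) c(shift, 0) else shift
  endo <- sweep(endo, 2, shiftP)
  epi <- sweep(epi, 2, shiftP)
  lm <- lm - shift
  list(endo = endo, epi = epi, landmark = lm,
       transform = list(R = frame$R,
                        t = frame$center + as.numeric(t(frame$R) %*% shift)))
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [CorrespondedMesh-class].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation, applied after rotation.
#' @return The transformed mesh.
#' @export
applyRigid <- function(mesh, R, t = c(0, 0, 0)) {
  tr <- function(P) sweep(P %*% t(R), 2, -t)
  initialize(mesh, endo = tr(mesh@endo), epi = tr(mesh@epi),
             lvLandmark = as.numeric(R %*% mesh@lvLandmark + t))
}

#' Standardize the pose of a mesh
#'
#' Mesh-level analogue of [standardizePose()], using the vertex cloud and
#' the stored LV landmark.
#'
#' @param mesh a [CorrespondedMesh-class].
#' @return The mesh in standard pose.
#' @export
standardizeMeshPose <- function(mesh) {
  nT <- mesh@nTheta
  centers <- t(vapply(seq_len(mesh@nRings), function(j)
    colMeans(mesh@epi[(j - 1L) * nT + seq_len(nT), , drop = FALSE]),
    numeric(3)))
  frame <- .poseFrame(centers, mesh@lvLandmark)
  apply3 <- function(P) t(frame$R %*% (t(P) - frame$center))
  endo <- apply3(mesh@endo); epi <- apply3(mesh@epi)
  lm <- as.numeric(frame$R %*% (mesh@lvLandmark - frame$center))
  nTheta <- mesh@nTheta
  basal <- endo[seq_len(nTheta), , drop = FALSE]
  shift <- c(mean(basal[, 1]), mean(basal[, 2]), mean(basal[, 3]))
  initialize(mesh,
             endo = sweep(endo, 2, shift), epi = sweep(epi, 2, shift),
             lvLandmark = lm - shift)
}
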