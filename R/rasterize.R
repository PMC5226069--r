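# Voxelisation of corresponded meshes into short-axis label stacks.
# Cross-sections are obtained by interpolating the ring grid at each slice
# plane; in-plane membership is an even-odd polygon test on voxel centres.

.LABELS <- c(background = 0L, myocardium = 1L, cavity = 2L, lv_landmark = 3L)

# even-odd point-in-polygon, vectorised over points
.inPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# interpolate the ring-grid surface polygon at height z (NULL beyond extent)
.slicePolygon <- function(V, nTheta, nRings, z) {
  zr <- colMeans(matrix(V[, 3], nTheta, nRings))   # per-ring mean z
  if (z > zr[1] + 1e-9) {
    if (z > zr[1] + abs(zr[nRings] - zr[1]) * 0.02) return(NULL)
    z <- zr[1]
  }
  if (z < zr[nRings]) return(NULL)
  j <- findInterval(-z, -zr)                       # zr is decreasing
  j <- min(max(j, 1L), nRings - 1L)
  w <- if (abs(zr[j + 1] - zr[j]) < 1e-12) 0 else (zr[j] - z) / (zr[j] - zr[j + 1])
  a <- V[(j - 1L) * nTheta + seq_len(nTheta), 1:2, drop = FALSE]
  b <- V[j * nTheta + seq_len(nTheta), 1:2, drop = FALSE]
  (1 - w) * a + w * b
}

#' Rasterize a mesh into a labelled short-axis stack
#'
#' Voxelises the endo/epicardial pair into a label volume with the package's
#' label convention (0 background, 1 RV myocardium, 2 RV cavity, 3 LV
#' landmark).  Slices are ordered base to apex; the LV landmark is drawn as
#' a small disc on the most basal slice only.  All-background slices beyond
#' the apex are trimmed.
#'
#' @param mesh a [CorrespondedMesh-class].
#' @param voxel_mm in-plane voxel size (mm).
#' @param slice_thickness_mm effective slice spacing (thickness + gap, mm).
#' @param landmark draw the LV landmark disc (default TRUE).
#' @return A [SegmentationStack-class].
#' @export
rasterizeSegmentation <- function(mesh, voxel_mm = 1.5,
                                  slice_thickness_mm = 2 * voxel_mm,
                                  landmark = TRUE) {
  stopifnot(is(mesh, "CorrespondedMesh"))
  if (voxel_mm <= 0 || slice_thickness_mm <= 0)
    stop("voxel_mm and slice_thickness_mm must be positive")
  allV <- rbind(mesh@endo, mesh@epi)
  zmax <- max(allV[, 3]); zmin <- min(allV[, 3])
  extent <- zmax - zmin
  if (slice_thickness_mm >= extent)
    stop("slice thickness (", slice_thickness_mm,
         " mm) exceeds the long-axis extent (", signif(extent, 4), " mm)")
  margin <- 4 * voxel_mm
  xr <- range(c(allV[, 1], mesh@lvLandmark[1])) + c(-margin, margin)
  yr <- range(c(allV[, 2], mesh@lvLandmark[2])) + c(-margin, margin)
  nx <- ceiling(diff(xr) / voxel_mm)
  ny <- ceiling(diff(yr) / voxel_mm)
  xs <- xr[1] + (seq_len(nx) - 0.5) * voxel_mm
  ys <- yr[1] + (seq_len(ny) - 0.5) * voxel_mm
  nS <- ceiling(extent / slice_thickness_mm)
  grid <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  vol <- array(0L, dim = c(nx, ny, nS))
  for (s in seq_len(nS)) {
    z <- zmax - (s - 0.5) * slice_thickness_mm
    polyEpi <- .slicePolygon(mesh@epi, mesh@nTheta, mesh@nRings, z)
    polyEndo <- .slicePolygon(mesh@endo, mesh@nTheta, mesh@nRings, z)
    sl <- rep(0L, nx * ny)
    if (!is.null(polyEpi)) sl[.inPolygon(grid[, 1], grid[, 2], polyEpi)] <- 1L
    if (!is.null(polyEndo)) sl[.inPolygon(grid[, 1], grid[, 2], polyEndo)] <- 2L
    vol[, , s] <- sl
  }
  if (landmark && all(is.finite(mesh@lvLandmark))) {
    d2 <- (grid[, 1] - mesh@lvLandmark[1])^2 + (grid[, 2] - mesh@lvLandmark[2])^2
    disc <- d2 <= 3^2
    sl <- vol[, , 1]
    sl[disc & sl == 0L] <- 3L
    vol[, , 1] <- sl
  }
  keep <- which(apply(vol, 3, function(m) any(m != 0L)))
  vol <- vol[, , seq_len(max(keep)), drop = FALSE]
  new("SegmentationStack", labels = vol,
      voxelSize = c(voxel_mm, voxel_mm), sliceSpacing = slice_thickness_mm,
      legend = .LABELS)
}

#' Voxel-count volume of a label
#'
#' @param stack a [SegmentationStack-class].
#' @param label label name (per the stack legend) or integer code.
#' @return Volume in mm^3 (voxel count times voxel volume, with the slice
#'   spacing as the through-plane dimension).
#' @export
labelVolume <- function(stack, label = "cavity") {
  code <- if (is.character(label)) stack@legend[[label]] else as.integer(label)
  n <- sum(stack@labels == code)
  n * prod(stack@voxelSize) * stack@sliceSpacing
}

# ---- analytic test solids with the same ring-grid topology ----

#' Ring-grid ellipsoid / cylinder meshes for validation
#'
#' Analytic solids expressed in the package's ring-grid mesh topology, used
#' to validate rasterisation and volumetry against closed-form volumes.
#' The "epi" surface is a uniform outward offset so the cavity label equals
#' the requested solid.
#'
#' @param a,b,c ellipsoid semi-axes (mm); \code{c} is along the slice
#'   normal.
#' @param radius,height cylinder radius and height (mm).
#' @param wall offset to the epicardial surface (mm).
#' @param nTheta,nRings grid resolution.
#' @return A [CorrespondedMesh-class].
#' @name testSolids
NULL

#' @rdname testSolids
#' @export
makeEllipsoidMesh <- function(a, b = a, c = a, wall = 3,
                              nTheta = 64L, nRings = 64L) {
  phi <- (seq_len(nRings) - 0.5) * pi / nRings
  th <- .ringTheta(nTheta)
  surf <- function(ax, by, cz) {
    f <- rep(sin(phi), each = nTheta)
    zz <- rep(cz * cos(phi), each = nTheta)
    thth <- rep(th, times = nRings)
    cbind(ax * f * cos(thth), by * f * sin(thth), zz)
  }
  new("CorrespondedMesh",
      endo = surf(a, b, c), epi = surf(a + wall, b + wall, c + wall),
      nTheta = as.integer(nTheta), nRings = as.integer(nRings),
      septalMask = rep(cos(rep(th, nRings)) > 0.5, 1),
      lvLandmark = c(a + wall + 10, 0, c * cos(pi / (2 * nRings))),
      fittingError = NA_real_)
}

#' @rdname testSolids
#' @export
makeCylinderMesh <- function(radius, height, wall = 3,
                             nTheta = 64L, nRings = 32L) {
  t <- seq(0, 1, length.out = nRings)
  th <- .ringTheta(nTheta)
  surf <- function(r, h) {
    thth <- rep(th, times = nRings)
    cbind(r * cos(thth), r * sin(thth), rep(-h * t, each = nTheta))
  }
  new("CorrespondedMesh",
      endo = surf(radius, height), epi = surf(radius + wall, height + wall),
      nTheta = as.integer(nTheta), nRings = as.integer(nRings),
      septalMask = rep(cos(rep(th, nRings)) > 0.5, 1),
      lvLandmark = c(radius + wall + 10, 0, 0),
      fittingError = NA_real_)
}
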