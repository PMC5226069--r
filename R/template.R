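# Template geometry: the systemic RV is idealised as a half-ellipsoid with a
# crescent (limacon) cross-section, so every geometric property has a
# closed-form or finely-integrable reference value.  The ring grid has
# nTheta circumferential samples and nRings long-axis rings per surface;
# the default 24 x 24 grid over endo + epi gives 1152 vertices and a
# 3456-entry shape vector.

.TEMPLATE_DEFAULTS <- list(
  nTheta = 24L, nRings = 24L,
  cavityRadius = 18, length = 45, wall = 4, crescent = 0.3
)

.ringT <- function(nRings) (seq_len(nRings) - 1) / nRings   # t=0 base ring

.ringTheta <- function(nTheta) 2 * pi * (seq_len(nTheta) - 1) / nTheta

# crescent radial modulation; smallest radius faces the LV at +x
.crescentG <- function(theta, kappa) 1 - kappa * cos(theta)

# surface points for given radial scale Rc, axial length L; `offset` adds a
# uniform in-plane thickness (the epicardium is the endocardial section plus
# a uniform wall)
.surfaceGrid <- function(nTheta, nRings, Rc, L, kappa, offset = 0) {
  t <- .ringT(nRings)
  th <- .ringTheta(nTheta)
  f <- sqrt(pmax(0, 1 - t^2))
  # vertex order: ring-major, theta within ring (base ring first)
  tt <- rep(t, each = nTheta)
  ff <- rep(f, each = nTheta)
  thth <- rep(th, times = nRings)
  g <- .crescentG(thth, kappa)
  r <- Rc * ff * g + offset
  cbind(x = r * cos(thth), y = r * sin(thth), z = -L * tt)
}

#' Generate the corresponded RV template mesh
#'
#' Builds the fixed-topology template used for synthesis and personalization:
#' a crescent-section half-ellipsoid endo/epicardial pair with an LV landmark
#' anchor on the basal plane and a labelled septal vertex subset.  The
#' default resolution (24 circumferential x 24 rings per surface) yields
#' 1152 corresponded vertices, i.e. a 3456-entry shape vector.
#'
#' @param nTheta circumferential samples per ring (default 24).
#' @param nRings rings base to apex per surface (default 24).
#' @param cavityRadius basal endocardial radius scale in mm.
#' @param length base-to-apex cavity length in mm.
#' @param wall wall thickness scale in mm.
#' @param crescent limacon crescent factor in [0, 1); 0 gives circular
#'   sections.
#' @return A [CorrespondedMesh-class].
#' @export
generateTemplate <- function(nTheta = 24L, nRings = 24L,
                             cavityRadius = 18, length = 45,
                             wall = 4, crescent = 0.3) {
  nTheta <- as.integer(nTheta); nRings <- as.integer(nRings)
  if (nTheta < 3L || nRings < 3L)
    stop("template resolution must have at least 3 samples per direction")
  if (cavityRadius <= 0 || length <= 0 || wall <= 0)
    stop("cavityRadius, length and wall must be positive")
  if (crescent < 0 || crescent >= 1)
    stop("crescent factor must be in [0, 1)")
  endo <- .surfaceGrid(nTheta, nRings, cavityRadius, length, crescent)
  epi <- .surfaceGrid(nTheta, nRings, cavityRadius, length + wall, crescent,
                      offset = wall)
  th <- rep(.ringTheta(nTheta), times = nRings)
  septal <- cos(th) > 0.5          # vertices within 60 degrees of +x (LV side)
  lv <- c(1.4 * (cavityRadius + wall), 0, 0)
  new("CorrespondedMesh", endo = endo, epi = epi,
      nTheta = nTheta, nRings = nRings, septalMask = septal,
      lvLandmark = lv, fittingError = NA_real_)
}

#' Shape deformation parameters
#'
#' Generative analogue of a single anatomical deformation: global dilation,
#' sphericity (long-axis length relative to diameter), basal widening, apex
#' tilt, wall thickness and vertex noise.  Identity is all factors 1, tilt 0,
#' noise 0.
#'
#' @param dilation_scale unitless global scale (> 0); cavity volume scales
#'   with its cube.
#' @param sphericity_factor unitless long-axis stretch (> 0); lower values
#'   give a rounder (more spherical) ventricle.
#' @param base_width_factor unitless basal in-plane widening (> 0), tapering
#'   linearly to no effect at the apex.
#' @param apex_tilt_deg apex shear angle in degrees (towards +x).
#' @param wall_thickness_mm wall thickness in mm (> 0); template default 4.
#' @param noise_sd_mm standard deviation of vertex noise along outward
#'   normals, mm (>= 0).
#' @return A validated list of class "ShapeParams".
#' @export
shapeParams <- function(dilation_scale = 1, sphericity_factor = 1,
                        base_width_factor = 1, apex_tilt_deg = 0,
                        wall_thickness_mm = 4, noise_sd_mm = 0) {
  if (dilation_scale <= 0) stop("dilation_scale must be > 0")
  if (sphericity_factor <= 0) stop("sphericity_factor must be > 0")
  if (base_width_factor <= 0) stop("base_width_factor must be > 0")
  if (wall_thickness_mm <= 0) stop("wall_thickness_mm must be > 0")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0")
  structure(list(dilation_scale = dilation_scale,
                 sphericity_factor = sphericity_factor,
                 base_width_factor = base_width_factor,
                 apex_tilt_deg = apex_tilt_deg,
                 wall_thickness_mm = wall_thickness_mm,
                 noise_sd_mm = noise_sd_mm),
            class = "ShapeParams")
}

# outward vertex normals from the ring-grid structure (cross product of
# circumferential and longitudinal tangents)
.vertexNormals <- function(V, nTheta, nRings) {
  idx <- function(j, k) (j - 1L) * nTheta + ((k - 1L) %% nTheta) + 1L
  j <- rep(seq_len(nRings), each = nTheta)
  k <- rep(seq_len(nTheta), times = nRings)
  tTheta <- V[idx(j, k + 1L), , drop = FALSE] - V[idx(j, k - 1L), , drop = FALSE]
  jp <- pmin(j + 1L, nRings); jm <- pmax(j - 1L, 1L)
  tLong <- V[idx(jp, k), , drop = FALSE] - V[idx(jm, k), , drop = FALSE]
  n <- cbind(tTheta[, 2] * tLong[, 3] - tTheta[, 3] * tLong[, 2],
             tTheta[, 3] * tLong[, 1] - tTheta[, 1] * tLong[, 3],
             tTheta[, 1] * tLong[, 2] - tTheta[, 2] * tLong[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  # orient outward: positive projection on the in-plane radial direction
  ringCent <- apply(array(V, c(nTheta, nRings, 3)), c(2, 3), mean)
  rad <- V - ringCent[j, , drop = FALSE]
  rad[, 3] <- 0
  flip <- rowSums(n * rad) < 0
  n[flip, ] <- -n[flip, ]
  n
}

#' Deform the template by shape parameters
#'
#' Applies, in this fixed order: wall-thickness adjustment, global dilation,
#' sphericity (long-axis) stretch, basal widening, apex tilt (volume
#' preserving shear), and finally vertex noise along outward normals.
#' Correspondence and topology are preserved.
#'
#' @param template a [CorrespondedMesh-class] from [generateTemplate()].
#' @param params a [shapeParams()] list.
#' @param seed integer seed for the vertex noise stream (ignored when
#'   \code{noise_sd_mm} is 0).
#' @param baseWall wall thickness the template was built with (mm).
#' @return A deformed [CorrespondedMesh-class].
#' @export
deformShape <- function(template, params, seed = 1L, baseWall = 4) {
  stopifnot(is(template, "CorrespondedMesh"), inherits(params, "ShapeParams"))
  endo <- template@endo
  epi <- template@epi
  nTheta <- template@nTheta; nRings <- template@nRings
  lv <- template@lvLandmark

  # 1. wall thickness: rescale the paired endo->epi offset
  wr <- params$wall_thickness_mm / baseWall
  epi <- endo + wr * (epi - endo)

  # 2. global dilation
  s <- params$dilation_scale
  endo <- endo * s; epi <- epi * s; lv <- lv * s

  # 3. sphericity: volume-preserving aspect change (long axis times s,
  # in-plane times s^-1/2) so that shape and size are distinct generative
  # axes; the length/diameter ratio scales with s^(3/2)
  sp <- params$sphericity_factor
  endo[, 3] <- endo[, 3] * sp; epi[, 3] <- epi[, 3] * sp
  endo[, 1:2] <- endo[, 1:2] / sqrt(sp); epi[, 1:2] <- epi[, 1:2] / sqrt(sp)

  # 4. basal widening, tapering linearly base -> apex
  b <- params$base_width_factor
  tt <- rep(.ringT(nRings), each = nTheta)
  m <- 1 + (b - 1) * (1 - tt)
  endo[, 1:2] <- endo[, 1:2] * m
  epi[, 1:2] <- epi[, 1:2] * m

  # 5. apex tilt: shear towards +x proportional to depth
  sh <- tan(params$apex_tilt_deg * pi / 180)
  endo[, 1] <- endo[, 1] - sh * endo[, 3]
  epi[, 1] <- epi[, 1] - sh * epi[, 3]

  # 6. vertex noise along outward normals, applied last
  if (params$noise_sd_mm > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    nE <- .vertexNormals(endo, nTheta, nRings)
    nP <- .vertexNormals(epi, nTheta, nRings)
    # spatially correlated noise: iid draws smoothed over the ring grid and
    # rescaled to the requested sd.  One shared field displaces both
    # surfaces along their own normals: segmentation error (breathing,
    # slice misregistration, boundary blur) moves the wall as a whole, and
    # a shared field cannot make thin walls self-intersect
    f <- .smoothField(matrix(rnorm(nTheta * nRings), nTheta, nRings),
                      lambda = 0.7, passes = 3L)
    f <- as.numeric(f) / sd(f) * params$noise_sd_mm
    endo <- endo + nE * f
    epi <- epi + nP * f
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  out <- new("CorrespondedMesh", endo = endo, epi = epi,
             nTheta = nTheta, nRings = nRings,
             septalMask = template@septalMask, lvLandmark = lv,
             fittingError = NA_real_)
  # signed intersection test: the endo-to-epi offset must point along the
  # outward endocardial normal everywhere
  nE <- .vertexNormals(endo, nTheta, nRings)
  gap <- rowSums((epi - endo) * nE)
  if (min(gap) <= 0)
    stop("deformation produced intersecting endo/epi surfaces (min signed ",
         "wall thickness ", signif(min(gap), 3), " mm)")
  out
}

.pairedWallThickness <- function(mesh) {
  sqrt(rowSums((mesh@epi - mesh@endo)^2))
}

# ---- closed-surface volume (divergence theorem) ----

# triangulate a ring-grid surface and cap base (centroid fan at ring 1) and
# apex (centroid fan at the last ring); returns signed volume, positive for
# outward-consistent orientation
.ringSurfaceVolume <- function(V, nTheta, nRings) {
  idx <- function(j, k) (j - 1L) * nTheta + ((k - 1L) %% nTheta) + 1L
  tris <- list()
  for (j in seq_len(nRings - 1L)) {
    k <- seq_len(nTheta)
    a <- idx(j, k); b <- idx(j, k + 1L)
    c2 <- idx(j + 1L, k); d <- idx(j + 1L, k + 1L)
    tris[[length(tris) + 1L]] <- cbind(a, b, d)
    tris[[length(tris) + 1L]] <- cbind(a, d, c2)
  }
  Tm <- do.call(rbind, tris)
  vol6 <- function(p1, p2, p3) {
    # scalar triple product p1 . (p2 x p3)
    p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
    p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  }
  v <- sum(vol6(V[Tm[, 1], , drop = FALSE], V[Tm[, 2], , drop = FALSE],
                V[Tm[, 3], , drop = FALSE]))
  # base cap (ring 1) and apex cap (ring nRings) as centroid fans
  for (j in c(1L, nRings)) {
    k <- seq_len(nTheta)
    ring <- V[idx(j, k), , drop = FALSE]
    cen <- matrix(colMeans(ring), nTheta, 3, byrow = TRUE)
    nxt <- V[idx(j, k + 1L), , drop = FALSE]
    if (j == 1L) v <- v + sum(vol6(cen, nxt, ring))   # base normal +z
    else v <- v + sum(vol6(cen, ring, nxt))           # apex normal -z
  }
  abs(v) / 6
}

#' Enclosed volume of a ring-grid surface
#'
#' Divergence-theorem volume of one closed surface of a mesh, with base and
#' apex closed by centroid fans.
#'
#' @param mesh a [CorrespondedMesh-class].
#' @param surface "endo" or "epi".
#' @return Volume in mm^3.
#' @export
meshVolume <- function(mesh, surface = c("endo", "epi")) {
  surface <- match.arg(surface)
  V <- if (surface == "endo") mesh@endo else mesh@epi
  .ringSurfaceVolume(V, mesh@nTheta, mesh@nRings)
}

# ---- shape vectors ----

#' Flatten a corresponded mesh to its shape vector
#'
#' Concatenates per-vertex (x, y, z) coordinates, endocardium first then
#' epicardium, ring-major from base to apex.  At the default resolution the
#' result has exactly 3456 entries.  The operation is invertible via
#' [unflattenShape()].
#'
#' @param mesh a [CorrespondedMesh-class].
#' @return Numeric shape vector.
#' @export
shapeVector <- function(mesh) {
  stopifnot(is(mesh, "CorrespondedMesh"))
  v <- c(t(mesh@endo), t(mesh@epi))
  if (length(v) != 6L * mesh@nTheta * mesh@nRings)
    stop("inconsistent vertex count")
  v
}

#' Rebuild a mesh from a shape vector
#'
#' Inverse of [shapeVector()]; requires a reference mesh supplying the grid
#' dimensions, septal mask and landmark.
#'
#' @param vec numeric shape vector.
#' @param reference a [CorrespondedMesh-class] with the target topology.
#' @return A [CorrespondedMesh-class].
#' @export
unflattenShape <- function(vec, reference) {
  nv <- reference@nTheta * reference@nRings
  if (length(vec) != 6L * nv)
    stop("shape vector length ", length(vec), " does not match topology (",
         6L * nv, " expected)")
  endo <- matrix(vec[seq_len(3L * nv)], ncol = 3, byrow = TRUE)
  epi <- matrix(vec[3L * nv + seq_len(3L * nv)], ncol = 3, byrow = TRUE)
  new("CorrespondedMesh", endo = endo, epi = epi,
      nTheta = reference@nTheta, nRings = reference@nRings,
      septalMask = reference@septalMask, lvLandmark = reference@lvLandmark,
      fittingError = NA_real_)
}

# ---- analytic ground-truth volumes ----

# exact volume of the solid whose cross-sections are the template's
# nTheta-gon sections, integrated finely in t down to the true apex.
# Deformation parameters enter analytically (tilt is a volume-preserving
# shear; noise is excluded).
.truthCavityVolume <- function(params = shapeParams(),
                               tmpl = .TEMPLATE_DEFAULTS,
                               surface = c("endo", "epi"),
                               nGrid = 4000L) {
  surface <- match.arg(surface)
  w <- if (surface == "endo") 0 else params$wall_thickness_mm
  L <- if (surface == "endo") tmpl$length else
    tmpl$length + params$wall_thickness_mm
  th <- .ringTheta(tmpl$nTheta)
  g <- .crescentG(th, tmpl$crescent)
  gn <- c(g[-1], g[1])
  sinD <- sin(2 * pi / tmpl$nTheta)
  t <- seq(0, 1, length.out = nGrid)
  f <- sqrt(pmax(0, 1 - t^2))
  b <- params$base_width_factor
  s <- params$dilation_scale
  # in-plane factor: dilation x basal widening x sphericity (the latter is
  # volume preserving: in-plane 1/sqrt(s) against the axial s)
  C <- s * (1 + (b - 1) * (1 - t)) / sqrt(params$sphericity_factor)
  # shoelace area of the crescent nTheta-gon section at each height
  area <- vapply(seq_len(nGrid), function(i) {
    r <- tmpl$cavityRadius * f[i] * g + w
    rn <- tmpl$cavityRadius * f[i] * gn + w
    0.5 * sinD * sum(r * rn) * C[i]^2
  }, numeric(1))
  dz <- L * s * params$sphericity_factor / (nGrid - 1)
  sum((area[-1] + area[-nGrid]) / 2) * dz
}

#' Analytic ground-truth cavity and wall volumes
#'
#' Exact volumes of the generative solid for given shape parameters,
#' integrated finely along the long axis (independent of the mesh
#' discretisation along that axis).  Used as the recovery oracle for
#' volumetry.
#'
#' @param params a [shapeParams()] list.
#' @param template named list of template constants (defaults match
#'   [generateTemplate()]).
#' @return Named list: \code{cavity_ml}, \code{epi_ml}, \code{wall_ml}.
#' @export
truthVolumes <- function(params = shapeParams(), template = .TEMPLATE_DEFAULTS) {
  vc <- .truthCavityVolume(params, template, "endo")
  ve <- .truthCavityVolume(params, template, "epi")
  list(cavity_ml = vc / 1000, epi_ml = ve / 1000, wall_ml = (ve - vc) / 1000)
}
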