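# Synthetic cine motion: a prescribed strain program deforms the subject
# mesh over one cardiac cycle.  In-plane (circumferential) and long-axis
# (longitudinal) scale factors follow a smooth systole/diastole activation;
# with the incompressible-wall flag the epicardial in-plane scale is solved
# each frame so wall volume is conserved exactly.  Frame 0 is end-diastole
# and the Lagrangian reference.

#' Per-frame cavity slice areas at fixed imaging planes
#'
#' Slices each frame of the motion model at fixed short-axis planes (as a
#' scanner would) and returns the cavity cross-section areas, ready for
#' Simpson slice-summation volumetry via [volumeCurve()].
#'
#' @param mesh end-diastolic [CorrespondedMesh-class].
#' @param motion a [motionParams()] list.
#' @param sliceSpacing plane spacing in mm.
#' @return List: \code{areas} (frames x slices, mm^2) and
#'   \code{spacing}.
#' @export
sliceAreaCurve <- function(mesh, motion = motionParams(), sliceSpacing = 1.5) {
  nF <- motion$n_frames
  rr <- motion$rr_interval_s
  phi <- .activation((seq_len(nF) - 1) * rr / nF, rr, motion$systole_fraction)
  ac <- 1 + motion$peak_circ_strain * phi
  al <- 1 + motion$peak_long_strain * phi
  nT <- mesh@nTheta; nR <- mesh@nRings
  zTop <- max(mesh@endo[, 3])
  zBot <- min(mesh@endo[, 3])
  zPlanes <- seq(zTop - sliceSpacing / 2, zBot, by = -sliceSpacing)
  shoelace <- function(P) {
    n <- nrow(P)
    j <- c(2:n, 1)
    abs(sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])) / 2
  }
  areas <- matrix(0, nF, length(zPlanes))
  for (f in seq_len(nF)) {
    V <- cbind(mesh@endo[, 1] * ac[f], mesh@endo[, 2] * ac[f],
               mesh@endo[, 3] * al[f])
    for (s in seq_along(zPlanes)) {
      poly <- .slicePolygon(V, nT, nR, zPlanes[s])
      if (!is.null(poly)) areas[f, s] <- shoelace(poly)
    }
  }
  list(areas = areas, spacing = sliceSpacing)
}

#' Cine motion parameters
#'
#' @param n_frames frames per cardiac cycle (>= 10).
#' @param rr_interval_s cycle length in seconds.
#' @param peak_circ_strain peak circumferential strain as a negative
#'   fraction in (-1, 0).
#' @param peak_long_strain peak longitudinal strain as a negative fraction
#'   in (-1, 0); shortening is negative, lengthening positive.
#' @param systole_fraction fraction of the cycle spent in systole (0, 1).
#' @param incompressible_wall conserve wall volume frame by frame.
#' @return Validated list of class "MotionParams".
#' @export
motionParams <- function(n_frames = 25L, rr_interval_s = 0.5,
                         peak_circ_strain = -0.169,
                         peak_long_strain = -0.148,
                         systole_fraction = 0.35,
                         incompressible_wall = TRUE) {
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (rr_interval_s <= 0) stop("rr_interval_s must be positive")
  if (peak_circ_strain <= -1 || peak_circ_strain >= 0)
    stop("peak_circ_strain must be in (-1, 0)")
  if (peak_long_strain <= -1 || peak_long_strain >= 0)
    stop("peak_long_strain must be in (-1, 0)")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must be in (0, 1)")
  structure(list(n_frames = as.integer(n_frames),
                 rr_interval_s = rr_interval_s,
                 peak_circ_strain = peak_circ_strain,
                 peak_long_strain = peak_long_strain,
                 systole_fraction = systole_fraction,
                 incompressible_wall = isTRUE(incompressible_wall)),
            class = "MotionParams")
}

# activation profile: 0 at frame 0, 1 at end-systole, back to 0 at cycle end
.activation <- function(t, rr, systoleFraction) {
  ts <- systoleFraction * rr
  ifelse(t <= ts,
         sin(pi * t / (2 * ts))^2,
         sin(pi * (rr - t) / (2 * (rr - ts)))^2)
}

.resampleClosed <- function(P, n) {
  Q <- rbind(P, P[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(Q)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- (seq_len(n) - 1) * L / n
  cbind(stats::approx(cum, Q[, 1], xout = s)$y,
        stats::approx(cum, Q[, 2], xout = s)$y)
}

.resampleOpen <- function(P, n) {
  seg <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, length.out = n)
  cbind(stats::approx(cum, P[, 1], xout = s)$y,
        stats::approx(cum, P[, 2], xout = s)$y)
}

.perimeter <- function(P, closed = TRUE) {
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  sum(sqrt(rowSums(diff(Q)^2)))
}

# 4-chamber cut: the plane through the long axis and the LV landmark (+x),
# i.e. y = 0; at the grid angles theta = 0 and pi the vertices lie on it
.fourChamberPolyline <- function(V, nTheta, nRings) {
  kA <- 1L
  kB <- nTheta %/% 2L + 1L
  sideA <- V[(seq_len(nRings) - 1L) * nTheta + kA, c(1, 3), drop = FALSE]
  sideB <- V[(seq_len(nRings) - 1L) * nTheta + kB, c(1, 3), drop = FALSE]
  rbind(sideA, sideB[rev(seq_len(nRings)), , drop = FALSE])
}

#' Generate a synthetic cine with analytic ground truth
#'
#' Deforms a subject mesh over one cardiac cycle and emits tracked contour
#' sequences at the four-chamber plane and three short-axis levels (basal,
#' mid, apical at 25/50/75\% of the long-axis extent), plus the analytic
#' ground truth: strain curves per direction and level, the cavity volume
#' curve and EDV/ESV/EF.
#'
#' @param mesh end-diastolic [CorrespondedMesh-class] in standard pose.
#' @param motion a [motionParams()] list.
#' @param truthCavityMl analytic end-diastolic cavity volume (ml) to anchor
#'   the truth volume curve; defaults to the mesh-integrated volume.
#' @return List with \code{contours} (named list of
#'   [ContourSequence-class]: endo at 4ch/basal/mid/apical and epi at the
#'   short-axis levels) and \code{truth}.
#' @export
generateCine <- function(mesh, motion = motionParams(), truthCavityMl = NULL) {
  stopifnot(is(mesh, "CorrespondedMesh"), inherits(motion, "MotionParams"))
  nF <- motion$n_frames
  rr <- motion$rr_interval_s
  dt <- rr / nF
  tms <- (seq_len(nF) - 1) * dt
  phi <- .activation(tms, rr, motion$systole_fraction)
  ac <- 1 + motion$peak_circ_strain * phi
  al <- 1 + motion$peak_long_strain * phi
  V0e <- meshVolume(mesh, "endo")
  V0p <- meshVolume(mesh, "epi")
  W0 <- V0p - V0e
  ap <- if (motion$incompressible_wall) {
    k2 <- (W0 / al + ac^2 * V0e) / V0p
    if (any(k2 <= 0)) stop("prescribed strains imply negative wall volume")
    sqrt(k2)
  } else ac
  nT <- mesh@nTheta; nR <- mesh@nRings
  zext <- diff(range(mesh@endo[, 3]))
  zbase <- max(mesh@endo[, 3])
  levelFrac <- c(basal = 0.25, mid = 0.50, apical = 0.75)
  saxZ <- zbase - levelFrac * zext

  frameSurface <- function(V, aXY, aZ)
    cbind(V[, 1] * aXY, V[, 2] * aXY, V[, 3] * aZ)

  sax <- list(endo = list(), epi = list())
  for (lv in names(levelFrac)) {
    sax$endo[[lv]] <- array(0, c(nF, nT, 2))
    sax$epi[[lv]] <- array(0, c(nF, nT, 2))
  }
  fourCh <- array(0, c(nF, 2L * nR, 2))
  for (f in seq_len(nF)) {
    Ve <- frameSurface(mesh@endo, ac[f], al[f])
    Vp <- frameSurface(mesh@epi, ap[f], al[f])
    for (lv in names(levelFrac)) {
      z <- saxZ[[lv]] * al[f]       # material slice follows the long axis
      pe <- .slicePolygon(Ve, nT, nR, z)
      pp <- .slicePolygon(Vp, nT, nR, z)
      if (is.null(pe) || is.null(pp))
        stop("short-axis level ", lv, " left the mesh at frame ", f)
      cen <- colMeans(pe)
      rE <- sqrt((pe[, 1] - cen[1])^2 + (pe[, 2] - cen[2])^2)
      rP <- sqrt((pp[, 1] - cen[1])^2 + (pp[, 2] - cen[2])^2)
      if (any(rP <= rE))
        stop("prescribed strains imply negative wall thickness at frame ", f)
      sax$endo[[lv]][f, , ] <- pe
      sax$epi[[lv]][f, , ] <- pp
    }
    fourCh[f, , ] <- .fourChamberPolyline(Ve, nT, nR)
  }

  mkSeq <- function(arr, level, surface, closed)
    new("ContourSequence", points = arr, frameInterval = dt,
        level = level, surface = surface, closed = closed)
  contours <- list(
    `4ch` = mkSeq(fourCh, "4ch", "endo", FALSE),
    basal = mkSeq(sax$endo$basal, "basal", "endo", TRUE),
    mid = mkSeq(sax$endo$mid, "mid", "endo", TRUE),
    apical = mkSeq(sax$endo$apical, "apical", "endo", TRUE),
    basal_epi = mkSeq(sax$epi$basal, "basal", "epi", TRUE),
    mid_epi = mkSeq(sax$epi$mid, "mid", "epi", TRUE),
    apical_epi = mkSeq(sax$epi$apical, "apical", "epi", TRUE))

  # analytic ground truth, recorded from the generated geometry itself
  circ <- sapply(names(levelFrac), function(lv) {
    P0 <- .perimeter(sax$endo[[lv]][1, , ])
    vapply(seq_len(nF), function(f)
      (.perimeter(sax$endo[[lv]][f, , ]) - P0) / P0 * 100, numeric(1))
  })
  long4 <- {
    L0 <- .perimeter(fourCh[1, , ], closed = FALSE)
    vapply(seq_len(nF), function(f)
      (.perimeter(fourCh[f, , ], closed = FALSE) - L0) / L0 * 100, numeric(1))
  }
  radialCentroid <- sapply(names(levelFrac), function(lv) {
    r <- vapply(seq_len(nF), function(f) {
      P <- sax$endo[[lv]][f, , ]
      cen <- colMeans(P)
      mean(sqrt((P[, 1] - cen[1])^2 + (P[, 2] - cen[2])^2))
    }, numeric(1))
    (r[1] - r) / r[1] * 100
  })
  edvMl <- if (is.null(truthCavityMl)) V0e / 1000 else truthCavityMl
  volCurve <- edvMl * ac^2 * al
  wallCurve <- (ap^2 * V0p - ac^2 * V0e) * al / 1000
  truth <- list(
    time_s = tms, activation = phi,
    circ_scale = ac, long_scale = al, epi_scale = ap,
    circ_strain_pct = circ, long_strain_pct = long4,
    radial_strain_centroid_pct = radialCentroid,
    volume_ml = volCurve, wall_volume_ml = wallCurve,
    edv_ml = max(volCurve), esv_ml = min(volCurve),
    ef_pct = (max(volCurve) - min(volCurve)) / max(volCurve) * 100,
    ed_frame = which.max(volCurve), es_frame = which.min(volCurve),
    peak_circ_strain = motion$peak_circ_strain,
    peak_long_strain = motion$peak_long_strain)
  list(contours = contours, truth = truth)
}
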