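test_that("motion parameters are validated", {
  expect_error(motionParams(n_frames = 5), "n_frames")
  expect_error(motionParams(peak_circ_strain = 0.1), "circ")
  expect_error(motionParams(systole_fraction = 1.2), "systole")
})

test_that("the cine reference frame has zero strain and exact EF bookkeeping", {
  mesh <- deformShape(theTemplate(), shapeParams(dilation_scale = 1.05))
  cine <- generateCine(mesh, motionParams())
  tr <- cine$truth
  expect_equal(tr$circ_strain_pct[1, ], c(basal = 0, mid = 0, apical = 0))
  expect_equal(tr$long_strain_pct[1], 0)
  expect_equal(tr$ef_pct, (tr$edv_ml - tr$esv_ml) / tr$edv_ml * 100)
  expect_equal(tr$ed_frame, 1L)
})

test_that("the incompressible wall conserves its volume each frame", {
  mesh <- deformShape(theTemplate(), shapeParams())
  cine <- generateCine(mesh, motionParams(incompressible_wall = TRUE))
  w <- cine$truth$wall_volume_ml
  expect_lt(max(abs(w / w[1] - 1)), 0.01)
  # without the flag the wall thins with the cavity
  cine2 <- generateCine(mesh, motionParams(incompressible_wall = FALSE))
  w2 <- cine2$truth$wall_volume_ml
  expect_gt(max(abs(w2 / w2[1] - 1)), 0.05)
})

test_that("ground-truth strain is the Lagrangian strain of its own contours", {
  mesh <- deformShape(theTemplate(), shapeParams())
  cine <- generateCine(mesh, motionParams())
  per <- function(P) { Q <- rbind(P, P[1, ]); sum(sqrt(rowSums(diff(Q)^2))) }
  for (lv in c("basal", "mid", "apical")) {
    pts <- contourPoints(cine$contours[[lv]])
    p0 <- per(pts[1, , ])
    lag <- vapply(seq_len(dim(pts)[1]),
                  function(f) (per(pts[f, , ]) - p0) / p0 * 100, numeric(1))
    expect_lt(max(abs(lag - cine$truth$circ_strain_pct[, lv])), 1e-6)
  }
})

test_that("contour propagation is exact under rigid and similarity motion", {
  # rigid translation: tracked points translate, strains identically zero
  radii <- rep(20, 12)
  centres <- cbind(seq(0, 11), seq(0, -11))
  seqT <- circleSequence(radii, centres = centres)
  tr <- propagateContour(seqT, nPoints = 48)
  st <- computeStrain(tr, nSegments = 6)
  expect_lt(max(abs(st@segmentStrain)), 1e-9)

  # 10% scale-down at one frame: circumferential strain -10% there
  seqS <- circleSequence(c(20, 18, 20))
  stS <- computeStrain(propagateContour(seqS, nPoints = 48), nSegments = 6)
  expect_equal(stS@globalStrain[2], -10, tolerance = 1e-6)

  # perimeter of tracked generator contours matches the analytic one
  mesh <- deformShape(theTemplate(), shapeParams())
  cine <- generateCine(mesh, motionParams())
  raw <- cine$contours$mid
  trk <- propagateContour(raw, nPoints = 96)
  per <- function(P) { Q <- rbind(P, P[1, ]); sum(sqrt(rowSums(diff(Q)^2))) }
  for (f in c(1, 7, 13)) {
    expect_equal(per(contourPoints(trk)[f, , ]),
                 per(contourPoints(raw)[f, , ]), tolerance = 0.01)
  }

  # empty frames are reported by index
  masks <- array(0L, c(3, 20, 20)); masks[1, 8:12, 8:12] <- 1L
  masks[2, 8:12, 8:12] <- 1L
  expect_error(propagateContour(masks, frameInterval = 0.04), "frame 3")
})

test_that("short-axis levels sit at the quartiles of the long axis", {
  lv <- selectSaxLevels(9)
  expect_identical(as.integer(lv), c(3L, 5L, 7L))
  expect_equal(unname(attr(lv, "fraction")), c(0.25, 0.5, 0.75))
  expect_identical(as.integer(selectSaxLevels(3)), c(1L, 2L, 3L))
  expect_true(all(abs(attr(selectSaxLevels(11), "fraction") -
                        c(0.25, 0.5, 0.75)) <= 1 / 10))
  expect_error(selectSaxLevels(2), "3")
  st <- rasterizeSegmentation(theTemplate(), voxel_mm = 1.5,
                              slice_thickness_mm = 3)
  lvS <- selectSaxLevels(st)
  expect_length(lvS, 3)
})

test_that("segmental Lagrangian strain follows its definition and signs", {
  # segment lengths 100 -> 85 gives -15%
  sq <- circleSequence(c(100 / (2 * pi), 85 / (2 * pi)))
  st <- computeStrain(sq, nSegments = 4)
  expect_equal(unname(st@segmentStrain[2, ]), rep(-15, 4), tolerance = 1e-9)

  # global strain is the arithmetic mean of the segments (exact assertion)
  mesh <- deformShape(theTemplate(), shapeParams())
  cine <- generateCine(mesh, motionParams())
  s2 <- computeStrain(propagateContour(cine$contours$mid, nPoints = 96), 6)
  expect_identical(s2@globalStrain, rowMeans(s2@segmentStrain))
  hand <- rowMeans(cbind(rep(-10, 2), rep(-20, 2)))
  expect_equal(mean(c(-10, -20)), -15)
  expect_equal(hand[1], -15)

  # segment arc lengths at frame 0 are equal within one point spacing
  trk <- propagateContour(cine$contours$mid, nPoints = 96)
  L <- rvatlas:::.segmentLengths(contourPoints(trk)[1, , ], 6, TRUE)
  spacingTol <- sum(L) / 96
  expect_lt(diff(range(L)), spacingTol)

  # radial strain: inward motion positive (endo-only centroid convention)
  sr <- computeStrain(circleSequence(c(20, 17)), 6, direction = "radial")
  expect_equal(sr@globalStrain[2], 15, tolerance = 1e-9)

  # thickness-based radial strain: wall 5 -> 7 mm is +40%
  endo <- circleSequence(c(20, 20))
  epi <- circleSequence(c(25, 27))
  stT <- computeStrain(endo, 6, direction = "radial", epiSeq = epi)
  expect_equal(stT@globalStrain[2], 40, tolerance = 1e-9)
  expect_equal(stT@radialMethod, "thickness")

  expect_error(computeStrain(endo, nSegments = 1), "nSegments")
})

test_that("strain rate uses finite differences with window-based peaks", {
  # linear strain to -15% over 0.3 s: rate -0.5 1/s
  nF <- 31; dt <- 0.01
  radii <- 20 * (1 + seq(0, -0.15, length.out = nF))
  st <- computeStrain(circleSequence(radii, dt = dt), 6)
  st <- strainRateAndPeaks(st, edFrame = 1, esFrame = nF)
  expect_equal(unname(st@peaks["systolic_rate_per_s"]), -0.5,
               tolerance = 1e-6)
  expect_equal(unname(st@peaks["systolic_strain_pct"]), -15,
               tolerance = 1e-6)

  # sinusoidal program: peak rate matches the analytic derivative
  tt <- seq(0, 0.3, by = 0.005)
  eps <- -0.15 * sin(pi * tt / 0.3)
  stS <- computeStrain(circleSequence(20 * (1 + eps), dt = 0.005), 6)
  es <- which.min(eps)
  stS <- strainRateAndPeaks(stS, edFrame = 1, esFrame = es)
  expect_equal(unname(stS@peaks["systolic_rate_per_s"]), -0.15 * pi / 0.3,
               tolerance = 0.05 * 0.15 * pi / 0.3)

  # constant strain: all rates zero
  stC <- strainRateAndPeaks(computeStrain(circleSequence(rep(20, 10)), 6),
                            1, 5)
  expect_equal(max(abs(stC@globalRate)), 0)

  # reversing a full-cycle cine (which keeps the frame-0 reference length)
  # negates the strain-rate curves
  cyc <- 20 * (1 - 0.15 * sin(pi * seq(0, 1, length.out = 21))^2)
  rFwd <- strainRateAndPeaks(computeStrain(circleSequence(cyc, dt = dt), 6),
                             1, 11)@globalRate
  rRev <- strainRateAndPeaks(computeStrain(circleSequence(rev(cyc), dt = dt),
                                           6), 1, 11)@globalRate
  expect_equal(rRev, -rev(rFwd), tolerance = 1e-9)

  short <- computeStrain(circleSequence(c(20, 19)), 6)
  expect_error(strainRateAndPeaks(short, 1, 2), "3 frames")
})

test_that("prescribed peak strains are recovered from tracked contours", {
  mesh <- deformShape(theTemplate(), shapeParams(dilation_scale = 1.05))
  for (pk in c(-0.05, -0.15, -0.25)) {
    cine <- generateCine(mesh, motionParams(peak_circ_strain = pk))
    tab <- strainTable(cine)
    rec <- tab$systolic_strain_pct[tab$level == "mid" &
                                     tab$direction == "circumferential"]
    expect_lt(abs(rec - pk * 100), 1)
    # radial strains positive, circumferential/longitudinal negative
    expect_true(all(tab$systolic_strain_pct[tab$direction == "radial"] > 0))
    expect_true(all(tab$systolic_strain_pct[
      tab$direction %in% c("circumferential", "longitudinal")] < 0))
  }
})

test_that("strains are invariant to per-frame rigid transforms", {
  mesh <- deformShape(theTemplate(), shapeParams())
  cine <- generateCine(mesh, motionParams())
  pts <- contourPoints(cine$contours$mid)
  set.seed(5)
  for (f in seq_len(dim(pts)[1])) {
    th <- runif(1, -pi, pi); sh <- rnorm(2, 0, 8)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    pts[f, , ] <- sweep(pts[f, , ] %*% t(R), 2, -sh)
  }
  moved <- new("ContourSequence", points = pts,
               frameInterval = cine$contours$mid@frameInterval,
               level = "mid", surface = "endo", closed = TRUE)
  s0 <- computeStrain(propagateContour(cine$contours$mid, nPoints = 96), 6)
  s1 <- computeStrain(propagateContour(moved, nPoints = 96), 6)
  expect_equal(s1@globalStrain, s0@globalStrain, tolerance = 1e-4)
})
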