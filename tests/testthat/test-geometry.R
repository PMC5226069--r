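test_that("Simpson slice summation and EF follow their defining formulas", {
  # 10 slices of a r = 20 mm circle at 8 mm spacing: an analytic cylinder
  areas <- rep(pi * 20^2, 10)
  vc <- volumeCurve(areas, spacing = 8)
  expect_equal(vc$edv_ml, pi * 20^2 * 80 / 1000, tolerance = 1e-12)

  # EDV 80, ESV 34 (clinical magnitudes): SV 46, EF 57.5
  frames <- rbind(rep(8, 10), rep(3.4, 10)) * 1000  # mm^2, spacing 1
  vc2 <- volumeCurve(frames, spacing = 1)
  expect_equal(vc2$edv_ml, 80)
  expect_equal(vc2$esv_ml, 34)
  expect_identical(vc2$sv_ml, vc2$edv_ml - vc2$esv_ml)
  expect_equal(vc2$sv_ml, 46)
  expect_equal(vc2$ef_pct, (80 - 34) / 80 * 100)
  expect_equal(vc2$ef_pct, 57.5)

  # volume additivity: splitting the stack and summing is exact
  left <- volumeCurve(frames[, 1:4], 1)$volume_ml
  right <- volumeCurve(frames[, 5:10], 1)$volume_ml
  expect_identical(left + right, vc2$volume_ml)

  expect_error(volumeCurve(matrix(0, 2, 3), 1), "zero end-diastolic")
  expect_error(volumeCurve(areas, 0), "positive")
})

test_that("myocardial mass matches the analytic shell and scales cubically", {
  sph <- makeEllipsoidMesh(20, 20, 20, wall = 5, nTheta = 96, nRings = 96)
  expect_equal(myocardialMass(sph),
               4 / 3 * pi * (25^3 - 20^3) / 1000 * 1.05, tolerance = 5e-3)
  degen <- sph; degen@epi <- degen@endo
  expect_equal(myocardialMass(degen), 0)
  scaled <- sph
  scaled@endo <- sph@endo * 1.3; scaled@epi <- sph@epi * 1.3
  expect_equal(myocardialMass(scaled) / myocardialMass(sph), 1.3^3,
               tolerance = 1e-10)
})

test_that("geometric indices behave on analytic shells", {
  sph <- makeEllipsoidMesh(20, 20, 20, wall = 5, nTheta = 96, nRings = 96)
  gi <- geometricIndices(sph)
  expect_equal(gi$sphericity_ratio, 1.0, tolerance = 0.01)
  expect_equal(gi$max_wall_thickness_mm, 5, tolerance = 1e-6)
  expect_lt(gi$septal_wall_sd_mm, 1e-9)
  expect_equal(gi$max_cavity_diameter_mm, 40, tolerance = 0.01 * 40)

  # the ratio is length over *cavity* diameter, matching cohort-scale
  # magnitudes (length ~78, cavity diameter ~53 gives ~1.47)
  tall <- makeEllipsoidMesh(26.5, 26.5, 38.9, wall = 4,
                            nTheta = 96, nRings = 96)
  giT <- geometricIndices(tall)
  expect_equal(giT$length_mm / giT$max_cavity_diameter_mm,
               giT$sphericity_ratio)
  expect_equal(giT$sphericity_ratio, 77.8 / 53.0, tolerance = 0.02)

  noMask <- sph; noMask@septalMask[] <- FALSE
  expect_warning(geometricIndices(noMask), "septal")
})

test_that("geometry is rigid-invariant and scale-covariant", {
  tm <- theTemplate()
  mesh <- deformShape(tm, shapeParams(dilation_scale = 1.1))
  th <- 25 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  # rigid motion preserves every measurement (indices are computed in the
  # standard frame, so re-standardize after the transform)
  again <- standardizeMeshPose(applyRigid(mesh, R, c(5, -3, 2)))
  gi <- geometricIndices(standardizeMeshPose(mesh))
  gi2 <- geometricIndices(again)
  for (f in names(gi)) expect_equal(gi2[[f]], gi[[f]], tolerance = 1e-6)
  expect_equal(meshVolume(again, "endo"), meshVolume(mesh, "endo"),
               tolerance = 1e-9)
  # uniform scaling: volumes s^3, lengths s, sphericity invariant
  s <- 1.2
  big <- mesh; big@endo <- mesh@endo * s; big@epi <- mesh@epi * s
  giB <- geometricIndices(big)
  expect_equal(meshVolume(big, "endo") / meshVolume(mesh, "endo"), s^3,
               tolerance = 1e-10)
  gi0 <- geometricIndices(mesh)
  expect_equal(giB$length_mm / gi0$length_mm, s, tolerance = 1e-10)
  expect_equal(giB$sphericity_ratio, gi0$sphericity_ratio, tolerance = 1e-10)
})

test_that("Haycock BSA evaluates the published coefficients", {
  direct <- function(w, h) 0.024265 * w^0.5378 * h^0.3964
  expect_equal(haycockBSA(3.2, 50), direct(3.2, 50), tolerance = 1e-9)
  expect_equal(haycockBSA(3.2, 50), 0.214, tolerance = 2e-3)
  expect_equal(haycockBSA(10, 80), 0.476, tolerance = 2e-3)
  expect_lt(haycockBSA(1e-6, 50), 1e-3)
  expect_error(haycockBSA(0, 50), "positive")
})

test_that("allometric indexing uses the kind-specific exponents", {
  expect_equal(allometricIndex(80, 1, "volume"), 80)
  expect_equal(allometricIndex(24.5, 0.40, "volume"), 24.5 / 0.40^1.3)
  expect_equal(allometricIndex(24.5, 0.40, "volume"), 80.6, tolerance = 1e-2)
  expect_equal(allometricIndex(55, 0.49, "length"), 55 / 0.7)
  expect_equal(allometricIndex(100, 0.5, "mass"), 100 / 0.5^1.3)
  expect_equal(allometricIndex(100, 0.5, "mass", mass_exponent = 0.5),
               100 / sqrt(0.5))
  expect_error(allometricIndex(1, 0.5, "area"))
  expect_error(allometricIndex(1, -1, "volume"), "positive")
})

test_that("indexed volumes are constant for a BSA^1.3 family", {
  bsa <- seq(0.3, 0.9, length.out = 13)
  vols <- 80 * bsa^1.3
  idx <- allometricIndex(vols, bsa, "volume")
  expect_lt(sd(idx) / mean(idx), 0.01)
})

test_that("tricuspid regurgitation grading follows the clinical bins", {
  expect_equal(as.character(gradeTR(0)), "none")
  expect_equal(as.character(gradeTR(0.10)), "mild")
  expect_equal(as.character(gradeTR(0.20)), "moderate")
  expect_equal(as.character(gradeTR(0.35)), "moderate-severe")
  expect_equal(as.character(gradeTR(0.50)), "severe")
  # boundaries go to the lower-severity grade
  expect_equal(as.character(gradeTR(c(0.15, 0.25, 0.45))),
               c("mild", "moderate", "moderate-severe"))
  expect_error(gradeTR(1.2), "within")
})
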