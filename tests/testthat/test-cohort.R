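smallConfig <- function(n = 4L, seed = 7L, ...) {
  cohortConfig(nPerArm = c(MBT_I = n, MBT_II = n, RVPA_I = n, RVPA_II = n),
               seed = seed, ...)
}

nullEffects <- list(I = c(dilation = 1, sphericity = 1),
                    II = c(dilation = 1, sphericity = 1))

test_that("cohort generation is deterministic and counter-seeded", {
  cfg <- smallConfig()
  c1 <- generateCohort(cfg, cine = TRUE)
  c2 <- generateCohort(cfg, cine = TRUE)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[7]]$vector, c2$subjects[[7]]$vector)
  expect_identical(contourPoints(c1$subjects[[3]]$cine$mid),
                   contourPoints(c2$subjects[[3]]$cine$mid))

  # resizing one arm does not reshuffle the other arms' subjects
  cfg2 <- cohortConfig(nPerArm = c(MBT_I = 4L, MBT_II = 7L, RVPA_I = 4L,
                                   RVPA_II = 4L), seed = 7L)
  c3 <- generateCohort(cfg2)
  expect_identical(c1$subjects[[1]]$vector, c3$subjects[[1]]$vector)
  # first RVPA-I subject: position shifts but the draw is identical
  i1 <- which(c1$table$group == "RVPA" & c1$table$stage == "I")[1]
  i3 <- which(c3$table$group == "RVPA" & c3$table$stage == "I")[1]
  expect_identical(c1$subjects[[i1]]$params, c3$subjects[[i3]]$params)
})

test_that("the default configuration reproduces the clinical cohort layout", {
  cfg <- cohortConfig()
  expect_identical(sum(cfg$nPerArm), 93L)
  coh <- generateCohort(cfg)
  expect_identical(nrow(coh$table), 93L)
  expect_identical(as.integer(table(coh$table$group)[c("MBT", "RVPA")]),
                   c(59L, 34L))
  # BSA drawn per arm near the configured means
  m <- aggregate(bsa_m2 ~ group + stage, coh$table, mean)
  expect_equal(m$bsa_m2[m$group == "MBT" & m$stage == "I"], 0.40,
               tolerance = 0.1)
  # Haycock consistency of the generated anthropometrics
  expect_equal(haycockBSA(coh$table$weight_kg, coh$table$height_cm),
               coh$table$bsa_m2, tolerance = 1e-6)
  # ground-truth EF bookkeeping is exact
  cohC <- generateCohort(smallConfig(n = 2L), cine = TRUE)
  for (s in cohC$subjects) {
    expect_equal(s$truth$ef_pct,
                 (s$truth$edv_ml - s$truth$esv_ml) / s$truth$edv_ml * 100)
  }
  expect_error(cohortConfig(nPerArm = c(MBT_I = 1L, MBT_II = 4L,
                                        RVPA_I = 4L, RVPA_II = 4L)),
               "n >= 2")
})

test_that("null cohorts show no systematic group differences", {
  pvals <- vapply(1:60, function(r) {
    cfg <- smallConfig(n = 6L, seed = 1000L + r, effects = nullEffects)
    coh <- generateCohort(cfg)
    dil <- vapply(coh$subjects, function(s) s$params$dilation_scale,
                  numeric(1))
    bsa <- coh$table$bsa_m2
    # compare the size-adjusted dilation draw across groups
    t.test((dil / (bsa / 0.5)^(1.3 / 3))[coh$table$group == "MBT"],
           (dil / (bsa / 0.5)^(1.3 / 3))[coh$table$group == "RVPA"],
           var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- smallConfig(n = 2L)
  coh <- generateCohort(cfg, rasterize = TRUE, cine = TRUE)
  dir <- tempfile("cohort")
  writeCohort(coh, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  expect_identical(tab$subject_id, coh$table$subject_id)
  expect_identical(names(tab),
                   c("subject_id", "group", "stage", "weight_kg", "height_cm",
                     "bsa_m2", "tr_fraction", "lv_shape"))
  st <- loadSegmentation(file.path(dir, "S001", "seg.nii.gz"))
  expect_identical(stackLabels(st), stackLabels(coh$subjects[[1]]$stack))
  cs <- readContours(file.path(dir, "S001", "contours_mid.json"))
  expect_equal(contourPoints(cs), contourPoints(coh$subjects[[1]]$cine$mid),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "S001", "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$cavity_ml, coh$subjects[[1]]$truth$cavity_ml)
  unlink(dir, recursive = TRUE)
})

test_that("generated anatomy supports the end-to-end recovery pipeline", {
  cfg <- smallConfig(n = 2L)
  coh <- generateCohort(cfg, rasterize = TRUE)
  s <- coh$subjects[[1]]
  fit <- personalizeMesh(s$stack)
  expect_lt(fittingError(fit), 1.5)
  expect_equal(meshVolume(fit, "endo") / 1000, s$truth$cavity_ml,
               tolerance = 0.08)
})
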