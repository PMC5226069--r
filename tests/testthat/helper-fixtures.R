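# Shared fixtures and simulation helpers; everything is generated in code.

theTemplate <- local({
  tm <- NULL
  function() {
    if (is.null(tm)) tm <<- generateTemplate()
    tm
  }
})

# boundary "clouds" sampled exactly at the template's own vertices
selfFitBoundary <- function(tm = theTemplate()) {
  ring <- rep(seq_len(tm@nRings), each = tm@nTheta)
  list(endo = cbind(tm@endo, ring), epi = cbind(tm@epi, ring),
       landmark = tm@lvLandmark)
}

# one two-group shape cohort in which the groups differ only in the
# generative dilation factor (d in population-SD units); all other shape
# factors are held at identity, with vertex noise
simulateDilationCohort <- function(nPerArm, d, seed, noise = 0.8,
                                   fullWorld = FALSE) {
  tm <- theTemplate()
  set.seed(seed)
  n2 <- 2L * nPerArm
  grp <- rep(c("MBT", "RVPA"), each = nPerArm)
  dil <- exp(rnorm(n2, 0, 0.08) + (grp == "RVPA") * d * 0.08)
  X <- matrix(0, n2, 3456)
  for (i in seq_len(n2)) {
    p <- if (fullWorld)
      shapeParams(dilation_scale = dil[i],
                  sphericity_factor = exp(rnorm(1, 0, 0.06)),
                  base_width_factor = exp(rnorm(1, 0, 0.05)),
                  apex_tilt_deg = rnorm(1, 0, 2),
                  wall_thickness_mm = 4 * exp(rnorm(1, 0, 0.1)),
                  noise_sd_mm = noise)
    else shapeParams(dilation_scale = dil[i], noise_sd_mm = noise)
    # same deterministic noise-rejection rule as the cohort generator
    m <- NULL
    for (try_ in 0:4) {
      m <- tryCatch(deformShape(tm, p, seed = seed * 1000L + i + try_ * 7717L),
                    error = function(e) NULL)
      if (!is.null(m)) break
    }
    X[i, ] <- shapeVector(m)
  }
  list(X = X, groups = grp, dilation = dil)
}

# circular contour sequence with prescribed per-frame radii (and optional
# per-frame centre offsets), for analytic strain fixtures
circleSequence <- function(radii, dt = 0.04, nPts = 48L, centres = NULL,
                           level = "mid") {
  th <- 2 * pi * (seq_len(nPts) - 1) / nPts
  arr <- array(0, c(length(radii), nPts, 2))
  for (f in seq_along(radii)) {
    cx <- if (is.null(centres)) 0 else centres[f, 1]
    cy <- if (is.null(centres)) 0 else centres[f, 2]
    arr[f, , 1] <- cx + radii[f] * cos(th)
    arr[f, , 2] <- cy + radii[f] * sin(th)
  }
  new("ContourSequence", points = arr, frameInterval = dt, level = level,
      surface = "endo", closed = TRUE)
}

# per-subject geometry rows for report-table assembly
cohortGeometry <- function(coh) {
  do.call(rbind, lapply(seq_along(coh$subjects), function(i) {
    s <- coh$subjects[[i]]
    vc <- if (!is.null(s$truth$edv_ml))
      list(edv_ml = s$truth$edv_ml, esv_ml = s$truth$esv_ml,
           sv_ml = s$truth$edv_ml - s$truth$esv_ml, ef_pct = s$truth$ef_pct)
    else NULL
    gr <- geometryReport(s$mesh, vc = vc, bsa = coh$table$bsa_m2[i])
    data.frame(subject_id = s$id,
               as.data.frame(gr[vapply(gr, length, 1L) == 1L]))
  }))
}
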