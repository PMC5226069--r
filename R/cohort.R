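# Synthetic two-group, two-stage cohorts of systemic-RV anatomies with
# known ground truth.  Defaults emulate the clinical setting: 93 subjects
# (MBT shunt 30 stage-I + 29 stage-II scans; RVPA conduit 20 + 14), BSA
# distributions per arm as reported for that population, shape differences
# concentrated in dilation and sphericity and appearing after stage II, and
# cine motion with peak strains in the clinically observed range.

.ARM_ORDER <- data.frame(
  group = c("MBT", "MBT", "RVPA", "RVPA"),
  stage = c("I", "II", "I", "II"),
  stringsAsFactors = FALSE
)

# counter-based per-subject seed stream: independent of other arms' sizes
.subjectSeed <- function(masterSeed, armIndex, subjectIndex, salt = 0L) {
  ((as.numeric(masterSeed) * 48271 + armIndex * 1e6 +
      subjectIndex * 101 + salt * 13) %% 2147483629) + 1
}

#' Cohort generation configuration
#'
#' @param nPerArm named integer vector of arm sizes, names
#'   \code{MBT_I, MBT_II, RVPA_I, RVPA_II}; all >= 2.  The default (30, 29,
#'   20, 14) gives the clinical cohort size of 93.
#' @param effects list of multiplicative group-effect factors applied to the
#'   RVPA arms' shape parameters, by stage.  The default injects mild
#'   dilation at stage I and dilation + reduced sphericity at stage II;
#'   set both to \code{c(dilation = 1, sphericity = 1)} for a null cohort.
#' @param bsa list of \code{c(mean, sd)} BSA (m^2) per arm.
#' @param paramSD population log-SDs of the shape factors and the tilt SD
#'   (degrees) and vertex noise (mm).
#' @param strain list of mean peak strains (fractions) per group.
#' @param seed master seed; all per-subject streams derive from it.
#' @return List of class "CohortConfig".
#' @export
cohortConfig <- function(nPerArm = c(MBT_I = 30L, MBT_II = 29L,
                                     RVPA_I = 20L, RVPA_II = 14L),
                         effects = list(
                           I = c(dilation = 1.07, sphericity = 0.97),
                           II = c(dilation = 1.09, sphericity = 0.88)),
                         bsa = list(MBT_I = c(0.40, 0.04),
                                    MBT_II = c(0.67, 0.12),
                                    RVPA_I = c(0.44, 0.06),
                                    RVPA_II = c(0.70, 0.11)),
                         paramSD = c(dilation = 0.08, sphericity = 0.06,
                                     base_width = 0.05, tilt_deg = 2,
                                     wall = 0.10, noise_mm = 0.8),
                         strain = list(MBT = c(circ = -0.169, long = -0.148),
                                       RVPA = c(circ = -0.130, long = -0.122)),
                         seed = 1L) {
  arms <- paste(.ARM_ORDER$group, .ARM_ORDER$stage, sep = "_")
  if (!all(arms %in% names(nPerArm))) stop("nPerArm must name all four arms")
  if (any(nPerArm < 2L)) stop("each arm needs n >= 2 (statistics undefined)")
  structure(list(nPerArm = nPerArm[arms], effects = effects, bsa = bsa,
                 paramSD = paramSD, strain = strain,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

# draw one subject's metadata and shape parameters from its own seed stream
.drawSubject <- function(config, group, stage, armIndex, i) {
  sd1 <- .subjectSeed(config$seed, armIndex, i)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(sd1)
  arm <- paste(group, stage, sep = "_")
  b <- config$bsa[[arm]]
  bsa <- max(0.25, rnorm(1, b[1], b[2]))
  height <- if (stage == "I") rnorm(1, 58, 3) else rnorm(1, 88, 6)
  # weight solved from the Haycock relation given BSA and height
  weight <- (bsa / (0.024265 * height^0.3964))^(1 / 0.5378)
  eff <- if (group == "RVPA") config$effects[[stage]] else
    c(dilation = 1, sphericity = 1)
  ps <- config$paramSD
  # allometric size: cavity volume tracks BSA^1.3 (reference BSA 0.5 m^2)
  params <- shapeParams(
    dilation_scale = (bsa / 0.5)^(1.3 / 3) * exp(rnorm(1, 0, ps[["dilation"]])) *
      eff[["dilation"]],
    sphericity_factor = exp(rnorm(1, 0, ps[["sphericity"]])) *
      eff[["sphericity"]],
    base_width_factor = exp(rnorm(1, 0, ps[["base_width"]])),
    apex_tilt_deg = rnorm(1, 0, ps[["tilt_deg"]]),
    # wall varies around the template's 4 mm; overall size (including the
    # wall) is carried by dilation_scale, so no separate BSA factor here
    wall_thickness_mm = 4 * exp(rnorm(1, 0, ps[["wall"]])),
    noise_sd_mm = ps[["noise_mm"]])
  trPool <- runif(1)
  tr <- if (trPool < 0.45) 0 else if (trPool < 0.85) runif(1, 0.02, 0.15) else
    if (trPool < 0.95) runif(1, 0.15, 0.25) else runif(1, 0.25, 0.50)
  lvShape <- sample(c("globular", "slit-like", "borderline"), 1,
                    prob = c(0.5, 0.3, 0.2))
  st <- config$strain[[group]]
  motion <- motionParams(
    n_frames = 25L, rr_interval_s = 0.5,
    peak_circ_strain = max(-0.6, min(-0.02, rnorm(1, st[["circ"]], 0.04))),
    peak_long_strain = max(-0.6, min(-0.02, rnorm(1, st[["long"]], 0.04))),
    systole_fraction = 0.35, incompressible_wall = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(bsa = bsa, height = height, weight = weight, params = params,
       tr = tr, lvShape = lvShape, motion = motion,
       meshSeed = .subjectSeed(config$seed, armIndex, i, salt = 1L))
}

#' Generate a synthetic cohort
#'
#' Draws every subject's metadata, shape parameters and deformed mesh, with
#' optional rasterised segmentation stacks and cine contour sequences.
#' Fully deterministic under the config seed; per-subject seed streams are
#' counter-based so changing one arm's size does not reshuffle the others.
#'
#' @param config a [cohortConfig()].
#' @param rasterize also voxelise each subject into a
#'   [SegmentationStack-class] (slower).
#' @param cine also generate each subject's cine contours and motion ground
#'   truth.
#' @param template template mesh (defaults to [generateTemplate()]).
#' @return List with \code{table} (the cohort data frame: subject_id, group,
#'   stage, weight_kg, height_cm, bsa_m2, tr_fraction, lv_shape) and
#'   \code{subjects} (per-subject list: params, mesh, shape vector, truth,
#'   and optionally stack / cine).
#' @export
generateCohort <- function(config = cohortConfig(), rasterize = FALSE,
                           cine = FALSE, template = generateTemplate()) {
  stopifnot(inherits(config, "CohortConfig"))
  rows <- list(); subjects <- list()
  sid <- 0L
  for (a in seq_len(nrow(.ARM_ORDER))) {
    group <- .ARM_ORDER$group[a]; stage <- .ARM_ORDER$stage[a]
    arm <- paste(group, stage, sep = "_")
    for (i in seq_len(config$nPerArm[[arm]])) {
      sid <- sid + 1L
      d <- .drawSubject(config, group, stage, a, i)
      # deterministic rejection sampling: redraw the vertex noise (not the
      # parameters) if a draw would self-intersect
      mesh <- NULL
      for (try_ in 0:4) {
        mesh <- tryCatch(deformShape(template, d$params,
                                     seed = d$meshSeed + try_ * 7717),
                         error = function(e) NULL)
        if (!is.null(mesh)) break
      }
      if (is.null(mesh))
        stop("subject ", group, "-", stage, " #", i,
             " could not be generated without self-intersection")
      tv <- truthVolumes(d$params)
      truth <- list(params = unclass(d$params),
                    cavity_ml = tv$cavity_ml, wall_ml = tv$wall_ml)
      subj <- list(id = sprintf("S%03d", sid), group = group, stage = stage,
                   params = d$params, motion = d$motion, mesh = mesh,
                   vector = shapeVector(mesh), truth = truth)
      if (rasterize)
        subj$stack <- rasterizeSegmentation(mesh, voxel_mm = 1.5,
                                            slice_thickness_mm = 3)
      if (cine) {
        cc <- generateCine(mesh, d$motion, truthCavityMl = tv$cavity_ml)
        subj$cine <- cc$contours
        subj$truth <- c(subj$truth, cc$truth[c(
          "edv_ml", "esv_ml", "ef_pct", "ed_frame", "es_frame",
          "peak_circ_strain", "peak_long_strain")])
        subj$cineTruth <- cc$truth
      }
      subjects[[sid]] <- subj
      rows[[sid]] <- data.frame(
        subject_id = subj$id, group = group, stage = stage,
        weight_kg = d$weight, height_cm = d$height, bsa_m2 = d$bsa,
        tr_fraction = d$tr, lv_shape = d$lvShape,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), subjects = subjects)
}

#' Shape-vector matrix of a cohort
#'
#' @param cohort output of [generateCohort()].
#' @return N x p matrix, one shape vector per subject.
#' @export
cohortShapeMatrix <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, `[[`, "vector"))
}

#' Write a cohort to disk
#'
#' Emits \code{cohort.csv} plus, per subject, \code{seg.nii.gz} (when
#' stacks were generated), \code{contours_<level>.json} (frames of ordered
#' [x, y] mm points with the frame interval) and \code{truth.json}.
#'
#' @param cohort output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (subj in cohort$subjects) {
    sdir <- file.path(dir, subj$id)
    dir.create(sdir, showWarnings = FALSE)
    if (!is.null(subj$stack))
      writeSegmentation(subj$stack, file.path(sdir, "seg.nii.gz"))
    if (!is.null(subj$cine)) {
      for (lv in c("4ch", "basal", "mid", "apical")) {
        cs <- subj$cine[[lv]]
        frames <- lapply(seq_len(dim(cs@points)[1]),
                         function(f) unname(cs@points[f, , ]))
        jsonlite::write_json(
          list(level = lv, frame_interval_s = cs@frameInterval,
               closed = cs@closed, frames = frames),
          file.path(sdir, paste0("contours_", lv, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
    jsonlite::write_json(subj$truth, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a generator contour JSON back as a ContourSequence
#'
#' @param path a \code{contours_<level>.json} written by [writeCohort()].
#' @param surface surface tag for the metadata.
#' @return A [ContourSequence-class].
#' @export
readContours <- function(path, surface = "endo") {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  frames <- j$frames
  if (is.list(frames)) {
    arr <- array(0, c(length(frames), nrow(frames[[1]]), 2))
    for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  } else arr <- frames
  new("ContourSequence", points = arr, frameInterval = j$frame_interval_s,
      level = j$level, surface = surface, closed = isTRUE(j$closed))
}
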