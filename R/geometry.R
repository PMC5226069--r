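# Volumetric and 2D geometric measurements of the systemic RV: Simpson
# slice-summation volumetry, EF, myocardial mass, length/diameter/sphericity
# and wall-thickness statistics, Haycock BSA and allometric indexing, and
# tricuspid regurgitation grading.

#' Simpson slice-summation volume curve with EDV/ESV/SV/EF
#'
#' Per-frame ventricular volume as the sum of per-slice cavity areas times
#' the effective slice spacing (thickness + gap).  End-diastole is the frame
#' of maximum volume, end-systole the minimum; stroke volume is their
#' difference and ejection fraction (EDV - ESV) / EDV x 100.
#'
#' @param areas numeric matrix (frames x slices) of cavity areas in mm^2, or
#'   a numeric vector for a single frame.
#' @param spacing effective slice spacing in mm.
#' @return List: \code{volume_ml} per frame, \code{edv_ml}, \code{esv_ml},
#'   \code{sv_ml}, \code{ef_pct}, \code{ed_frame}, \code{es_frame}.
#' @export
volumeCurve <- function(areas, spacing) {
  if (is.vector(areas)) areas <- matrix(areas, nrow = 1)
  if (nrow(areas) < 1L) stop("at least one frame required")
  if (spacing <= 0) stop("slice spacing must be positive")
  vol <- rowSums(areas) * spacing / 1000   # ml
  ed <- which.max(vol); es <- which.min(vol)
  edv <- vol[ed]; esv <- vol[es]
  if (edv <= 0) stop("EF undefined: zero end-diastolic volume")
  list(volume_ml = vol, edv_ml = edv, esv_ml = esv, sv_ml = edv - esv,
       ef_pct = (edv - esv) / edv * 100, ed_frame = ed, es_frame = es)
}

#' Myocardial mass from the endo/epicardial surface pair
#'
#' Wall volume (epicardial minus endocardial enclosed volume) times the
#' standard myocardial density of 1.05 g/ml.
#'
#' @param mesh a [CorrespondedMesh-class].
#' @param density_g_ml myocardial density (g/ml), default 1.05.
#' @return Mass in grams.
#' @export
myocardialMass <- function(mesh, density_g_ml = 1.05) {
  gap <- .pairedWallThickness(mesh)
  if (any(gap < 0)) stop("endo and epi surfaces intersect")
  wall <- meshVolume(mesh, "epi") - meshVolume(mesh, "endo")
  if (wall < -1e-9) stop("endo and epi surfaces intersect (negative wall volume)")
  max(wall, 0) / 1000 * density_g_ml
}

# caliper width of a ring: the maximum pairwise in-plane distance
.ringCaliper <- function(V, nTheta, nRings) {
  vapply(seq_len(nRings), function(j) {
    P <- V[(j - 1L) * nTheta + seq_len(nTheta), 1:2, drop = FALSE]
    max(stats::dist(P))
  }, numeric(1))
}

#' 2D geometric indices of a fitted mesh
#'
#' Traditional measurements extracted from the personalised mesh (assumed in
#' standard pose, long axis along z): base-to-apex length, maximum cavity
#' and epicardial caliper diameters perpendicular to the long axis, the
#' sphericity ratio (length / maximum cavity diameter; lower = rounder),
#' and wall-thickness statistics from paired endo-epi vertex distances
#' (maximum overall; standard deviation over the septal vertex subset).
#'
#' @param mesh a [CorrespondedMesh-class].
#' @return Named list of measurements (mm, unitless for sphericity).
#' @export
geometricIndices <- function(mesh) {
  stopifnot(is(mesh, "CorrespondedMesh"))
  nT <- mesh@nTheta; nR <- mesh@nRings
  # cavity (endocardial) base-to-apex extent, consistent with the cavity
  # diameter used in the sphericity ratio
  len <- diff(range(mesh@endo[, 3]))
  dCav <- max(.ringCaliper(mesh@endo, nT, nR))
  dEpi <- max(.ringCaliper(mesh@epi, nT, nR))
  thick <- .pairedWallThickness(mesh)
  septSD <- if (any(mesh@septalMask)) sd(thick[mesh@septalMask]) else {
    warning("missing septal mask: septal wall-thickness SD omitted")
    NA_real_
  }
  list(length_mm = len,
       max_cavity_diameter_mm = dCav,
       max_epicardial_diameter_mm = dEpi,
       sphericity_ratio = len / dCav,
       max_wall_thickness_mm = max(thick),
       septal_wall_sd_mm = septSD)
}

#' Haycock body surface area
#'
#' BSA = 0.024265 x weight^0.5378 x height^0.3964, with weight in kg and
#' height in cm (published Haycock coefficients).
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm body height in cm (> 0).
#' @return BSA in m^2.
#' @export
haycockBSA <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive")
  0.024265 * weight_kg^0.5378 * height_cm^0.3964
}

#' Allometric BSA indexing
#'
#' Indexes a measurement to body surface area with the exponent appropriate
#' to its kind: volumes by BSA^1.3 (ml/BSA^1.3), lengths by the square root
#' of BSA (mm/sqrt(m^2)), mass by a configurable exponent (default 1.3).
#'
#' @param value measurement to index.
#' @param bsa body surface area in m^2 (> 0).
#' @param kind "volume", "length" or "mass".
#' @param mass_exponent exponent used for \code{kind = "mass"}.
#' @return Indexed value.
#' @export
allometricIndex <- function(value, bsa, kind = c("volume", "length", "mass"),
                            mass_exponent = 1.3) {
  if (any(bsa <= 0)) stop("BSA must be positive")
  kind <- match.arg(kind)
  expo <- switch(kind, volume = 1.3, length = 0.5, mass = mass_exponent)
  value / bsa^expo
}

#' Grade tricuspid regurgitation from regurgitant fraction
#'
#' Clinical bins: mild < 15\%, moderate 15-25\%, moderate-severe 25-45\%,
#' severe > 45\%; a fraction of exactly 0 is "none" and bin boundaries are
#' assigned to the lower-severity grade.
#'
#' @param fraction regurgitant fraction in [0, 1].
#' @return Factor with levels none < mild < moderate < moderate-severe <
#'   severe.
#' @export
gradeTR <- function(fraction) {
  if (any(fraction < 0 | fraction > 1))
    stop("regurgitant fraction must be within [0, 1]")
  lev <- c("none", "mild", "moderate", "moderate-severe", "severe")
  g <- ifelse(fraction == 0, "none",
       ifelse(fraction <= 0.15, "mild",
       ifelse(fraction <= 0.25, "moderate",
       ifelse(fraction <= 0.45, "moderate-severe", "severe"))))
  factor(g, levels = lev, ordered = TRUE)
}

#' Full geometry report for one subject
#'
#' Combines volumetry (from a cine volume curve), mass, 2D indices and
#' allometric indexing into the per-subject measurement set used by the
#' cohort report tables.
#'
#' @param mesh fitted [CorrespondedMesh-class] at end-diastole.
#' @param vc output of [volumeCurve()] (optional; mesh volumes used if
#'   absent).
#' @param bsa body surface area in m^2.
#' @param mass_exponent allometric exponent for mass indexing.
#' @return Named list mirroring the report-table rows, including indexed
#'   variants (prefix \code{i}) and the indexing metadata.
#' @export
geometryReport <- function(mesh, vc = NULL, bsa, mass_exponent = 1.3) {
  gi <- geometricIndices(mesh)
  mass <- myocardialMass(mesh)
  if (is.null(vc)) {
    edv <- meshVolume(mesh, "endo") / 1000
    vc <- list(edv_ml = edv, esv_ml = NA_real_, sv_ml = NA_real_,
               ef_pct = NA_real_)
  }
  list(edv_ml = vc$edv_ml, esv_ml = vc$esv_ml, sv_ml = vc$sv_ml,
       ef_pct = vc$ef_pct, mass_g = mass,
       length_mm = gi$length_mm,
       max_cavity_diameter_mm = gi$max_cavity_diameter_mm,
       max_epicardial_diameter_mm = gi$max_epicardial_diameter_mm,
       sphericity_ratio = gi$sphericity_ratio,
       max_wall_thickness_mm = gi$max_wall_thickness_mm,
       septal_wall_sd_mm = gi$septal_wall_sd_mm,
       bsa_m2 = bsa,
       iedv = allometricIndex(vc$edv_ml, bsa, "volume"),
       iesv = allometricIndex(vc$esv_ml, bsa, "volume"),
       isv = allometricIndex(vc$sv_ml, bsa, "volume"),
       imass = allometricIndex(mass, bsa, "mass", mass_exponent),
       ilength = allometricIndex(gi$length_mm, bsa, "length"),
       icav_diam = allometricIndex(gi$max_cavity_diameter_mm, bsa, "length"),
       iepi_diam = allometricIndex(gi$max_epicardial_diameter_mm, bsa, "length"),
       iwall_max = allometricIndex(gi$max_wall_thickness_mm, bsa, "length"),
       iseptal_sd = allometricIndex(gi$septal_wall_sd_mm, bsa, "length"),
       mass_exponent = mass_exponent)
}
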