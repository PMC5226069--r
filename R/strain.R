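# Feature-tracking style strain analysis: contour propagation by arc-length
# reparameterisation and minimal-shift correspondence, segmental Lagrangian
# strain against the frame-0 reference, strain rate by finite differences,
# and peak extraction in the systolic/diastolic windows.

#' Propagate and correspond a contour sequence
#'
#' Re-parameterises every frame's boundary to a fixed point count by arc
#' length, then matches it to frame 0 by the circular shift (and, for closed
#' contours, orientation) minimising the summed squared point displacement.
#' This replaces the proprietary image-based tracker and is exact on
#' label-derived synthetic cines.
#'
#' @param x a [ContourSequence-class], a list of per-frame point matrices,
#'   or a (frames, nx, ny) binary mask array.
#' @param nPoints points per resampled contour (must be divisible by the
#'   segment count used downstream).
#' @param frameInterval seconds between frames (required unless \code{x} is
#'   a ContourSequence).
#' @param closed is the contour closed (SAX) or open (4ch)?
#' @param level,surface metadata for the output sequence.
#' @param voxelSize in-plane voxel size when \code{x} is a mask array.
#' @return A [ContourSequence-class] with corresponded points.
#' @export
propagateContour <- function(x, nPoints = 96L, frameInterval = NULL,
                             closed = TRUE, level = "mid", surface = "endo",
                             voxelSize = c(1, 1)) {
  if (is(x, "ContourSequence")) {
    frames <- lapply(seq_len(dim(x@points)[1]), function(f) x@points[f, , ])
    frameInterval <- x@frameInterval
    closed <- x@closed
    level <- x@level
    surface <- x@surface
  } else if (is.array(x) && length(dim(x)) == 3L) {
    frames <- lapply(seq_len(dim(x)[1]), function(f) {
      mask <- x[f, , ]
      if (!any(mask > 0)) stop("empty mask in frame ", f)
      cl <- .sliceContours(mask > 0, voxelSize)
      cl[[which.max(vapply(cl, nrow, integer(1)))]]
    })
  } else if (is.list(x)) {
    frames <- x
  } else stop("unsupported input for contour propagation")
  if (is.null(frameInterval)) stop("frameInterval is required")
  nF <- length(frames)
  for (f in seq_len(nF))
    if (is.null(frames[[f]]) || nrow(frames[[f]]) < 3L)
      stop("empty mask in frame ", f)
  out <- array(0, c(nF, nPoints, 2))
  ref <- if (closed) .resampleClosed(frames[[1]], nPoints) else
    .resampleOpen(frames[[1]], nPoints)
  out[1, , ] <- ref
  for (f in seq_len(nF)[-1]) {
    Q <- if (closed) .resampleClosed(frames[[f]], nPoints) else
      .resampleOpen(frames[[f]], nPoints)
    if (closed) {
      best <- NULL; bestCost <- Inf
      for (orient in c(1L, -1L)) {
        Qo <- if (orient == 1L) Q else Q[rev(seq_len(nPoints)), , drop = FALSE]
        # translation-invariant circular alignment
        for (s in 0:(nPoints - 1L)) {
          idx <- ((seq_len(nPoints) - 1L + s) %% nPoints) + 1L
          d <- Qo[idx, , drop = FALSE] - ref
          d <- sweep(d, 2, colMeans(d))
          cost <- sum(d^2)
          if (cost < bestCost) { bestCost <- cost; best <- Qo[idx, , drop = FALSE] }
        }
      }
      Q <- best
    }
    out[f, , ] <- Q
  }
  new("ContourSequence", points = out, frameInterval = frameInterval,
      level = level, surface = surface, closed = closed)
}

#' Choose basal/mid/apical short-axis levels
#'
#' Returns the RV-containing slice indices nearest to 25/50/75\% of the
#' base-to-apex extent.
#'
#' @param x a [SegmentationStack-class] or the number of RV-containing
#'   slices.
#' @return Named integer vector (basal, mid, apical), 1-based slice indices,
#'   with the achieved extent fractions as attribute \code{"fraction"}.
#' @export
selectSaxLevels <- function(x) {
  if (is(x, "SegmentationStack")) {
    lg <- x@legend
    rv <- which(apply(x@labels, 3, function(m)
      any(m == lg[["myocardium"]] | m == lg[["cavity"]])))
  } else {
    rv <- seq_len(as.integer(x))
  }
  n <- length(rv)
  if (n < 3L) stop("at least 3 RV-containing slices are required")
  frac <- (seq_len(n) - 1) / (n - 1)
  # nearest slice to each quartile position; exact half-way ties resolve by
  # rounding so that 3 slices map to basal/mid/apical in order
  pick <- as.integer(round(c(0.25, 0.5, 0.75) * (n - 1))) + 1L
  out <- rv[pick]
  names(out) <- c("basal", "mid", "apical")
  attr(out, "fraction") <- frac[pick]
  out
}

.segmentLengths <- function(P, nSegments, closed) {
  n <- nrow(P)
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  edges <- sqrt(rowSums(diff(Q)^2))       # n edges closed, n-1 open
  nE <- length(edges)
  segId <- ceiling(seq_len(nE) / (nE / nSegments))
  as.numeric(tapply(edges, segId, sum))
}

.segmentRadii <- function(P, nSegments) {
  cen <- colMeans(P)
  r <- sqrt((P[, 1] - cen[1])^2 + (P[, 2] - cen[2])^2)
  segId <- ceiling(seq_len(nrow(P)) / (nrow(P) / nSegments))
  as.numeric(tapply(r, segId, mean))
}

#' Segmental and global Lagrangian strain
#'
#' Circumferential (closed SAX) or longitudinal (open 4ch) strain from
#' per-segment arc lengths, \code{(L(t) - L(0)) / L(0) x 100}; radial strain
#' either from inverted centroid-distance change (endo-only, inward systolic
#' motion positive) or from wall thickness when an epicardial sequence is
#' supplied.  Global strain is the arithmetic mean of the segments at every
#' frame; negative values are shortening, positive lengthening.
#'
#' @param seq endocardial [ContourSequence-class] (from
#'   [propagateContour()] or the generator).
#' @param nSegments segments per level (default 6).
#' @param direction "circumferential", "longitudinal" or "radial"; defaults
#'   to longitudinal for the 4ch level, circumferential otherwise.
#' @param epiSeq optional epicardial [ContourSequence-class] for
#'   thickness-based radial strain.
#' @return A [StrainResult-class] (strain curves; rates and peaks are
#'   filled by [strainRateAndPeaks()]).
#' @export
computeStrain <- function(seq, nSegments = 6L,
                          direction = NULL, epiSeq = NULL) {
  stopifnot(is(seq, "ContourSequence"))
  if (nSegments < 2L) stop("nSegments must be >= 2")
  if (is.null(direction))
    direction <- if (seq@level == "4ch") "longitudinal" else "circumferential"
  nF <- dim(seq@points)[1]
  radialMethod <- NA_character_
  if (direction == "radial") {
    if (!seq@closed) stop("radial strain requires closed short-axis contours")
    if (!is.null(epiSeq)) {
      radialMethod <- "thickness"
      segs <- t(vapply(seq_len(nF), function(f) {
        cen <- colMeans(seq@points[f, , ])
        rE <- .segmentRadiiAbout(seq@points[f, , ], cen, nSegments)
        rP <- .segmentRadiiAbout(epiSeq@points[f, , ], cen, nSegments)
        rP - rE
      }, numeric(nSegments)))
      strain <- sweep(segs, 2, segs[1, ], function(a, b) (a - b) / b * 100)
    } else {
      radialMethod <- "centroid"
      segs <- t(vapply(seq_len(nF), function(f)
        .segmentRadii(seq@points[f, , ], nSegments), numeric(nSegments)))
      strain <- sweep(segs, 2, segs[1, ], function(a, b) (b - a) / b * 100)
    }
  } else {
    segs <- t(vapply(seq_len(nF), function(f)
      .segmentLengths(seq@points[f, , ], nSegments, seq@closed),
      numeric(nSegments)))
    strain <- sweep(segs, 2, segs[1, ], function(a, b) (a - b) / b * 100)
  }
  tms <- (seq_len(nF) - 1) * seq@frameInterval
  new("StrainResult", direction = direction, level = seq@level,
      time = tms, segmentStrain = strain, globalStrain = rowMeans(strain),
      segmentRate = matrix(NA_real_, nF, nSegments),
      globalRate = rep(NA_real_, nF),
      peaks = c(systolic_strain_pct = NA_real_,
                systolic_rate_per_s = NA_real_,
                diastolic_rate_per_s = NA_real_),
      radialMethod = radialMethod)
}

# mean radial distance of points about a given centre, segmented to match
# the endo segmentation
.segmentRadiiAbout <- function(P, cen, nSegments) {
  r <- sqrt((P[, 1] - cen[1])^2 + (P[, 2] - cen[2])^2)
  segId <- ceiling(seq_len(nrow(P)) / (nrow(P) / nSegments))
  as.numeric(tapply(r, segId, mean))
}

# finite-difference derivative: central in the interior, one-sided at the
# ends (keeps time reversal antisymmetric)
.timeDerivative <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

#' Strain rate and systolic/diastolic peaks
#'
#' Adds strain-rate curves (finite difference of the strain fraction, in
#' 1/s) and peak values to a [StrainResult-class].  The systolic peaks are
#' the largest-magnitude values between end-diastole and end-systole; the
#' diastolic rate peak is taken after end-systole.
#'
#' @param result a [StrainResult-class] from [computeStrain()].
#' @param edFrame,esFrame end-diastolic and end-systolic frame indices,
#'   typically from [volumeCurve()] (or the generator truth).
#' @return The completed [StrainResult-class].
#' @export
strainRateAndPeaks <- function(result, edFrame = 1L, esFrame) {
  stopifnot(is(result, "StrainResult"))
  nF <- length(result@time)
  if (nF < 3L) stop("strain rate undefined: fewer than 3 frames")
  dt <- result@time[2] - result@time[1]
  segRate <- apply(result@segmentStrain / 100, 2, .timeDerivative, dt = dt)
  globRate <- .timeDerivative(result@globalStrain / 100, dt)
  sysIdx <- edFrame:esFrame
  diaIdx <- if (esFrame < nF) (esFrame + 1L):nF else integer(0)
  pick <- function(v, idx) if (length(idx) == 0) NA_real_ else
    v[idx][which.max(abs(v[idx]))]
  peaks <- c(systolic_strain_pct = pick(result@globalStrain, sysIdx),
             systolic_rate_per_s = pick(globRate, sysIdx),
             diastolic_rate_per_s = pick(globRate, diaIdx))
  initialize(result, segmentRate = segRate, globalRate = globRate,
             peaks = peaks)
}

#' Full strain analysis of a generated cine
#'
#' Runs propagation, strain, rate and peak extraction for every direction
#' and level of a generator cine (longitudinal at 4ch; circumferential and
#' radial at basal/mid/apical).
#'
#' @param cine output of [generateCine()].
#' @param nSegments segments per level.
#' @param nPoints resampled points per contour.
#' @return Data frame of peaks (level, direction, peak strain and rates)
#'   with the list of [StrainResult-class] objects as attribute
#'   \code{"results"}.
#' @export
strainTable <- function(cine, nSegments = 6L, nPoints = 96L) {
  ed <- cine$truth$ed_frame; es <- cine$truth$es_frame
  res <- list()
  for (lv in c("basal", "mid", "apical")) {
    tr <- propagateContour(cine$contours[[lv]], nPoints = nPoints)
    trEpi <- propagateContour(cine$contours[[paste0(lv, "_epi")]],
                              nPoints = nPoints)
    res[[paste0(lv, "_circumferential")]] <- strainRateAndPeaks(
      computeStrain(tr, nSegments), ed, es)
    res[[paste0(lv, "_radial")]] <- strainRateAndPeaks(
      computeStrain(tr, nSegments, direction = "radial"), ed, es)
    res[[paste0(lv, "_radial_thickness")]] <- strainRateAndPeaks(
      computeStrain(tr, nSegments, direction = "radial", epiSeq = trEpi),
      ed, es)
  }
  tr4 <- propagateContour(cine$contours[["4ch"]], nPoints = nPoints)
  res[["4ch_longitudinal"]] <- strainRateAndPeaks(
    computeStrain(tr4, nSegments), ed, es)
  peaks <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(level = r@level, direction = r@direction,
               radial_method = r@radialMethod,
               systolic_strain_pct = r@peaks[["systolic_strain_pct"]],
               systolic_rate_per_s = r@peaks[["systolic_rate_per_s"]],
               diastolic_rate_per_s = r@peaks[["diastolic_rate_per_s"]])
  }))
  attr(peaks, "results") <- res
  peaks
}
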