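# Mesh personalization: deforms the corresponded template onto the
# standardized boundary point clouds of one subject.  Correspondence uses
# polar rays about the per-slice cavity centre (the closest-point rule
# specialised to star-shaped short-axis sections), followed by Laplacian
# smoothing of the radius field over the ring grid.  A decreasing smoothing
# schedule with an accept-only-if-error-improves rule makes the per-iteration
# fitting-error log monotone non-increasing.

# circular linear interpolation of radius at query angles
.interpRadiusTheta <- function(theta, r, query) {
  o <- order(theta)
  th <- theta[o]; rr <- r[o]
  th <- c(th, th[1] + 2 * pi)
  rr <- c(rr, rr[1])
  q <- th[1] + ((query - th[1]) %% (2 * pi))
  stats::approx(th, rr, xout = q, rule = 2, ties = mean)$y
}

# per-slice radius model of one surface's boundary cloud; points carry a
# slice index in column 4 (else slices are recovered from rounded z)
.sliceRadiusModel <- function(pts) {
  sliceId <- if (ncol(pts) >= 4L) pts[, 4] else round(pts[, 3], 6)
  groups <- split(seq_len(nrow(pts)), sliceId)
  zOf <- vapply(groups, function(ix) mean(pts[ix, 3]), numeric(1))
  o <- order(zOf, decreasing = TRUE)
  groups <- groups[o]; zOf <- zOf[o]
  models <- lapply(groups, function(ix) {
    p <- pts[ix, , drop = FALSE]
    cen <- c(mean(p[, 1]), mean(p[, 2]))
    d <- sweep(p[, 1:2, drop = FALSE], 2, cen)
    list(center = cen, theta = atan2(d[, 2], d[, 1]),
         r = sqrt(rowSums(d^2)))
  })
  list(z = unname(zOf), models = models)
}

# evaluate target radius + centre at height z and angles theta
.targetAtZ <- function(rm, z, theta) {
  zs <- rm$z
  n <- length(zs)
  if (z >= zs[1]) {
    m <- rm$models[[1]]
    return(list(center = m$center, r = .interpRadiusTheta(m$theta, m$r, theta)))
  }
  if (z <= zs[n]) {
    # beyond the most apical slice: taper the last contour towards the apex
    m <- rm$models[[n]]
    sp <- if (n > 1) abs(zs[n - 1] - zs[n]) else 1
    apexZ <- zs[n] - 1.5 * sp
    u <- max(0, min(1, (z - apexZ) / (zs[n] - apexZ)))
    fac <- sqrt(u)
    return(list(center = m$center,
                r = fac * .interpRadiusTheta(m$theta, m$r, theta)))
  }
  j <- findInterval(-z, -zs)
  w <- (zs[j] - z) / (zs[j] - zs[j + 1])
  a <- rm$models[[j]]; b <- rm$models[[j + 1]]
  ra <- .interpRadiusTheta(a$theta, a$r, theta)
  rb <- .interpRadiusTheta(b$theta, b$r, theta)
  list(center = (1 - w) * a$center + w * b$center, r = (1 - w) * ra + w * rb)
}

# Laplacian smoothing of a ring-grid scalar field (nTheta x nRings)
.smoothField <- function(f, lambda, passes = 2L) {
  if (lambda <= 0) return(f)
  nT <- nrow(f); nR <- ncol(f)
  for (p in seq_len(passes)) {
    up <- f[c(nT, seq_len(nT - 1L)), , drop = FALSE]
    dn <- f[c(seq_len(nT - 1L) + 1L, 1L), , drop = FALSE]
    lf <- f[, c(1L, seq_len(nR - 1L)), drop = FALSE]
    rt <- f[, c(seq_len(nR - 1L) + 1L, nR), drop = FALSE]
    f <- (1 - lambda) * f + lambda * (up + dn + lf + rt) / 4
  }
  f
}

# mean in-plane distance of boundary points to the mesh surface, using the
# interpolated ring polygon at each point's slice height
.pointToSurfaceError <- function(pts, V, nTheta, nRings) {
  sliceId <- if (ncol(pts) >= 4L) pts[, 4] else round(pts[, 3], 6)
  groups <- split(seq_len(nrow(pts)), sliceId)
  total <- 0; n <- 0
  for (ix in groups) {
    z <- mean(pts[ix, 3])
    poly <- .slicePolygon(V, nTheta, nRings, z)
    if (is.null(poly)) {
      # beyond the mesh: distance to the nearest mesh vertex
      p <- pts[ix, , drop = FALSE]
      for (i in seq_len(nrow(p))) {
        d2 <- (V[, 1] - p[i, 1])^2 + (V[, 2] - p[i, 2])^2 + (V[, 3] - p[i, 3])^2
        total <- total + sqrt(min(d2)); n <- n + 1
      }
      next
    }
    p <- pts[ix, 1:2, drop = FALSE]
    nx <- poly[c(seq_len(nTheta - 1L) + 1L, 1L), , drop = FALSE]
    ex <- nx[, 1] - poly[, 1]; ey <- nx[, 2] - poly[, 2]
    el2 <- ex^2 + ey^2 + 1e-300
    for (i in seq_len(nrow(p))) {
      tpar <- pmin(1, pmax(0, ((p[i, 1] - poly[, 1]) * ex +
                               (p[i, 2] - poly[, 2]) * ey) / el2))
      dx <- poly[, 1] + tpar * ex - p[i, 1]
      dy <- poly[, 2] + tpar * ey - p[i, 2]
      total <- total + sqrt(min(dx^2 + dy^2)); n <- n + 1
    }
  }
  total / n
}

# fit one surface: returns vertex matrix given targets at the template's
# ring heights, with smoothing weight lambda
.fitSurface <- function(rm, ringZ, nTheta, lambda) {
  th <- .ringTheta(nTheta)
  nR <- length(ringZ)
  rF <- matrix(0, nTheta, nR)
  cx <- numeric(nR); cy <- numeric(nR)
  for (j in seq_len(nR)) {
    tgt <- .targetAtZ(rm, ringZ[j], th)
    rF[, j] <- tgt$r
    cx[j] <- tgt$center[1]; cy[j] <- tgt$center[2]
  }
  rF <- .smoothField(rF, lambda)
  V <- matrix(0, nTheta * nR, 3)
  for (j in seq_len(nR)) {
    idx <- (j - 1L) * nTheta + seq_len(nTheta)
    V[idx, 1] <- cx[j] + rF[, j] * cos(th)
    V[idx, 2] <- cy[j] + rF[, j] * sin(th)
    V[idx, 3] <- ringZ[j]
  }
  V
}

#' Fit the corresponded template to boundary point clouds
#'
#' Personalises the template mesh to a subject's pose-standardized boundary
#' points (output of [standardizePose()]).  The template's rings are mapped
#' affinely onto the subject's long-axis extent; each vertex is then matched
#' along its polar ray to the interpolated boundary radius, with Laplacian
#' smoothing over the ring grid decreasing across iterations.  Iterations
#' that would increase the fitting error are rejected, so the recorded error
#' log is monotone non-increasing.
#'
#' @param bnd list with \code{endo}, \code{epi} point matrices (x, y, z mm)
#'   and \code{landmark}; typically from [standardizePose()].
#' @param template a [CorrespondedMesh-class] from [generateTemplate()].
#' @param maxIter maximum number of smoothing-schedule iterations.
#' @param tol convergence tolerance on the fitting error (mm).
#' @return A fitted [CorrespondedMesh-class] with \code{fittingError} set
#'   (mean point-to-surface distance over all boundary points, mm) and an
#'   attribute \code{"errorLog"} holding the per-iteration error.
#' @export
fitTemplate <- function(bnd, template, maxIter = 8L, tol = 1e-4) {
  stopifnot(is(template, "CorrespondedMesh"))
  if (is.null(bnd$endo) || is.null(bnd$epi))
    stop("boundary clouds must contain endo and epi points")
  nTheta <- template@nTheta; nRings <- template@nRings
  t <- .ringT(nRings)
  rmE <- .sliceRadiusModel(bnd$endo)
  rmP <- .sliceRadiusModel(bnd$epi)
  # ring heights: cover the full slab extent (slice centres plus half a
  # spacing at base and apex) unless the slices already span single planes
  spE <- if (length(rmE$z) > 1) abs(stats::median(diff(rmE$z))) else 0
  # data at least as finely sliced as the ring grid are treated as surface
  # samples (no half-slice slab extension)
  singlePlane <- spE == 0 || length(rmE$z) >= nRings
  half <- if (singlePlane) 0 else spE / 2
  tLast <- t[length(t)]
  ringsOver <- function(rm) {
    top <- max(rm$z) + half
    bottom <- min(rm$z) - half
    top - t * ((top - bottom) / tLast)
  }
  ringZE <- ringsOver(rmE)
  ringZP <- ringsOver(rmP)
  lambdas <- c(0.5, 0.3, 0.2, 0.1, 0.05, 0.02, 0.01, 0)
  lambdas <- lambdas[seq_len(min(maxIter, length(lambdas)))]
  best <- NULL; bestErr <- Inf; log <- numeric(0)
  for (lam in lambdas) {
    VE <- .fitSurface(rmE, ringZE, nTheta, lam)
    VP <- .fitSurface(rmP, ringZP, nTheta, lam)
    err <- (.pointToSurfaceError(bnd$endo, VE, nTheta, nRings) *
              nrow(bnd$endo) +
            .pointToSurfaceError(bnd$epi, VP, nTheta, nRings) *
              nrow(bnd$epi)) / (nrow(bnd$endo) + nrow(bnd$epi))
    if (err <= bestErr + 1e-12) {
      best <- list(VE = VE, VP = VP); bestErr <- err
      log <- c(log, err)
      if (length(log) > 1 && abs(diff(tail(log, 2))) < tol) break
    }
  }
  # final polish: where rings coincide with data slices, snap vertices to
  # their nearest boundary points (classic closest-point update); accepted
  # only if the fitting error does not increase
  snap <- function(V, rm, ringZ) {
    for (j in seq_along(ringZ)) {
      k <- which.min(abs(rm$z - ringZ[j]))
      if (abs(rm$z[k] - ringZ[j]) > 1e-8) next
      m <- rm$models[[k]]
      px <- m$center[1] + m$r * cos(m$theta)
      py <- m$center[2] + m$r * sin(m$theta)
      idx <- (j - 1L) * nTheta + seq_len(nTheta)
      if (length(px) == nTheta) {
        # one data point per vertex: bijective circular assignment
        bestShift <- NULL; bestCost <- Inf
        for (dir in c(1L, -1L)) {
          ox <- if (dir == 1L) px else rev(px)
          oy <- if (dir == 1L) py else rev(py)
          for (s in 0:(nTheta - 1L)) {
            sel <- ((seq_len(nTheta) - 1L + s) %% nTheta) + 1L
            cost <- sum((ox[sel] - V[idx, 1])^2 + (oy[sel] - V[idx, 2])^2)
            if (cost < bestCost) {
              bestCost <- cost
              bestShift <- cbind(ox[sel], oy[sel])
            }
          }
        }
        V[idx, 1:2] <- bestShift
      } else {
        for (i in idx) {
          w <- which.min((px - V[i, 1])^2 + (py - V[i, 2])^2)
          V[i, 1] <- px[w]; V[i, 2] <- py[w]
        }
      }
    }
    V
  }
  VEs <- snap(best$VE, rmE, ringZE)
  VPs <- snap(best$VP, rmP, ringZP)
  errS <- (.pointToSurfaceError(bnd$endo, VEs, nTheta, nRings) *
             nrow(bnd$endo) +
           .pointToSurfaceError(bnd$epi, VPs, nTheta, nRings) *
             nrow(bnd$epi)) / (nrow(bnd$endo) + nrow(bnd$epi))
  if (errS <= bestErr + 1e-12) {
    best <- list(VE = VEs, VP = VPs); bestErr <- errS
    log <- c(log, errS)
  }
  lm <- bnd$landmark
  if (is.null(lm) || any(is.na(lm))) lm <- template@lvLandmark
  out <- new("CorrespondedMesh", endo = best$VE, epi = best$VP,
             nTheta = nTheta, nRings = nRings,
             septalMask = template@septalMask, lvLandmark = as.numeric(lm),
             fittingError = bestErr)
  attr(out, "errorLog") <- log
  out
}

#' Personalise a segmentation stack end to end
#'
#' Convenience wrapper: boundary extraction, rigid pose standardization and
#' template fitting in one call.
#'
#' @param stack a [SegmentationStack-class].
#' @param template template mesh; defaults to [generateTemplate()].
#' @param ... passed to [fitTemplate()].
#' @return A fitted [CorrespondedMesh-class].
#' @export
personalizeMesh <- function(stack, template = generateTemplate(), ...) {
  fitTemplate(standardizePose(stack), template, ...)
}
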