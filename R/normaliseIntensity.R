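# Spatial normalisation of slice point patterns onto the reference contour
# (rigid rotation followed by the radial polar transform) and edge-corrected
# Gaussian kernel intensity estimation with group-wise averaging.

#' Rigid rotational alignment of a slice onto its model contour
#'
#' Finds the rotation minimising the asymmetry between the (centred) slice
#' contour and the (centred) model stem contour (coarse 1-degree scan then
#' golden-section refinement) and applies it to the contour and to the
#' point pattern.
#'
#' @param sliceContour centred [Polygon-class] observed on the macroscopy
#'   image.
#' @param pattern [PointPattern-class] of bundle centroids (window =
#'   `sliceContour`).
#' @param modelContour centred [Polygon-class] predicted by the contour
#'   model for this slice.
#' @return A list with `pattern` (rotated [PointPattern-class]), `contour`
#'   (rotated slice contour) and `angle` (radians).
#' @export
rigidAlign <- function(sliceContour, pattern, modelContour) {
  v <- sliceContour@coords
  m <- modelContour@coords
  if (nrow(v) < 3L || nrow(m) < 3L) stop("degenerate contour")
  angle <- minimiseRotation(v[, 1L], v[, 2L], m[, 1L], m[, 2L])
  rc <- rotatePolygon(sliceContour, angle)
  rp <- pattern@points %*% t(rotationMatrix(angle))
  rw <- rotatePolygon(pattern@window, angle)
  list(pattern = PointPattern(rp, rw), contour = rc, angle = angle)
}

#' Polar normalisation of a point pattern onto the reference contour
#'
#' Every point keeps its angular position; its distance to the origin is
#' rescaled by the ratio of the reference-contour to slice-model-contour
#' ray distances at that angle, so that the slice model contour maps exactly
#' onto the reference contour. The same map is applied to the vertices of
#' the pattern's own window.
#'
#' Points marginally outside the slice model (model versus observed contour
#' mismatch) are tolerated up to `maxOutsideFrac` of the points and clamped
#' radially onto the model boundary with a warning; beyond that fraction an
#' error is raised.
#'
#' @param pattern a [PointPattern-class] (window = observed slice contour,
#'   centred).
#' @param sliceModel centred [Polygon-class] model contour of the slice;
#'   must contain the origin.
#' @param reference centred [Polygon-class] reference contour.
#' @param maxOutsideFrac tolerated fraction of points outside `sliceModel`.
#' @return The normalised [PointPattern-class].
#' @export
polarNormalise <- function(pattern, sliceModel, reference,
                           maxOutsideFrac = 0.01) {
  mapPts <- function(xy) {
    theta <- atan2(xy[, 2L], xy[, 1L])
    rho <- sqrt(rowSums(xy^2))
    rhoSlice <- rayIntersectionDistance(sliceModel, theta)
    rhoRef <- rayIntersectionDistance(reference, theta)
    list(theta = theta, rho = rho, rhoSlice = rhoSlice, rhoRef = rhoRef)
  }
  pts <- pattern@points
  if (nrow(pts) > 0L) {
    pm <- mapPts(pts)
    out <- pm$rho > pm$rhoSlice
    if (any(out)) {
      frac <- mean(out)
      if (frac > maxOutsideFrac)
        stop(sprintf("%.1f%% of points outside the slice model contour",
                     100 * frac))
      warning(sprintf(
        "%d point(s) outside the slice model contour; clamped to boundary",
        sum(out)))
      pm$rho[out] <- pm$rhoSlice[out] * (1 - 1e-9)
    }
    newRho <- pm$rho * pm$rhoRef / pm$rhoSlice
    pts <- cbind(newRho * cos(pm$theta), newRho * sin(pm$theta))
  }
  wv <- pattern@window@coords
  wm <- mapPts(wv)
  newW <- cbind(wm$rho * wm$rhoRef / wm$rhoSlice * cos(wm$theta),
                wm$rho * wm$rhoRef / wm$rhoSlice * sin(wm$theta))
  window <- Polygon(newW, metadata = pattern@window@metadata)
  # guard against chord-discretisation pushing near-boundary points out
  if (nrow(pts) > 0L) {
    inside <- cpp_point_in_polygon(pts[, 1L], pts[, 2L],
                                   newW[, 1L], newW[, 2L])
    if (any(!inside)) {
      theta <- atan2(pts[!inside, 2L], pts[!inside, 1L])
      rho <- sqrt(rowSums(pts[!inside, , drop = FALSE]^2))
      rw <- rayIntersectionDistance(window, theta)
      shrink <- pmin(1, rw / rho) * (1 - 1e-9)
      pts[!inside, ] <- pts[!inside, , drop = FALSE] * shrink
    }
  }
  PointPattern(pts, window)
}

#' Rule-of-thumb kernel bandwidth
#'
#' One-eighth of the shorter side of the window's axis-aligned bounding box.
#'
#' @param window a [Polygon-class].
#' @return Bandwidth sigma in mm.
#' @export
defaultBandwidth <- function(window) {
  bb <- apply(window@coords, 2L, range)
  min(bb[2L, ] - bb[1L, ]) / 8
}

#' Grid specification over a window
#'
#' A fixed raster over the window's bounding box expanded by a margin
#' fraction; all maps of a study share one grid specification so that they
#' can be averaged pixel-wise.
#'
#' @param window a [Polygon-class] (normally the reference contour).
#' @param n grid resolution (pixels per side), default 128.
#' @param expand bounding-box expansion fraction, default 0.05.
#' @return A list with `origin` (xmin, ymin), `pixelSize` (dx, dy) and
#'   `dim` (nx, ny).
#' @export
intensityGridSpec <- function(window, n = 128L, expand = 0.05) {
  bb <- apply(window@coords, 2L, range)
  span <- bb[2L, ] - bb[1L, ]
  lo <- bb[1L, ] - expand / 2 * span
  span <- span * (1 + expand)
  list(origin = as.numeric(lo), pixelSize = as.numeric(span / n),
       dim = c(as.integer(n), as.integer(n)))
}

#' Gaussian kernel intensity estimate of a point pattern
#'
#' Estimates the point-process intensity on a fixed grid with an isotropic
#' Gaussian kernel and edge correction. With `correction = "uniform"` the
#' kernel sum at location u is divided by e(u), the kernel mass retained
#' inside the window around u. With `correction = "per_point"` each point's
#' kernel is divided by the mass retained around that point, which makes
#' the integral of the estimate over the window equal the point count
#' exactly (up to grid discretisation).
#'
#' @param pattern a [PointPattern-class].
#' @param grid a grid specification from [intensityGridSpec()].
#' @param sigma kernel standard deviation in mm (default:
#'   [defaultBandwidth()] of the pattern window).
#' @param correction edge-correction type, "uniform" (default) or
#'   "per_point".
#' @return An [IntensityGrid-class] in points per mm^2; an empty pattern
#'   yields an all-zero map.
#' @export
kdeIntensity <- function(pattern, grid, sigma = NULL,
                         correction = c("uniform", "per_point")) {
  correction <- match.arg(correction)
  if (is.null(sigma)) sigma <- defaultBandwidth(pattern@window)
  if (sigma <= 0) stop("sigma must be positive")
  nx <- grid$dim[1L]; ny <- grid$dim[2L]
  dx <- grid$pixelSize[1L]; dy <- grid$pixelSize[2L]
  xc <- grid$origin[1L] + (seq_len(nx) - 0.5) * dx
  yc <- grid$origin[2L] + (seq_len(ny) - 0.5) * dy
  w <- pattern@window@coords
  mask <- matrix(cpp_point_in_polygon(rep(xc, times = ny), rep(yc, each = nx),
                                      w[, 1L], w[, 2L]), nx, ny)
  pts <- pattern@points
  if (nrow(pts) == 0L)
    return(new("IntensityGrid", values = matrix(0, nx, ny), mask = mask,
               origin = as.numeric(grid$origin),
               pixelSize = as.numeric(grid$pixelSize)))
  Gx <- stats::dnorm(outer(xc, pts[, 1L], "-"), sd = sigma)
  Gy <- stats::dnorm(outer(yc, pts[, 2L], "-"), sd = sigma)
  M <- mask * 1
  if (correction == "uniform") {
    raw <- Gx %*% t(Gy)
    Kx <- stats::dnorm(outer(xc, xc, "-"), sd = sigma) * dx
    Ky <- stats::dnorm(outer(yc, yc, "-"), sd = sigma) * dy
    e <- Kx %*% M %*% t(Ky)
    vals <- raw / pmax(e, 1e-6)
  } else {
    ei <- rowSums((t(Gx) %*% M) * t(Gy)) * dx * dy
    vals <- Gx %*% (t(Gy) * (1 / ei))
  }
  vals[!mask] <- 0
  new("IntensityGrid", values = vals, mask = mask,
      origin = as.numeric(grid$origin),
      pixelSize = as.numeric(grid$pixelSize))
}

#' Integral of an intensity map over its window
#'
#' @param g an [IntensityGrid-class].
#' @return Estimated total number of points (intensity integrated over the
#'   masked pixels).
#' @export
integrateIntensity <- function(g) {
  sum(g@values[g@mask]) * prod(g@pixelSize)
}

.sameSpec <- function(a, b) {
  isTRUE(all.equal(a@origin, b@origin)) &&
    isTRUE(all.equal(a@pixelSize, b@pixelSize)) &&
    identical(dim(a@values), dim(b@values))
}

#' Point-wise average of intensity maps
#'
#' Per-pixel mean over the maps whose mask covers the pixel; the output
#' mask requires coverage by at least `minCoverage` of the maps.
#'
#' @param maps list of [IntensityGrid-class] sharing one grid specification.
#' @param minCoverage minimal coverage fraction for a pixel to remain in
#'   the output mask (default 0.5).
#' @return An [IntensityGrid-class].
#' @export
averageMaps <- function(maps, minCoverage = 0.5) {
  if (length(maps) == 0L) stop("no maps to average")
  for (m in maps[-1L])
    if (!.sameSpec(maps[[1L]], m)) stop("grid specifications differ")
  d <- dim(maps[[1L]]@values)
  total <- matrix(0, d[1L], d[2L])
  count <- matrix(0, d[1L], d[2L])
  for (m in maps) {
    total <- total + m@values * m@mask
    count <- count + m@mask
  }
  vals <- ifelse(count > 0, total / pmax(count, 1), 0)
  mask <- (count / length(maps)) >= minCoverage
  vals[!mask] <- 0
  new("IntensityGrid", values = vals, mask = mask,
      origin = maps[[1L]]@origin, pixelSize = maps[[1L]]@pixelSize)
}

#' Average intensity map for one factor level
#'
#' @param maps list of [IntensityGrid-class].
#' @param labels vector of factor labels, one per map.
#' @param level the level to average.
#' @param minCoverage passed to [averageMaps()].
#' @return An [IntensityGrid-class].
#' @export
factorAverage <- function(maps, labels, level, minCoverage = 0.5) {
  if (length(labels) != length(maps))
    stop("labels must match maps in length")
  sel <- which(labels == level)
  if (length(sel) == 0L) stop("unknown level: ", level)
  averageMaps(maps[sel], minCoverage = minCoverage)
}
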