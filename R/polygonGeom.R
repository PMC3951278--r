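# Polygon primitives shared by all pipeline stages. Coordinates follow the
# mathematical convention: x right, y up, angles in radians CCW from +x.
# Image row/column indices are converted on load (see pixelsToXY).

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise loops.
#' @param p a [Polygon-class].
#' @return Signed area in mm^2.
#' @export
polygonArea <- function(p) {
  xy <- p@coords
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a polygon
#'
#' @param p a [Polygon-class].
#' @return Numeric length-2 vector (x, y) in mm.
#' @export
polygonCentroid <- function(p) {
  xy <- p@coords
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(xy), 1))
    stop("degenerate polygon: zero area")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Perimeter of a polygon
#' @param p a [Polygon-class].
#' @return Perimeter in mm.
#' @export
polygonPerimeter <- function(p) {
  xy <- p@coords
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

rotationMatrix <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)

#' Rotate a polygon about the origin
#' @param p a [Polygon-class].
#' @param theta rotation angle in radians, counter-clockwise.
#' @return The rotated [Polygon-class].
#' @export
rotatePolygon <- function(p, theta) {
  Polygon(p@coords %*% t(rotationMatrix(theta)), metadata = p@metadata)
}

#' Ensure counter-clockwise orientation
#'
#' Reverses the vertex order if the signed area is negative; idempotent.
#' @param p a [Polygon-class].
#' @return A [Polygon-class] with positive signed area.
#' @export
orientCcw <- function(p) {
  a <- polygonArea(p)
  scale2 <- max(abs(p@coords), 1)^2
  if (abs(a) < 1e-12 * scale2)
    stop("degenerate polygon: zero signed area")
  if (a < 0)
    p@coords <- p@coords[rev(seq_len(nrow(p@coords))), , drop = FALSE]
  p
}

#' Translate a polygon so its area centroid is at the origin
#'
#' @param p a [Polygon-class].
#' @return A list with elements `polygon` (the centred [Polygon-class]) and
#'   `centroid` (the original area centroid, mm).
#' @export
centrePolygon <- function(p) {
  ctr <- polygonCentroid(p)
  q <- p
  q@coords <- sweep(p@coords, 2L, ctr)
  list(polygon = q, centroid = ctr)
}

#' Asymmetry between two polygons
#'
#' Sum, over the vertices of `moving`, of the minimal Euclidean distance from
#' each vertex to the boundary (edges) of `fixed`. Zero iff every vertex of
#' `moving` lies on the boundary of `fixed`.
#'
#' @param moving,fixed [Polygon-class] objects.
#' @return Non-negative total distance in mm.
#' @export
polygonAsymmetry <- function(moving, fixed) {
  v <- moving@coords; w <- fixed@coords
  sum(cpp_dist_to_boundary(v[, 1L], v[, 2L], w[, 1L], w[, 2L]))
}

# Golden-section minimisation of f on [lo, hi]
goldenSection <- function(f, lo, hi, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

# Minimise the rotation objective: coarse scan at `step` over [0, 2pi) then
# golden-section refinement in the bracketing interval.
minimiseRotation <- function(vx, vy, px, py, step = pi / 180) {
  grid <- seq(0, 2 * pi, by = step)
  obj <- cpp_asymmetry_rotations(vx, vy, px, py, grid)
  i <- which.min(obj)
  f <- function(a) cpp_asymmetry_rotations(vx, vy, px, py, a)
  goldenSection(f, grid[i] - step, grid[i] + step)
}

#' Rotation aligning a polygon's bilateral symmetry axis with the y-axis
#'
#' The polygon is mirrored about the y-axis; a rotation of the mirrored copy
#' minimising [polygonAsymmetry()] against the original (coarse 1-degree scan
#' followed by golden-section refinement) identifies the symmetry axis, and
#' half that rotation is the alignment angle. For shapes without bilateral
#' symmetry the global minimiser of the scanned objective is returned.
#'
#' @param p a centred [Polygon-class].
#' @return Rotation angle (radians) to apply to `p` so its symmetry axis is
#'   vertical; defined modulo pi (see [alignUpwards()] for the up/down
#'   tie-break).
#' @export
findSymmetryAxis <- function(p) {
  xy <- p@coords
  flip <- cbind(-xy[, 1L], xy[, 2L])
  phi <- minimiseRotation(flip[, 1L], flip[, 2L], xy[, 1L], xy[, 2L])
  -phi / 2
}

#' Align a polygon to point upwards
#'
#' Rotates the centred polygon by [findSymmetryAxis()] so its bilateral
#' symmetry axis is vertical, resolves the up/down ambiguity by requiring the
#' vertex farthest from the centroid to have positive y, and rolls the vertex
#' list so that vertex 1 is the top vertex (maximal y, ties broken by minimal
#' x).
#'
#' @param p a centred [Polygon-class].
#' @return The aligned [Polygon-class].
#' @export
alignUpwards <- function(p) {
  theta <- findSymmetryAxis(p)
  q <- rotatePolygon(p, theta)
  far <- which.max(rowSums(q@coords^2))
  if (q@coords[far, 2L] < 0)
    q <- rotatePolygon(q, pi)
  xy <- q@coords
  top <- order(-xy[, 2L], xy[, 1L])[1L]
  q@coords <- xy[c(top:nrow(xy), seq_len(top - 1L))[seq_len(nrow(xy))], ,
                 drop = FALSE]
  q
}

#' Resample a polygon to a fixed vertex count
#'
#' Vertices are placed at equal arc-length spacing along the loop, starting
#' from (and preserving) the current first vertex; orientation is preserved.
#'
#' @param p a [Polygon-class].
#' @param nV target vertex count (>= 3).
#' @return A [Polygon-class] with exactly `nV` vertices.
#' @export
resamplePolygon <- function(p, nV) {
  if (nV < 3L) stop("nV must be at least 3")
  xy <- rbind(p@coords, p@coords[1L, ])
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- L * (seq_len(nV) - 1) / nV
  ix <- findInterval(target, s, rightmost.closed = TRUE)
  t <- (target - s[ix]) / pmax(seg[ix], .Machine$double.xmin)
  Polygon(xy[ix, , drop = FALSE] +
            (xy[ix + 1L, , drop = FALSE] - xy[ix, , drop = FALSE]) * t,
          metadata = p@metadata)
}

# squared distance from points (px, py) to segment a-b
.segDist <- function(px, py, a, b) {
  dx <- b[1L] - a[1L]; dy <- b[2L] - a[2L]
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmin(1, pmax(0, ((px - a[1L]) * dx + (py - a[2L]) * dy) / len2)) else 0
  sqrt((a[1L] + t * dx - px)^2 + (a[2L] + t * dy - py)^2)
}

# Douglas-Peucker on an open chain (matrix of vertices); returns indices kept
.dpChain <- function(xy, tol) {
  n <- nrow(xy)
  if (n <= 2L) return(seq_len(n))
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1L]; j <- rng[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .segDist(xy[mid, 1L], xy[mid, 2L], xy[i, ], xy[j, ])
    k <- mid[which.max(d)]
    if (max(d) > tol) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}

#' Simplify a polygon with the Douglas-Peucker algorithm
#'
#' The closed loop is split at two anchor vertices (vertex 1 and the vertex
#' farthest from it) and each open chain is simplified recursively: a chain
#' is subdivided at its vertex farthest from the segment joining the chain
#' extremities until every vertex lies within `tol` of the simplified loop.
#' Output vertices are a subset of the input vertices.
#'
#' @param p a [Polygon-class].
#' @param tol tolerance in mm (> 0); the study default for slice contours is
#'   0.1 mm.
#' @return The simplified [Polygon-class].
#' @export
simplifyDP <- function(p, tol) {
  if (tol <= 0) stop("tol must be positive")
  xy <- p@coords
  n <- nrow(xy)
  far <- which.max((xy[, 1L] - xy[1L, 1L])^2 + (xy[, 2L] - xy[1L, 2L])^2)
  if (far == 1L) far <- 1L + n %/% 2L
  c1 <- xy[1L:far, , drop = FALSE]
  c2 <- xy[c(far:n, 1L), , drop = FALSE]
  k1 <- .dpChain(c1, tol)
  k2 <- .dpChain(c2, tol)
  idx <- unique(c(k1, (far:n)[k2[k2 <= (n - far + 1L)]]))
  out <- xy[sort(idx), , drop = FALSE]
  if (nrow(out) < 3L) {  # extremely coarse tolerance: keep a minimal triangle
    extra <- setdiff(round(seq(1L, n, length.out = 4L))[1:3], sort(idx))
    out <- xy[sort(unique(c(idx, extra)))[1:3], , drop = FALSE]
  }
  Polygon(out, metadata = p@metadata)
}

#' Distance from the origin to a polygon boundary along a ray
#'
#' Casts a ray from the origin at angle `theta` and returns the distance to
#' its intersection with the polygon boundary. Contours are assumed
#' star-shaped with respect to the origin; if a ray crosses the boundary more
#' than once the nearest intersection is returned with a warning.
#'
#' @param p a [Polygon-class] strictly containing the origin.
#' @param theta angle(s) in radians, CCW from the +x axis; vectorised.
#' @return Numeric vector of distances (mm), one per angle.
#' @export
rayIntersectionDistance <- function(p, theta) {
  xy <- p@coords
  if (!cpp_point_in_polygon(0, 0, xy[, 1L], xy[, 2L]))
    stop("origin lies outside the polygon")
  a <- xy
  b <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  dx <- cos(theta); dy <- sin(theta)
  # solve a + t*e = rho*d : rho = (a x e) / (d x e), t = (a x d) / (d x e)
  den <- outer(dx, ey) - outer(dy, ex)                    # d x e
  cross_ae <- a[, 1L] * ey - a[, 2L] * ex                 # a x e (per edge)
  num_rho <- matrix(cross_ae, length(theta), nrow(a), byrow = TRUE)
  num_t <- outer(dy, a[, 1L]) - outer(dx, a[, 2L])        # -(a x d)
  tt <- num_t / den
  rho <- num_rho / den
  # small slack in t so rays passing exactly through a vertex hit one of the
  # two adjacent edges instead of falling between them
  ok <- is.finite(rho) & rho > 1e-12 & tt >= -1e-9 & tt <= 1 + 1e-9
  rho[!ok] <- Inf
  rmin <- apply(rho, 1L, min)
  if (any(!is.finite(rmin)))
    stop("ray does not intersect the polygon boundary")
  # a genuine star-shape violation shows distinct intersection distances
  # (vertex pass-through yields two coincident hits)
  rho[!is.finite(rho)] <- NA
  rmax <- suppressWarnings(apply(rho, 1L, max, na.rm = TRUE))
  multi <- (rmax - rmin) > 1e-6 * pmax(rmin, 1e-12)
  if (any(multi))
    warning(sprintf(
      "polygon not star-shaped for %d of %d rays; using nearest intersection",
      sum(multi), length(theta)))
  rmin
}

#' Chain the pixels of a one-pixel-wide closed contour curve
#'
#' Walks the 8-connected curve from its top-most pixel, visiting every
#' foreground pixel exactly once, and returns the traversal as a polygon in
#' pixel units (mathematical orientation: x right, y up; see
#' [pixelsToXY()]).
#'
#' @param mask logical or 0/1 matrix in image orientation
#'   (`mask[i, j]`, i = x pixel index, j = y pixel index from the top).
#' @return A [Polygon-class] whose vertices are the contour pixels in
#'   traversal order (coordinates in pixel units).
#' @export
chainContourPixels <- function(mask) {
  mask <- mask != 0
  ncomp <- .countComponents8(mask)
  if (ncomp != 1L)
    stop(sprintf("expected a single closed curve, found %d components", ncomp))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("curve too short to form a polygon")
  key <- function(i, j) paste(i, j)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(idx))) assign(key(idx[r, 1L], idx[r, 2L]), TRUE, present)
  # start at top pixel in image terms (minimal j, then minimal i)
  ordidx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  start <- ordidx[1L, ]
  # neighbour preference: 4-adjacent before diagonal
  noff <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1),
                c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  path <- matrix(0L, nrow(idx), 2L)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  cur <- start; prev <- c(NA_integer_, NA_integer_)
  for (step in seq_len(nrow(idx))) {
    path[step, ] <- cur
    assign(key(cur[1L], cur[2L]), TRUE, visited)
    nb <- sweep(noff, 2L, cur, "+")
    cand <- NULL
    for (r in seq_len(8L)) {
      k <- key(nb[r, 1L], nb[r, 2L])
      if (!is.null(present[[k]]) && is.null(visited[[k]])) { cand <- nb[r, ]; break }
    }
    if (is.null(cand)) break
    prev <- cur; cur <- cand
  }
  if (any(path[nrow(idx), ] == 0L))
    stop("open curve: traversal could not visit every contour pixel")
  if (max(abs(path[nrow(idx), ] - start)) > 1L)
    stop("open curve: last pixel not adjacent to the first")
  Polygon(pixelsToXY(path, ncolMask = ncol(mask), resolution = 1))
}

# count 8-connected components of a binary matrix (BFS on pixel indices)
.countComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  count <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (lab[p] != 0L) next
    count <- count + 1L
    queue <- p; lab[p] <- count
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      i <- (q - 1L) %% nr + 1L; j <- (q - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- count
          queue <- c(queue, ii + (jj - 1L) * nr)
        }
      }
    }
  }
  count
}

#' Convert pixel indices to mathematical coordinates
#'
#' Pixel (i, j) of an image stored as `m[i, j]` (i = x index, j = y index
#' counted from the top row) maps to the centre of that pixel with y up:
#' x = (i - 0.5) * resolution, y = (ncolMask - j + 0.5) * resolution.
#'
#' @param ij integer matrix of (i, j) pixel indices.
#' @param ncolMask number of pixel rows in the y direction (ncol of the
#'   internal image matrix).
#' @param resolution mm per pixel.
#' @return Numeric matrix of (x, y) coordinates.
#' @export
pixelsToXY <- function(ij, ncolMask, resolution) {
  cbind(x = (ij[, 1L] - 0.5) * resolution,
        y = (ncolMask - ij[, 2L] + 0.5) * resolution)
}
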