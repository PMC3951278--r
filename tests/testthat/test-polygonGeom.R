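# Polygon primitives: tracing, orientation, centring, symmetry alignment,
# resampling, simplification and ray casting.

test_that("chainContourPixels orders closed curves and rejects bad input", {
  h <- matrix(FALSE, 5, 5)
  h[2:4, 2:4] <- TRUE; h[3, 3] <- FALSE
  p <- chainContourPixels(h)
  expect_equal(nVertices(p), 8L)
  # consecutive traversal pixels are 8-adjacent, loop closes
  xy <- vertices(p)
  steps <- rbind(diff(xy), xy[1L, ] - xy[8L, ])
  expect_true(all(abs(steps) <= 1))

  # rasterised circle: vertex count within 5% of an independent
  # boundary-pixel scan
  r <- 50L
  m <- matrix(FALSE, 110, 110)
  for (i in 1:110) for (j in 1:110)
    if ((i - 55)^2 + (j - 55)^2 <= r^2) m[i, j] <- TRUE
  # inner boundary: foreground pixels with a 4-neighbour background
  nb <- m &
    !(rbind(m[-1, ], FALSE) & rbind(FALSE, m[-110, ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -110]))
  p2 <- chainContourPixels(nb)
  expect_lt(abs(nVertices(p2) - sum(nb)) / sum(nb), 0.05)

  two <- matrix(FALSE, 9, 9)
  two[2:4, 2:4] <- TRUE; two[3, 3] <- FALSE
  two[6:8, 6:8] <- TRUE; two[7, 7] <- FALSE
  expect_error(chainContourPixels(two), "2 components")
})

test_that("orientCcw establishes positive signed area and is idempotent", {
  ccw <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(vertices(orientCcw(ccw)), vertices(ccw))
  cw <- Polygon(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)))
  fixed <- orientCcw(cw)
  expect_equal(polygonArea(fixed), 1)
  expect_setequal(asplit(vertices(fixed), 1L), asplit(vertices(cw), 1L))
  expect_equal(vertices(orientCcw(fixed)), vertices(fixed))
  expect_error(orientCcw(Polygon(cbind(0:2, 0:2))), "degenerate")
})

test_that("centrePolygon moves the area centroid to the origin", {
  sq <- Polygon(cbind(c(1, 3, 3, 1), c(1, 1, 3, 3)))
  cp <- centrePolygon(sq)
  expect_equal(cp$centroid, c(2, 2))
  expect_equal(max(abs(polygonCentroid(cp$polygon))), 0, tolerance = 1e-9)
  again <- centrePolygon(cp$polygon)
  expect_equal(max(abs(again$centroid)), 0, tolerance = 1e-12)

  # L-shape against an independent shoelace/area-moment computation
  L <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 3, 3))
  # decompose into two rectangles: [0,2]x[0,1] area 2 centroid (1, .5);
  # [0,1]x[1,3] area 2 centroid (.5, 2)
  want <- (2 * c(1, 0.5) + 2 * c(0.5, 2)) / 4
  expect_equal(polygonCentroid(Polygon(L)), want)
})

test_that("polygonAsymmetry equals brute-force vertex-to-edge minimisation", {
  sq <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(polygonAsymmetry(sq, sq), 0)
  moved <- Polygon(vertices(sq) + matrix(c(0, 0.1), 4, 2, byrow = TRUE))
  expect_equal(polygonAsymmetry(moved, sq),
               sum(bruteDistToBoundary(vertices(moved), sq)),
               tolerance = 1e-12)
  set.seed(7)
  a <- randomStarPolygon(40)
  b <- randomStarPolygon(35)
  expect_equal(polygonAsymmetry(a, b),
               sum(bruteDistToBoundary(vertices(a), b)),
               tolerance = 1e-12)
  # single-vertex geometry: point (2,0) against the unit circle
  one <- Polygon(rbind(c(2, 0), c(2, 1e-9), c(2 + 1e-9, 0)))
  expect_equal(polygonAsymmetry(one, circlePolygon(1, 720)), 3,
               tolerance = 1e-3)
})

test_that("findSymmetryAxis recovers known rotations of symmetric shapes", {
  ell <- Polygon(cbind(0.5 * cos(seq(0, 2 * pi, length.out = 181)[-181]),
                       sin(seq(0, 2 * pi, length.out = 181)[-181])))
  expect_lt(angleDiff(findSymmetryAxis(ell), 0, pi), 0.01)
  rot <- rotatePolygon(ell, 30 * pi / 180)
  a <- findSymmetryAxis(rot)
  expect_lt(angleDiff(a, -30 * pi / 180, pi), 0.5 * pi / 180)
  # circle: objective flat, any angle acceptable
  circ <- circlePolygon(1, 180)
  ac <- findSymmetryAxis(circ)
  expect_lt(polygonAsymmetry(rotatePolygon(circ, ac), circ), 1e-6)
})

test_that("alignUpwards restores the vertical axis and rolls to the top vertex", {
  egg <- synthContour(3, elongation = 1.3, asym = -0.2)
  up <- alignUpwards(egg)
  expect_lt(polygonAsymmetry(up, egg), 1e-6 * polygonPerimeter(egg))
  expect_equal(which.max(vertices(up)[, 2L]), 1L)

  rot <- rotatePolygon(egg, pi / 2)
  up2 <- alignUpwards(rot)
  expect_lt(polygonAsymmetry(up2, egg), 1e-3 * polygonPerimeter(egg))
  # symmetric polygon invariant: post-alignment asymmetry of the mirrored
  # copy is tiny
  mir <- Polygon(cbind(-vertices(up2)[, 1L], vertices(up2)[, 2L]))
  expect_lt(polygonAsymmetry(mir, up2), 1e-6 * polygonPerimeter(egg))

  # square: alignment at least as good as every 0.1-degree alternative
  sq <- Polygon(0.5 * cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
  upsq <- alignUpwards(rotatePolygon(sq, 0.3))
  flip <- Polygon(cbind(-vertices(upsq)[, 1L], vertices(upsq)[, 2L]))
  best <- gridBestRotation(flip, upsq)
  obj0 <- polygonAsymmetry(flip, upsq)
  expect_lte(obj0, polygonAsymmetry(rotatePolygon(flip, best), upsq) + 1e-9)
})

test_that("resamplePolygon places vertices at uniform arc length", {
  big <- circlePolygon(1, 1000)
  rs <- resamplePolygon(big, 200)
  expect_equal(nVertices(rs), 200L)
  rad <- sqrt(rowSums(vertices(rs)^2))
  expect_true(all(abs(rad - 1) < 1e-4))
  seg <- sqrt(rowSums((rbind(vertices(rs)[-1, ], vertices(rs)[1, ]) -
                         vertices(rs))^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)

  eq <- Polygon(cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2)))
  expect_equal(vertices(resamplePolygon(eq, 3)), vertices(eq),
               tolerance = 1e-9)

  sq <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  r8 <- resamplePolygon(sq, 8)
  expect_equal(vertices(r8),
               cbind(c(0, 0.5, 1, 1, 1, 0.5, 0, 0),
                     c(0, 0, 0, 0.5, 1, 1, 1, 0.5)),
               ignore_attr = TRUE)
  expect_error(resamplePolygon(sq, 2), "at least 3")

  # loop preservation: Hausdorff bounded by the longest input edge
  set.seed(3)
  p <- randomStarPolygon(50)
  q <- resamplePolygon(p, 37)
  maxEdge <- max(sqrt(rowSums((rbind(p@coords[-1, ], p@coords[1, ]) -
                                 p@coords)^2)))
  expect_lt(polygonHausdorff(p, q), maxEdge)
})

test_that("simplifyDP keeps a vertex subset within tolerance", {
  # one side of 100 collinear points collapses to its endpoints
  side <- cbind(seq(0, 1, length.out = 100), rep(0, 100))
  tri <- Polygon(rbind(side, c(1, 1), c(0, 1)))
  s <- simplifyDP(tri, 0.001)
  expect_equal(nVertices(s), 4L)

  sq10 <- resamplePolygon(Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 40)
  s2 <- simplifyDP(sq10, 0.01)
  expect_equal(nVertices(s2), 4L)
  expect_setequal(lapply(asplit(vertices(s2), 1L), unname),
                  list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))

  set.seed(11)
  for (k in 1:5) {
    p <- randomStarPolygon(80)
    tol <- stats::runif(1, 0.01, 0.2)
    s3 <- simplifyDP(p, tol)
    expect_lte(nVertices(s3), nVertices(p))
    # vertex subset
    expect_true(all(asplit(vertices(s3), 1L) %in% asplit(vertices(p), 1L)))
    # every input vertex within tol of the simplified loop (brute force)
    expect_lte(max(bruteDistToBoundary(vertices(p), s3)), tol + 1e-12)
  }
})

test_that("rayIntersectionDistance matches geometry and brute force", {
  circ <- circlePolygon(2, 720)
  expect_equal(rayIntersectionDistance(circ, c(0, 1, 2.5, 4.4)),
               rep(2, 4), tolerance = 1e-3)
  rect <- Polygon(cbind(c(-1, 1, 1, -1), c(-2, -2, 2, 2)))
  expect_equal(rayIntersectionDistance(rect, 0), 1)
  expect_equal(rayIntersectionDistance(rect, pi / 2), 2)

  set.seed(5)
  star <- randomStarPolygon(30)
  th <- stats::runif(20, 0, 2 * pi)
  got <- rayIntersectionDistance(star, th)
  # brute-force segment-by-segment scan
  w <- rbind(star@coords, star@coords[1, ])
  brute <- vapply(th, function(a) {
    d <- c(cos(a), sin(a))
    best <- Inf
    for (j in seq_len(nrow(w) - 1L)) {
      p0 <- w[j, ]; e <- w[j + 1L, ] - w[j, ]
      den <- d[1] * e[2] - d[2] * e[1]
      if (abs(den) < 1e-14) next
      rho <- (p0[1] * e[2] - p0[2] * e[1]) / den
      t <- (d[2] * p0[1] - d[1] * p0[2]) / den
      if (rho > 1e-12 && t >= -1e-9 && t <= 1 + 1e-9) best <- min(best, rho)
    }
    best
  }, numeric(1L))
  expect_equal(got, brute, tolerance = 1e-9)

  shifted <- Polygon(sweep(circlePolygon(1, 90)@coords, 2L, c(-3, 0)))
  expect_error(rayIntersectionDistance(shifted, 0), "outside")
})
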