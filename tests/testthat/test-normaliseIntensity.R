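# Rigid alignment, the radial polar transform, and edge-corrected kernel
# intensity estimation with group-wise averaging.

test_that("rigidAlign recovers known rotations and preserves points", {
  model <- synthContour(5, elongation = 1.3, asym = -0.15)
  rot <- rotatePolygon(model, 25 * pi / 180)
  set.seed(1)
  pts <- coords(sampleInhomPoisson(function(x, y) rep(1, length(x)), rot,
                                   lambdaMax = 1))
  ra <- rigidAlign(rot, PointPattern(pts, rot), model)
  expect_lt(angleDiff(ra$angle, -25 * pi / 180), 0.5 * pi / 180)
  # agreement with the exhaustive 0.1-degree grid search
  best <- gridBestRotation(rot, model)
  expect_lt(angleDiff(ra$angle, best), 0.2 * pi / 180)
  expect_equal(npoints(ra$pattern), nrow(pts))

  # identical contours: no rotation needed
  ra0 <- rigidAlign(model, PointPattern(matrix(numeric(0), 0, 2), model),
                    model)
  expect_lt(min(angleDiff(ra0$angle, 0), angleDiff(ra0$angle, pi)),
            0.01)
})

test_that("polarNormalise matches closed forms and maps boundaries", {
  circ2 <- circlePolygon(2, 720)
  circ1 <- circlePolygon(1, 720)
  ell <- Polygon(cbind(2 * cos(2 * pi * (0:719) / 720),
                       sin(2 * pi * (0:719) / 720)))

  got <- coords(polarNormalise(PointPattern(rbind(c(1, 0)), circ2),
                               circ2, circ1))
  expect_equal(as.vector(got), c(0.5, 0), tolerance = 1e-6)

  got2 <- coords(polarNormalise(PointPattern(rbind(c(1, 0), c(0, 0.5)), ell),
                                ell, circ1))
  expect_equal(got2, rbind(c(0.5, 0), c(0, 0.5)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # identity map when slice model equals the reference
  set.seed(2)
  pts <- matrix(stats::runif(600, -0.7, 0.7), ncol = 2)
  pts <- pts[pts[, 1]^2 + pts[, 2]^2 < 0.95, ]
  pn <- polarNormalise(PointPattern(pts, circ1), circ1, circ1)
  expect_lt(max(abs(coords(pn) - pts)), 1e-9)

  # the slice model boundary maps onto the reference boundary
  sl <- synthContour(4, elongation = 1.2, asym = -0.1)
  ref <- synthContour(3, elongation = 1.1, asym = -0.05)
  pnw <- polarNormalise(PointPattern(matrix(numeric(0), 0, 2), sl), sl, ref)
  wv <- vertices(patternWindow(pnw))
  expect_lt(max(bruteDistToBoundary(wv, ref)), 1e-6)

  # angular order preserved
  set.seed(3)
  pts2 <- coords(sampleInhomPoisson(function(x, y) rep(3, length(x)), sl,
                                    lambdaMax = 3))
  pn2 <- polarNormalise(PointPattern(pts2, sl), sl, ref)
  expect_equal(order(atan2(coords(pn2)[, 2], coords(pn2)[, 1])),
               order(atan2(pts2[, 2], pts2[, 1])))
  expect_equal(npoints(pn2), nrow(pts2))
})

test_that("defaultBandwidth follows the min-side/8 rule", {
  sq <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(defaultBandwidth(sq), 0.125)
  rect <- Polygon(cbind(c(0, 2, 2, 0), c(0, 0, 8, 8)))
  expect_equal(defaultBandwidth(rect), 0.25)
  scaled <- Polygon(3 * vertices(rect))
  expect_equal(defaultBandwidth(scaled), 3 * 0.25)
})

test_that("kdeIntensity normalises mass and recovers flat intensity", {
  w <- synthContour(10, elongation = 1.2, asym = -0.1)
  grid <- intensityGridSpec(w)

  # single point at an exact pixel centre: peak near 1 / (2 pi sigma^2)
  xc <- grid$origin[1] + (64 - 0.5) * grid$pixelSize[1]
  yc <- grid$origin[2] + (64 - 0.5) * grid$pixelSize[2]
  g1 <- kdeIntensity(PointPattern(rbind(c(xc, yc)), w), grid, sigma = 0.5,
                     correction = "per_point")
  expect_equal(max(gridValues(g1)), 1 / (2 * pi * 0.25), tolerance = 0.01)

  # per-point correction conserves mass
  pat <- sampleInhomPoisson(function(x, y) rep(1.5, length(x)), w, seed = 4)
  gp <- kdeIntensity(pat, grid, sigma = 1.5, correction = "per_point")
  expect_equal(integrateIntensity(gp), npoints(pat), tolerance = 0.005)

  # homogeneous pattern: spatial mean of the estimate near the truth
  lam <- 100
  usq <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  patu <- sampleInhomPoisson(function(x, y) rep(lam, length(x)), usq,
                             seed = 5, lambdaMax = lam)
  gu <- kdeIntensity(patu, intensityGridSpec(usq), sigma = 0.125,
                     correction = "uniform")
  se <- sqrt(lam)  # count-level fluctuation dominates the spatial mean
  expect_lt(abs(mean(gridValues(gu)[gridMask(gu)]) - lam), 3 * se)

  # empty pattern: all-zero map
  g0 <- kdeIntensity(PointPattern(matrix(numeric(0), 0, 2), w), grid,
                     sigma = 1)
  expect_true(all(gridValues(g0) == 0))
})

test_that("averageMaps and factorAverage combine maps correctly", {
  w <- circlePolygon(3, 120)
  grid <- intensityGridSpec(w)
  pat <- sampleInhomPoisson(function(x, y) rep(5, length(x)), w, seed = 6)
  g <- kdeIntensity(pat, grid, sigma = 0.5)
  avg <- averageMaps(list(g, g, g))
  expect_equal(gridValues(avg), gridValues(g))
  expect_equal(gridMask(avg), gridMask(g))

  # MSE decreases like 1/K for independent replicates of one intensity
  set.seed(7)
  maps <- lapply(1:16, function(k)
    kdeIntensity(sampleInhomPoisson(function(x, y) rep(20, length(x)), w),
                 grid, sigma = 0.25, correction = "uniform"))
  wv <- vertices(w)
  nx <- grid$dim[1]
  xs <- grid$origin[1] + (seq_len(nx) - 0.5) * grid$pixelSize[1]
  ys <- grid$origin[2] + (seq_len(nx) - 0.5) * grid$pixelSize[2]
  db <- matrix(stemAtlas:::cpp_dist_to_boundary(
    rep(xs, times = nx), rep(ys, each = nx), wv[, 1], wv[, 2]), nx, nx)
  interior <- gridMask(maps[[1]]) & db > 1
  mse <- vapply(c(1, 4, 16), function(K) {
    a <- averageMaps(maps[1:K])
    mean((gridValues(a)[interior] - 20)^2)
  }, numeric(1))
  expect_gt(mse[1] / mse[3], 8)
  expect_lt(mse[1] / mse[3], 32)

  # coverage threshold
  half <- g
  half@mask[, seq_len(ncol(half@mask) / 2)] <- FALSE
  avg2 <- averageMaps(list(g, g, half, half), minCoverage = 0.75)
  expect_true(all(!gridMask(avg2)[, seq_len(ncol(half@mask) / 2)] |
                    !gridMask(g)[, seq_len(ncol(half@mask) / 2)]))

  bad <- kdeIntensity(pat, intensityGridSpec(w, n = 64), sigma = 0.5)
  expect_error(averageMaps(list(g, bad)), "grid specifications differ")

  # factor averages: two groups with intensity ratio 1.3
  set.seed(8)
  mk <- function(lam) kdeIntensity(
    sampleInhomPoisson(function(x, y) rep(lam, length(x)), w),
    grid, sigma = 0.5, correction = "per_point")
  maps2 <- c(lapply(1:4, function(i) mk(100)), lapply(1:4, function(i) mk(130)))
  labels <- rep(c("WT", "M"), each = 4)
  mWT <- mean(gridValues(factorAverage(maps2, labels, "WT"))[interior])
  mM <- mean(gridValues(factorAverage(maps2, labels, "M"))[interior])
  expect_equal(mM / mWT, 1.3, tolerance = 0.08)
  expect_error(factorAverage(maps2, labels, "XX"), "unknown level")
})
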