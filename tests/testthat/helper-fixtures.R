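# Shared fixtures and oracles. The rendered macroscopy scene is expensive
# (~30 s) and is built lazily once per test run.

.fixtureCache <- new.env(parent = emptyenv())

sectionFixture <- function() {
  if (is.null(.fixtureCache$scene)) {
    ct <- synthContour(2.5, elongation = 1.15, asym = 0.1)
    truth <- sectionSceneTruth(ct, lambda0 = 2, lambdaRatio = 3,
                               rMin = 0.35, seed = 5)
    img <- renderSectionImage(truth, resolution = 0.005, seed = 5)
    .fixtureCache$scene <- list(truth = truth, img = img, res = 0.005)
  }
  .fixtureCache$scene
}

circlePolygon <- function(r = 1, n = 200L, centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  Polygon(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)))
}

# precision / recall of detected points against true points at a matching
# radius (greedy by distance matrix; adequate for well-separated patterns)
matchRates <- function(detected, truth, radius) {
  if (nrow(detected) == 0L)
    return(list(recall = 0, precision = NA_real_))
  D <- sqrt(outer(detected[, 1L], truth[, 1L], "-")^2 +
            outer(detected[, 2L], truth[, 2L], "-")^2)
  list(recall = mean(apply(D, 2L, min) <= radius),
       precision = mean(apply(D, 1L, min) <= radius))
}

# random star-shaped polygon about the origin (well-defined ray casting)
randomStarPolygon <- function(n = 60L, rMean = 1, wobble = 0.35) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- rMean * (1 + wobble * (stats::runif(n) - 0.5))
  Polygon(cbind(r * cos(th), r * sin(th)))
}

# brute-force minimal distance from points to a closed polygon boundary
bruteDistToBoundary <- function(pts, poly) {
  w <- rbind(poly@coords, poly@coords[1L, ])
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(w) - 1L), function(j) {
      a <- w[j, ]; b <- w[j + 1L, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(1, max(0, t))
      sqrt(sum((a + t * ab - p)^2))
    }, numeric(1L)))
  }, numeric(1L))
}

# Hausdorff distance between two polygon boundaries (vertex-sampled)
polygonHausdorff <- function(p, q) {
  v <- p@coords; w <- q@coords
  max(max(bruteDistToBoundary(v, q)), max(bruteDistToBoundary(w, p)))
}

# exhaustive grid-search oracle for the symmetry/alignment rotation:
# returns the angle in `angles` minimising the asymmetry of the rotated
# moving polygon against the fixed polygon
gridBestRotation <- function(moving, fixed, step = 0.1 * pi / 180) {
  angles <- seq(0, 2 * pi, by = step)
  v <- moving@coords; w <- fixed@coords
  obj <- stemAtlas:::cpp_asymmetry_rotations(v[, 1L], v[, 2L],
                                             w[, 1L], w[, 2L], angles)
  angles[which.min(obj)]
}

angleDiff <- function(a, b, period = 2 * pi) {
  d <- (a - b) %% period
  min(d, period - d)
}
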