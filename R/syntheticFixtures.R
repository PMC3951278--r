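# Synthetic study generator: parametric stem contours with genotype /
# cutting-position / stem effects, bundle point patterns with known
# intensity, and rendered slab-scan and macroscopy section images. Every
# generator is deterministic given its seed, and ground truth is returned
# next to the data so recovery can be tested at every stage.

#' Bilaterally symmetric synthetic stem contour
#'
#' An egg-like closed curve: an ellipse with a height-dependent width
#' modulation (`asym`), optionally perturbed by smooth low-order harmonics
#' that respect the mirror symmetry about the y-axis. The curve starts at
#' its top vertex and runs counter-clockwise; the polygon is centred.
#'
#' @param size nominal radius in mm (> 0).
#' @param elongation height / width ratio of the bounding box.
#' @param asym width modulation coefficient (0 = pure ellipse).
#' @param noiseSd standard deviation (mm) of the radial harmonic
#'   perturbation; the perturbation is an even function of the angular
#'   distance from the top, so mirror symmetry is exact.
#' @param seed optional integer seed for the harmonic coefficients.
#' @param nV vertex count (default 400).
#' @param nHarmonics number of perturbation harmonics.
#' @return A centred [Polygon-class].
#' @export
synthContour <- function(size, elongation = 1, asym = 0, noiseSd = 0,
                         seed = NULL, nV = 400L, nHarmonics = 4L) {
  if (size <= 0) stop("size must be positive")
  u <- 2 * pi * (seq_len(nV) - 1L) / nV          # 0 at the top vertex
  t <- pi / 2 + u                                # curve parameter, CCW
  x <- size * cos(t) * (1 + asym * sin(t))
  y <- size * elongation * sin(t)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ak <- stats::rnorm(nHarmonics, 0, noiseSd / sqrt(nHarmonics))
    delta <- as.vector(cos(outer(u, seq_len(nHarmonics))) %*% ak)
    rho <- sqrt(x^2 + y^2)
    f <- 1 + delta / rho
    x <- x * f; y <- y * f
  }
  centrePolygon(Polygon(cbind(x, y)))$polygon
}

#' Design of a synthetic contour study
#'
#' Defaults emulate the study conditions: two genotypes (the mutant about
#' 10 percent larger than the wild type), seven stems per genotype, seven
#' cutting positions labelled "ab".."gh" whose elongation tapers down the
#' internode, and two faces (independent observations) per cut.
#'
#' @param genotypes genotype labels.
#' @param genotypeSize named size multipliers per genotype.
#' @param stemsPerGenotype number of stems per genotype.
#' @param cuts cutting-position labels, top of the internode first.
#' @param elongation elongation per cut (recycled to `length(cuts)`).
#' @param faces number of faces observed per cut.
#' @param baseSize nominal stem radius in mm.
#' @param asym width-modulation coefficient of the contour family.
#' @param stemSd standard deviation (mm) of the smooth per-stem contour
#'   perturbation.
#' @param noiseSd standard deviation (mm) of the per-coordinate measurement
#'   noise.
#' @param nV vertex count per contour.
#' @return A list of class parameters for [synthContourDataset()].
#' @export
stemDesign <- function(genotypes = c("WT", "M"),
                       genotypeSize = c(WT = 1, M = 1.1),
                       stemsPerGenotype = 7L,
                       cuts = c("ab", "bc", "cd", "de", "ef", "fg", "gh"),
                       elongation = seq(1.2, 1.0, length.out = 7L),
                       faces = 2L,
                       baseSize = 10,
                       asym = -0.15,
                       stemSd = 0.15,
                       noiseSd = 0.05,
                       nV = 200L) {
  stopifnot(stemsPerGenotype >= 1L, faces >= 1L, baseSize > 0,
            stemSd >= 0, noiseSd >= 0)
  list(genotypes = genotypes, genotypeSize = genotypeSize,
       stemsPerGenotype = as.integer(stemsPerGenotype), cuts = cuts,
       elongation = rep_len(elongation, length(cuts)),
       faces = as.integer(faces), baseSize = baseSize, asym = asym,
       stemSd = stemSd, noiseSd = noiseSd, nV = as.integer(nV))
}

#' Generate a synthetic contour dataset with known effects
#'
#' Each contour is built additively on the coordinate scale as
#' mu + alpha_genotype + beta_cut + s_stem + noise, where the genotype and
#' cut effect vectors are centred differences within the parametric contour
#' family (so they satisfy the sum-to-zero constraints of the contour model
#' exactly) and the stem effects are smooth symmetric perturbations centred
#' within genotype. Optionally each contour is then rotated and translated
#' at random so that the alignment stage has work to undo.
#'
#' @param design a list from [stemDesign()].
#' @param seed integer seed.
#' @param rigidJitter logical; apply a random global rotation and
#'   translation to each contour (default FALSE).
#' @return A list with `polygons` (list of [Polygon-class]), `factors`
#'   (data.frame genotype/stem/cut/face), and `truth` (mu, alpha, beta,
#'   stemEffects as coordinate vectors; rotations/translations if jittered).
#' @export
synthContourDataset <- function(design = stemDesign(), seed = 1L,
                                rigidJitter = FALSE) {
  set.seed(seed)
  d <- design
  gl <- d$genotypes; cl <- d$cuts
  meanElong <- mean(d$elongation)
  A <- t(vapply(gl, function(g)
    polygonToRow(synthContour(d$baseSize * d$genotypeSize[[g]], meanElong,
                              d$asym, 0, nV = d$nV)), numeric(2L * d$nV)))
  mu <- colMeans(A)
  alpha <- sweep(A, 2L, mu)
  rownames(alpha) <- gl
  Bm <- t(vapply(seq_along(cl), function(k)
    polygonToRow(synthContour(d$baseSize, d$elongation[k], d$asym, 0,
                              nV = d$nV)), numeric(2L * d$nV)))
  beta <- sweep(Bm, 2L, colMeans(Bm))
  rownames(beta) <- cl
  base <- polygonToRow(synthContour(d$baseSize, meanElong, d$asym, 0,
                                    nV = d$nV))
  stems <- paste0("s", seq_len(d$stemsPerGenotype))
  stemEff <- matrix(0, length(gl) * length(stems), 2L * d$nV)
  rownames(stemEff) <- as.vector(t(outer(gl, stems, paste, sep = "/")))
  if (d$stemSd > 0) {
    for (g in gl) {
      rows <- paste0(g, "/", stems)
      pert <- t(vapply(stems, function(s)
        polygonToRow(synthContour(d$baseSize, meanElong, d$asym,
                                  noiseSd = d$stemSd, nV = d$nV)) - base,
        numeric(2L * d$nV)))
      stemEff[rows, ] <- sweep(pert, 2L, colMeans(pert))
    }
  }
  grid <- expand.grid(face = seq_len(d$faces), cut = cl, stem = stems,
                      genotype = gl, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "stem", "cut", "face")]
  n <- nrow(grid)
  rot <- if (rigidJitter) stats::runif(n, 0, 2 * pi) else numeric(n)
  trans <- if (rigidJitter)
    matrix(stats::runif(2L * n, -d$baseSize, d$baseSize), n, 2L)
  else matrix(0, n, 2L)
  polygons <- vector("list", n)
  for (i in seq_len(n)) {
    v <- mu + alpha[grid$genotype[i], ] + beta[grid$cut[i], ] +
      stemEff[paste0(grid$genotype[i], "/", grid$stem[i]), ]
    if (d$noiseSd > 0) v <- v + stats::rnorm(length(v), 0, d$noiseSd)
    p <- rowToPolygon(v)
    if (rigidJitter) {
      p <- rotatePolygon(p, rot[i])
      p@coords <- sweep(p@coords, 2L, -trans[i, ])
    }
    polygons[[i]] <- p
  }
  list(polygons = polygons, factors = grid,
       truth = list(mu = mu, alpha = alpha, beta = beta,
                    stemEffects = stemEff,
                    rotations = rot, translations = trans))
}

#' Sample an inhomogeneous Poisson point pattern by thinning
#'
#' A homogeneous Poisson pattern of intensity `lambdaMax` on the bounding
#' box is thinned with retention probability lambda(x) / lambdaMax and
#' restricted to the window.
#'
#' @param lambdaFn vectorised intensity function `f(x, y)` (points per mm^2).
#' @param window a [Polygon-class] observation window.
#' @param seed optional integer seed.
#' @param lambdaMax upper bound on lambda over the window; estimated from a
#'   grid evaluation (with 20 percent headroom) when NULL.
#' @return A [PointPattern-class].
#' @export
sampleInhomPoisson <- function(lambdaFn, window, seed = NULL,
                               lambdaMax = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- window@coords
  bb <- apply(w, 2L, range)
  if (is.null(lambdaMax)) {
    gx <- seq(bb[1L, 1L], bb[2L, 1L], length.out = 60L)
    gy <- seq(bb[1L, 2L], bb[2L, 2L], length.out = 60L)
    lambdaMax <- max(lambdaFn(rep(gx, times = 60L), rep(gy, each = 60L))) * 1.2
  }
  if (!is.finite(lambdaMax) || lambdaMax < 0)
    stop("lambdaMax must be non-negative and finite")
  if (lambdaMax == 0)
    return(PointPattern(matrix(numeric(0), 0L, 2L), window))
  area <- prod(bb[2L, ] - bb[1L, ])
  N <- stats::rpois(1L, lambdaMax * area)
  if (N == 0L) return(PointPattern(matrix(numeric(0), 0L, 2L), window))
  x <- stats::runif(N, bb[1L, 1L], bb[2L, 1L])
  y <- stats::runif(N, bb[1L, 2L], bb[2L, 2L])
  u <- stats::runif(N)
  keep <- cpp_point_in_polygon(x, y, w[, 1L], w[, 2L]) &
    u < lambdaFn(x, y) / lambdaMax
  PointPattern(cbind(x[keep], y[keep]), window)
}

#' Sample a hard-core (Matern II) point pattern
#'
#' Proposals form a homogeneous Poisson pattern of intensity `lambda` on the
#' window with independent uniform marks; a proposal is retained iff no
#' other proposal lies within `rMin` with a smaller mark. No two retained
#' points are closer than `rMin`. With `rMin = 0` the pattern reduces to the
#' Poisson proposals.
#'
#' @param lambda proposal intensity (points per mm^2).
#' @param rMin hard-core distance in mm.
#' @param window a [Polygon-class].
#' @param seed optional integer seed.
#' @return A [PointPattern-class].
#' @export
sampleHardcore <- function(lambda, rMin, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rMin > 0 && lambda * pi * rMin^2 >= 1)
    warning("infeasible packing intensity; returning a best-effort pattern")
  prop <- sampleInhomPoisson(function(x, y) rep(lambda, length(x)), window,
                             lambdaMax = lambda)
  pts <- prop@points
  n <- nrow(pts)
  if (n == 0L || rMin <= 0) return(prop)
  marks <- stats::runif(n)
  D <- as.matrix(stats::dist(pts))
  keep <- vapply(seq_len(n), function(i) {
    close <- which(D[i, ] < rMin & seq_len(n) != i)
    !any(marks[close] < marks[i])
  }, logical(1L))
  PointPattern(pts[keep, , drop = FALSE], window)
}

#' Scene truth for a rendered macroscopy section
#'
#' Builds the ground truth behind a rendered section image: the section
#' contour, hard-core bundle positions drawn from a peripherally enriched
#' intensity surface (bundles are denser towards the stem periphery, with a
#' low-intensity outer collar), and the intensity function itself.
#'
#' @param contour a centred [Polygon-class] section contour.
#' @param lambda0 central bundle intensity (points per mm^2).
#' @param lambdaRatio peripheral / central intensity ratio.
#' @param collar width (mm) of the low-intensity outer collar.
#' @param rMin hard-core distance between bundles (mm).
#' @param seed integer seed.
#' @return A list with `contour`, `bundles` (n x 2 matrix, mm, same centred
#'   frame as the contour) and `lambdaFn`.
#' @export
sectionSceneTruth <- function(contour, lambda0 = 2, lambdaRatio = 3,
                              collar = 0.25, rMin = 0.35, seed = 1L) {
  w <- contour@coords
  lambdaFn <- function(x, y) {
    rho <- sqrt(x^2 + y^2)
    rim <- rayIntersectionDistance(contour, atan2(y, x))
    rel <- pmin(rho / rim, 1)
    lam <- lambda0 * (1 + (lambdaRatio - 1) * rel^2)
    lam[rho > rim - collar] <- lambda0 * 0.3
    lam
  }
  set.seed(seed)
  lambdaMax <- lambda0 * lambdaRatio
  prop <- sampleInhomPoisson(lambdaFn, contour, lambdaMax = lambdaMax)
  pts <- prop@points
  if (nrow(pts) > 1L && rMin > 0) {
    marks <- stats::runif(nrow(pts))
    D <- as.matrix(stats::dist(pts))
    keep <- vapply(seq_len(nrow(pts)), function(i) {
      close <- which(D[i, ] < rMin & seq_len(nrow(pts)) != i)
      !any(marks[close] < marks[i])
    }, logical(1L))
    pts <- pts[keep, , drop = FALSE]
  }
  list(contour = contour, bundles = pts, lambdaFn = lambdaFn)
}

#' Render a macroscopy-like section image
#'
#' Draws a grey-level image of a stem section: bright parenchyma tessellated
#' by darker cell walls (Voronoi cells of a hard-core seed pattern, cell
#' sizes in the 50-150 micrometre range), vascular bundles as ~300
#' micrometre darker clusters at the true coordinates, and a dark
#' background outside the contour; mild Gaussian read-out noise is added.
#'
#' @param truth a list from [sectionSceneTruth()] (fields `contour`,
#'   `bundles`).
#' @param resolution mm per pixel, in [0.002, 0.01].
#' @param seed integer seed.
#' @param cellDiameter typical parenchyma cell diameter (mm).
#' @param bundleRadius bundle radius (mm).
#' @return A numeric matrix (x index by y index, grey 0-255) with attribute
#'   `resolution`.
#' @export
renderSectionImage <- function(truth, resolution, seed = 1L,
                               cellDiameter = 0.1, bundleRadius = 0.15) {
  if (resolution < 0.002 || resolution > 0.01)
    stop("resolution must lie in [0.002, 0.01] mm/px")
  set.seed(seed)
  w <- truth$contour@coords
  margin <- 0.4
  xmin <- min(w[, 1L]) - margin; ymin <- min(w[, 2L]) - margin
  nx <- ceiling((max(w[, 1L]) - xmin + margin) / resolution)
  ny <- ceiling((max(w[, 2L]) - ymin + margin) / resolution)
  px <- xmin + (seq_len(nx) - 0.5) * resolution
  # image convention: column index j runs from the top, so y decreases with j
  py <- ymin + (ny - seq_len(ny) + 0.5) * resolution
  X <- matrix(px, nx, ny)
  Y <- matrix(py, nx, ny, byrow = TRUE)
  inside <- matrix(cpp_point_in_polygon(as.vector(X), as.vector(Y),
                                        w[, 1L], w[, 2L]), nx, ny)
  img <- matrix(10, nx, ny)
  img[inside] <- 200
  # parenchyma walls: Voronoi boundaries of a hard-core seed pattern
  seeds <- sampleHardcore(0.7 / cellDiameter^2, 0.5 * cellDiameter,
                          truth$contour)@points
  if (nrow(seeds) >= 3L) {
    si <- pmin(pmax(round((seeds[, 1L] - xmin) / resolution + 0.5), 1L), nx)
    sj <- pmin(pmax(round(ny + 0.5 - (seeds[, 2L] - ymin) / resolution), 1L), ny)
    seedLab <- matrix(0L, nx, ny)
    seedLab[cbind(si, sj)] <- seq_len(nrow(seeds))
    vor <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(matrix(0, nx, ny)), seedLab, lambda = 1e8))
    wall <- (vor != rbind(vor[-1L, , drop = FALSE], vor[nx, ])) |
      (vor != cbind(vor[, -1L, drop = FALSE], vor[, ny]))
    img[wall & inside] <- 90
  }
  # bundles: darker disks with a slightly darker rim
  b <- truth$bundles
  if (nrow(b) > 0L) {
    rpx <- ceiling(bundleRadius / resolution)
    for (k in seq_len(nrow(b))) {
      ci <- (b[k, 1L] - xmin) / resolution + 0.5
      cj <- ny + 0.5 - (b[k, 2L] - ymin) / resolution
      ii <- max(1L, floor(ci - rpx)):min(nx, ceiling(ci + rpx))
      jj <- max(1L, floor(cj - rpx)):min(ny, ceiling(cj + rpx))
      dd <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+"))
      sub <- img[ii, jj, drop = FALSE]
      sub[dd <= rpx] <- 120
      sub[dd <= rpx & dd >= 0.75 * rpx] <- 100
      img[ii, jj] <- sub
    }
  }
  img <- img + stats::rnorm(length(img), 0, 4)
  img <- pmin(pmax(img, 0), 255)
  attr(img, "resolution") <- resolution
  img
}

#' Render an RGB slab-scan image
#'
#' Places slab cross-sections side by side as bright regions (value channel
#' about 0.8) on a dark background (about 0.1), emulating a flatbed scan of
#' stem slabs.
#'
#' @param polygons list of centred [Polygon-class] slab contours.
#' @param resolution mm per pixel (default 0.0353, i.e. 35.3 um/px).
#' @param gapMm horizontal gap between slabs.
#' @param seed integer seed for pixel noise.
#' @return A numeric array (nx x ny x 3) with channels 0-255 and attribute
#'   `resolution`.
#' @export
renderSlabScan <- function(polygons, resolution = 0.0353, gapMm = 4,
                           seed = 1L) {
  set.seed(seed)
  widths <- vapply(polygons, function(p) diff(range(p@coords[, 1L])),
                   numeric(1L))
  heights <- vapply(polygons, function(p) diff(range(p@coords[, 2L])),
                    numeric(1L))
  totalW <- sum(widths) + gapMm * (length(polygons) + 1L)
  totalH <- max(heights) + 2 * gapMm
  nx <- ceiling(totalW / resolution); ny <- ceiling(totalH / resolution)
  val <- matrix(0.1, nx, ny)
  xoff <- gapMm
  for (k in seq_along(polygons)) {
    w <- polygons[[k]]@coords
    cx <- xoff + widths[k] / 2 - mean(range(w[, 1L]))
    xoff <- xoff + widths[k] + gapMm
    sh <- cbind(w[, 1L] + cx, w[, 2L] + totalH / 2)
    bb <- apply(sh, 2L, range)
    ii <- max(1L, floor(bb[1L, 1L] / resolution)):min(nx, ceiling(bb[2L, 1L] / resolution))
    # column index j runs from the top: j = ny + 0.5 - y / resolution
    jj <- max(1L, floor(ny + 0.5 - bb[2L, 2L] / resolution)):
      min(ny, ceiling(ny + 0.5 - bb[1L, 2L] / resolution))
    pxi <- (ii - 0.5) * resolution
    pyj <- (ny - jj + 0.5) * resolution
    ins <- matrix(cpp_point_in_polygon(rep(pxi, times = length(jj)),
                                       rep(pyj, each = length(ii)),
                                       sh[, 1L], sh[, 2L]),
                  length(ii), length(jj))
    sub <- val[ii, jj, drop = FALSE]
    sub[ins] <- 0.8
    val[ii, jj] <- sub
  }
  val <- pmin(pmax(val + stats::rnorm(length(val), 0, 0.01), 0), 1)
  img <- array(0, c(nx, ny, 3L))
  img[, , 1L] <- val * 255
  img[, , 2L] <- val * 225
  img[, , 3L] <- val * 180
  attr(img, "resolution") <- resolution
  img
}
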