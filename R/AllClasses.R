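#' @useDynLib stemAtlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Polygon: a closed planar contour
#'
#' An ordered loop of vertices in millimetres. The loop is stored open (the
#' last vertex connects implicitly to the first). Most operations expect
#' counter-clockwise orientation, which [orientCcw()] establishes.
#'
#' @slot coords numeric matrix with columns `x` and `y` (mm), one row per
#'   vertex, at least 3 rows, no repeated consecutive vertices.
#' @slot metadata list of optional provenance fields (e.g. `sourceId`,
#'   `centroid` of the original, un-centred contour).
#' @export
setClass("Polygon",
  representation(coords = "matrix", metadata = "list"),
  prototype(metadata = list()))

setValidity("Polygon", function(object) {
  xy <- object@coords
  if (!is.numeric(xy) || ncol(xy) != 2L)
    return("coords must be a numeric matrix with 2 columns")
  if (nrow(xy) < 3L)
    return("a polygon needs at least 3 vertices")
  if (any(!is.finite(xy)))
    return("coords contain non-finite values")
  nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  if (any(rowSums(abs(xy - nxt)) == 0))
    return("repeated consecutive vertices (the loop is stored open)")
  TRUE
})

#' Construct a Polygon
#'
#' @param coords two-column numeric matrix (or data.frame) of vertex
#'   coordinates in mm; the loop is stored open.
#' @param metadata optional list of provenance fields.
#' @return A [Polygon-class] object.
#' @examples
#' sq <- Polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygonArea(sq)
#' @export
Polygon <- function(coords, metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(coords)
  if (n > 3L && all(coords[1L, ] == coords[n, ]))
    coords <- coords[-n, , drop = FALSE]
  new("Polygon", coords = coords, metadata = metadata)
}

#' PointPattern: points observed inside a polygonal window
#'
#' @slot points numeric matrix (n x 2) of point coordinates in mm; may have
#'   zero rows.
#' @slot window a [Polygon-class] bounding the observation region. Every
#'   point must lie inside the window or within 1e-6 mm of its boundary.
#' @export
setClass("PointPattern",
  representation(points = "matrix", window = "Polygon"))

setValidity("PointPattern", function(object) {
  pts <- object@points
  if (!is.numeric(pts) || ncol(pts) != 2L)
    return("points must be a numeric matrix with 2 columns")
  if (nrow(pts) > 0L) {
    w <- object@window@coords
    inside <- cpp_point_in_polygon(pts[, 1L], pts[, 2L], w[, 1L], w[, 2L])
    if (!all(inside)) {
      d <- cpp_dist_to_boundary(pts[!inside, 1L], pts[!inside, 2L],
                                w[, 1L], w[, 2L])
      if (any(d > 1e-6))
        return(sprintf("%d point(s) outside the window by up to %.3g mm",
                       sum(d > 1e-6), max(d)))
    }
  }
  TRUE
})

#' Construct a PointPattern
#'
#' @param points n x 2 numeric matrix of point coordinates (mm).
#' @param window a [Polygon-class] observation window.
#' @return A [PointPattern-class] object.
#' @export
PointPattern <- function(points, window) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 2L)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  new("PointPattern", points = points, window = window)
}

#' ContourTable: aligned contour coordinates with experimental factors
#'
#' Row i holds the 2 * nv coordinates (x1..x_nv, y1..y_nv, in mm) of one
#' aligned, resampled slab contour; the accompanying factor table assigns
#' each row to genotype, stem (nested in genotype), cutting position and
#' slab face.
#'
#' @slot XY numeric matrix, rows = contours, columns = x then y coordinates.
#' @slot factors data.frame with columns `genotype`, `stem`, `cut`, `face`.
#' @export
setClass("ContourTable",
  representation(XY = "matrix", factors = "data.frame"))

setValidity("ContourTable", function(object) {
  if (ncol(object@XY) %% 2L != 0L)
    return("XY must have an even number of columns (x then y blocks)")
  if (ncol(object@XY) < 6L)
    return("XY must describe polygons with at least 3 vertices")
  if (nrow(object@XY) != nrow(object@factors))
    return("XY and factors disagree on the number of contours")
  if (any(!is.finite(object@XY)))
    return("XY contains missing or non-finite coordinates")
  needed <- c("genotype", "stem", "cut", "face")
  if (!all(needed %in% names(object@factors)))
    return(paste("factors must contain columns:",
                 paste(needed, collapse = ", ")))
  TRUE
})

#' ContourPCA: principal component decomposition of a contour table
#'
#' @slot center column means of the training table (the average contour).
#' @slot loadings orthonormal loading vectors, one column per component.
#' @slot scores component scores SC(i, j), zero column means.
#' @slot inertia fraction of total variance per component (sums to 1).
#' @export
setClass("ContourPCA",
  representation(center = "numeric", loadings = "matrix",
                 scores = "matrix", inertia = "numeric"))

setValidity("ContourPCA", function(object) {
  if (ncol(object@loadings) != ncol(object@scores))
    return("loadings and scores disagree on component count")
  if (length(object@inertia) != ncol(object@loadings))
    return("one inertia fraction per component required")
  if (abs(sum(object@inertia) - 1) > 1e-6)
    return("inertia fractions must sum to 1")
  TRUE
})

#' ContourLinearModel: per-coordinate linear model of contour shape
#'
#' For every coordinate j the model decomposes XY(i, j) into an intercept
#' mu(j), a genotype effect, a cutting-position effect and a stem-within-
#' genotype effect, all under sum-to-zero constraints, plus residuals. The
#' intercept vector reshaped to a polygon is the reference (atlas) contour.
#'
#' @slot mu numeric vector of intercepts, length n_c.
#' @slot alpha matrix of genotype effects (rows = genotype levels).
#' @slot beta matrix of cutting-position effects (rows = cut levels).
#' @slot stemEffects matrix of stem effects (rows = "genotype/stem").
#' @slot stemIndex data.frame mapping stemEffects rows to (genotype, stem).
#' @slot residuals matrix of residuals, same shape as the training XY.
#' @slot fitted matrix of fitted values.
#' @export
setClass("ContourLinearModel",
  representation(mu = "numeric", alpha = "matrix", beta = "matrix",
                 stemEffects = "matrix", stemIndex = "data.frame",
                 residuals = "matrix", fitted = "matrix"))

#' BundleSet: detected vascular bundle centroids
#'
#' @slot centroids n x 2 matrix of bundle centroid coordinates (mm),
#'   expressed relative to the centroid of the slice contour.
#' @slot sourceId identifier of the source image.
#' @export
setClass("BundleSet",
  representation(centroids = "matrix", sourceId = "character"))

setValidity("BundleSet", function(object) {
  if (ncol(object@centroids) != 2L)
    return("centroids must have 2 columns")
  if (anyDuplicated(object@centroids) > 0L)
    return("duplicate centroids")
  TRUE
})

#' IntensityGrid: a raster of estimated point-process intensity
#'
#' Values are in points per square millimetre on a fixed grid; the mask marks
#' pixels inside the observation window. All grids of one study share the
#' same grid specification so that maps can be averaged pixel-wise.
#'
#' @slot values numeric matrix (nx x ny); element (i, j) sits at
#'   x = xmin + (i - 0.5) * dx, y = ymin + (j - 0.5) * dy.
#' @slot mask logical matrix, TRUE where the pixel centre is inside the window.
#' @slot origin numeric(2), (xmin, ymin) corner of the grid in mm.
#' @slot pixelSize numeric(2), (dx, dy) in mm.
#' @export
setClass("IntensityGrid",
  representation(values = "matrix", mask = "matrix",
                 origin = "numeric", pixelSize = "numeric"))

setValidity("IntensityGrid", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask dimensions differ")
  if (length(object@origin) != 2L || length(object@pixelSize) != 2L)
    return("origin and pixelSize must each have length 2")
  if (any(object@pixelSize <= 0))
    return("pixelSize must be positive")
  v <- object@values[object@mask]
  if (length(v) && any(v < -1e-12, na.rm = TRUE))
    return("negative intensity inside the mask")
  TRUE
})

#' StemModel3D: stacked predicted contours along the internode
#'
#' @slot contours list of [Polygon-class], one per cutting position, in
#'   order from the top of the internode downwards.
#' @slot z numeric vector of slab height indices.
#' @slot genotype genotype label the model was built for.
#' @export
setClass("StemModel3D",
  representation(contours = "list", z = "numeric", genotype = "character"))
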