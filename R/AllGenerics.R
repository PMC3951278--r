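#' @name accessors
#' @title Accessors for stemAtlas classes
#' @param x an object of the documented classes.
#' @param object an object of the documented classes.
#' @param ... unused.
#' @return The slot content documented for each method.
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "Polygon", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setMethod("nVertices", "Polygon", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "PointPattern", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("coords", "BundleSet", function(x) x@centroids)

#' @rdname accessors
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))
#' @rdname accessors
#' @export
setMethod("npoints", "PointPattern", function(x) nrow(x@points))

#' @rdname accessors
#' @export
setGeneric("patternWindow", function(x) standardGeneric("patternWindow"))
#' @rdname accessors
#' @export
setMethod("patternWindow", "PointPattern", function(x) x@window)

#' @rdname accessors
#' @export
setGeneric("contourMatrix", function(x) standardGeneric("contourMatrix"))
#' @rdname accessors
#' @export
setMethod("contourMatrix", "ContourTable", function(x) x@XY)

#' @rdname accessors
#' @export
setGeneric("contourFactors", function(x) standardGeneric("contourFactors"))
#' @rdname accessors
#' @export
setMethod("contourFactors", "ContourTable", function(x) x@factors)

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ContourPCA", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setMethod("loadings", "ContourPCA", function(x, ...) x@loadings)

#' @rdname accessors
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))
#' @rdname accessors
#' @export
setMethod("inertia", "ContourPCA", function(x) x@inertia)

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "IntensityGrid", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @rdname accessors
#' @export
setMethod("gridMask", "IntensityGrid", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname accessors
#' @export
setMethod("gridSpec", "IntensityGrid", function(x)
  list(origin = x@origin, pixelSize = x@pixelSize, dim = dim(x@values)))

#' @rdname accessors
#' @export
setMethod("show", "Polygon", function(object) {
  a <- polygonArea(object)
  cat(sprintf("Polygon with %d vertices, signed area %.4g mm^2\n",
              nrow(object@coords), a))
})

#' @rdname accessors
#' @export
setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d points in a %d-vertex window\n",
              nrow(object@points), nrow(object@window@coords)))
})

#' @rdname accessors
#' @export
setMethod("show", "ContourTable", function(object) {
  cat(sprintf("ContourTable: %d contours x %d coordinates (%d vertices)\n",
              nrow(object@XY), ncol(object@XY), ncol(object@XY) %/% 2L))
  print(utils::head(object@factors, 3L))
})

#' @rdname accessors
#' @export
setMethod("show", "ContourPCA", function(object) {
  cat(sprintf("ContourPCA: %d components on %d observations\n",
              ncol(object@loadings), nrow(object@scores)))
  k <- min(5L, length(object@inertia))
  cat("inertia:", paste0(sprintf("%.1f%%", 100 * object@inertia[seq_len(k)]),
                         collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "ContourLinearModel", function(object) {
  cat(sprintf(paste0("ContourLinearModel: %d coordinates; genotypes: %s; ",
                     "cuts: %s; %d stems\n"),
              length(object@mu), paste(rownames(object@alpha), collapse = ","),
              paste(rownames(object@beta), collapse = ","),
              nrow(object@stemEffects)))
})

#' @rdname accessors
#' @export
setMethod("show", "BundleSet", function(object) {
  cat(sprintf("BundleSet '%s': %d bundle centroids\n",
              object@sourceId, nrow(object@centroids)))
})

#' @rdname accessors
#' @export
setMethod("show", "IntensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("IntensityGrid %dx%d, pixel %.3g x %.3g mm, ",
                     "%d masked-in pixels\n"),
              d[1L], d[2L], object@pixelSize[1L], object@pixelSize[2L],
              sum(object@mask)))
})

#' @rdname accessors
#' @export
setMethod("show", "StemModel3D", function(object) {
  cat(sprintf("StemModel3D (%s): %d stacked contours\n",
              object@genotype, length(object@contours)))
})
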