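# Detection of vascular-bundle centroids in macroscopy images: alternate
# sequential filtering to erase the parenchyma cell walls, extended-minima
# detection of the darker bundle clusters at two depths, watershed
# separation of touching bundles, and centroid extraction.

#' Alternate sequential filter
#'
#' Applies, for r = 1..rMax, a morphological opening followed by a closing
#' with a discrete disk of radius r. Small-scale structures (cell walls) are
#' removed while structures larger than the final disk (vascular bundles)
#' persist. Output grey levels stay within the input range.
#'
#' @param img numeric matrix, grey 0-255.
#' @param rMax largest structuring-element radius in pixels (default 10).
#' @return Filtered numeric matrix.
#' @export
asf <- function(img, rMax = 10L) {
  if (rMax < 1L) stop("rMax must be at least 1")
  out <- img / 255  # EBImage grey morphology operates on [0, 1]
  for (r in seq_len(rMax)) {
    brush <- EBImage::makeBrush(2L * r + 1L, "disc")
    out <- EBImage::imageData(EBImage::closing(
      EBImage::opening(out, brush), brush))
  }
  out * 255
}

#' Extended minima (h-minima) of a grey image
#'
#' Regional minima of the h-minima transform: the connected regions that are
#' local minima with depth at least `h` relative to their lowest escape
#' saddle. Computed with greyscale morphological reconstruction by erosion
#' (8-connectivity).
#'
#' @param img numeric matrix, grey 0-255.
#' @param h minimum depth in grey levels (> 0); the study uses 30 for large
#'   bundles and 20 for small bundles.
#' @return Logical matrix marking the extended-minima regions.
#' @export
extendedMinima <- function(img, h) {
  if (h <= 0) stop("h must be positive")
  hm <- cpp_reconstruct_erosion(img + h, img)
  rec <- cpp_reconstruct_erosion(hm + 1, hm)
  em <- (rec - hm) > 0.5
  # an image whose minima are all shallower than h flattens completely; the
  # resulting rimless plateau is not a detection
  if (all(em)) em[] <- FALSE
  em
}

#' Separate touching blobs with a distance-map watershed
#'
#' A watershed applied to (the complement of) the distance map of the mask
#' splits touching near-convex blobs along the ridges of the distance map.
#'
#' @param mask logical or 0/1 matrix.
#' @return Integer label matrix partitioning the mask (0 = background).
#' @export
separateTouching <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask)
  lab <- EBImage::imageData(EBImage::watershed(d, tolerance = 1, ext = 1L))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# centroids (pixel coordinates) and areas of the labels of a label image
.labelCentroids <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L)
    return(list(centroids = matrix(numeric(0), 0L, 2L), areas = integer(0)))
  l <- lab[pos]
  i <- (pos - 1L) %% nrow(lab) + 1L
  j <- (pos - 1L) %/% nrow(lab) + 1L
  n <- as.vector(rowsum(rep(1L, length(l)), l))
  ci <- as.vector(rowsum(as.numeric(i), l)) / n
  cj <- as.vector(rowsum(as.numeric(j), l)) / n
  list(centroids = cbind(ci, cj), areas = n)
}

#' Detect vascular bundle centroids in a macroscopy image
#'
#' Full chain: alternate sequential filtering, extended minima at the large
#' and small depth thresholds, watershed separation of touching detections,
#' and centroid extraction. Detections from the small threshold whose
#' regions overlap a large-threshold detection are merged into it (the
#' large-threshold centroid is kept). Centroids are converted to mm and
#' expressed relative to the centroid of the slice contour.
#'
#' @param img numeric matrix, grey 0-255; bundles darker than the
#'   surrounding parenchyma after filtering (set `invert = TRUE` for the
#'   opposite convention).
#' @param resolution mm per pixel.
#' @param hLarge extended-minima depth for large bundles (default 30).
#' @param hSmall depth for small bundles (default 20).
#' @param rMax alternate-sequential-filter radius (default 10).
#' @param invert detect maxima instead of minima.
#' @param contour optional centred slice contour ([Polygon-class]) as
#'   returned by [segmentSliceContour()]; its metadata centroid is used to
#'   centre the detections and detections outside the contour are dropped.
#' @param centre explicit centring translation (mm, image frame) if no
#'   contour is supplied.
#' @param maxAreaMm2 detections larger than this area are discarded
#'   (suppresses the background region, which is itself a deep minimum).
#' @param sourceId identifier stored in the result.
#' @return A [BundleSet-class]; empty detection yields an empty set.
#' @export
detectBundles <- function(img, resolution, hLarge = 30, hSmall = 20,
                          rMax = 10L, invert = FALSE, contour = NULL,
                          centre = c(0, 0), maxAreaMm2 = 0.3,
                          sourceId = "image") {
  f <- asf(img, rMax)
  if (invert) f <- max(f) - f
  emL <- extendedMinima(f, hLarge)
  emS <- extendedMinima(f, hSmall)
  labL <- separateTouching(emL)
  labS <- separateTouching(emS)
  maxAreaPx <- maxAreaMm2 / resolution^2
  ccL <- .labelCentroids(labL)
  keepL <- ccL$areas <= maxAreaPx
  cents <- ccL$centroids[keepL, , drop = FALSE]
  # small-threshold detections that do not overlap any large-threshold region
  ccS <- .labelCentroids(labS)
  if (nrow(ccS$centroids) > 0L) {
    overlap <- as.vector(rowsum(as.numeric(emL[labS > 0L]),
                                labS[labS > 0L])) > 0
    keepS <- !overlap & ccS$areas <= maxAreaPx
    cents <- rbind(cents, ccS$centroids[keepS, , drop = FALSE])
  }
  if (nrow(cents) == 0L)
    return(new("BundleSet", centroids = matrix(numeric(0), 0L, 2L),
               sourceId = sourceId))
  xy <- pixelsToXY(cents, ncolMask = ncol(img), resolution = resolution)
  if (!is.null(contour)) {
    ctr <- contour@metadata$centroid
    if (is.null(ctr)) stop("contour metadata lacks the original centroid")
    xy <- sweep(xy, 2L, ctr)
    w <- contour@coords
    keep <- cpp_point_in_polygon(xy[, 1L], xy[, 2L], w[, 1L], w[, 2L])
    xy <- xy[keep, , drop = FALSE]
  } else {
    xy <- sweep(xy, 2L, centre)
  }
  xy <- unique(xy)
  new("BundleSet", centroids = xy, sourceId = sourceId)
}
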