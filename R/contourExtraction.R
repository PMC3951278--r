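# Segmentation of slab scans and macroscopy section images into binary
# masks and centred contour polygons. Images are stored as matrices m[i, j]
# with i the x pixel index and j the y pixel index counted from the top row
# (EBImage orientation); pixelsToXY() converts to mathematical coordinates.

#' LabelledMask: a binary mask with its physical resolution
#'
#' @slot mask logical matrix (image orientation) with at least one
#'   foreground pixel.
#' @slot resolution mm per pixel (> 0).
#' @slot sourceId identifier of the source image.
#' @export
setClass("LabelledMask",
  representation(mask = "matrix", resolution = "numeric",
                 sourceId = "character"))

setValidity("LabelledMask", function(object) {
  if (object@resolution <= 0) return("resolution must be positive")
  if (!any(object@mask)) return("mask has no foreground pixel")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("show", "LabelledMask", function(object) {
  cat(sprintf("LabelledMask '%s': %dx%d px at %.4g mm/px, %d foreground px\n",
              object@sourceId, nrow(object@mask), ncol(object@mask),
              object@resolution, sum(object@mask)))
})

#' Value channel of an RGB image
#'
#' The HSV value channel: V = max(R, G, B) / 255.
#'
#' @param img numeric array with three channels in the last dimension,
#'   values in 0-255.
#' @return A numeric matrix in [0, 1] with the spatial dimensions of `img`.
#' @export
rgbToValue <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L)
    stop("expected a 3-channel RGB array, got dimensions ",
         paste(d, collapse = "x"))
  pmax(img[, , 1L], img[, , 2L], img[, , 3L]) / 255
}

#' Segment slab cross-sections from a value-channel image
#'
#' Thresholds the value channel (foreground = value > threshold), labels
#' connected components, discards components below `minAreaPx`, and fills
#' holes, yielding one mask per slab.
#'
#' @param value numeric matrix in [0, 1] (image orientation).
#' @param threshold value threshold separating slabs (bright, around 0.8)
#'   from background (dark, around 0.1); default 0.5.
#' @param minAreaPx minimal component area in pixels (rejects dust).
#' @param resolution mm per pixel (default 0.0353).
#' @param sourceId identifier recorded in each mask.
#' @return List of [LabelledMask-class], ordered left to right in the image.
#' @export
segmentSlabs <- function(value, threshold = 0.5, minAreaPx = 1000L,
                         resolution = 0.0353, sourceId = "image") {
  fg <- value > threshold
  if (!any(fg))
    stop(sprintf("no foreground at threshold %g", threshold))
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  areas <- tabulate(lab)
  keep <- which(areas >= minAreaPx)
  if (length(keep) == 0L)
    stop(sprintf("no slab component of at least %d px at threshold %g",
                 minAreaPx, threshold))
  # order slabs by the x position of their leftmost pixel
  xmin <- vapply(keep, function(k)
    min(which(lab == k, arr.ind = TRUE)[, 1L]), numeric(1L))
  keep <- keep[order(xmin)]
  lapply(seq_along(keep), function(s) {
    m <- lab == keep[s]
    m <- EBImage::imageData(EBImage::fillHull(m)) > 0
    new("LabelledMask", mask = m, resolution = resolution,
        sourceId = sprintf("%s#%d", sourceId, s))
  })
}

# Moore boundary tracing of the single foreground component of `mask`.
# Returns the ordered (i, j) boundary pixel sequence (closed loop, first
# vertex not repeated). Robust to filled regions and to one-pixel-wide
# curves; consecutive duplicates are removed.
.mooreTrace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2L:(nr + 1L), 2L:(nc + 1L)] <- mask != 0
  # clockwise Moore neighbourhood in display terms (x right, j down)
  off <- rbind(c(-1, -1), c(0, -1), c(1, -1), c(1, 0),
               c(1, 1), c(0, 1), c(-1, 1), c(-1, 0))
  # scan in j-then-i order so the pixel above the start is background
  fg <- which(m, arr.ind = TRUE)
  fg <- fg[order(fg[, 2L], fg[, 1L]), , drop = FALSE]
  s <- fg[1L, ]
  b0 <- s + c(0L, -1L)
  path <- matrix(0L, 8L * sum(m), 2L)
  np <- 0L
  cur <- s; b <- b0
  repeat {
    np <- np + 1L
    path[np, ] <- cur
    # index of the backtrack pixel in the neighbour ring
    rel <- b - cur
    k0 <- which(off[, 1L] == rel[1L] & off[, 2L] == rel[2L])
    found <- FALSE
    for (step in 1L:8L) {
      k <- (k0 + step - 1L) %% 8L + 1L
      nb <- cur + off[k, ]
      if (m[nb[1L], nb[2L]]) {
        bnew <- cur + off[(k - 2L) %% 8L + 1L, ]
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    # stop when the walk is about to repeat its first move
    if (np > 1L && all(cur == s) && all(nb == path[2L, ])) break
    b <- bnew; cur <- nb
    if (np >= nrow(path)) break
  }
  path <- path[seq_len(np), , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(path))) == 0)
  path <- path[!dup, , drop = FALSE]
  if (nrow(path) > 1L && all(path[nrow(path), ] == path[1L, ]))
    path <- path[-nrow(path), , drop = FALSE]
  sweep(path, 2L, c(1L, 1L))  # undo padding
}

#' Contour polygon of a labelled mask
#'
#' Traces the boundary pixels of the (single-component, hole-filled) mask as
#' an ordered one-pixel chain, converts pixel indices to millimetres, and
#' returns the centred, counter-clockwise polygon. The centroid of the
#' un-centred contour (mm, image frame) is stored in the polygon metadata.
#'
#' @param m a [LabelledMask-class].
#' @return A centred [Polygon-class].
#' @export
maskToContour <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(m@mask != 0))
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop(sprintf("expected a single-component mask, found %d components",
                 ncomp))
  ij <- .mooreTrace(m@mask)
  if (nrow(ij) < 3L) stop("component too small to trace a contour")
  p <- Polygon(pixelsToXY(ij, ncolMask = ncol(m@mask),
                          resolution = m@resolution))
  cp <- centrePolygon(p)
  out <- orientCcw(cp$polygon)
  out@metadata <- list(sourceId = m@sourceId, centroid = cp$centroid)
  out
}

#' Segment the contour of a cellular section image
#'
#' Detects cells with a watershed on the Gaussian-smoothed image (basins
#' grown from bright cell interiors), keeps the basins whose interior is
#' brighter than the global Otsu threshold, fills holes, smooths the
#' boundary with a morphological closing, and converts the traced boundary
#' to a Douglas-Peucker-simplified, centred polygon in millimetres.
#'
#' @param img numeric matrix, grey values 0-255 (image orientation).
#' @param resolution mm per pixel.
#' @param closingRadiusPx radius of the closing disk in pixels (default 30).
#' @param dpTolMm Douglas-Peucker tolerance in mm (default 0.1, i.e.
#'   100 micrometres).
#' @param smoothSigma Gaussian pre-smoothing standard deviation in pixels.
#' @param downsample integer decimation factor for the cell-detection
#'   watershed (the foreground mask is re-expanded before the closing, so
#'   the contour precision loss is bounded by `downsample` pixels).
#' @return A centred [Polygon-class]; the original centroid (mm, image
#'   frame) is stored in the metadata.
#' @export
segmentSliceContour <- function(img, resolution, closingRadiusPx = 30L,
                                dpTolMm = 0.1, smoothSigma = 2,
                                downsample = 2L) {
  sm <- EBImage::imageData(EBImage::gblur(img / 255, sigma = smoothSigma))
  ii <- seq(1L, nrow(sm), by = downsample)
  jj <- seq(1L, ncol(sm), by = downsample)
  ds <- sm[ii, jj]
  ws <- EBImage::imageData(EBImage::watershed(ds, tolerance = 0.05, ext = 1L))
  thr <- EBImage::otsu(EBImage::Image(ds))
  # a basin is a cell if it peaks above the Otsu threshold; the background
  # (which has no watershed maximum of its own and joins boundary-cell
  # basins) is trimmed afterwards with the per-pixel brightness floor
  level <- tapply(as.vector(ds), as.vector(ws), max)
  bright <- as.integer(names(level))[level > thr]
  bright <- bright[bright > 0L]
  if (length(bright) == 0L) stop("empty foreground: no cells detected")
  fgd <- matrix(ws %in% bright, nrow(ws), ncol(ws))
  fg <- fgd[rep(seq_along(ii), each = downsample)[seq_len(nrow(sm))],
            rep(seq_along(jj), each = downsample)[seq_len(ncol(sm))]]
  # cell basins bleed into the empty background where no wall stops the
  # flooding; trim them with a per-pixel brightness floor before filling
  fg <- fg & (sm > 0.5 * thr)
  fg <- EBImage::imageData(EBImage::fillHull(fg)) > 0
  brush <- EBImage::makeBrush(2L * closingRadiusPx + 1L, "disc")
  fg <- EBImage::imageData(EBImage::closing(fg, brush)) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  if (max(lab) > 1L) {
    areas <- tabulate(lab)
    fg <- lab == which.max(areas)
  }
  fg <- EBImage::imageData(EBImage::fillHull(fg)) > 0
  lm <- new("LabelledMask", mask = fg, resolution = resolution,
            sourceId = "slice")
  p <- maskToContour(lm)
  meta <- p@metadata
  p <- simplifyDP(p, dpTolMm)
  cp <- centrePolygon(p)  # re-centre after simplification
  out <- orientCcw(cp$polygon)
  out@metadata <- list(sourceId = meta$sourceId,
                       centroid = meta$centroid + cp$centroid)
  out
}

#' Read a grey-level image file
#'
#' Reads PNG (or TIFF, if the tiff package is installed) into the internal
#' image orientation, grey values 0-255.
#'
#' @param path image file path.
#' @return Numeric matrix m[i, j] with i = x index, j = y index from the top.
#' @export
readGreyImage <- function(path) {
  raster <- .readRaster(path)
  if (length(dim(raster)) == 3L)
    raster <- apply(raster, c(1L, 2L), max)
  t(raster) * 255
}

#' Read an RGB image file
#'
#' @param path image file path.
#' @return Numeric array (nx x ny x 3), channels 0-255, image orientation.
#' @export
readRgbImage <- function(path) {
  raster <- .readRaster(path)
  if (length(dim(raster)) == 2L)
    raster <- array(rep(raster, 3L), c(dim(raster), 3L))
  aperm(raster[, , 1:3, drop = FALSE], c(2L, 1L, 3L)) * 255
}

.readRaster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE))
    return(png::readPNG(path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: ", path)
}

#' Write a grey image matrix as PNG
#' @param img numeric matrix, 0-255, image orientation.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGreyImage <- function(img, path) {
  png::writePNG(t(pmin(pmax(img / 255, 0), 1)), path)
  invisible(path)
}

#' Write an RGB image array as PNG
#' @param img numeric array (nx x ny x 3), 0-255, image orientation.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRgbImage <- function(img, path) {
  png::writePNG(aperm(pmin(pmax(img / 255, 0), 1), c(2L, 1L, 3L)), path)
  invisible(path)
}
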