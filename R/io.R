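# Plain-text serialisation: polygons and point patterns as CSV, models and
# grid specifications as JSON, intensity grids as whitespace-separated
# matrices with a JSON sidecar.

#' Write polygons to CSV
#'
#' Columns: contour_id, vertex_index, x_mm, y_mm; loops stored open.
#'
#' @param polygons named list of [Polygon-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writePolygonsCsv <- function(polygons, path) {
  ids <- names(polygons)
  if (is.null(ids)) ids <- as.character(seq_along(polygons))
  rows <- do.call(rbind, lapply(seq_along(polygons), function(k) {
    xy <- polygons[[k]]@coords
    data.frame(contour_id = ids[k], vertex_index = seq_len(nrow(xy)),
               x_mm = xy[, 1L], y_mm = xy[, 2L])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read polygons from CSV
#' @param path CSV path written by [writePolygonsCsv()].
#' @return Named list of [Polygon-class].
#' @export
readPolygonsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$contour_id), function(g) {
    g <- g[order(g$vertex_index), ]
    Polygon(cbind(g$x_mm, g$y_mm))
  })
  out[unique(d$contour_id)]
}

#' Write point sets to CSV
#'
#' Columns: source_id, x_mm, y_mm.
#'
#' @param sets named list of [BundleSet-class] or [PointPattern-class] or
#'   plain n x 2 matrices.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writePointsCsv <- function(sets, path) {
  ids <- names(sets)
  if (is.null(ids)) ids <- as.character(seq_along(sets))
  rows <- do.call(rbind, lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    xy <- if (is(s, "BundleSet")) s@centroids
          else if (is(s, "PointPattern")) s@points
          else as.matrix(s)
    if (nrow(xy) == 0L) return(NULL)
    data.frame(source_id = ids[k], x_mm = xy[, 1L], y_mm = xy[, 2L])
  }))
  if (is.null(rows))
    rows <- data.frame(source_id = character(0), x_mm = numeric(0),
                       y_mm = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read point sets from CSV
#' @param path CSV path written by [writePointsCsv()].
#' @return Named list of n x 2 matrices.
#' @export
readPointsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$source_id), function(g) cbind(x = g$x_mm, y = g$y_mm))
}

#' Write a contour table to CSV (factors followed by coordinate columns)
#' @param t a [ContourTable-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeContourTableCsv <- function(t, path) {
  utils::write.csv(cbind(t@factors, as.data.frame(t@XY)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour table from CSV
#' @param path CSV path written by [writeContourTableCsv()].
#' @return A [ContourTable-class].
#' @export
readContourTableCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- c("genotype", "stem", "cut", "face")
  XY <- as.matrix(d[, setdiff(names(d), fcols), drop = FALSE])
  factors <- d[, fcols]
  for (f in fcols) factors[[f]] <- factor(factors[[f]])
  new("ContourTable", XY = XY, factors = factors)
}

#' Serialise a contour linear model to JSON
#' @param m a [ContourLinearModel-class].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeContourModelJson <- function(m, path) {
  obj <- list(mu = m@mu,
              alpha = as.data.frame(t(m@alpha)),
              beta = as.data.frame(t(m@beta)),
              stemEffects = as.data.frame(t(m@stemEffects)),
              stemIndex = m@stemIndex)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a contour linear model from JSON
#' @param path JSON path written by [writeContourModelJson()].
#' @return A [ContourLinearModel-class] (residuals and fitted values are
#'   not serialised and come back empty).
#' @export
readContourModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(df) {
    m <- t(as.matrix(df))
    storage.mode(m) <- "double"
    m
  }
  new("ContourLinearModel", mu = as.numeric(obj$mu),
      alpha = toMat(obj$alpha), beta = toMat(obj$beta),
      stemEffects = toMat(obj$stemEffects),
      stemIndex = as.data.frame(obj$stemIndex),
      residuals = matrix(numeric(0), 0L, 0L),
      fitted = matrix(numeric(0), 0L, 0L))
}

#' Write an intensity grid as text matrix plus JSON sidecar
#'
#' The matrix file holds the values (rows = x index); `<path>.json` records
#' origin, pixel size, dimensions and the mask (run-length encoded).
#'
#' @param g an [IntensityGrid-class].
#' @param path output path for the matrix (sidecar written at
#'   `paste0(path, ".json")`).
#' @return Invisibly, `path`.
#' @export
writeIntensityGrid <- function(g, path) {
  utils::write.table(g@values, path, row.names = FALSE, col.names = FALSE)
  rle_ <- rle(as.vector(g@mask))
  jsonlite::write_json(
    list(origin = g@origin, pixelSize = g@pixelSize, dim = dim(g@values),
         mask_lengths = rle_$lengths, mask_values = rle_$values),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read an intensity grid written by [writeIntensityGrid()]
#' @param path matrix file path.
#' @return An [IntensityGrid-class].
#' @export
readIntensityGrid <- function(path) {
  spec <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path))
  dimnames(vals) <- NULL
  mask <- matrix(inverse.rle(list(lengths = spec$mask_lengths,
                                  values = spec$mask_values)),
                 spec$dim[1L], spec$dim[2L])
  new("IntensityGrid", values = vals, mask = mask,
      origin = as.numeric(spec$origin),
      pixelSize = as.numeric(spec$pixelSize))
}
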