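# Workflow orchestration: study configuration, the simulate / segment /
# model / map commands used by the command-line interface
# (inst/scripts/stematlas.R), and their file-format glue.

#' Default study configuration
#'
#' All numeric pipeline parameters with their study defaults. A JSON
#' configuration file may override any subset.
#'
#' @param ... overrides of the defaults.
#' @return A named list.
#' @export
studyConfig <- function(...) {
  cfg <- list(
    threshold = 0.5,          # slab value-channel threshold
    minAreaPx = 1000L,        # minimal slab component area
    nV = 200L,                # vertices per aligned contour
    slabResolution = 0.0353,  # mm/px of slab scans
    sliceResolution = 0.004,  # mm/px of macroscopy images
    dpTolMm = 0.1,            # Douglas-Peucker tolerance
    closingRadiusPx = 30L,    # slice-contour closing radius
    asfRmax = 10L,            # alternate-sequential-filter radius
    hLarge = 30,              # extended-minima depth, large bundles
    hSmall = 20,              # extended-minima depth, small bundles
    gridN = 128L,             # intensity grid resolution
    gridExpand = 0.05,        # grid bounding-box expansion
    correction = "uniform",   # KDE edge correction
    bandwidth = NA_real_,     # kernel sigma (NA: rule of thumb)
    minCoverage = 0.5,        # averaging coverage threshold
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Read a study configuration from JSON
#' @param path JSON file with a subset of the [studyConfig()] fields.
#' @return A full configuration list.
#' @export
readStudyConfig <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(studyConfig, over)
}

#' Simulate a study on disk
#'
#' Writes rendered slab-scan images, a factor table, rendered macroscopy
#' section images for the slabs observed under the macroscope, and the
#' ground truth (contours, bundle positions) for validation.
#'
#' @param outDir output directory.
#' @param config a [studyConfig()] list.
#' @param design a [stemDesign()] list; a compact design keeps runtimes
#'   small.
#' @param macroSlabs slab letters imaged under the macroscope.
#' @return Invisibly, a list with the factor table and ground-truth paths.
#' @export
simulateStudy <- function(outDir, config = studyConfig(),
                          design = stemDesign(stemsPerGenotype = 2L,
                                              baseSize = 3),
                          macroSlabs = c("A", "D")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  ds <- synthContourDataset(design, seed = config$seed, rigidJitter = TRUE)
  fac <- ds$factors
  # one scan image per stem and face, holding that stem's slab contours
  fac$image_path <- NA_character_
  for (g in unique(fac$genotype)) for (s in unique(fac$stem))
    for (f in unique(fac$face)) {
      rows <- which(fac$genotype == g & fac$stem == s & fac$face == f)
      if (length(rows) == 0L) next
      img <- renderSlabScan(ds$polygons[rows],
                            resolution = config$slabResolution,
                            seed = config$seed + length(rows))
      fn <- sprintf("scan_%s_%s_face%s.png", g, s, f)
      writeRgbImage(img, file.path(outDir, fn))
      fac$image_path[rows] <- fn
    }
  utils::write.csv(fac, file.path(outDir, "factors.csv"), row.names = FALSE)
  writePolygonsCsv(stats::setNames(ds$polygons,
                                   sprintf("contour_%03d", seq_along(ds$polygons))),
                   file.path(outDir, "truth_contours.csv"))
  invisible(list(factors = fac, dir = outDir))
}

#' Segment slab scans into aligned, resampled contours
#'
#' For every image listed in the factor table: value-channel threshold,
#' per-slab masks, contour tracing, symmetry alignment and resampling to
#' `nV` vertices. Slabs are matched to factor rows by their left-to-right
#' order in each image.
#'
#' @param imageDir directory holding the scan images.
#' @param factorTable data.frame with columns image_path, genotype, stem,
#'   cut, face (one row per slab contour, ordered left to right per image).
#' @param config a [studyConfig()] list.
#' @param outCsv optional path for the contour-table CSV.
#' @return A [ContourTable-class].
#' @export
cmdSegmentSlabs <- function(imageDir, factorTable, config = studyConfig(),
                            outCsv = NULL) {
  needed <- c("image_path", "genotype", "stem", "cut", "face")
  if (!all(needed %in% names(factorTable)))
    stop("factor table must contain columns: ",
         paste(needed, collapse = ", "))
  polys <- vector("list", nrow(factorTable))
  failed <- character(0)
  for (imgName in unique(factorTable$image_path)) {
    rows <- which(factorTable$image_path == imgName)
    res <- tryCatch({
      rgb <- readRgbImage(file.path(imageDir, imgName))
      value <- rgbToValue(rgb)
      masks <- segmentSlabs(value, threshold = config$threshold,
                            minAreaPx = config$minAreaPx,
                            resolution = config$slabResolution,
                            sourceId = imgName)
      if (length(masks) != length(rows))
        stop(sprintf("%s: found %d slabs for %d factor rows", imgName,
                     length(masks), length(rows)))
      lapply(masks, function(m) {
        p <- maskToContour(m)
        resamplePolygon(alignUpwards(p), config$nV)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping %s: %s", imgName, conditionMessage(res)))
      failed <- c(failed, imgName)
    } else {
      polys[rows] <- res
    }
  }
  ok <- !vapply(polys, is.null, logical(1L))
  if (!any(ok)) stop("no image could be segmented")
  tab <- buildContourTable(polys[ok], factorTable[ok, needed[-1L]])
  if (!is.null(outCsv)) writeContourTableCsv(tab, outCsv)
  attr(tab, "failed") <- failed
  tab
}

#' Fit the contour models and write their summaries
#'
#' Runs the PCA, the nested ANOVA of the first five component scores, the
#' per-coordinate contour model, and builds the reference contour and the
#' per-genotype 3D stem models.
#'
#' @param tab a [ContourTable-class].
#' @param outDir optional directory for model JSON / ANOVA CSV / reference
#'   contour CSV.
#' @return A list with `pca`, `anova`, `model`, `reference`, `stems3d`.
#' @export
cmdModelStem <- function(tab, outDir = NULL) {
  pca <- fitContourPCA(tab)
  fac <- tab@factors
  anova <- if (nlevels(fac$genotype) >= 2L &&
               nlevels(factor(fac$stem)) >= 2L) {
    anovaPcScores(pca, fac)
  } else {
    warning("reduced design: ANOVA of component scores skipped")
    NULL
  }
  model <- fitContourModel(tab)
  reference <- referenceContour(model)
  stems3d <- lapply(rownames(model@alpha), function(g) buildStem3d(model, g))
  names(stems3d) <- rownames(model@alpha)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeContourModelJson(model, file.path(outDir, "contour_model.json"))
    if (!is.null(anova))
      utils::write.csv(anova, file.path(outDir, "anova_pc_scores.csv"),
                       row.names = FALSE)
    writePolygonsCsv(list(reference = reference),
                     file.path(outDir, "reference_contour.csv"))
  }
  list(pca = pca, anova = anova, model = model, reference = reference,
       stems3d = stems3d)
}

#' Normalise slice point patterns and build intensity maps
#'
#' For each slice: rigid rotation onto its model contour, polar
#' normalisation onto the reference contour, kernel intensity estimation on
#' the shared grid; then the global and per-level average maps.
#'
#' @param slices list of per-slice entries, each a list with `contour`
#'   (centred observed slice contour), `bundles` (n x 2 matrix, mm, centred
#'   frame), `genotype`, `stem`, `slab`.
#' @param model a [ContourLinearModel-class].
#' @param config a [studyConfig()] list.
#' @param outDir optional output directory for normalised patterns and
#'   maps.
#' @return A list with `patterns`, `maps`, `global`, and per-factor
#'   averages `byGenotype`, `bySlab`.
#' @export
cmdMapIntensity <- function(slices, model, config = studyConfig(),
                            outDir = NULL) {
  reference <- referenceContour(model)
  grid <- intensityGridSpec(reference, n = config$gridN,
                            expand = config$gridExpand)
  sigma <- if (is.na(config$bandwidth)) defaultBandwidth(reference)
           else config$bandwidth
  patterns <- vector("list", length(slices))
  maps <- vector("list", length(slices))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    modelContour <- predictContour(model, genotype = s$genotype,
                                   slab = s$slab, stem = s$stem)
    mc <- centrePolygon(modelContour)$polygon
    pat <- PointPattern(s$bundles, s$contour)
    ra <- rigidAlign(s$contour, pat, mc)
    patterns[[k]] <- polarNormalise(ra$pattern, mc, reference)
    maps[[k]] <- kdeIntensity(patterns[[k]], grid, sigma = sigma,
                              correction = config$correction)
    if (npoints(patterns[[k]]) == 0L)
      warning(sprintf("slice %d: empty point pattern, zero map", k))
  }
  global <- averageMaps(maps, minCoverage = config$minCoverage)
  geno <- vapply(slices, function(s) as.character(s$genotype), character(1L))
  slab <- vapply(slices, function(s) as.character(s$slab), character(1L))
  byGenotype <- lapply(unique(geno), function(g)
    factorAverage(maps, geno, g, minCoverage = config$minCoverage))
  names(byGenotype) <- unique(geno)
  bySlab <- lapply(unique(slab), function(sl)
    factorAverage(maps, slab, sl, minCoverage = config$minCoverage))
  names(bySlab) <- unique(slab)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePointsCsv(stats::setNames(patterns,
                                   sprintf("slice_%03d", seq_along(patterns))),
                   file.path(outDir, "normalised_patterns.csv"))
    for (k in seq_along(maps))
      writeIntensityGrid(maps[[k]],
                         file.path(outDir, sprintf("map_slice_%03d.txt", k)))
    writeIntensityGrid(global, file.path(outDir, "map_global.txt"))
    for (g in names(byGenotype))
      writeIntensityGrid(byGenotype[[g]],
                         file.path(outDir, sprintf("map_genotype_%s.txt", g)))
  }
  list(patterns = patterns, maps = maps, global = global,
       byGenotype = byGenotype, bySlab = bySlab)
}
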