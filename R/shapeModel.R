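# Statistical analysis and modelling of aligned contours: PCA of the
# coordinate table, nested ANOVA of component scores, and a per-coordinate
# linear model whose intercepts define the reference (atlas) contour.

# reshape one row of a contour table (x1..x_nv, y1..y_nv) into a Polygon
rowToPolygon <- function(v) {
  n <- length(v) %/% 2L
  Polygon(cbind(v[seq_len(n)], v[n + seq_len(n)]))
}

polygonToRow <- function(p) as.vector(p@coords)

#' Assemble aligned contours into a ContourTable
#'
#' @param polygons list of aligned, centred [Polygon-class] objects sharing
#'   one vertex count (vertices in direct correspondence across contours).
#' @param factors data.frame with one row per polygon and columns
#'   `genotype`, `stem`, `cut`, `face`.
#' @return A [ContourTable-class]: rows are contours, columns the x then y
#'   vertex coordinates.
#' @export
buildContourTable <- function(polygons, factors) {
  nv <- vapply(polygons, nVertices, integer(1))
  if (length(unique(nv)) != 1L) {
    bad <- which(nv != stats::median(nv))
    stop("vertex-count mismatch for contours: ",
         paste(bad, collapse = ", "))
  }
  XY <- t(vapply(polygons, polygonToRow, numeric(2L * nv[1L])))
  colnames(XY) <- c(paste0("x", seq_len(nv[1L])), paste0("y", seq_len(nv[1L])))
  factors <- as.data.frame(factors)
  for (f in c("genotype", "stem", "cut", "face"))
    factors[[f]] <- factor(factors[[f]])
  new("ContourTable", XY = XY, factors = factors)
}

#' Principal component analysis of a contour table
#'
#' Eigendecomposition of the covariance of the coordinate table (columns
#' centred internally, not scaled: all coordinates share mm units). Inertia
#' fractions are eigenvalue shares of the total variance; scores are the
#' centred data projected on the loadings.
#'
#' @param t a [ContourTable-class] with at least two rows.
#' @return A [ContourPCA-class].
#' @export
fitContourPCA <- function(t) {
  X <- t@XY
  if (nrow(X) < 2L) stop("need at least 2 contours")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  tolr <- max(sv$d) * 1e-12
  r <- sum(sv$d > tolr)
  if (r == 0L) stop("rank-0 data: all contours identical")
  ev <- sv$d^2 / (nrow(X) - 1L)
  new("ContourPCA",
      center = ctr,
      loadings = sv$v[, seq_len(r), drop = FALSE],
      scores = Xc %*% sv$v[, seq_len(r), drop = FALSE],
      inertia = ev[seq_len(r)] / sum(ev))
}

#' Synthetic contour at an extreme component score
#'
#' Reconstructs the contour `mean + score * loading` for one principal
#' component, e.g. at the minimum and maximum observed scores to visualise
#' what the component encodes.
#'
#' @param pca a [ContourPCA-class].
#' @param component component index.
#' @param score score value at which to reconstruct.
#' @return A [Polygon-class].
#' @export
syntheticExtremeContour <- function(pca, component, score) {
  if (component < 1L || component > ncol(pca@loadings))
    stop("component out of range")
  rowToPolygon(pca@center + score * pca@loadings[, component])
}

#' Nested analysis of variance of principal component scores
#'
#' For each of the first `nComponents` scores, fits the linear model with
#' fixed genotype, cutting-position and genotype x cut effects and a stem
#' effect nested in genotype. The genotype effect is tested against the
#' stem-within-genotype mean square (honouring the random-stem
#' interpretation); cut, interaction and stem are tested against the
#' residual.
#'
#' @param pca a [ContourPCA-class].
#' @param factors data.frame with columns `genotype`, `stem`, `cut` (rows
#'   matching the score rows); `stem` labels are interpreted within genotype.
#' @param nComponents number of leading components to test (default 5).
#' @return A data.frame with columns `component`, `effect`, `df1`, `df2`,
#'   `statistic`, `p.value`.
#' @export
anovaPcScores <- function(pca, factors, nComponents = 5L) {
  nComponents <- min(nComponents, ncol(pca@scores))
  G <- factor(factors$genotype)
  C <- factor(factors$cut)
  S <- droplevels(interaction(G, factor(factors$stem), sep = "/"))
  if (nlevels(G) < 2L || nlevels(C) < 2L)
    stop("need at least 2 levels for genotype and cut")
  dfS <- nlevels(S) - nlevels(G)
  if (dfS < 1L)
    stop("genotype test undefined: a single stem per genotype")
  out <- vector("list", nComponents)
  for (j in seq_len(nComponents)) {
    d <- data.frame(y = pca@scores[, j], G = G, C = C, S = S)
    an <- stats::anova(stats::lm(y ~ G + C + G:C + S, data = d))
    ms <- an[, "Mean Sq"]
    names(ms) <- rownames(an)
    if (!is.finite(ms[["Residuals"]]) || ms[["Residuals"]] <= 0 ||
        ms[["S"]] <= 0)
      stop("zero-variance scores: F statistics undefined")
    eff <- data.frame(
      component = j,
      effect = c("genotype", "cut", "genotype:cut", "stem"),
      df1 = an[c("G", "C", "G:C", "S"), "Df"],
      df2 = c(an["S", "Df"], rep(an["Residuals", "Df"], 3L)),
      statistic = c(ms[["G"]] / ms[["S"]],
                    ms[["C"]] / ms[["Residuals"]],
                    ms[["G:C"]] / ms[["Residuals"]],
                    ms[["S"]] / ms[["Residuals"]]))
    eff$p.value <- stats::pf(eff$statistic, eff$df1, eff$df2,
                             lower.tail = FALSE)
    out[[j]] <- eff
  }
  do.call(rbind, out)
}

# sum-to-zero design matrix for the contour model; returns the matrix plus
# bookkeeping needed to expand coefficients into full effect vectors
.contourDesign <- function(G, C, S) {
  n <- length(G)
  gl <- levels(G); cl <- levels(C)
  X <- matrix(1, n, 1L)
  colnames(X) <- "mu"
  contrCols <- function(f, prefix) {
    k <- nlevels(f)
    M <- matrix(0, length(f), k - 1L)
    for (m in seq_len(k - 1L)) {
      M[f == levels(f)[m], m] <- 1
      M[f == levels(f)[k], m] <- -1
    }
    colnames(M) <- paste0(prefix, levels(f)[seq_len(k - 1L)])
    M
  }
  if (length(gl) > 1L) X <- cbind(X, contrCols(G, "g_"))
  if (length(cl) > 1L) X <- cbind(X, contrCols(C, "c_"))
  stemIndex <- unique(data.frame(genotype = as.character(G),
                                 stem = as.character(S)))
  stemIndex <- stemIndex[order(stemIndex$genotype, stemIndex$stem), ]
  for (g in gl) {
    st <- stemIndex$stem[stemIndex$genotype == g]
    if (length(st) < 2L) next
    for (m in seq_len(length(st) - 1L)) {
      col <- numeric(length(G))
      col[G == g & S == st[m]] <- 1
      col[G == g & S == st[length(st)]] <- -1
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("s_", g, "/", st[m])
    }
  }
  list(X = X, stemIndex = stemIndex)
}

#' Fit the per-coordinate linear contour model
#'
#' For every coordinate j, fits by least squares the decomposition
#' mu(j) + alpha_G(j) + beta_C(j) + s_S(G)(j) under sum-to-zero constraints
#' (effects sum to zero across genotypes, across cuts, and across stems
#' within each genotype). With this coding the intercept vector mu is the
#' reference average contour. Fitted values plus residuals reproduce the
#' table exactly.
#'
#' @param t a [ContourTable-class]; every (genotype, stem, cut) cell must be
#'   non-empty.
#' @return A [ContourLinearModel-class].
#' @export
fitContourModel <- function(t) {
  G <- droplevels(factor(t@factors$genotype))
  C <- droplevels(factor(t@factors$cut))
  S <- droplevels(factor(t@factors$stem))
  cells <- table(interaction(G, S, drop = TRUE), C)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[bad[, 1L]], colnames(cells)[bad[, 2L]],
               sep = " x ", collapse = "; "))
  }
  des <- .contourDesign(G, C, S)
  X <- des$X
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("rank-deficient design: effects not estimable")
  B <- qr.coef(q, t@XY)
  fitted <- X %*% B
  resid <- t@XY - fitted
  nc <- ncol(t@XY)
  gl <- levels(G); cl <- levels(C)
  expand <- function(prefix, lev) {
    M <- matrix(0, length(lev), nc, dimnames = list(lev, NULL))
    if (length(lev) > 1L) {
      rows <- paste0(prefix, lev[-length(lev)])
      M[-length(lev), ] <- B[rows, , drop = FALSE]
      M[length(lev), ] <- -colSums(B[rows, , drop = FALSE])
    }
    M
  }
  alpha <- expand("g_", gl)
  beta <- expand("c_", cl)
  si <- des$stemIndex
  stemEff <- matrix(0, nrow(si), nc,
                    dimnames = list(paste0(si$genotype, "/", si$stem), NULL))
  for (g in gl) {
    st <- si$stem[si$genotype == g]
    if (length(st) < 2L) next
    rows <- paste0("s_", g, "/", st[-length(st)])
    stemEff[paste0(g, "/", st[-length(st)]), ] <- B[rows, , drop = FALSE]
    stemEff[paste0(g, "/", st[length(st)]), ] <- -colSums(B[rows, , drop = FALSE])
  }
  new("ContourLinearModel",
      mu = as.numeric(B["mu", ]), alpha = alpha, beta = beta,
      stemEffects = stemEff,
      stemIndex = si, residuals = resid, fitted = fitted)
}

#' Reference (atlas) contour of a fitted contour model
#'
#' The intercept vector mu reshaped into a polygon: the average contour used
#' as the target of spatial normalisation.
#'
#' @param m a [ContourLinearModel-class].
#' @return A [Polygon-class].
#' @export
referenceContour <- function(m) rowToPolygon(m@mu)

# cutting positions adjacent to a slab: the cut labels containing the slab
# letter, e.g. slab "D" is bounded by cuts "cd" and "de"; end slabs keep
# their single available cut.
.slabCuts <- function(slab, cutLevels) {
  hit <- grepl(tolower(slab), cutLevels, fixed = TRUE)
  if (!any(hit)) stop("unknown slab level: ", slab)
  cutLevels[hit]
}

#' Predicted contour for chosen factor levels
#'
#' Sums the intercept vector with the requested effect vectors. A slab
#' effect is the mean of the effects of the two cutting positions bounding
#' the slab (end slabs use their single available cut). With no levels
#' requested the reference contour is returned.
#'
#' @param m a [ContourLinearModel-class].
#' @param genotype optional genotype level.
#' @param cut optional cutting-position level (exclusive with `slab`).
#' @param slab optional slab letter (e.g. "A", "D", "G").
#' @param stem optional stem level; requires `genotype`.
#' @return A [Polygon-class].
#' @export
predictContour <- function(m, genotype = NULL, cut = NULL, slab = NULL,
                           stem = NULL) {
  v <- m@mu
  if (!is.null(genotype)) {
    if (!genotype %in% rownames(m@alpha))
      stop("unknown genotype level: ", genotype)
    v <- v + m@alpha[genotype, ]
  }
  if (!is.null(cut) && !is.null(slab))
    stop("give either cut or slab, not both")
  if (!is.null(cut)) {
    if (!cut %in% rownames(m@beta)) stop("unknown cut level: ", cut)
    v <- v + m@beta[cut, ]
  }
  if (!is.null(slab)) {
    cc <- .slabCuts(slab, rownames(m@beta))
    v <- v + colMeans(m@beta[cc, , drop = FALSE])
  }
  if (!is.null(stem)) {
    if (is.null(genotype)) stop("stem effect requires a genotype")
    key <- paste0(genotype, "/", stem)
    if (!key %in% rownames(m@stemEffects))
      stop("unknown stem level: ", key)
    v <- v + m@stemEffects[key, ]
  }
  rowToPolygon(v)
}

#' 3D stem model from predicted contours
#'
#' Stacks the predicted contour of each cutting position (in level order,
#' top of the internode first) for one genotype.
#'
#' @param m a [ContourLinearModel-class].
#' @param genotype genotype level.
#' @return A [StemModel3D-class].
#' @export
buildStem3d <- function(m, genotype) {
  cl <- rownames(m@beta)
  new("StemModel3D",
      contours = lapply(cl, function(cc)
        predictContour(m, genotype = genotype, cut = cc)),
      z = seq_along(cl),
      genotype = as.character(genotype))
}
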