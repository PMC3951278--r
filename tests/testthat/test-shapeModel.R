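# Contour table assembly, PCA, nested ANOVA of scores, and the
# per-coordinate linear contour model.

squareAt <- function(s) Polygon(s * cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))

test_that("buildContourTable assembles coordinates and validates counts", {
  polys <- list(squareAt(1), squareAt(2), squareAt(3))
  fac <- data.frame(genotype = "WT", stem = "s1",
                    cut = c("ab", "bc", "cd"), face = 1)
  tab <- buildContourTable(polys, fac)
  expect_equal(dim(contourMatrix(tab)), c(3L, 8L))
  expect_equal(contourMatrix(tab)[2L, ], 2 * contourMatrix(tab)[1L, ],
               ignore_attr = TRUE)

  ds <- synthContourDataset(stemDesign(), seed = 1)
  tab2 <- buildContourTable(ds$polygons, ds$factors)
  expect_equal(dim(contourMatrix(tab2)), c(196L, 400L))

  bad <- list(squareAt(1), Polygon(cbind(c(0, 1, 1, 0, -1), c(0, 0, 1, 1, 1))))
  expect_error(buildContourTable(bad, fac[1:2, ]), "mismatch")
})

test_that("fitContourPCA decomposes variance correctly", {
  # pure scalings of one shape: one dominant mode
  set.seed(2)
  base <- polygonToRow <- as.vector(vertices(squareAt(1)))
  X <- t(sapply(seq(0.5, 2, length.out = 20),
                function(s) s * base + rnorm(8, 0, 1e-4)))
  tab <- new("ContourTable", XY = X,
             factors = data.frame(genotype = "WT", stem = "s1", cut = "ab",
                                  face = seq_len(20)))
  pca <- fitContourPCA(tab)
  expect_gt(inertia(pca)[1L], 0.99)
  expect_equal(sum(inertia(pca)), 1)

  # completeness: mean + scores %*% t(loadings) reproduces the data
  rec <- sweep(scores(pca) %*% t(loadings(pca)), 2L, pca@center, "+")
  expect_equal(rec, X, tolerance = 1e-9, ignore_attr = TRUE)

  # scores covariance is diagonal
  cv <- crossprod(scores(pca)) / (nrow(X) - 1L)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9 * max(diag(cv)))

  # two orthogonal deformation modes with variances 9 and 1
  set.seed(3)
  n <- 400L
  u1 <- c(1, 0, 0, 0, 0, 0, 0, 0); u2 <- c(0, 0, 0, 0, 0, 1, 0, 0)
  X2 <- matrix(rep(base, n), n, 8L, byrow = TRUE) +
    outer(rnorm(n, 0, 3), u1) + outer(rnorm(n, 0, 1), u2)
  pca2 <- fitContourPCA(new("ContourTable", XY = X2,
                            factors = data.frame(genotype = "WT", stem = "s1",
                                                 cut = "ab",
                                                 face = seq_len(n))))
  expect_equal(inertia(pca2)[1:2], c(0.9, 0.1), tolerance = 0.05)

  same <- new("ContourTable", XY = matrix(rep(base, 3), 3, 8, byrow = TRUE),
              factors = data.frame(genotype = "WT", stem = "s1", cut = "ab",
                                   face = 1:3))
  expect_error(fitContourPCA(same), "rank-0")
})

test_that("syntheticExtremeContour reconstructs along loadings", {
  ds <- synthContourDataset(stemDesign(stemsPerGenotype = 2L), seed = 4)
  tab <- buildContourTable(ds$polygons, ds$factors)
  pca <- fitContourPCA(tab)
  m0 <- syntheticExtremeContour(pca, 1L, 0)
  expect_equal(as.vector(vertices(m0)), as.numeric(pca@center),
               ignore_attr = TRUE)
  # linearity: mean of +s and -s reconstructions equals the mean contour
  s <- max(scores(pca)[, 1L])
  vp <- vertices(syntheticExtremeContour(pca, 1L, s))
  vm <- vertices(syntheticExtremeContour(pca, 1L, -s))
  expect_equal((vp + vm) / 2, vertices(m0), tolerance = 1e-9)
  expect_error(syntheticExtremeContour(pca, 99L, 0), "out of range")
})

test_that("anovaPcScores detects planted effects and rejects degenerate designs", {
  fac <- expand.grid(face = 1:2, cut = paste0("c", 1:4), stem = paste0("s", 1:4),
                     genotype = c("WT", "M"), stringsAsFactors = FALSE)
  n <- nrow(fac)
  mkpca <- function(y) new("ContourPCA", center = 0, inertia = 1,
                           loadings = matrix(1, 1, 1),
                           scores = matrix(y - mean(y), ncol = 1))
  set.seed(9)
  y <- 10 * (fac$genotype == "M") + rnorm(n)
  an <- anovaPcScores(mkpca(y), fac, 1L)
  expect_lt(an$p.value[an$effect == "genotype"], 0.01)
  expect_true(all(an$p.value >= 0 & an$p.value <= 1))

  expect_error(anovaPcScores(mkpca(rep(0, n)), fac, 1L), "zero-variance")
  fac1 <- fac[fac$stem == "s1", ]
  expect_error(anovaPcScores(mkpca(rnorm(nrow(fac1))), fac1, 1L),
               "single stem")
})

test_that("fitContourModel recovers generating effects", {
  # zero noise: exact recovery of every effect vector
  ds <- synthContourDataset(stemDesign(noiseSd = 0), seed = 2)
  tab <- buildContourTable(ds$polygons, ds$factors)
  m <- fitContourModel(tab)
  expect_lt(max(abs(m@mu - ds$truth$mu)), 1e-9)
  expect_lt(max(abs(m@alpha[rownames(ds$truth$alpha), ] - ds$truth$alpha)),
            1e-9)
  expect_lt(max(abs(m@beta[rownames(ds$truth$beta), ] - ds$truth$beta)), 1e-9)
  expect_lt(max(abs(m@stemEffects[rownames(ds$truth$stemEffects), ] -
                      ds$truth$stemEffects)), 1e-9)
  expect_lt(max(abs(m@residuals)), 1e-9)

  # noisy: coefficients recovered within 4 sigma / sqrt(n)
  sigma <- 0.1
  dsn <- synthContourDataset(stemDesign(noiseSd = sigma), seed = 3)
  tabn <- buildContourTable(dsn$polygons, dsn$factors)
  mn <- fitContourModel(tabn)
  expect_lt(max(abs(mn@mu - dsn$truth$mu)), 4 * sigma / sqrt(nrow(tabn@XY)))
  expect_lt(max(abs(mn@alpha[rownames(dsn$truth$alpha), ] - dsn$truth$alpha)),
            4 * sigma / sqrt(nrow(tabn@XY) / 2))

  # fitted + residuals reproduce the table exactly
  expect_equal(mn@fitted + mn@residuals, tabn@XY, tolerance = 1e-12,
               ignore_attr = TRUE)

  # missing cell is named
  keep <- !(tab@factors$genotype == "WT" & tab@factors$stem == "s1" &
              tab@factors$cut == "ab")
  tb <- new("ContourTable", XY = tab@XY[keep, ], factors = tab@factors[keep, ])
  expect_error(fitContourModel(tb), "empty design cell")
})

test_that("referenceContour and predictContour honour the sum-to-zero coding", {
  ds <- synthContourDataset(stemDesign(noiseSd = 0), seed = 5)
  tab <- buildContourTable(ds$polygons, ds$factors)
  m <- fitContourModel(tab)
  ref <- referenceContour(m)
  # balanced zero-noise design: reference = grand mean contour
  expect_equal(as.vector(vertices(ref)), as.numeric(colMeans(tab@XY)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # centred training contours give a centred reference
  expect_lt(max(abs(polygonCentroid(ref))), 1e-6)

  expect_equal(vertices(predictContour(m)), vertices(ref))
  # genotype-only request equals the genotype mean contour at zero noise
  gWT <- colMeans(tab@XY[tab@factors$genotype == "WT", ])
  expect_equal(as.vector(vertices(predictContour(m, genotype = "WT"))),
               as.numeric(gWT), tolerance = 1e-9, ignore_attr = TRUE)

  # additivity: predict(G,C) - predict(G) - predict(C) + reference = 0
  pg <- vertices(predictContour(m, genotype = "M"))
  pc <- vertices(predictContour(m, cut = "cd"))
  pgc <- vertices(predictContour(m, genotype = "M", cut = "cd"))
  expect_lt(max(abs(pgc - pg - pc + vertices(ref))), 1e-9)

  # slab effect = mean of the two adjacent cut effects; end slab uses one
  pd <- vertices(predictContour(m, slab = "D"))
  want <- m@mu + colMeans(m@beta[c("cd", "de"), ])
  expect_equal(as.vector(pd), as.numeric(want), ignore_attr = TRUE)
  pa <- vertices(predictContour(m, slab = "A"))
  expect_equal(as.vector(pa), as.numeric(m@mu + m@beta["ab", ]),
               ignore_attr = TRUE)

  expect_error(predictContour(m, genotype = "XX"), "unknown genotype")
  expect_error(predictContour(m, cut = "zz"), "unknown cut")
})

test_that("buildStem3d stacks ordered per-cut contours with genotype scaling", {
  d <- stemDesign(noiseSd = 0, stemSd = 0, genotypeSize = c(WT = 1, M = 1.1))
  ds <- synthContourDataset(d, seed = 6)
  tab <- buildContourTable(ds$polygons, ds$factors)
  m <- fitContourModel(tab)
  s3 <- buildStem3d(m, "WT")
  expect_equal(length(s3@contours), 7L)
  expect_equal(s3@z, 1:7)
  # zero-noise: every layer equals its generating contour
  for (k in c(1L, 4L, 7L)) {
    gen <- ds$truth$mu + ds$truth$alpha["WT", ] + ds$truth$beta[d$cuts[k], ]
    expect_equal(as.vector(vertices(s3@contours[[k]])), as.numeric(gen),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # +10% genotype size: areas scale by about 1.21 layer by layer
  sM <- buildStem3d(m, "M")
  ratio <- vapply(1:7, function(k)
    polygonArea(sM@contours[[k]]) / polygonArea(s3@contours[[k]]), numeric(1L))
  expect_equal(ratio, rep(1.21, 7L), tolerance = 0.02)
})
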