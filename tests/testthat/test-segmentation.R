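test_that("superpixel count scales with area over spacing squared", {
  set.seed(20)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  sp <- computeSuperpixels(img, spacing = 32, seed = 1, pixelSize = 1)
  expect_gte(nSuperpixels(sp), 128)
  expect_lte(nSuperpixels(sp), 384)
  # every pixel assigned, labels dense in 1..K
  expect_true(all(sort(unique(as.vector(labelImage(sp)))) ==
                    seq_len(nSuperpixels(sp))))
})

test_that("superpixel segmentation is deterministic for a fixed seed", {
  set.seed(21)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  a <- computeSuperpixels(img, spacing = 16, seed = 4)
  b <- computeSuperpixels(img, spacing = 16, seed = 4)
  expect_identical(labelImage(a), labelImage(b))
})

test_that("uniform images tile into a near-regular lattice", {
  img <- array(0.5, c(128, 128, 3))
  sp <- computeSuperpixels(img, spacing = 16, seed = 2)
  lab <- labelImage(sp)
  cy <- tapply(row(lab), lab, mean)
  cx <- tapply(col(lab), lab, mean)
  # centroid nearest-neighbour spacing has low dispersion
  d <- as.matrix(stats::dist(cbind(cy, cx)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(stats::sd(nn) / mean(nn), 0.25)
})

test_that("every superpixel is 4-connected", {
  set.seed(22)
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  sp <- computeSuperpixels(img, spacing = 14, seed = 3)
  lab <- labelImage(sp)
  frag <- mppscore:::.cc_label4(lab, background = -1L)
  # one fragment per superpixel label
  expect_equal(max(frag), nSuperpixels(sp))
})

test_that("spacing larger than the image collapses to one superpixel", {
  img <- array(0.4, c(32, 32, 3))
  expect_warning(sp <- computeSuperpixels(img, spacing = 64, seed = 1),
                 "single superpixel")
  expect_equal(nSuperpixels(sp), 1L)
})

test_that("scribble training covers the vocabulary or fails loudly", {
  fx <- histologyFixture(R = 100, resolution = 0.5, seed = 6)
  spmap <- computeSuperpixels(fx$image, spacing = 25, seed = 2,
                              pixelSize = fx$pixelSize)
  feats <- superpixelFeatures(fx$image, spmap)
  expect_error(trainTissueClassifier(feats, list(), spmap), "empty scribble")
  off <- rectScribble(fx$n, 1:4, 1:4, "muscle")
  off$mask[] <- FALSE
  expect_error(
    trainTissueClassifier(feats, c(fx$scribbles, list(off)), spmap),
    "no superpixel overlaps")
  # one-class scribbles: everything is predicted as that class
  clf1 <- trainTissueClassifier(feats, fx$scribbles[1], spmap)
  pred <- mppscore:::predictSuperpixels(clf1, feats)
  expect_true(all(pred == "tumor"))
})

test_that("well-separated classes are classified almost perfectly", {
  fx <- histologyFixture(R = 100, resolution = 0.5, seed = 7)
  spmap <- computeSuperpixels(fx$image, spacing = 25, seed = 2,
                              pixelSize = fx$pixelSize)
  feats <- superpixelFeatures(fx$image, spmap)
  clf <- trainTissueClassifier(feats, fx$scribbles, spmap)
  pred <- mppscore:::predictSuperpixels(clf, feats)
  # held-out evaluation: majority ground-truth class per superpixel,
  # restricted to superpixels not overlapping any scribble
  lab <- labelImage(fx$truth)
  spl <- labelImage(spmap)
  truthName <- ifelse(lab == 1L, "tumor", "background")
  maj <- tapply(truthName, spl, function(v)
    names(sort(table(v), decreasing = TRUE))[1])
  inScribble <- Reduce(`|`, lapply(fx$scribbles, `[[`, "mask"))
  touched <- unique(spl[inScribble])
  held <- setdiff(seq_len(nSuperpixels(spmap)), touched)
  acc <- mean(pred[held] == maj[held])
  expect_gte(acc, 0.95)
  # schema mismatch is refused
  feats2 <- feats
  feats2$schema <- feats2$schema[-1]
  expect_error(mppscore:::predictSuperpixels(clf, feats2), "schema")
})

test_that("same-class superpixels merge into one annotation per component", {
  # block checkerboard of two colors at superpixel scale
  n <- 120; cellpx <- 30
  cells <- outer(ceiling(seq_len(n) / cellpx), ceiling(seq_len(n) / cellpx),
                 function(i, j) (i + j) %% 2)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- ifelse(cells == 1, 0.85, 0.2)
  spmap <- computeSuperpixels(img, spacing = cellpx / 2, compactness = 10,
                              seed = 3, preBlur = 0)
  feats <- superpixelFeatures(img, spmap)
  scr <- list(list(mask = cells == 1, class = "light"),
              list(mask = cells == 0, class = "dark"))
  clf <- trainTissueClassifier(feats, scr, spmap)
  ann <- classifyAndMerge(spmap, clf, feats, background = character())
  # 4-connectivity: diagonal same-color cells stay separate, so the
  # annotation count per color equals the cell count per color
  cellsPerColor <- (n / cellpx)^2 / 2
  cl <- classLabels(ann)
  expect_equal(sum(cl == "light"), cellsPerColor)
  expect_equal(sum(cl == "dark"), cellsPerColor)
})

test_that("single-class prediction yields one annotation covering the ROI", {
  img <- array(0.6, c(60, 60, 3))
  img <- img + array(rnorm(length(img), sd = 0.01), dim(img))
  spmap <- computeSuperpixels(img, spacing = 12, seed = 5)
  feats <- superpixelFeatures(img, spmap)
  clf <- trainTissueClassifier(feats,
                               list(rectScribble(60, 10:20, 10:20, "tumor")),
                               spmap)
  ann <- classifyAndMerge(spmap, clf, feats)
  expect_equal(length(ann), 1L)
  m <- measurePolygon(regions(ann)[[1]])
  expect_gt(m$area, 0.95 * 60 * 60)
})

test_that("stromal ratio from annotations matches areas and handles edge cases", {
  sq <- function(x0, side, cls)
    PolygonRegion(cbind(c(x0, x0 + side, x0 + side, x0),
                        c(0, 0, side, side)), classLabel = cls)
  ann <- AnnotationSet(list(sq(0, 10, "tumor"), sq(20, 8, "fibrous_stroma"),
                            sq(40, 6, "lymphocytic_stroma")))
  r <- stromaTumorRatio(ann)
  expect_equal(r$percent_stroma, 100 * (64 + 36) / (64 + 36 + 100))
  onlyT <- AnnotationSet(list(sq(0, 10, "tumor")))
  expect_equal(stromaTumorRatio(onlyT)$percent_stroma, 0)
  noT <- AnnotationSet(list(sq(0, 10, "fibrous_stroma")))
  expect_error(stromaTumorRatio(noT), "tumor")
})

test_that("segment-measure-score recovers the analytic MPP of the tumor mask", {
  fx <- histologyFixture(R = 200, eps = 0.15, m = 6, resolution = 0.5,
                         seed = 3)
  res <- segmentAndScore(fx$image, fx$scribbles, spacing = 50, seed = 5,
                         pixelSize = fx$pixelSize)
  expect_lt(abs(mppValue(res$score) - fx$analytic$mpp), 0.15)
})

test_that("recovery error shrinks as superpixel spacing shrinks", {
  # boundary wavelength comparable to the superpixel size so the spacing
  # dependence has signal
  fx <- histologyFixture(R = 200, eps = 0.12, m = 24, resolution = 0.5,
                         seed = 3)
  prof <- mppSpacingProfile(fx$image, fx$scribbles, spacing = 50, seed = 5,
                            pixelSize = fx$pixelSize)
  expect_equal(nrow(prof), 3)
  err <- abs(prof$mpp - fx$analytic$mpp)
  expect_lt(err[prof$spacing == 25], err[prof$spacing == 100])
})

test_that("stroma carved into the tumor is recovered within 5 points", {
  wd <- makeWavyDisk(R = 180, eps = 0.1, m = 5, resolution = 0.5, pad = 15)
  hi <- makeHistologyImage(wd$mask, stromaFraction = 0.4, noiseSd = 0.04,
                           seed = 4)
  lab <- labelImage(hi$truth)
  n <- nrow(lab)
  truthPct <- 100 * sum(lab == 2L) / sum(lab > 0L)
  # scribbles from ground truth: a pure patch per class
  pickPatch <- function(target) {
    w <- which(lab == target, arr.ind = TRUE)
    ctr <- w[which.min(abs(w[, 1] - stats::median(w[, 1])) +
                         abs(w[, 2] - stats::median(w[, 2]))), ]
    m <- matrix(FALSE, n, n)
    m[max(1, ctr[1] - 4):min(n, ctr[1] + 4),
      max(1, ctr[2] - 4):min(n, ctr[2] + 4)] <- TRUE
    m
  }
  scr <- list(list(mask = pickPatch(1L), class = "tumor"),
              list(mask = pickPatch(2L), class = "fibrous_stroma"),
              rectScribble(n, 1:12, 1:12, "background"))
  res <- segmentAndScore(hi$image, scr, spacing = 25, seed = 5, pixelSize = 2)
  got <- stromaTumorRatio(res$annotations)$percent_stroma
  expect_lt(abs(got - truthPct), 5)
})
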