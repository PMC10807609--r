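test_that("polygon measurement matches hand geometry", {
  sq <- PolygonRegion(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  m <- measurePolygon(sq)
  expect_equal(m$perimeter, 4)
  expect_equal(m$area, 1)
  expect_equal(m$n_rings, 1L)

  # explicit closing vertex is tolerated
  sq2 <- PolygonRegion(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  expect_equal(measurePolygon(sq2)$perimeter, 4)

  # regular 4096-gon inscribed in the unit circle converges to 2*pi / pi
  m <- measurePolygon(circlePolygon(1, 4096))
  expect_lt(abs(m$perimeter / (2 * pi) - 1), 1e-4)
  expect_lt(abs(m$area / pi - 1), 1e-4)

  # unit square with centred half-side hole: hole boundary counts toward
  # perimeter, hole area is subtracted
  hole <- cbind(c(0.25, 0.75, 0.75, 0.25), c(0.25, 0.25, 0.75, 0.75))
  mh <- measurePolygon(PolygonRegion(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                                     list(hole)))
  expect_equal(mh$area, 0.75)
  expect_equal(mh$perimeter, 6)
  expect_equal(mh$n_rings, 2L)
})

test_that("degenerate polygons are rejected", {
  expect_error(PolygonRegion(cbind(c(0, 1), c(0, 0))), "3 distinct")
  expect_error(PolygonRegion(cbind(c(0, 1, 2, 1), c(0, 0, 0, 0))),
               "positive area")
  big_hole <- PolygonRegion(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                            list(cbind(c(-1, 2, 2, -1), c(-1, -1, 2, 2))))
  expect_error(measurePolygon(big_hole), "hole")
})

test_that("region extraction from raster masks is accurate and ordered", {
  empty <- LabeledMask(matrix(0L, 30, 30))
  expect_identical(extractRegions(empty, 1L), list())

  # disk of radius 100 px: perimeter and area within 1 % of the circle
  rs <- extractRegions(diskMask(100), 1L)
  expect_length(rs, 1)
  m <- measurePolygon(rs[[1]])
  expect_lt(abs(m$perimeter / (2 * pi * 100) - 1), 0.01)
  expect_lt(abs(m$area / (pi * 100^2) - 1), 0.01)

  # two disjoint filled squares -> two regions, ordered by area
  mm <- matrix(0L, 60, 60)
  mm[10:30, 10:30] <- 1L   # 21x21
  mm[40:50, 40:50] <- 1L   # 11x11
  rs2 <- extractRegions(LabeledMask(mm), 1L)
  expect_length(rs2, 2)
  a <- vapply(rs2, function(r) measurePolygon(r)$area, numeric(1))
  expect_true(a[1] > a[2])

  # annulus: one region with one hole
  ann <- matrix(0L, 120, 120)
  xs <- (1:120) - 60.5
  d2 <- outer(xs, xs, function(p, q) p^2 + q^2)
  ann[d2 <= 50^2] <- 1L
  ann[d2 <= 20^2] <- 0L
  rs3 <- extractRegions(LabeledMask(ann), 1L)
  expect_length(rs3, 1)
  expect_length(rs3[[1]]@holes, 1)
  m3 <- measurePolygon(rs3[[1]])
  expect_lt(abs(m3$perimeter / (2 * pi * 70) - 1), 0.01)
  expect_lt(abs(m3$area / (pi * (50^2 - 20^2)) - 1), 0.01)

  # deterministic: identical input gives byte-identical output
  expect_identical(extractRegions(diskMask(40), 1L),
                   extractRegions(diskMask(40), 1L))
})

test_that("measureClass filters small regions and resolves class names", {
  mm <- labelImage(diskMask(30, n = 100))
  mm[5:9, 5:9] <- 1L  # 25-px speck
  msk <- LabeledMask(mm, labelNames = c("1" = "tumor"))
  all_regions <- measureClass(msk, "tumor", minArea = 0)
  expect_equal(nrow(all_regions), 2)
  filtered <- measureClass(msk, "tumor", minArea = 100)
  expect_equal(nrow(filtered), 1)
  expect_error(measureClass(msk, "stroma"), "unknown class")
})

test_that("measurements are unit-consistent across raster resolution", {
  lo <- makeWavyDisk(R = 80, eps = 0.1, m = 5, resolution = 0.5)
  hi <- makeWavyDisk(R = 80, eps = 0.1, m = 5, resolution = 1)
  mlo <- measureClass(lo$mask, "tumor")
  mhi <- measureClass(hi$mask, "tumor")
  expect_lt(abs(mlo$perimeter / mhi$perimeter - 1), 0.01)
  expect_lt(abs(mlo$area / mhi$area - 1), 0.01)
})

test_that("raster error decays monotonically with resolution", {
  an <- wavyDiskAnalytic(120, 0.15, 6)
  errP <- errA <- numeric(0)
  for (res in c(0.5, 1, 2)) {
    wd <- makeWavyDisk(R = 120, eps = 0.15, m = 6, resolution = res)
    m <- measureClass(wd$mask, "tumor")
    errP <- c(errP, abs(m$perimeter - an$perimeter) / an$perimeter)
    errA <- c(errA, abs(m$area - an$area) / an$area)
  }
  expect_true(all(diff(errP) < 0))
  # area converges faster than perimeter; at the 1e-4 level individual
  # steps are raster-noise-dominated, so assert decay across the range
  expect_lt(errA[3], errA[1])
  expect_true(all(errA < 1e-3))
})

test_that("hole-free regions respect the isoperimetric bound", {
  specs <- list(c(60, 0, 0), c(80, 0.1, 4), c(90, 0.2, 7), c(70, 0.3, 3))
  for (s in specs) {
    wd <- makeWavyDisk(R = s[1], eps = s[2], m = s[3], resolution = 1)
    m <- measureClass(wd$mask, "tumor")
    hole_free <- m[m$n_rings == 1, ]
    expect_true(all(hole_free$perimeter^2 >=
                      4 * pi * hole_free$area * (1 - 1e-3)))
  }
})

test_that("rasterizing a polygon and re-extracting reproduces it within 1%", {
  poly <- wavyPolygon(100, 0.15, 5, centre = c(140, 140))
  ref <- measurePolygon(poly)
  msk <- rasterizePolygon(poly, pixelSize = 0.5)
  m <- measureClass(msk, "tumor")
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$perimeter / ref$perimeter - 1), 0.01)
  expect_lt(abs(m$area / ref$area - 1), 0.01)
})

test_that("measurement tables round-trip through CSV", {
  m <- measureClass(diskMask(30), "tumor")
  path <- tempfile(fileext = ".csv")
  writeMeasurements(m, "img1", "tumor", path)
  back <- utils::read.csv(path)
  expect_equal(back$perimeter_um, m$perimeter)
  expect_equal(back$area_um2, m$area)
  expect_equal(back$image_id[1], "img1")
})
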