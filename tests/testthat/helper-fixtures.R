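# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures on disk.

# Binary disk mask of radius R pixels centred in an n x n grid.
diskMask <- function(R, n = ceiling(2 * R) + 20, pixelSize = 1) {
  ctr <- n / 2
  xs <- seq_len(n) - 0.5
  d2 <- outer(xs - ctr, xs - ctr, function(a, b) a^2 + b^2)
  LabeledMask(matrix(as.integer(d2 <= R^2), n, n), pixelSize = pixelSize,
              labelNames = c("1" = "tumor"))
}

# Grid of k disjoint circles of radius r px, one per cell of size `cell`.
circlesGridMask <- function(k, r = 30, cell = 70, pixelSize = 1) {
  side <- ceiling(sqrt(k))
  n <- side * cell + 20
  m <- matrix(0L, n, n)
  xs <- seq_len(n) - 0.5
  placed <- 0
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (placed >= k) break
      cy <- 10 + (i - 0.5) * cell
      cx <- 10 + (j - 0.5) * cell
      d2 <- outer((xs - cy)^2, (xs - cx)^2, `+`)
      m[d2 <= r^2] <- 1L
      placed <- placed + 1
    }
  }
  LabeledMask(m, pixelSize = pixelSize, labelNames = c("1" = "tumor"))
}

# Rectangular scribble covering rows x cols of an n x n image.
rectScribble <- function(n, rows, cols, class) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  list(mask = m, class = class)
}

# Closed regular polygon approximating a circle of radius R (um).
circlePolygon <- function(R = 1, nv = 4096, centre = c(0, 0),
                          class = "tumor") {
  th <- 2 * pi * (0:(nv - 1)) / nv
  PolygonRegion(cbind(centre[1] + R * cos(th), centre[2] + R * sin(th)),
                classLabel = class)
}

# Wavy-disk boundary as a polygon (dense angular sampling).
wavyPolygon <- function(R, eps, m, nv = 4096, centre = c(0, 0)) {
  th <- 2 * pi * (0:(nv - 1)) / nv
  r <- R * (1 + eps * sin(m * th))
  PolygonRegion(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)),
                classLabel = "tumor")
}

# Histology fixture: wavy-disk tumor rendered to RGB with scribbles in
# guaranteed-pure areas. Returns image, truth mask, scribbles, analytic.
histologyFixture <- function(R = 200, eps = 0.15, m = 6, resolution = 0.5,
                             noiseSd = 0.04, seed = 3) {
  wd <- makeWavyDisk(R = R, eps = eps, m = m, resolution = resolution,
                     pad = 15)
  hi <- makeHistologyImage(wd$mask, noiseSd = noiseSd, seed = seed)
  n <- nrow(labelImage(hi$truth))
  ctr <- round(n / 2)
  half <- round(R * (1 - eps) * resolution * 0.3)
  scribbles <- list(
    rectScribble(n, (ctr - half):(ctr + half), (ctr - half):(ctr + half),
                 "tumor"),
    rectScribble(n, 1:15, 1:15, "background"),
    rectScribble(n, (n - 14):n, (n - 14):n, "background"))
  # second scribble entry merged by class during training
  list(image = hi$image, truth = hi$truth, scribbles = scribbles,
       analytic = wd$analytic, pixelSize = 1 / resolution, n = n)
}

# Empirical AUC by mid-ranks (independent of pROC), for DeLong oracles.
empiricalAUC <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
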