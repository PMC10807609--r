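# Internal geometry / numeric helpers.

# Drop a repeated closing vertex and consecutive duplicates.
dedupeRing <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) > 1 && all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) > 1) {
    d <- rowSums(abs(diff(xy)))
    keep <- c(TRUE, d > 1e-12)
    xy <- xy[keep, , drop = FALSE]
  }
  xy
}

# Signed shoelace area of an (implicitly closed) ring. Sign depends on
# orientation; callers use abs() for physical area.
shoelace <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

ringPerimeter <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2) return(0)
  j <- c(2:n, 1)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

# Even-odd ray-casting point-in-polygon test (single point, one ring).
pointInRing <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  crosses <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crosses) %% 2L == 1L
}

# Separable Gaussian smoothing of a numeric matrix with replicated-edge
# padding. sigma in pixels; sigma <= 0 returns the input untouched.
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- stats::dnorm(seq(-k, k), sd = sigma)
  g <- g / sum(g)
  pad <- function(v) c(rep(v[1], k), v, rep(v[length(v)], k))
  smooth1 <- function(mat) {
    apply(mat, 2, function(col) {
      f <- stats::filter(pad(col), g, sides = 2)
      as.numeric(f[(k + 1):(k + length(col))])
    })
  }
  t(smooth1(t(smooth1(m))))
}

# Smoothing bandwidth (pixels) for sub-pixel contour tracing: 1.5 px at
# 1 px/um, scaled with the square root of the resolution so both the
# grid-roughness and the physical smoothing bias vanish as resolution grows.
autoSigma <- function(pixelSize) {
  max(0.75, 1.5 * sqrt(1 / pixelSize))
}

# Sample event times from a piecewise-constant hazard with break points
# `knots` (increasing) and hazards `h` (length(knots) + 1). Vectorized
# inverse-transform; returns Inf where the total hazard is 0.
rPiecewiseExp <- function(n, knots, h, u = stats::runif(n)) {
  stopifnot(length(h) == length(knots) + 1)
  target <- -log(u)
  lo <- c(0, knots)
  hi <- c(knots, Inf)
  cum <- c(0, cumsum(h[-length(h)] * diff(lo)))
  t <- rep(Inf, n)
  for (i in seq_along(h)) {
    idx <- target >= cum[i] &
      (if (i < length(h)) target < cum[i + 1] else TRUE)
    if (any(idx) && h[i] > 0)
      t[idx] <- lo[i] + (target[idx] - cum[i]) / h[i]
    else if (any(idx) && h[i] == 0 && i < length(h))
      t[idx] <- NA  # mass passes through a zero-hazard piece
  }
  # redistribute NA (zero-hazard middle piece): survival flat there, so the
  # event happens in a later piece; handle by recursion on the remainder
  if (anyNA(t)) {
    bad <- which(is.na(t))
    for (i in bad) {
      j <- which(target[i] >= cum)
      j <- max(j)
      while (j <= length(h) && h[j] == 0) j <- j + 1
      t[i] <- if (j > length(h)) Inf else lo[j]
    }
  }
  t
}

# Convert survival anchors S(24), S(60) into piecewise-constant hazards on
# [0,24), [24,60), [60,Inf); the tail reuses the middle-piece hazard.
anchorsToHazards <- function(s24, s60, knots = c(24, 60)) {
  if (s60 > s24 + 1e-12) stop("survival anchors must be non-increasing")
  h1 <- -log(s24) / knots[1]
  h2 <- (-log(s60) + log(s24)) / (knots[2] - knots[1])
  c(h1, h2, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
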