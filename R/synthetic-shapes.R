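#' Analytic perimeter of a wavy disk
#'
#' The wavy disk has polar boundary r(theta) = R * (1 + eps * sin(m*theta)),
#' a simple closed curve for 0 <= eps < 1.  Its perimeter is computed by
#' adaptive quadrature of sqrt(r^2 + r'^2) (relative tolerance 1e-8); its
#' area has the closed form pi * R^2 * (1 + eps^2/2) for m >= 1 (and
#' pi * R^2 for m = 0).
#'
#' @param R base radius, micrometres.
#' @param eps perturbation amplitude, 0 <= eps < 1.
#' @param m integer harmonic count >= 0.
#' @return list with \code{perimeter}, \code{area}, \code{mpp} (analytic).
#' @examples
#' wavyDiskAnalytic(500, 0, 0)$mpp   # circle -> 0
#' @export
wavyDiskAnalytic <- function(R, eps, m) {
  checkWavySpec(R, eps, m)
  if (eps == 0 || m == 0) {
    P <- 2 * pi * R
    A <- pi * R^2
  } else {
    P <- stats::integrate(function(th) {
      r <- R * (1 + eps * sin(m * th))
      rp <- R * eps * m * cos(m * th)
      sqrt(r^2 + rp^2)
    }, 0, 2 * pi, rel.tol = 1e-8, subdivisions = 500L)$value
    A <- pi * R^2 * (1 + eps^2 / 2)
  }
  list(perimeter = P, area = A, mpp = mppScore(P, A))
}

checkWavySpec <- function(R, eps, m) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(eps) || eps < 0 || eps >= 1)
    stop("eps must lie in [0, 1) for a simple boundary")
  if (m < 0 || m != round(m)) stop("m must be a non-negative integer")
  invisible(TRUE)
}

#' Rasterize a wavy disk with its analytic measurement
#'
#' The oracle family for the compactness scores: a disk whose boundary
#' radius is modulated by a single sinusoidal harmonic, emulating tumor
#' fronts from compact (eps = 0) to strongly undulating.  The mask is
#' produced by exact point classification of pixel centres; the analytic
#' perimeter/area come from \code{\link{wavyDiskAnalytic}}.
#'
#' @inheritParams wavyDiskAnalytic
#' @param resolution pixels per micrometre of the raster.
#' @param pad background margin around the shape, pixels.
#' @param classLabel class name stored in the mask (default "tumor").
#' @return list with \code{mask} (a \linkS4class{LabeledMask},
#'   \code{pixelSize = 1/resolution}) and \code{analytic} (see
#'   \code{\link{wavyDiskAnalytic}}).
#' @examples
#' wd <- makeWavyDisk(R = 100, eps = 0.1, m = 6, resolution = 0.5)
#' wd$analytic$mpp
#' @export
makeWavyDisk <- function(R, eps = 0, m = 0, resolution = 1, pad = 10,
                         classLabel = "tumor") {
  checkWavySpec(R, eps, m)
  ps <- 1 / resolution
  rmax <- R * (1 + eps)
  n <- as.integer(ceiling(2 * rmax * resolution) + 2 * pad)
  ctr <- n / 2 * ps
  xs <- (seq_len(n) - 0.5) * ps
  dx <- matrix(xs - ctr, n, n, byrow = TRUE)   # columns are x
  dy <- matrix(xs - ctr, n, n)                 # rows are y
  th <- atan2(dy, dx)
  inside <- dx^2 + dy^2 <= (R * (1 + eps * sin(m * th)))^2
  mask <- LabeledMask(matrix(as.integer(inside), n, n), pixelSize = ps,
                      labelNames = stats::setNames(classLabel, "1"))
  list(mask = mask, analytic = wavyDiskAnalytic(R, eps, m))
}

#' Wavy main mass plus disjoint satellite islands
#'
#' Emulates the discontinuous infiltration pattern: scattered tumor-cell
#' islands around a main mass, each at least \code{minGap} micrometres
#' (default 1 mm, the defining distance for the discontinuous pattern)
#' away from the main mass.  Satellites are circles placed by rejection
#' sampling; analytic totals are the sums of the component measurements,
#' so the MPP of the totals always exceeds the MPP of the main mass alone.
#'
#' @inheritParams makeWavyDisk
#' @param nSatellites number of satellite islands (>= 0).
#' @param satelliteRadius satellite radius, micrometres.
#' @param minGap minimum boundary gap between each satellite and the main
#'   mass, micrometres.
#' @param canvas canvas edge length, micrometres; defaults to a square
#'   large enough to hold the main mass plus the gap annulus.
#' @param seed integer seed for satellite placement.
#' @param maxTries rejection-sampling budget per satellite.
#' @return list with \code{mask} and \code{analytic} totals
#'   (\code{perimeter}, \code{area}, \code{mpp}, \code{n_regions}).
#' @export
makeSatelliteMask <- function(R, eps = 0, m = 0, nSatellites = 0,
                              satelliteRadius = R / 5, minGap = 1000,
                              resolution = 1, canvas = NULL, seed = 1,
                              maxTries = 200L, classLabel = "tumor") {
  checkWavySpec(R, eps, m)
  if (nSatellites < 0 || nSatellites != round(nSatellites))
    stop("nSatellites must be a non-negative integer")
  ps <- 1 / resolution
  rmax <- R * (1 + eps)
  if (is.null(canvas))
    canvas <- 2 * (rmax + minGap + 4 * satelliteRadius) + 20 * ps
  n <- as.integer(ceiling(canvas * resolution))
  ctr <- canvas / 2
  xs <- (seq_len(n) - 0.5) * ps
  dx <- matrix(xs - ctr, n, n, byrow = TRUE)
  dy <- matrix(xs - ctr, n, n)
  th <- atan2(dy, dx)
  inside <- dx^2 + dy^2 <= (R * (1 + eps * sin(m * th)))^2
  main <- wavyDiskAnalytic(R, eps, m)

  centers <- matrix(numeric(0), 0, 2)
  if (nSatellites > 0) {
    set.seed(as.integer(seed))
    rIn <- rmax + minGap + satelliteRadius
    rOut <- canvas / 2 - satelliteRadius - 2 * ps
    if (rOut <= rIn)
      stop("capacity error: canvas too small for the requested satellite gap")
    for (k in seq_len(nSatellites)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        rr <- sqrt(stats::runif(1, rIn^2, rOut^2))
        aa <- stats::runif(1, 0, 2 * pi)
        cx <- ctr + rr * cos(aa); cy <- ctr + rr * sin(aa)
        if (nrow(centers)) {
          dmin <- min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2))
          if (dmin < 2 * satelliteRadius + 2 * ps) next
        }
        centers <- rbind(centers, c(cx, cy))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("capacity error: could not place all satellites; enlarge the canvas")
    }
    for (k in seq_len(nrow(centers)))
      inside <- inside |
        ((dx - (centers[k, 1] - ctr))^2 + (dy - (centers[k, 2] - ctr))^2 <=
           satelliteRadius^2)
  }
  mask <- LabeledMask(matrix(as.integer(inside), n, n), pixelSize = ps,
                      labelNames = stats::setNames(classLabel, "1"))
  P <- main$perimeter + nSatellites * 2 * pi * satelliteRadius
  A <- main$area + nSatellites * pi * satelliteRadius^2
  list(mask = mask,
       analytic = list(perimeter = P, area = A, mpp = mppScore(P, A),
                       n_regions = 1L + as.integer(nSatellites)),
       centers = centers)
}

#' Default H&E-like class palette
#'
#' Base RGB colors (0..1) for the synthetic histology renderer.
#'
#' @return named list of length-3 RGB vectors.
#' @export
defaultPalette <- function() {
  list(tumor = c(0.45, 0.28, 0.58),
       fibrous_stroma = c(0.93, 0.69, 0.80),
       lymphocytic_stroma = c(0.32, 0.30, 0.62),
       muscle = c(0.85, 0.45, 0.50),
       background = c(0.96, 0.94, 0.96),
       other = c(0.75, 0.75, 0.78))
}

#' Render a labeled mask as a synthetic histology-like RGB image
#'
#' Each class is painted in its base color, Gaussian pixel noise and a
#' smooth multiplicative illumination field are added, and (optionally) a
#' fraction of the tumor compartment is converted into fibrous stroma by
#' thresholding a smoothed noise field, so the ground-truth stromal ratio
#' of the returned mask equals \code{stromaFraction} up to rasterization.
#'
#' @param mask a \linkS4class{LabeledMask} whose label names are covered by
#'   \code{palette} (label 0 renders as "background").
#' @param palette named list of RGB triplets, see
#'   \code{\link{defaultPalette}}.
#' @param noiseSd per-pixel Gaussian noise SD on each channel (0..1 scale).
#' @param illumAmp amplitude of the smooth illumination field (fraction).
#' @param stromaFraction target stroma / (stroma + tumor) area fraction to
#'   carve out of the tumor compartment (0 disables).
#' @param stromaScale characteristic width of the carved stroma bands,
#'   micrometres (stromal septa are tens to hundreds of micrometres wide).
#' @param seed integer seed.
#' @return list with \code{image} (h x w x 3 array in [0, 1]) and
#'   \code{truth} (the possibly stroma-augmented \linkS4class{LabeledMask}).
#' @export
makeHistologyImage <- function(mask, palette = defaultPalette(),
                               noiseSd = 0.05, illumAmp = 0.05,
                               stromaFraction = 0, stromaScale = 150,
                               seed = 1) {
  stopifnot(is(mask, "LabeledMask"))
  set.seed(as.integer(seed))
  lab <- mask@labels
  nmap <- mask@labelNames
  classOf <- function(v) {
    if (v == 0L) return("background")
    nmap[[as.character(v)]] %||% stop(sprintf("unknown class for label %d", v))
  }
  if (stromaFraction > 0) {
    tumorLabs <- as.integer(names(nmap)[nmap == "tumor"])
    if (!length(tumorLabs)) stop("unknown class in mask: no 'tumor' label to carve stroma from")
    tpix <- lab %in% tumorLabs
    field <- gaussianSmooth(matrix(stats::rnorm(length(lab)), nrow(lab)),
                            sigma = max(2, stromaScale / (2 * mask@pixelSize)))
    cut <- stats::quantile(field[tpix], probs = stromaFraction, type = 7)
    newLab <- max(c(0L, as.integer(names(nmap)))) + 1L
    lab[tpix & field <= cut] <- newLab
    nmap <- c(nmap, stats::setNames("fibrous_stroma", as.character(newLab)))
  }
  vals <- sort(unique(as.vector(lab)))
  h <- nrow(lab); w <- ncol(lab)
  img <- array(0, c(h, w, 3))
  for (v in vals) {
    cls <- classOf(v)
    col <- palette[[cls]]
    if (is.null(col)) stop(sprintf("unknown class '%s' not in palette", cls))
    sel <- lab == v
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- col[ch]
      img[, , ch] <- plane
    }
  }
  if (illumAmp > 0) {
    gx <- matrix(seq(0, 2 * pi, length.out = w), h, w, byrow = TRUE)
    gy <- matrix(seq(0, 2 * pi, length.out = h), h, w)
    illum <- 1 + illumAmp * 0.5 * (sin(gx) + cos(gy))
    for (ch in 1:3) img[, , ch] <- img[, , ch] * illum
  }
  if (noiseSd > 0)
    img <- img + array(stats::rnorm(length(img), sd = noiseSd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img,
       truth = LabeledMask(lab, pixelSize = mask@pixelSize, labelNames = nmap))
}
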