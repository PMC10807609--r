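#' Measure perimeter and area of a polygonal region
#'
#' Area is the shoelace area of the outer ring minus the summed areas of the
#' holes; perimeter is the edge-length sum of the outer ring plus all hole
#' rings.  Hole boundaries count towards the perimeter because a
#' stroma-filled cavity inside a tumor compartment is tumor/host interface,
#' which is exactly what the compactness scores are meant to see.
#'
#' @param region a \linkS4class{PolygonRegion}.
#' @return one-row data.frame with columns \code{perimeter}, \code{area},
#'   \code{n_rings} (micrometres and square micrometres when the region is
#'   in physical coordinates).
#' @examples
#' sq <- PolygonRegion(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' measurePolygon(sq)  # P = 4, A = 1
#' @export
measurePolygon <- function(region) {
  stopifnot(is(region, "PolygonRegion"))
  outer <- dedupeRing(region@outer)
  if (nrow(outer) < 3)
    stop("invalid geometry: outer ring has fewer than 3 distinct vertices")
  aOut <- abs(shoelace(outer))
  if (aOut <= 0)
    stop("invalid geometry: outer ring encloses no area")
  holes <- lapply(region@holes, dedupeRing)
  for (h in holes)
    if (nrow(h) < 3)
      stop("invalid geometry: hole ring has fewer than 3 distinct vertices")
  aHoles <- sum(vapply(holes, function(h) abs(shoelace(h)), numeric(1)))
  if (aHoles >= aOut)
    stop("invalid geometry: hole area >= outer ring area")
  P <- ringPerimeter(outer) + sum(vapply(holes, ringPerimeter, numeric(1)))
  data.frame(perimeter = P, area = aOut - aHoles,
             n_rings = 1L + length(holes))
}

# Trace closed 0.5 iso-contours of one binary component (already smoothed),
# given pixel-centre coordinate vectors. Returns a list of closed rings.
traceContours <- function(z, xc, yc) {
  cl <- grDevices::contourLines(x = xc, y = yc, z = z, levels = 0.5)
  rings <- list()
  for (cc in cl) {
    ring <- cbind(cc$x, cc$y)
    ring <- dedupeRing(ring)
    if (nrow(ring) >= 3) rings[[length(rings) + 1L]] <- ring
  }
  rings
}

#' Extract polygonal regions of one label from a raster mask
#'
#' Traces sub-pixel boundaries of the binary indicator of \code{label} at
#' the 0.5 iso-level of a Gaussian-presmoothed copy (tracing the raw binary
#' grid would overestimate perimeters by several percent and bias the MPP
#' score upwards).  Each 4-connected component yields one
#' \linkS4class{PolygonRegion} whose holes are interior contours.
#' Coordinates are scaled to micrometres using the mask's pixel size; image
#' convention (x right, y down, origin at the top-left pixel corner).
#' Regions are ordered by decreasing area, ties broken by the topmost,
#' then leftmost outer vertex.
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @param label integer label to extract; absent labels give an empty list.
#' @param sigma smoothing bandwidth in pixels; \code{NULL} (default) uses
#'   \code{1.5 * sqrt(1/pixelSize)} px, floored at 0.75.
#' @return list of \linkS4class{PolygonRegion} (possibly empty).
#' @examples
#' m <- matrix(0L, 40, 40); m[10:30, 10:30] <- 1L
#' rs <- extractRegions(LabeledMask(m, pixelSize = 2), 1L)
#' measurePolygon(rs[[1]])
#' @export
extractRegions <- function(mask, label, sigma = NULL) {
  stopifnot(is(mask, "LabeledMask"))
  ps <- mask@pixelSize
  if (is.null(sigma)) sigma <- autoSigma(ps)
  bin <- (mask@labels == as.integer(label))
  if (!any(bin)) return(list())
  cls <- if (as.character(label) %in% names(mask@labelNames))
    mask@labelNames[[as.character(label)]] else as.character(label)
  comp <- .cc_label4(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  ncomp <- max(comp)
  pad <- max(2L, as.integer(ceiling(3 * sigma)) + 1L)
  out <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(bin), max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(bin), max(idx[, 2]) + pad)
    sub <- matrix(0, r1 - r0 + 1L + 2L * pad, c1 - c0 + 1L + 2L * pad)
    sub[pad + seq_len(r1 - r0 + 1L), pad + seq_len(c1 - c0 + 1L)] <-
      (comp[r0:r1, c0:c1, drop = FALSE] == k) + 0
    sm <- gaussianSmooth(sub, sigma)
    # pixel-centre coordinates of the padded window, in um; matrix rows are
    # y, columns are x, and contourLines indexes z[x, y], hence t().
    ys <- (r0 - pad - 1L + seq_len(nrow(sub)) - 0.5) * ps
    xs <- (c0 - pad - 1L + seq_len(ncol(sub)) - 0.5) * ps
    rings <- traceContours(t(sm), xs, ys)
    if (!length(rings)) next
    areas <- vapply(rings, function(r) abs(shoelace(r)), numeric(1))
    # containment depth decides outer rings (even) vs holes (odd)
    depth <- integer(length(rings))
    for (i in seq_along(rings)) {
      for (j in seq_along(rings)) {
        if (i == j || areas[j] <= areas[i]) next
        if (pointInRing(rings[[i]][1, 1], rings[[i]][1, 2], rings[[j]]))
          depth[i] <- depth[i] + 1L
      }
    }
    outerIdx <- which(depth %% 2L == 0L)
    for (oi in outerIdx) {
      holeIdx <- which(depth == depth[oi] + 1L & areas < areas[oi])
      holeIdx <- holeIdx[vapply(holeIdx, function(hj)
        pointInRing(rings[[hj]][1, 1], rings[[hj]][1, 2], rings[[oi]]),
        logical(1))]
      out[[length(out) + 1L]] <-
        PolygonRegion(rings[[oi]], rings[holeIdx], classLabel = cls)
    }
  }
  orderRegions(out)
}

# Deterministic ordering: decreasing outer area, ties by topmost then
# leftmost outer-ring vertex.
orderRegions <- function(regs) {
  if (length(regs) <= 1) return(regs)
  a <- vapply(regs, function(r) abs(shoelace(dedupeRing(r@outer))), numeric(1))
  ty <- vapply(regs, function(r) min(r@outer[, 2]), numeric(1))
  tx <- vapply(regs, function(r) min(r@outer[, 1]), numeric(1))
  regs[order(-a, ty, tx)]
}

#' Measure all regions of one tissue class
#'
#' Works on either a \linkS4class{LabeledMask} (regions are traced with
#' \code{\link{extractRegions}}) or an \linkS4class{AnnotationSet} (regions
#' are measured as polygons).  Regions smaller than \code{minArea} are
#' dropped; the pipeline default for that filter is the area of one default
#' superpixel (see \code{\link{defaultMinArea}}), but the bare function
#' defaults to 0 so nothing is filtered implicitly.
#'
#' @param x \linkS4class{LabeledMask} or \linkS4class{AnnotationSet}.
#' @param classLabel class name (or, for masks, a label name registered in
#'   \code{labelNames}).
#' @param minArea minimum region area in square micrometres.
#' @param sigma passed to \code{\link{extractRegions}} for masks.
#' @return data.frame with one row per kept region: \code{region_index},
#'   \code{perimeter}, \code{area}, \code{n_rings}.
#' @export
measureClass <- function(x, classLabel, minArea = 0, sigma = NULL) {
  if (is(x, "LabeledMask")) {
    lab <- classToLabel(x, classLabel)
    regs <- extractRegions(x, lab, sigma = sigma)
  } else if (is(x, "AnnotationSet")) {
    cls <- classLabels(x)
    if (!classLabel %in% cls)
      stop(sprintf("unknown class label '%s'", classLabel))
    regs <- orderRegions(x@regions[cls == classLabel])
  } else stop("x must be a LabeledMask or an AnnotationSet")
  if (!length(regs))
    return(data.frame(region_index = integer(), perimeter = numeric(),
                      area = numeric(), n_rings = integer()))
  m <- do.call(rbind, lapply(regs, measurePolygon))
  m <- m[m$area >= minArea, , drop = FALSE]
  if (nrow(m)) m <- cbind(region_index = seq_len(nrow(m)), m)
  else m <- cbind(region_index = integer(), m)
  rownames(m) <- NULL
  m
}

# Resolve a class name to its integer label in a mask.
classToLabel <- function(mask, classLabel) {
  ln <- mask@labelNames
  if (length(ln) && classLabel %in% ln)
    return(as.integer(names(ln)[match(classLabel, ln)]))
  lab <- suppressWarnings(as.integer(classLabel))
  present <- setdiff(unique(as.vector(mask@labels)), 0L)
  if (!is.na(lab) && lab %in% present) return(lab)
  stop(sprintf("unknown class label '%s'", classLabel))
}

#' Pipeline default for the minimum-area region filter
#'
#' The area of one default superpixel (diameter \code{spacing}), used to
#' keep classification specks from dominating perimeter totals.
#'
#' @param spacing superpixel spacing in micrometres (default 50).
#' @return area in square micrometres.
#' @export
defaultMinArea <- function(spacing = 50) spacing^2

#' Rasterize a polygonal region onto a pixel grid
#'
#' Even-odd scanline fill at pixel centres, in the same coordinate
#' convention used by \code{\link{extractRegions}}; used to check
#' polygon/raster agreement and to build synthetic fixtures.
#'
#' @param region a \linkS4class{PolygonRegion} in micrometre coordinates.
#' @param pixelSize micrometres per pixel of the target grid.
#' @param dim optional c(nrow, ncol) of the target grid; defaults to the
#'   polygon bounding box plus a margin.
#' @return a \linkS4class{LabeledMask} with the region as label 1.
#' @export
rasterizePolygon <- function(region, pixelSize = 1, dim = NULL) {
  stopifnot(is(region, "PolygonRegion"))
  rings <- c(list(dedupeRing(region@outer)), lapply(region@holes, dedupeRing))
  allxy <- do.call(rbind, rings)
  if (is.null(dim)) {
    nr <- ceiling(max(allxy[, 2]) / pixelSize) + 3L
    nc <- ceiling(max(allxy[, 1]) / pixelSize) + 3L
  } else { nr <- dim[1]; nc <- dim[2] }
  m <- matrix(0L, nr, nc)
  ys <- (seq_len(nr) - 0.5) * pixelSize
  for (i in seq_len(nr)) {
    py <- ys[i]
    xs <- numeric(0)
    for (ring in rings) {
      x <- ring[, 1]; y <- ring[, 2]
      n <- length(x); j <- c(n, seq_len(n - 1))
      cross <- (y > py) != (y[j] > py)
      if (any(cross))
        xs <- c(xs, (x[j][cross] - x[cross]) * (py - y[cross]) /
                      (y[j][cross] - y[cross]) + x[cross])
    }
    if (!length(xs)) next
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[k] / pixelSize + 0.5))
      c1 <- min(nc, floor(xs[k + 1] / pixelSize + 0.5))
      if (c0 <= c1) m[i, c0:c1] <- 1L
    }
  }
  LabeledMask(m, pixelSize = pixelSize,
              labelNames = stats::setNames(as.character(region@classLabel), "1"))
}

#' Write a per-region measurement table as CSV
#'
#' @param measurements data.frame from \code{\link{measureClass}}.
#' @param imageId image identifier recorded in every row.
#' @param classLabel class name recorded in every row.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMeasurements <- function(measurements, imageId, classLabel, path) {
  df <- data.frame(image_id = imageId, class = classLabel,
                   region_index = measurements$region_index,
                   perimeter_um = measurements$perimeter,
                   area_um2 = measurements$area,
                   n_rings = measurements$n_rings)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
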