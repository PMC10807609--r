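#' SLIC-style superpixel segmentation
#'
#' Partitions an image into approximately regular, perceptually coherent
#' atomic regions by localized k-means in joint color + position space
#' (the classic SLIC construction): cluster centres start on a regular
#' grid of step \code{spacing}, each pixel is assigned to the nearest
#' centre within a 2-step search window under the distance
#' \code{d_color^2 + (d_xy/S)^2 * compactness^2} (color on a 0..255
#' scale), centres are recomputed, and after the final iteration every
#' superpixel is made 4-connected by reassigning stray fragments to an
#' adjacent superpixel.  The whole procedure is deterministic for a fixed
#' seed.
#'
#' @param image h x w x 3 RGB array or h x w grayscale matrix, values in
#'   [0, 1].
#' @param spacing target superpixel diameter in micrometres.
#' @param compactness trade-off between color similarity and spatial
#'   regularity (larger = more regular); classic default 10.
#' @param seed integer seed, recorded in the result.
#' @param pixelSize micrometres per pixel.
#' @param iterations number of k-means sweeps.
#' @param preBlur Gaussian bandwidth (pixels) of the image pre-smoothing
#'   applied before clustering, as in the original SLIC implementation;
#'   suppresses pixel-noise-driven boundary raggedness.  0 disables.
#' @return a \linkS4class{SuperpixelMap}.
#' @export
computeSuperpixels <- function(image, spacing = 50, compactness = 10,
                               seed = 1, pixelSize = 1, iterations = 10L,
                               preBlur = 1) {
  if (spacing <= 0) stop("spacing must be positive")
  set.seed(as.integer(seed))
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  h <- dim(image)[1]; w <- dim(image)[2]; nch <- dim(image)[3]
  S <- spacing / pixelSize
  if (S >= max(h, w)) {
    warning("spacing exceeds the image; returning a single superpixel")
    return(new("SuperpixelMap", labels = matrix(1L, h, w), K = 1L,
               spacing = spacing, pixelSize = pixelSize,
               seed = as.integer(seed)))
  }
  if (preBlur > 0)
    for (ch in seq_len(nch))
      image[, , ch] <- gaussianSmooth(image[, , ch, drop = TRUE], preBlur)
  feat <- matrix(image, h * w, nch) * 255
  py <- rep(seq_len(h), times = w)
  px <- rep(seq_len(w), each = h)

  cy <- seq(S / 2, h, by = S); cx <- seq(S / 2, w, by = S)
  centers <- cbind(rep(cy, times = length(cx)), rep(cx, each = length(cy)))
  K <- nrow(centers)
  cfeat <- matrix(0, K, nch)
  for (k in seq_len(K)) {
    i <- pmin(h, pmax(1, round(centers[k, 1])))
    j <- pmin(w, pmax(1, round(centers[k, 2])))
    cfeat[k, ] <- feat[i + (j - 1) * h, ]
  }

  lab <- integer(h * w)
  best <- rep(Inf, h * w)
  ratio <- (compactness / S)^2
  for (it in seq_len(iterations)) {
    best[] <- Inf
    lab[] <- 0L
    for (k in seq_len(K)) {
      r0 <- max(1L, floor(centers[k, 1] - S)); r1 <- min(h, ceiling(centers[k, 1] + S))
      c0 <- max(1L, floor(centers[k, 2] - S)); c1 <- min(w, ceiling(centers[k, 2] + S))
      rows <- r0:r1
      idx <- as.vector(outer(rows, (c0:c1 - 1L) * h, `+`))
      d <- ratio * ((py[idx] - centers[k, 1])^2 + (px[idx] - centers[k, 2])^2)
      for (ch in seq_len(nch))
        d <- d + (feat[idx, ch] - cfeat[k, ch])^2
      upd <- d < best[idx]
      ii <- idx[upd]
      best[ii] <- d[upd]
      lab[ii] <- k
    }
    # orphans (outside every window) go to the nearest grid centre
    if (any(lab == 0L)) {
      z <- which(lab == 0L)
      gi <- pmin(length(cy), pmax(1, ceiling(py[z] / S)))
      gj <- pmin(length(cx), pmax(1, ceiling(px[z] / S)))
      lab[z] <- (gj - 1L) * length(cy) + gi
    }
    counts <- tabulate(lab, K)
    sy <- rowsum(py, lab); sx <- rowsum(px, lab)
    keep <- counts > 0
    centers[keep, 1] <- sy[, 1] / counts[keep]
    centers[keep, 2] <- sx[, 1] / counts[keep]
    for (ch in seq_len(nch))
      cfeat[keep, ch] <- rowsum(feat[, ch], lab)[, 1] / counts[keep]
  }
  labm <- matrix(lab, h, w)
  labm <- enforceConnectivity(labm)
  new("SuperpixelMap", labels = labm, K = max(labm), spacing = spacing,
      pixelSize = pixelSize, seed = as.integer(seed))
}

# Make every superpixel 4-connected: the largest fragment of each label is
# kept; every other fragment is merged into the adjacent kept superpixel
# with the longest shared border (deterministic tie-break: smallest label).
# Merges within one pass are resolved against the pass-start state, so
# fragments cannot chain into elongated superpixels.
enforceConnectivity <- function(labm) {
  h <- nrow(labm); w <- ncol(labm)
  for (pass in seq_len(50L)) {
    frag <- .cc_label4(labm, background = -1L)
    nf <- max(frag)
    fsize <- tabulate(frag, nf)
    fsp <- labm[match(seq_len(nf), frag)]
    keep <- logical(nf)
    for (sp in unique(fsp)) {
      fr <- which(fsp == sp)
      best <- fr[fsize[fr] == max(fsize[fr])]
      keep[min(best)] <- TRUE
    }
    orphan <- which(!keep)
    if (!length(orphan)) break
    cellsOf <- split(seq_along(frag), frag)
    newLab <- labm
    for (f in orphan) {
      cells <- cellsOf[[f]]
      ri <- (cells - 1L) %% h + 1L
      ci <- (cells - 1L) %/% h + 1L
      nb <- c(cells[ri > 1] - 1L, cells[ri < h] + 1L,
              cells[ci > 1] - h, cells[ci < w] + h)
      nb <- nb[keep[frag[nb]]]
      if (!length(nb)) next
      cnt <- table(labm[nb])
      tgt <- as.integer(names(cnt)[cnt == max(cnt)])
      newLab[cells] <- min(tgt)
    }
    if (identical(newLab, labm)) break  # isolated orphan islands: give up
    labm <- newLab
  }
  u <- sort(unique(as.vector(labm)))
  matrix(match(labm, u), h, w)
}

#' Per-superpixel intensity features
#'
#' For every superpixel: the mean and standard deviation of each color
#' channel plus the mean grayscale intensity, together with z-scored
#' copies standardized over the whole ROI.
#'
#' @param image the image the map was computed on.
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @return list with \code{features} (K x p matrix), \code{z}
#'   (standardized copy), \code{center}, \code{scale}, \code{schema}.
#' @export
superpixelFeatures <- function(image, spmap) {
  stopifnot(is(spmap, "SuperpixelMap"))
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  nch <- dim(image)[3]
  lab <- as.vector(spmap@labels)
  K <- spmap@K
  n <- tabulate(lab, K)
  cols <- list()
  gray <- 0
  for (ch in seq_len(nch)) {
    x <- as.vector(image[, , ch])
    s1 <- rowsum(x, lab)[, 1]
    s2 <- rowsum(x^2, lab)[, 1]
    mu <- s1 / n
    va <- pmax(0, (s2 - s1^2 / n) / pmax(1, n - 1))
    cols[[paste0("mean_ch", ch)]] <- mu
    cols[[paste0("sd_ch", ch)]] <- sqrt(va)
    gray <- gray + mu / nch
  }
  cols[["mean_gray"]] <- gray
  f <- do.call(cbind, cols)
  ctr <- colMeans(f)
  scl <- apply(f, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(f, 2, ctr), 2, scl, "/")
  list(features = f, z = z, center = ctr, scale = scl,
       schema = colnames(f))
}

#' Train a tissue classifier from scribble annotations
#'
#' A single supervised pass replacing the interactive retraining loop of
#' visually supervised tissue detection: superpixels whose largest
#' scribble overlap belongs to a class become training examples, and a
#' nearest-centroid rule on standardized features is fitted.
#'
#' @param features output of \code{\link{superpixelFeatures}}.
#' @param scribbles list of scribbles; each a list with \code{mask} (a
#'   logical matrix over the image) and \code{class} (tissue class name).
#' @param spmap the \linkS4class{SuperpixelMap} the features refer to.
#' @param classes class vocabulary to train; defaults to the classes
#'   present in the scribbles.  A declared class with no overlapping
#'   superpixel is an error.
#' @return classifier state (list with centroids, schema, class names).
#' @export
trainTissueClassifier <- function(features, scribbles, spmap,
                                  classes = NULL) {
  if (!length(scribbles))
    stop("insufficient training data: empty scribble set")
  lab <- spmap@labels
  K <- spmap@K
  cls <- vapply(scribbles, function(s) s$class, character(1))
  if (is.null(classes)) classes <- sort(unique(cls))
  overlap <- matrix(0, K, length(classes),
                    dimnames = list(NULL, classes))
  for (s in scribbles) {
    if (!s$class %in% classes) next
    if (!identical(dim(s$mask), dim(lab)))
      stop("scribble mask dimensions must match the image")
    cnt <- tabulate(lab[s$mask], K)
    overlap[, s$class] <- overlap[, s$class] + cnt
  }
  miss <- classes[colSums(overlap) == 0]
  if (length(miss))
    stop(sprintf("insufficient training data: no superpixel overlaps class %s",
                 paste(miss, collapse = ", ")))
  trainIdx <- which(rowSums(overlap) > 0)
  trainCls <- classes[max.col(overlap[trainIdx, , drop = FALSE],
                              ties.method = "first")]
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(features$z[trainIdx[trainCls == cl], , drop = FALSE])
  }))
  rownames(centroids) <- classes
  structure(list(centroids = centroids, schema = features$schema,
                 center = features$center, scale = features$scale,
                 classes = classes),
            class = "tissueClassifier")
}

# Nearest-centroid prediction for each superpixel.
predictSuperpixels <- function(classifier, features) {
  if (!identical(classifier$schema, features$schema))
    stop("feature-schema error: classifier and features disagree")
  z <- sweep(sweep(features$features, 2, classifier$center), 2,
             classifier$scale, "/")
  d2 <- outer(rowSums(z^2), rowSums(classifier$centroids^2), `+`) -
    2 * z %*% t(classifier$centroids)
  classifier$classes[max.col(-d2, ties.method = "first")]
}

#' Classify superpixels and merge same-class neighbours into annotations
#'
#' Predicts a tissue class for every superpixel with the nearest-centroid
#' classifier, paints the prediction back onto the pixel grid, and traces
#' each 4-connected same-class component into a polygonal annotation
#' (holes included), ready for \code{\link{measureClass}} /
#' \code{\link{scoreClass}}.
#'
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @param classifier state from \code{\link{trainTissueClassifier}}.
#' @param features output of \code{\link{superpixelFeatures}} for the same
#'   map.
#' @param imageId identifier stored in the result.
#' @param background classes rendered as background (not annotated).
#' @return an \linkS4class{AnnotationSet}.
#' @export
classifyAndMerge <- function(spmap, classifier, features,
                             imageId = NA_character_,
                             background = "background") {
  pred <- predictSuperpixels(classifier, features)
  classes <- setdiff(classifier$classes, background)
  code <- match(pred, classes)          # NA for background classes
  code[is.na(code)] <- 0L
  classImg <- matrix(code[spmap@labels], nrow(spmap@labels))
  mask <- LabeledMask(classImg, pixelSize = spmap@pixelSize,
                      labelNames = stats::setNames(classes,
                                                   seq_along(classes)))
  regs <- list()
  for (i in seq_along(classes)) {
    if (!any(classImg == i)) next
    regs <- c(regs, extractRegions(mask, i))
  }
  AnnotationSet(regions = regs, pixelSize = spmap@pixelSize,
                imageId = imageId)
}

#' Stromal ratio from a classified annotation set
#'
#' Sums the areas of the stroma classes (fibrous plus lymphocytic by
#' default) and of the tumor class and applies the stromal-ratio formula
#' 100 * stroma / (stroma + tumor).
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param tumorClass tumor class name (must be present).
#' @param stromaClasses stroma class names (absent ones contribute 0).
#' @return list as from \code{\link{stromalRatio}}.
#' @export
stromaTumorRatio <- function(annotations,
                             tumorClass = "tumor",
                             stromaClasses = c("fibrous_stroma",
                                               "lymphocytic_stroma")) {
  cls <- classLabels(annotations)
  if (!tumorClass %in% cls)
    stop(sprintf("unknown class label '%s': no tumor annotations", tumorClass))
  areaOf <- function(sel) {
    if (!any(sel)) return(0)
    sum(vapply(annotations@regions[sel],
               function(r) measurePolygon(r)$area, numeric(1)))
  }
  stromalRatio(areaOf(cls %in% stromaClasses), areaOf(cls == tumorClass))
}

#' Segment an image and score one tissue class
#'
#' Full pipeline for one image: superpixels, features, scribble-trained
#' classifier, merge to annotations, minimum-area filter, MPP score.
#'
#' @inheritParams computeSuperpixels
#' @param scribbles scribble list, see \code{\link{trainTissueClassifier}}.
#' @param classLabel class to score (default "tumor").
#' @param minArea minimum region area, square micrometres; \code{NULL}
#'   uses \code{\link{defaultMinArea}} at this spacing.
#' @param imageId identifier stored in the result.
#' @return list with \code{score} (an \linkS4class{MPPResult}),
#'   \code{annotations}, and \code{spmap}.
#' @export
segmentAndScore <- function(image, scribbles, classLabel = "tumor",
                            spacing = 50, compactness = 10, seed = 1,
                            pixelSize = 1, minArea = NULL,
                            imageId = NA_character_) {
  if (is.null(minArea)) minArea <- defaultMinArea(spacing)
  spmap <- computeSuperpixels(image, spacing = spacing,
                              compactness = compactness, seed = seed,
                              pixelSize = pixelSize)
  feats <- superpixelFeatures(image, spmap)
  clf <- trainTissueClassifier(feats, scribbles, spmap)
  ann <- classifyAndMerge(spmap, clf, feats, imageId = imageId)
  sc <- scoreClass(ann, classLabel, minArea = minArea, imageId = imageId)
  list(score = sc, annotations = ann, spmap = spmap)
}

#' Superpixel-size sensitivity profile of the MPP score
#'
#' The measured perimeter (and hence the MPP score) depends on
#' resolution-type parameters such as the superpixel size, so the score is
#' reported at half, nominal and double spacing together.
#'
#' @inheritParams segmentAndScore
#' @param spacings spacings to profile; default \code{spacing * c(.5, 1, 2)}.
#' @return data.frame with one row per spacing: spacing, n_regions,
#'   total_perimeter_um, total_area_um2, pp, mpp.
#' @export
mppSpacingProfile <- function(image, scribbles, classLabel = "tumor",
                              spacing = 50, spacings = spacing * c(0.5, 1, 2),
                              compactness = 10, seed = 1, pixelSize = 1,
                              imageId = NA_character_) {
  rows <- lapply(spacings, function(s) {
    r <- segmentAndScore(image, scribbles, classLabel = classLabel,
                         spacing = s, compactness = compactness,
                         seed = seed, pixelSize = pixelSize,
                         imageId = imageId)$score
    data.frame(spacing = s, n_regions = r@nRegions,
               total_perimeter_um = r@totalPerimeter,
               total_area_um2 = r@totalArea, pp = r@pp, mpp = r@mpp)
  })
  do.call(rbind, rows)
}
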