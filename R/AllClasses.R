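#' @import methods
NULL

#' PolygonRegion: one closed region with optional holes
#'
#' A single tissue region delimited by an outer ring and zero or more
#' interior rings (holes), in physical coordinates (micrometres by
#' convention).  Image coordinates are used throughout: x grows to the
#' right, y grows downwards, origin at the top-left corner of the image.
#'
#' @slot outer numeric matrix with two columns (x, y); the closing vertex
#'   may be repeated or left implicit.
#' @slot holes list of two-column numeric matrices, each fully inside the
#'   outer ring.
#' @slot classLabel single character string naming the tissue class.
#' @export
setClass("PolygonRegion",
  representation(outer = "matrix", holes = "list", classLabel = "character"),
  prototype(holes = list(), classLabel = NA_character_))

setValidity("PolygonRegion", function(object) {
  msg <- character()
  if (!is.numeric(object@outer) || ncol(object@outer) != 2)
    msg <- c(msg, "outer ring must be a numeric matrix with 2 columns")
  else {
    ring <- dedupeRing(object@outer)
    if (nrow(ring) < 3)
      msg <- c(msg, "outer ring must have at least 3 distinct vertices")
    else if (abs(shoelace(ring)) <= 0)
      msg <- c(msg, "outer ring must enclose positive area")
  }
  for (h in object@holes) {
    if (!is.numeric(h) || ncol(h) != 2)
      msg <- c(msg, "holes must be numeric matrices with 2 columns")
  }
  if (length(object@classLabel) != 1)
    msg <- c(msg, "classLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{PolygonRegion}
#'
#' @param outer two-column matrix of outer-ring vertices (x, y).
#' @param holes list of two-column matrices of hole vertices.
#' @param classLabel tissue class name.
#' @return a \linkS4class{PolygonRegion}.
#' @examples
#' sq <- PolygonRegion(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), classLabel = "tumor")
#' @export
PolygonRegion <- function(outer, holes = list(), classLabel = NA_character_) {
  outer <- as.matrix(outer)
  storage.mode(outer) <- "double"
  holes <- lapply(holes, function(h) {
    h <- as.matrix(h); storage.mode(h) <- "double"; h
  })
  new("PolygonRegion", outer = outer, holes = holes,
      classLabel = as.character(classLabel))
}

#' LabeledMask: integer label image with a physical pixel size
#'
#' @slot labels integer matrix; rows index y (top to bottom), columns index
#'   x (left to right); 0 is background.
#' @slot pixelSize physical edge length of one pixel in micrometres.
#' @slot labelNames named character vector mapping label values (as names)
#'   to class names; may be empty.
#' @export
setClass("LabeledMask",
  representation(labels = "matrix", pixelSize = "numeric",
                 labelNames = "character"),
  prototype(pixelSize = 1, labelNames = character()))

setValidity("LabeledMask", function(object) {
  msg <- character()
  if (!is.numeric(object@labels))
    msg <- c(msg, "labels must be an integer matrix")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (is.numeric(object@labels) && any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative (0 = background)")
  if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{LabeledMask}
#'
#' @param labels integer matrix of labels (0 = background).
#' @param pixelSize micrometres per pixel edge (> 0).
#' @param labelNames named character vector mapping label values to class
#'   names, e.g. \code{c("1" = "tumor")}.
#' @return a \linkS4class{LabeledMask}.
#' @export
LabeledMask <- function(labels, pixelSize = 1, labelNames = character()) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("LabeledMask", labels = labels, pixelSize = as.numeric(pixelSize),
      labelNames = labelNames)
}

#' AnnotationSet: classified polygons from one image
#'
#' @slot regions list of \linkS4class{PolygonRegion}.
#' @slot pixelSize micrometres per pixel used when the polygons were
#'   extracted (coordinates themselves are already physical).
#' @slot imageId identifier of the source image.
#' @export
setClass("AnnotationSet",
  representation(regions = "list", pixelSize = "numeric",
                 imageId = "character"),
  prototype(regions = list(), pixelSize = 1, imageId = NA_character_))

setValidity("AnnotationSet", function(object) {
  ok <- vapply(object@regions, function(r) is(r, "PolygonRegion"), logical(1))
  if (!all(ok)) return("all regions must be PolygonRegion objects")
  TRUE
})

#' Constructor for \linkS4class{AnnotationSet}
#'
#' @param regions list of \linkS4class{PolygonRegion}.
#' @param pixelSize micrometres per pixel of the source image.
#' @param imageId identifier of the source image.
#' @return an \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(regions = list(), pixelSize = 1,
                          imageId = NA_character_) {
  new("AnnotationSet", regions = regions, pixelSize = as.numeric(pixelSize),
      imageId = as.character(imageId))
}

#' SuperpixelMap: partition of an image into atomic regions
#'
#' @slot labels integer matrix assigning every pixel to one superpixel
#'   (1..K).
#' @slot K number of superpixels.
#' @slot spacing target superpixel diameter in micrometres.
#' @slot pixelSize micrometres per pixel.
#' @slot seed integer seed the segmentation was run with.
#' @export
setClass("SuperpixelMap",
  representation(labels = "matrix", K = "integer", spacing = "numeric",
                 pixelSize = "numeric", seed = "integer"))

setValidity("SuperpixelMap", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (any(object@labels < 1L) || any(object@labels > object@K))
    msg <- c(msg, "every pixel must carry a superpixel label in 1..K")
  if (length(msg)) msg else TRUE
})

#' MPPResult: aggregated compactness scores for one class on one image
#'
#' Totals over all regions of a class plus the Polsby-Popper score
#' PP = 4*pi*A/P^2 and the modified score MPP = 0.5*ln(P^2/(4*pi*A)).
#'
#' @slot imageId image identifier.
#' @slot classLabel tissue class scored.
#' @slot totalPerimeter sum of region perimeters, micrometres.
#' @slot totalArea sum of region areas, square micrometres.
#' @slot nRegions number of regions aggregated.
#' @slot pp Polsby-Popper score in (0, 1].
#' @slot mpp modified Polsby-Popper score, >= 0.
#' @export
setClass("MPPResult",
  representation(imageId = "character", classLabel = "character",
                 totalPerimeter = "numeric", totalArea = "numeric",
                 nRegions = "integer", pp = "numeric", mpp = "numeric"))

setValidity("MPPResult", function(object) {
  msg <- character()
  if (object@totalPerimeter <= 0 || object@totalArea <= 0)
    msg <- c(msg, "totals must be positive")
  if (object@pp <= 0 || object@pp > 1)
    msg <- c(msg, "pp must lie in (0, 1]")
  if (object@mpp < 0) msg <- c(msg, "mpp must be >= 0")
  if (object@nRegions < 1L) msg <- c(msg, "nRegions must be >= 1")
  if (abs(exp(-2 * object@mpp) - object@pp) > 1e-12)
    msg <- c(msg, "pp and mpp must satisfy exp(-2*mpp) == pp")
  if (length(msg)) msg else TRUE
})

#' SurvivalCurve: Kaplan-Meier estimate with Greenwood confidence bands
#'
#' @slot time event-time grid (months).
#' @slot surv product-limit survival estimates.
#' @slot lower,upper Greenwood log-transformed confidence band.
#' @slot nRisk,nEvent at-risk and event counts at each time.
#' @slot median estimated median survival (NA when the curve never crosses
#'   0.5).
#' @slot medianCI two-sided confidence interval for the median.
#' @slot fit the underlying \code{survival::survfit} object.
#' @export
setClass("SurvivalCurve",
  representation(time = "numeric", surv = "numeric", lower = "numeric",
                 upper = "numeric", nRisk = "numeric", nEvent = "numeric",
                 median = "numeric", medianCI = "numeric", fit = "ANY"))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival estimates must be non-increasing")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
    msg <- c(msg, "survival estimates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TestResult: statistic, p-value and effect size of one comparison
#'
#' @slot method short description of the test performed.
#' @slot statistic test statistic value (chi-squared, t, F, z, r, ...).
#' @slot df degrees of freedom (possibly fractional; NA where undefined).
#' @slot p two-sided p-value.
#' @slot effectSize named numeric vector (e.g. d, eta2, r, auc_a, auc_b).
#' @slot groups data.frame of per-group summaries (may have 0 rows).
#' @slot details list of additional method-specific quantities.
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric", df = "numeric",
                 p = "numeric", effectSize = "numeric", groups = "data.frame",
                 details = "list"),
  prototype(effectSize = numeric(), groups = data.frame(), details = list()))

setValidity("TestResult", function(object) {
  if (length(object@p) == 1 && is.finite(object@p) &&
      (object@p < 0 || object@p > 1)) return("p must lie in [0, 1]")
  TRUE
})

#' CohortConfig: parameters of the synthetic clinicopathologic cohort
#'
#' Defaults reproduce the published study conditions: 100 cases split
#' 40/39/17/4 over pT1..pT4a, per-group MPP and tumor-thickness normal
#' marginals, a pooled MPP-thickness correlation of 0.736 induced through
#' a Gaussian copula, and piecewise-exponential survival calibrated so each
#' MPP stratum passes through its configured 2-year/5-year anchors.
#'
#' @slot nCases number of cases per cohort.
#' @slot groups data.frame with columns pT, prop, mppMean, mppSd,
#'   thickMean, thickSd.
#' @slot rho target pooled Pearson correlation between MPP and thickness.
#' @slot latentRho within-case latent normal correlation solved from
#'   \code{rho} and the group structure (computed, do not set by hand).
#' @slot threshold MPP value splitting the survival strata (high > low).
#' @slot anchors named list per endpoint (os, tcss, rfs, mfs); each element
#'   a list with \code{low} and \code{high} numeric vectors c(s24, s60) of
#'   survival probabilities at 24 and 60 months.
#' @slot censorRange range (months) of the uniform administrative censoring
#'   time; defaults give a reverse-KM median follow-up of 93.6 months and a
#'   maximum of 185.
#' @slot observerSd standard deviation (percentage points) of the emulated
#'   pathologist's naked-eye stromal estimate around the true ratio.
#' @export
setClass("CohortConfig",
  representation(nCases = "integer", groups = "data.frame", rho = "numeric",
                 latentRho = "numeric", threshold = "numeric",
                 anchors = "list", censorRange = "numeric",
                 observerSd = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  g <- object@groups
  need <- c("pT", "prop", "mppMean", "mppSd", "thickMean", "thickSd")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("groups must have columns", paste(need, collapse = ", ")))
  else {
    if (abs(sum(g$prop) - 1) > 1e-8)
      msg <- c(msg, "group proportions must sum to 1")
    if (any(g$mppSd <= 0) || any(g$thickSd <= 0))
      msg <- c(msg, "all group SDs must be positive")
  }
  if (!is.finite(object@latentRho) || abs(object@latentRho) >= 1)
    msg <- c(msg, "latent correlation must lie in (-1, 1); the requested pooled correlation is infeasible for these group marginals")
  for (ep in names(object@anchors)) {
    a <- object@anchors[[ep]]
    for (s in c("low", "high")) {
      v <- a[[s]]
      if (length(v) != 2 || any(v <= 0) || any(v > 1))
        msg <- c(msg, sprintf("anchors$%s$%s must be two probabilities in (0, 1]", ep, s))
      else if (v[2] > v[1] + 1e-12)
        msg <- c(msg, sprintf("anchors$%s$%s must be non-increasing in time", ep, s))
    }
  }
  if (length(object@censorRange) != 2 || object@censorRange[1] < 0 ||
      diff(object@censorRange) <= 0)
    msg <- c(msg, "censorRange must be an increasing non-negative pair")
  if (length(msg)) msg else TRUE
})
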