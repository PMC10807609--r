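#' Polsby-Popper compactness score
#'
#' PP = 4*pi*A / P^2: the isoperimetric quotient, 1 for a perfect circle
#' and tending to 0 for increasingly irregular (wavier, more fragmented)
#' regions.  Exact geometry can never exceed 1; raster measurements may
#' overshoot marginally, in which case the value is clipped to 1 with a
#' warning.
#'
#' @param P perimeter (> 0), micrometres.
#' @param A area (> 0), square micrometres.
#' @param clipTol amount by which raster noise may push PP above 1 before
#'   clipping is considered an error rather than noise.
#' @return dimensionless score in (0, 1].
#' @examples
#' polsbyPopper(2 * pi, pi)  # unit circle -> 1
#' polsbyPopper(4, 1)        # unit square -> pi/4
#' @export
polsbyPopper <- function(P, A, clipTol = 0.02) {
  checkPA(P, A)
  pp <- 4 * pi * A / P^2
  if (any(pp > 1 + clipTol))
    stop("PP exceeds 1 beyond raster tolerance; check the input geometry")
  if (any(pp > 1 + 1e-9))
    warning("PP marginally above 1 (raster noise); clipped to 1")
  pmin(pp, 1)
}

#' Modified Polsby-Popper score
#'
#' MPP = 0.5 * ln(P^2 / (4*pi*A)), the natural-log transform of the
#' reciprocal isoperimetric quotient: 0 for a perfect circle, growing
#' without bound for wavier or more disjoint regions, and equal to
#' -0.5 * ln(PP).  The log transform makes slide-level perimeter/area
#' ratios approximately normal, which is what the downstream statistics
#' assume.  A different log base would only rescale the score.
#'
#' @inheritParams polsbyPopper
#' @return dimensionless score >= 0.
#' @examples
#' mppScore(2 * pi, pi)              # circle -> 0
#' mppScore(4 * pi, 2 * pi)          # two unit circles -> 0.5 * log(2)
#' @export
mppScore <- function(P, A, clipTol = 0.02) {
  pp <- polsbyPopper(P, A, clipTol = clipTol)
  -0.5 * log(pp)
}

checkPA <- function(P, A) {
  if (!all(is.finite(P)) || !all(is.finite(A)) || any(P <= 0) || any(A <= 0))
    stop("perimeter and area must be positive finite numbers")
  invisible(TRUE)
}

#' Aggregate region measurements into one slide-level score
#'
#' The score is computed on the summed totals (total perimeter, total
#' area) of all regions of the class on the image -- not as a per-region
#' average, which would erase exactly the disjointedness signal the score
#' is designed to capture: n congruent copies of a shape raise the MPP of
#' the totals by 0.5 * ln(n) while leaving every per-region score
#' unchanged.
#'
#' @param measurements data.frame with columns \code{perimeter} and
#'   \code{area} (one row per region), e.g. from
#'   \code{\link{measureClass}}.
#' @param imageId,classLabel identifiers stored in the result.
#' @return an \linkS4class{MPPResult}.
#' @examples
#' two <- data.frame(perimeter = c(2 * pi, 2 * pi), area = c(pi, pi))
#' mppValue(aggregateMPP(two))  # 0.5 * log(2)
#' @export
aggregateMPP <- function(measurements, imageId = NA_character_,
                         classLabel = NA_character_) {
  if (is.null(measurements) || nrow(measurements) == 0)
    stop("empty input: no regions to aggregate")
  P <- sum(measurements$perimeter)
  A <- sum(measurements$area)
  pp <- polsbyPopper(P, A)
  new("MPPResult", imageId = as.character(imageId),
      classLabel = as.character(classLabel),
      totalPerimeter = P, totalArea = A,
      nRegions = nrow(measurements), pp = pp, mpp = -0.5 * log(pp))
}

#' Computer-assisted stromal ratio
#'
#' Percentage of stroma within the (stroma + tumor) compartment area:
#' 100 * stroma / (stroma + tumor).
#'
#' @param stromaArea stromal compartment area, square micrometres (>= 0).
#' @param tumorArea tumor compartment area, square micrometres (>= 0).
#' @return list with \code{percent_stroma}, \code{stroma_area},
#'   \code{tumor_area}.
#' @examples
#' stromalRatio(30, 70)$percent_stroma  # 30
#' @export
stromalRatio <- function(stromaArea, tumorArea) {
  if (stromaArea < 0 || tumorArea < 0)
    stop("areas must be non-negative")
  if (stromaArea + tumorArea <= 0)
    stop("stroma + tumor area must be positive")
  list(percent_stroma = 100 * stromaArea / (stromaArea + tumorArea),
       stroma_area = stromaArea, tumor_area = tumorArea)
}

#' Score one class of an image end to end
#'
#' Convenience wrapper: measure all regions of a class (mask or annotation
#' set), apply the minimum-area filter, and aggregate to an
#' \linkS4class{MPPResult}.
#'
#' @inheritParams measureClass
#' @param imageId identifier stored in the result.
#' @return an \linkS4class{MPPResult}.
#' @export
scoreClass <- function(x, classLabel, minArea = 0, sigma = NULL,
                       imageId = NA_character_) {
  m <- measureClass(x, classLabel, minArea = minArea, sigma = sigma)
  aggregateMPP(m, imageId = imageId, classLabel = classLabel)
}
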