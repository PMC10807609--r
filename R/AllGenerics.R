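#' Accessors for mppscore classes
#'
#' @param object an mppscore S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("labelNames", function(object) standardGeneric("labelNames"))
#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("nSuperpixels", function(object) standardGeneric("nSuperpixels"))
#' @rdname accessors
#' @export
setGeneric("ppScore", function(object) standardGeneric("ppScore"))
#' @rdname accessors
#' @export
setGeneric("mppValue", function(object) standardGeneric("mppValue"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "LabeledMask", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "AnnotationSet", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SuperpixelMap", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("labelImage", "LabeledMask", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("labelImage", "SuperpixelMap", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("labelNames", "LabeledMask", function(object) object@labelNames)
#' @rdname accessors
#' @export
setMethod("regions", "AnnotationSet", function(object) object@regions)
#' @rdname accessors
#' @export
setMethod("classLabels", "AnnotationSet", function(object)
  vapply(object@regions, function(r) r@classLabel, character(1)))
#' @rdname accessors
#' @export
setMethod("classLabels", "PolygonRegion", function(object) object@classLabel)
#' @rdname accessors
#' @export
setMethod("nSuperpixels", "SuperpixelMap", function(object) object@K)
#' @rdname accessors
#' @export
setMethod("ppScore", "MPPResult", function(object) object@pp)
#' @rdname accessors
#' @export
setMethod("mppValue", "MPPResult", function(object) object@mpp)

#' @rdname accessors
#' @param x an \linkS4class{AnnotationSet}.
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@regions))

setMethod("show", "PolygonRegion", function(object) {
  cat(sprintf("PolygonRegion [%s]: %d outer vertices, %d hole(s)\n",
              object@classLabel, nrow(dedupeRing(object@outer)),
              length(object@holes)))
})

setMethod("show", "LabeledMask", function(object) {
  labs <- setdiff(sort(unique(as.vector(object@labels))), 0L)
  cat(sprintf("LabeledMask: %d x %d px, pixel size %g um, %d label(s)\n",
              nrow(object@labels), ncol(object@labels), object@pixelSize,
              length(labs)))
  if (length(object@labelNames))
    cat("  classes:", paste(sprintf("%s=%s", names(object@labelNames),
                                    object@labelNames), collapse = ", "), "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cl <- table(classLabels(object))
  cat(sprintf("AnnotationSet '%s': %d region(s)\n", object@imageId,
              length(object@regions)))
  if (length(cl))
    cat("  ", paste(sprintf("%s: %d", names(cl), cl), collapse = ", "), "\n")
})

setMethod("show", "SuperpixelMap", function(object) {
  cat(sprintf("SuperpixelMap: %d x %d px, K = %d, spacing %g um (seed %d)\n",
              nrow(object@labels), ncol(object@labels), object@K,
              object@spacing, object@seed))
})

setMethod("show", "MPPResult", function(object) {
  cat(sprintf("MPPResult '%s' class '%s'\n", object@imageId, object@classLabel))
  cat(sprintf("  n regions       : %d\n", object@nRegions))
  cat(sprintf("  total perimeter : %.2f um\n", object@totalPerimeter))
  cat(sprintf("  total area      : %.2f um^2\n", object@totalArea))
  cat(sprintf("  PP  = %.4f\n  MPP = %.4f\n", object@pp, object@mpp))
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve: %d time points, median %s (95%% CI %s-%s)\n",
              length(object@time),
              formatC(object@median, digits = 4),
              formatC(object@medianCI[1], digits = 4),
              formatC(object@medianCI[2], digits = 4)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n  statistic = %.4g, df = %s, p = %.4g\n", object@method,
              object@statistic,
              paste(formatC(object@df, digits = 4), collapse = ", "),
              object@p))
  if (length(object@effectSize))
    cat("  effect size:", paste(sprintf("%s = %.4g", names(object@effectSize),
                                        object@effectSize), collapse = ", "),
        "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d cases, pooled MPP-thickness r = %.3f (latent %.3f)\n",
              object@nCases, object@rho, object@latentRho))
  print(object@groups, row.names = FALSE)
})
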