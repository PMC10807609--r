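#' Read classified polygon annotations from GeoJSON
#'
#' Parses the GeoJSON FeatureCollection dialect exported by digital
#' pathology viewers: each Feature carries a Polygon or MultiPolygon
#' geometry plus a classification name in
#' \code{properties$classification$name} (or a plain \code{properties$class}
#' fallback).  MultiPolygons are split into one region per part; ring
#' orientation is normalized on load (outer counter-clockwise in the
#' y-down image convention, holes clockwise).  Coordinates are interpreted
#' in pixel units and scaled by \code{pixelSize}; a
#' \code{pixel_size_um} member at the top level or in feature properties
#' overrides the argument.
#'
#' @param path GeoJSON file.
#' @param pixelSize micrometres per pixel used to scale coordinates.
#' @return an \linkS4class{AnnotationSet}; features without a
#'   classification are skipped with one warning giving the count.
#' @export
readAnnotations <- function(path, pixelSize = 1) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("parse error: ", conditionMessage(e)))
  if (!identical(gj$type, "FeatureCollection"))
    stop("parse error: not a GeoJSON FeatureCollection")
  if (!is.null(gj$pixel_size_um)) pixelSize <- as.numeric(gj$pixel_size_um)
  skipped <- 0L
  regs <- list()
  ringMat <- function(r)
    do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
  for (ft in gj$features) {
    cls <- ft$properties$classification$name %||% ft$properties$class
    if (is.null(cls)) { skipped <- skipped + 1L; next }
    if (!is.null(ft$properties$pixel_size_um))
      pixelSize <- as.numeric(ft$properties$pixel_size_um)
    geom <- ft$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop(sprintf("unsupported geometry type '%s'", geom$type)))
    for (poly in polys) {
      rings <- lapply(poly, ringMat)
      rings <- lapply(rings, function(r) orientRing(r * pixelSize))
      outer <- rings[[1]]
      holes <- if (length(rings) > 1)
        lapply(rings[-1], function(r) r[rev(seq_len(nrow(r))), , drop = FALSE])
      else list()
      regs[[length(regs) + 1L]] <-
        PolygonRegion(outer, holes, classLabel = as.character(cls))
    }
  }
  if (skipped > 0)
    warning(sprintf("%d feature(s) without classification skipped", skipped))
  AnnotationSet(regions = regs, pixelSize = pixelSize,
                imageId = sub("\\.[^.]+$", "", basename(path)))
}

# Normalize a ring to counter-clockwise order in the y-down convention
# (negative shoelace sign under the usual formula).
orientRing <- function(r) {
  r <- dedupeRing(r)
  if (shoelace(r) > 0) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
  r
}

#' Write an annotation set as GeoJSON
#'
#' Inverse of \code{\link{readAnnotations}}: polygons are stored in pixel
#' units with the pixel size carried at the top level, classes in
#' \code{properties$classification$name}.  The y-down image coordinate
#' convention is recorded in the collection's \code{description} member.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  ps <- annotations@pixelSize
  closeRing <- function(r) rbind(r, r[1, , drop = FALSE])
  toCoords <- function(r)
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1] / ps, r[i, 2] / ps))
  feats <- lapply(annotations@regions, function(reg) {
    rings <- c(list(dedupeRing(reg@outer)), lapply(reg@holes, dedupeRing))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = lapply(rings, function(r)
                           toCoords(closeRing(r)))),
         properties = list(classification = list(name = reg@classLabel)))
  })
  gj <- list(type = "FeatureCollection",
             description = "image coordinates: x right, y down, origin top-left; coordinates in pixels",
             pixel_size_um = ps,
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labeled mask from a PNG or TIFF file
#'
#' Integer label images stored as 8-bit PNG (labels 0..255) or as TIFF
#' (read with the sample values as stored).  Non-integer pixel data is a
#' type error.
#'
#' @param path image file (.png or .tif/.tiff).
#' @param pixelSize micrometres per pixel (> 0).
#' @param labelNames optional named character vector mapping labels to
#'   class names.
#' @return a \linkS4class{LabeledMask}.
#' @export
readMask <- function(path, pixelSize = 1, labelNames = character()) {
  if (pixelSize <= 0) stop("config error: pixelSize must be positive")
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop(sprintf("unsupported mask format '%s'", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  # readers normalize to [0, 1]; recover integer labels from the 8- or
  # 16-bit scale, rejecting genuinely non-integer (e.g. float) pixel data
  vals <- NULL
  for (scale in c(255, 65535)) {
    v <- img * scale
    if (max(abs(v - round(v))) < 1e-3) { vals <- round(v); break }
  }
  if (is.null(vals))
    stop("type error: mask pixels are not integer labels")
  LabeledMask(vals, pixelSize = pixelSize, labelNames = labelNames)
}

#' Write a labeled mask to PNG or TIFF
#'
#' @param mask a \linkS4class{LabeledMask} with labels in 0..255.
#' @param path output file (.png or .tif/.tiff).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabeledMask"))
  m <- mask@labels
  if (max(m) > 255) stop("labels above 255 are not supported by the 8-bit writers")
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") png::writePNG(m / 255, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  else stop(sprintf("unsupported mask format '%s'", ext))
  invisible(path)
}

#' Write an RGB image to PNG
#'
#' @param image h x w x 3 array in [0, 1].
#' @param path output PNG file.
#' @return the path, invisibly.
#' @export
writeImage <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Write a schema-versioned JSON report
#'
#' Serializes scoring or analysis results as JSON with full numeric
#' precision and a schema version so downstream tooling can evolve.
#'
#' @param results a named list (or an \linkS4class{MPPResult}).
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeReport <- function(results, path) {
  if (is(results, "MPPResult"))
    results <- list(image_id = results@imageId, class = results@classLabel,
                    n_regions = results@nRegions,
                    total_perimeter_um = results@totalPerimeter,
                    total_area_um2 = results@totalArea,
                    pp = results@pp, mpp = results@mpp)
  payload <- list(schema_version = "1.0", generated_by = "mppscore",
                  results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a schema-versioned JSON report
#'
#' @param path JSON file written by \code{\link{writeReport}}.
#' @return the \code{results} element.
#' @export
readReport <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  payload$results
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param path CSV path.
#' @return the path (write) or the cohort data.frame (read).
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
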