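# Raster I/O. All scanner-export products are 8-bit TIFF or PNG; region
# label maps are 16-bit TIFF with a JSON name-table sidecar. Physical
# calibration is always supplied by the caller (default 2 um/px for
# ULM-derived rasters), never read from file metadata.

rasterFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else stop(sprintf("unsupported raster extension '%s' (use tif/tiff/png)", ext))
}

#' Read an 8-bit scanner-export raster
#'
#' Greyscale files are accepted for the `density` and `speed` modalities,
#' 3-channel RGB for `directional`; anything else (16-bit input, wrong
#' channel count) is a format error.
#'
#' @param path TIFF or PNG file
#' @param modality `"density"`, `"speed"` or `"directional"`
#' @param pixelSizeUm micrometres per pixel (default 2)
#' @return an [IntensityMap-class]
#' @export
readRasterMap <- function(path, modality = c("density", "speed", "directional"),
                          pixelSizeUm = 2) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  fmt <- rasterFormat(path)
  if (fmt == "tiff") {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (is.double(raw)) {
      # multi-channel reads come back as normalized floats; x/255 is exact
      # for 8-bit samples, so scaling back loses nothing
      norm <- tiff::readTIFF(path)
      raw <- round(norm * 255)
    }
    if (max(raw) > 255) stop("not an 8-bit raster (16-bit input?)")
  } else {
    norm <- png::readPNG(path)
    raw <- round(norm * 255)
  }
  nd <- length(dim(raw))
  if (modality == "directional") {
    if (nd != 3L || dim(raw)[3] < 3L)
      stop("directional maps must be RGB; got a greyscale raster")
    raw <- raw[, , 1:3, drop = FALSE]
  } else {
    if (nd == 3L) stop(sprintf("%s maps must be greyscale; got %d channels",
                               modality, dim(raw)[3]))
  }
  intensityMap(raw, modality, pixelSizeUm)
}

#' Write an 8-bit raster
#'
#' @param map an [IntensityMap-class]
#' @param path output TIFF or PNG path (by extension)
#' @return `path`, invisibly
#' @export
writeRasterMap <- function(map, path) {
  stopifnot(is(map, "IntensityMap"))
  v <- mapValues(map) / 255
  if (rasterFormat(path) == "tiff") tiff::writeTIFF(v, path, bits.per.sample = 8L)
  else png::writePNG(v, path)
  invisible(path)
}

#' Write a calibrated floating-point map (thickness or flow)
#'
#' Values are stored as 32-bit float TIFF scaled into [0, 1] by the recorded
#' maximum; the scale, pixel size and unit go in a JSON sidecar
#' (`<path>.json`). Round trip is exact to float32 precision (~1e-7
#' relative).
#'
#' @param map a [ThicknessMap-class] or [FlowMap-class]
#' @param path output TIFF path
#' @param unit unit string recorded in the sidecar
#' @return `path`, invisibly
#' @export
writeFloatMap <- function(map, path, unit = if (is(map, "FlowMap")) "mL/min" else "um") {
  v <- mapValues(map)
  scale <- max(v, 1e-300)
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, pixelSizeUm = pixelSize(map),
                            unit = unit, class = class(map)[1]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a floating-point map written by [writeFloatMap()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist)
#' @return the matrix of physical values with `pixelSizeUm` and `unit`
#'   attributes
#' @export
readFloatMap <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * meta$scale
  structure(v, pixelSizeUm = meta$pixelSizeUm, unit = meta$unit)
}

#' Write a RegionSet as 16-bit label TIFF plus JSON name table
#'
#' @param regions a [RegionSet-class]
#' @param tifPath output label TIFF
#' @param jsonPath output JSON name table (default `<tifPath>.json`)
#' @return `tifPath`, invisibly
#' @export
writeRegionSet <- function(regions, tifPath, jsonPath = paste0(tifPath, ".json")) {
  tiff::writeTIFF(mapValues(regions) / 65535, tifPath, bits.per.sample = 16L)
  jsonlite::write_json(list(pixelSizeUm = pixelSize(regions),
                            nameTable = as.list(regions@nameTable)),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(tifPath)
}

#' Read a RegionSet written by [writeRegionSet()]
#'
#' @param tifPath label TIFF
#' @param jsonPath JSON name table (default `<tifPath>.json`)
#' @param pixelSizeUm override calibration; default uses the sidecar value
#' @return a [RegionSet-class]
#' @export
readRegionSet <- function(tifPath, jsonPath = paste0(tifPath, ".json"),
                          pixelSizeUm = NULL) {
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  labels <- tiff::readTIFF(tifPath, as.is = TRUE)
  storage.mode(labels) <- "integer"
  tab <- unlist(meta$nameTable)
  storage.mode(tab) <- "integer"
  new("RegionSet", labels = labels, nameTable = tab,
      pixelSizeUm = if (is.null(pixelSizeUm)) meta$pixelSizeUm else pixelSizeUm)
}

#' Logical mask of one named region
#'
#' `whole_brain` selects every labeled pixel and is always a superset of the
#' named regions.
#'
#' @param regions a [RegionSet-class]
#' @param name region name
#' @return logical matrix
#' @export
regionMask <- function(regions, name) {
  if (name == "whole_brain") return(mapValues(regions) > 0L)
  if (!name %in% names(regions@nameTable))
    stop(sprintf("unknown region '%s'; available: %s", name,
                 paste(regionNames(regions), collapse = ", ")))
  mapValues(regions) == regions@nameTable[[name]]
}

#' Select the pixel values of a map inside a named region
#'
#' @param x a map-like object (any [PixelMap-class] subclass)
#' @param regions a [RegionSet-class] of the same grid shape
#' @param name region name (see [regionNames()])
#' @return vector of pixel values inside the region (channel-wise columns for
#'   RGB maps)
#' @export
selectRegion <- function(x, regions, name) {
  v <- mapValues(x)
  sel <- regionMask(regions, name)
  if (length(dim(v)) == 3L) {
    if (!identical(dim(v)[1:2], dim(sel))) stop("shape mismatch between map and regions")
    return(cbind(r = v[, , 1][sel], g = v[, , 2][sel], b = v[, , 3][sel]))
  }
  if (!identical(dim(v), dim(sel))) stop("shape mismatch between map and regions")
  v[sel]
}
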