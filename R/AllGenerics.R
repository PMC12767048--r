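#' @useDynLib VasculoMap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Extract the pixel grid of a map object
#'
#' @param x a map-like object (an [IntensityMap-class], [BinaryMask-class],
#'   [ThicknessMap-class], [SpeedMap-class], [FlowMap-class],
#'   [DirectionalMap-class] or [RegionSet-class])
#' @return the underlying matrix (or, for RGB maps, a rows x cols x 3 array)
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Physical pixel size of a map object
#'
#' @param x a map-like object
#' @return pixel edge length in micrometres
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Modality of an intensity map
#'
#' @param x an [IntensityMap-class]
#' @return one of `"density"`, `"speed"`, `"directional"`
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Region names of a RegionSet
#'
#' @param x a [RegionSet-class]
#' @return character vector of region names (including the implicit
#'   `whole_brain` region)
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
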