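# Vascular coverage: binarize the density export and count vessel-positive
# pixels per region.

#' Binarize a density map
#'
#' Every pixel at or above the threshold becomes foreground. The default
#' threshold of 1 turns every nonzero ("colored") pixel into vessel signal,
#' the same rule as converting each colored pixel to white; it is exposed for
#' sensitivity analysis. No morphological cleanup is applied.
#'
#' @param map an [IntensityMap-class] with modality `"density"`
#' @param threshold minimum intensity counted as vessel (default 1)
#' @return a [BinaryMask-class]
#' @export
binarize <- function(map, threshold = 1) {
  stopifnot(is(map, "IntensityMap"))
  if (modality(map) != "density")
    stop(sprintf("binarize expects a density map, got '%s'", modality(map)))
  binaryMask(mapValues(map) >= threshold, pixelSize(map))
}

#' Regional vascular coverage
#'
#' The percentage of vessel-positive pixels in a region — the vascular
#' density ratio.
#'
#' @param mask a [BinaryMask-class]
#' @param regions a [RegionSet-class] on the same grid
#' @param name region name (default `"whole_brain"`)
#' @return coverage in percent, in [0, 100]
#' @export
coverage <- function(mask, regions, name = "whole_brain") {
  stopifnot(is(mask, "BinaryMask"))
  sel <- regionMask(regions, name)
  if (!identical(dim(sel), dim(mapValues(mask))))
    stop("shape mismatch between mask and regions")
  n <- sum(sel)
  if (n == 0L) stop(sprintf("region '%s' is empty: coverage undefined", name))
  100 * sum(mapValues(mask)[sel]) / n
}
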