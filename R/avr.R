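# Arteriole-to-venule ratio from the RGB axial-direction export. The flow
# direction is resolved along the image's vertical axis only; in the cortex
# this aligns with penetrating arterioles (descending, red) and ascending
# venules (blue), so the analysis is restricted to a cortical region by
# default.

#' Classify pixels as arteriole / venule / none from an RGB direction map
#'
#' Channel-split rule: a pixel is an arteriole if its red channel exceeds its
#' blue channel (and red > 0), a venule if blue exceeds red (and blue > 0),
#' and none otherwise — including exact red/blue ties, which are left
#' unclassified rather than split fractionally.
#'
#' @param map an [IntensityMap-class] with modality `"directional"`
#' @return a [DirectionalMap-class] (0 none, 1 arteriole, 2 venule)
#' @export
classifyDirection <- function(map) {
  stopifnot(is(map, "IntensityMap"))
  if (modality(map) != "directional")
    stop(sprintf("classifyDirection expects a directional map, got '%s'",
                 modality(map)))
  v <- mapValues(map)
  r <- v[, , 1]; b <- v[, , 3]
  cls <- matrix(0L, nrow(r), ncol(r))
  cls[r > b & r > 0] <- 1L
  cls[b > r & b > 0] <- 2L
  new("DirectionalMap", values = cls, pixelSizeUm = pixelSize(map))
}

#' Cortical arteriole-to-venule ratio
#'
#' Counts arteriole and venule pixels in a region and reports the AVR (the
#' arteriole:venule pixel-count ratio) together with each class as a
#' percentage of the total classified vasculature, so either reading of the
#' biomarker can be reproduced.
#'
#' @param dmap a [DirectionalMap-class]
#' @param regions a [RegionSet-class]
#' @param name region name (default `"cortex"`)
#' @return an [AvrResult-class]; errors if the region holds no venule pixels
#'   (the ratio would be undefined)
#' @export
computeAvr <- function(dmap, regions, name = "cortex") {
  stopifnot(is(dmap, "DirectionalMap"))
  sel <- regionMask(regions, name)
  if (!identical(dim(sel), dim(mapValues(dmap))))
    stop("shape mismatch between directional map and regions")
  cls <- mapValues(dmap)[sel]
  nArt <- sum(cls == 1L); nVen <- sum(cls == 2L)
  if (nVen == 0L) stop("no venule pixels in region: AVR undefined")
  tot <- nArt + nVen
  new("AvrResult", arteriolePixels = nArt, venulePixels = nVen,
      totalVascularPixels = tot, avr = nArt / nVen,
      arteriolePctOfTotal = 100 * nArt / tot,
      venulePctOfTotal = 100 * nVen / tot)
}
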