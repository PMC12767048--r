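# Speed decoding and Poiseuille-derived volumetric flow:
# Q = v * A * K = v * pi * r^2 * K, with v in mm/s, r in um and K the unit
# conversion into mL/min.

#' Derive the flow unit-conversion constant from dimensional analysis
#'
#' With v in mm/s and r in um, v * pi * r^2 has units mm/s * um^2
#' = 1e-3 m/s * 1e-12 m^2 = 1e-15 m^3/s = 1e-9 mL/s = 6e-8 mL/min.
#' So K = 6e-8 converts v * pi * r^2 into mL/min.
#'
#' @return the constant K in mL/min per (mm/s * um^2)
#' @export
deriveFlowConstant <- function() {
  mPerMm <- 1e-3; mPerUm <- 1e-6
  m3PerMl <- 1e-6
  sPerMin <- 60
  (mPerMm * mPerUm^2) / m3PerMl * sPerMin
}

#' Derive the greyscale-to-velocity divisor
#'
#' The 8-bit full scale (255) encodes the 0-100 mm/s velocity range, so
#' intensities are divided by 255/100 = 2.55 to decode mm/s.
#'
#' @param maxIntensity full-scale intensity (255)
#' @param maxSpeedMmS full-scale velocity (100 mm/s)
#' @return the divisor (2.55)
#' @export
deriveGreyDivisor <- function(maxIntensity = 255, maxSpeedMmS = 100) {
  maxIntensity / maxSpeedMmS
}

#' Flow-model parameters
#'
#' @param K unit-conversion constant (default 6e-8, mL/min per mm/s um^2)
#' @param maxSpeedMmS full-scale velocity (100 mm/s)
#' @param greyDivisor 8-bit-to-velocity divisor; must equal
#'   255 / maxSpeedMmS (2.55)
#' @param floorRadiusUm reliability floor radius for the thickness filter
#' @return a `FlowModelParams` list
#' @export
flowModelParams <- function(K = 6e-8, maxSpeedMmS = 100,
                            greyDivisor = 255 / maxSpeedMmS,
                            floorRadiusUm = 5) {
  if (K <= 0) stop("K must be positive")
  if (abs(greyDivisor - 255 / maxSpeedMmS) > 1e-12)
    stop("greyDivisor must equal 255 / maxSpeedMmS")
  structure(list(K = K, maxSpeedMmS = maxSpeedMmS, greyDivisor = greyDivisor,
                 floorRadiusUm = floorRadiusUm), class = "FlowModelParams")
}

#' Decode an 8-bit speed export to mm/s
#'
#' Intensities are divided by the grey divisor (2.55), mapping 0..255 onto
#' 0..100 mm/s; decoded values are clipped defensively to that range.
#'
#' @param map an [IntensityMap-class] with modality `"speed"`
#' @param params a [flowModelParams()] list
#' @return a [SpeedMap-class]
#' @export
decodeSpeed <- function(map, params = flowModelParams()) {
  stopifnot(is(map, "IntensityMap"))
  if (modality(map) != "speed")
    stop(sprintf("decodeSpeed expects a speed map, got '%s'", modality(map)))
  v <- mapValues(map) / params$greyDivisor
  v <- matrix(pmin(params$maxSpeedMmS, pmax(0, v)), nrow(v), ncol(v))
  new("SpeedMap", values = v, pixelSizeUm = pixelSize(map))
}

#' Poiseuille-derived volumetric flow for scalar inputs
#'
#' Q = v * pi * (d/2)^2 * K in mL/min.
#'
#' @param velocityMmS velocity in mm/s (>= 0)
#' @param diameterUm vessel diameter in um (>= 0)
#' @param params a [flowModelParams()] list
#' @return flow in mL/min (vectorized)
#' @export
flowRate <- function(velocityMmS, diameterUm, params = flowModelParams()) {
  if (any(velocityMmS < 0) || any(diameterUm < 0))
    stop("velocity and diameter must be >= 0")
  velocityMmS * pi * (diameterUm / 2)^2 * params$K
}

#' Per-pixel flow map from speed and local thickness
#'
#' Fuses the decoded speed map with the local-thickness diameter map
#' pixel-by-pixel: Q(p) = v(p) * pi * (d(p)/2)^2 * K. Pixels flagged by the
#' reliability floor contribute 0 when the filter is enabled.
#'
#' @param speed a [SpeedMap-class]
#' @param tmap a [ThicknessMap-class] on the same grid and calibration
#' @param params a [flowModelParams()] list
#' @param useFloor zero out pixels flagged below the reliability floor
#'   (default TRUE; flags must have been set with [applyReliabilityFloor()])
#' @return a [FlowMap-class] in mL/min
#' @export
flowRateMap <- function(speed, tmap, params = flowModelParams(),
                        useFloor = TRUE) {
  stopifnot(is(speed, "SpeedMap"), is(tmap, "ThicknessMap"))
  v <- mapValues(speed); d <- mapValues(tmap)
  if (!identical(dim(v), dim(d))) stop("speed and thickness grids differ in shape")
  if (abs(pixelSize(speed) - pixelSize(tmap)) > 1e-9)
    stop("speed and thickness calibrations differ")
  q <- v * pi * (d / 2)^2 * params$K
  if (useFloor) q[tmap@flagged] <- 0
  new("FlowMap", values = q, pixelSizeUm = pixelSize(speed))
}

#' Regional resting cerebral blood flow
#'
#' The average Q value in the selected region. By default the average runs
#' over vessel-positive, unflagged pixels only (Q is undefined off-vessel);
#' `domain = "all"` averages over every region pixel instead, which makes
#' the metric density-weighted.
#'
#' @param fmap a [FlowMap-class]
#' @param mask the [BinaryMask-class] defining vessel pixels
#' @param regions a [RegionSet-class]
#' @param name region name
#' @param domain `"vessel"` (default) or `"all"`
#' @param tmap optional [ThicknessMap-class] whose flags exclude unreliable
#'   pixels from the average
#' @return mean Q in mL/min
#' @export
regionalCbf <- function(fmap, mask, regions, name,
                        domain = c("vessel", "all"), tmap = NULL) {
  domain <- match.arg(domain)
  sel <- regionMask(regions, name)
  q <- mapValues(fmap)
  if (!identical(dim(sel), dim(q))) stop("shape mismatch between flow map and regions")
  keep <- if (domain == "vessel") sel & mapValues(mask) else sel
  if (!is.null(tmap)) keep <- keep & !tmap@flagged
  if (!any(keep)) stop(sprintf("no eligible pixels in region '%s'", name))
  mean(q[keep])
}

#' Regional velocity distribution
#'
#' @param speed a [SpeedMap-class]
#' @param mask vessel [BinaryMask-class]
#' @param regions a [RegionSet-class]
#' @param name region name
#' @param binWidthMmS bin width in mm/s (default 2)
#' @return relative-frequency histogram data frame (see
#'   [diameterDistribution()] for the columns)
#' @export
speedDistribution <- function(speed, mask, regions, name, binWidthMmS = 2) {
  sel <- regionMask(regions, name) & mapValues(mask)
  h <- buildHistogram(mapValues(speed)[sel], binWidthMmS)
  attr(h, "n") <- sum(sel)
  h
}

#' Regional flow distribution (logarithmic bins)
#'
#' Q spans orders of magnitude across vessel diameters, so bins are
#' logarithmic in Q; zero-flow pixels are excluded.
#'
#' @param fmap a [FlowMap-class]
#' @param mask vessel [BinaryMask-class]
#' @param regions a [RegionSet-class]
#' @param name region name
#' @param binsPerDecade log10 bins per decade (default 4)
#' @return relative-frequency histogram data frame, edges in mL/min
#' @export
flowDistribution <- function(fmap, mask, regions, name, binsPerDecade = 4) {
  sel <- regionMask(regions, name) & mapValues(mask)
  q <- mapValues(fmap)[sel]
  q <- q[q > 0]
  h <- buildHistogram(log10(q), 1 / binsPerDecade)
  h$binLower <- 10^h$binLower; h$binUpper <- 10^h$binUpper
  attr(h, "n") <- length(q)
  h
}
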