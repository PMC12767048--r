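# Central data containers. All raster classes carry their physical
# calibration (micrometres per pixel) so every downstream quantity is
# reported in physical units.

#' @include AllGenerics.R
NULL

setClassUnion("matrixOrArray", c("matrix", "array"))

#' PixelMap: virtual base for calibrated rasters
#'
#' Every raster product carries a `pixelSizeUm` calibration; the default for
#' ULM-derived exports is 2 um/pixel. Calibration is supplied explicitly,
#' never inferred from file metadata.
#'
#' @slot values the pixel grid
#' @slot pixelSizeUm micrometres per pixel edge (> 0)
#' @export
setClass("PixelMap",
  representation("VIRTUAL", values = "matrixOrArray", pixelSizeUm = "numeric"))

setValidity("PixelMap", function(object) {
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' IntensityMap: an 8-bit scanner-export raster
#'
#' The common currency of the exported modalities: a vascular density map
#' (greyscale), a speed map (greyscale, 0-255 encoding 0-100 mm/s) or an
#' axial-direction map (RGB; red = descending flow, blue = ascending).
#'
#' @slot values greyscale matrix or rows x cols x 3 RGB array, integer values
#'   in 0..255
#' @slot pixelSizeUm micrometres per pixel
#' @slot modality `"density"`, `"speed"` or `"directional"`
#' @seealso [intensityMap()], [readRasterMap()], [binarize()], [decodeSpeed()],
#'   [classifyDirection()]
#' @export
setClass("IntensityMap", contains = "PixelMap",
  representation(modality = "character"))

setValidity("IntensityMap", function(object) {
  v <- object@values
  if (!object@modality %in% c("density", "speed", "directional"))
    return("modality must be density, speed or directional")
  if (object@modality == "directional") {
    if (length(dim(v)) != 3L || dim(v)[3] != 3L)
      return("directional maps must be rows x cols x 3 RGB arrays")
  } else if (length(dim(v)) != 2L) {
    return("greyscale maps must be 2-D matrices")
  }
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > 255 || any(v != round(v)))
    return("values must be integers in [0, 255] (8-bit)")
  TRUE
})

#' Construct an IntensityMap
#'
#' @param values greyscale matrix or RGB array with integer values in 0..255
#' @param modality `"density"`, `"speed"` or `"directional"`
#' @param pixelSizeUm micrometres per pixel (default 2, the resolution of the
#'   high-resolution ULM exports)
#' @return an [IntensityMap-class]
#' @export
intensityMap <- function(values, modality, pixelSizeUm = 2) {
  storage.mode(values) <- "integer"
  new("IntensityMap", values = values, modality = modality,
      pixelSizeUm = pixelSizeUm)
}

#' BinaryMask: a binarized vessel map
#'
#' @slot values logical matrix, TRUE = vessel-positive pixel
#' @slot pixelSizeUm micrometres per pixel
#' @seealso [binarize()], [coverage()], [localThickness()]
#' @export
setClass("BinaryMask", contains = "PixelMap")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@values) || length(dim(object@values)) != 2L)
    return("values must be a logical matrix")
  TRUE
})

#' Construct a BinaryMask
#' @param values logical matrix
#' @param pixelSizeUm micrometres per pixel
#' @return a [BinaryMask-class]
#' @export
binaryMask <- function(values, pixelSizeUm = 2) {
  new("BinaryMask", values = values, pixelSizeUm = pixelSizeUm)
}

#' ThicknessMap: per-pixel vessel diameter in micrometres
#'
#' Produced by the local-thickness transform: each foreground pixel holds the
#' diameter of the largest circle fully inscribed in the vessel mask and
#' covering that pixel; background pixels are 0. The `flagged` slot marks
#' pixels below the reliability floor (diameter < 2 x floor radius), which
#' are excluded from distributions and flow maps when the filter is on but
#' retained in the map itself.
#'
#' @slot values numeric matrix of diameters in um (0 on background)
#' @slot pixelSizeUm micrometres per pixel
#' @slot floorRadiusUm reliability floor radius in um (NA before flagging)
#' @slot flagged logical matrix, TRUE = below the reliability floor
#' @seealso [localThickness()], [applyReliabilityFloor()],
#'   [diameterDistribution()]
#' @export
setClass("ThicknessMap", contains = "PixelMap",
  representation(floorRadiusUm = "numeric", flagged = "matrix"))

setValidity("ThicknessMap", function(object) {
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 2L) return("values must be a numeric matrix")
  if (any(v < 0)) return("thickness values must be >= 0")
  if (!identical(dim(object@flagged), dim(v)))
    return("flagged must have the same shape as values")
  diag_um <- sqrt(sum(dim(v)^2)) * object@pixelSizeUm
  if (max(v) > diag_um + 1e-9) return("thickness exceeds the image diagonal")
  TRUE
})

#' SpeedMap: per-pixel blood velocity in mm/s
#'
#' Decoded from the 8-bit speed export; values span 0-100 mm/s.
#'
#' @slot values numeric matrix of velocities in mm/s
#' @slot pixelSizeUm micrometres per pixel
#' @seealso [decodeSpeed()], [flowRateMap()]
#' @export
setClass("SpeedMap", contains = "PixelMap")

setValidity("SpeedMap", function(object) {
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 2L) return("values must be a numeric matrix")
  if (min(v) < 0 || max(v) > 100) return("velocities must lie in [0, 100] mm/s")
  TRUE
})

#' FlowMap: per-pixel volumetric flow in mL/min
#'
#' Poiseuille-derived flow Q = v * pi * r^2 * K per pixel, fusing the decoded
#' speed map with the local-thickness diameter map.
#'
#' @slot values numeric matrix of Q in mL/min
#' @slot pixelSizeUm micrometres per pixel
#' @seealso [flowRateMap()], [regionalCbf()]
#' @export
setClass("FlowMap", contains = "PixelMap")

setValidity("FlowMap", function(object) {
  if (any(object@values < 0)) return("flow values must be >= 0")
  TRUE
})

#' DirectionalMap: per-pixel arteriole/venule classification
#'
#' Codes: 0 = none, 1 = arteriole (descending axial flow, red channel),
#' 2 = venule (ascending, blue channel).
#'
#' @slot values integer matrix of class codes
#' @slot pixelSizeUm micrometres per pixel
#' @seealso [classifyDirection()], [computeAvr()]
#' @export
setClass("DirectionalMap", contains = "PixelMap")

setValidity("DirectionalMap", function(object) {
  if (!all(object@values %in% 0:2)) return("codes must be 0 (none), 1 (arteriole) or 2 (venule)")
  TRUE
})

#' RegionSet: labeled anatomical regions of interest
#'
#' A label raster plus a name table. Label 0 is unlabeled; `whole_brain` is
#' implicit and equals the union of all labeled pixels (so it is always a
#' superset of every named region).
#'
#' @slot labels integer matrix of region labels (0 = unlabeled)
#' @slot nameTable named integer vector mapping region name -> label
#' @slot pixelSizeUm micrometres per pixel
#' @seealso [makeRegionSet()], [selectRegion()], [regionMask()]
#' @export
setClass("RegionSet",
  representation(labels = "matrix", nameTable = "integer",
                 pixelSizeUm = "numeric"))

setValidity("RegionSet", function(object) {
  if (is.null(names(object@nameTable)) || any(!nzchar(names(object@nameTable))))
    return("nameTable must be a named integer vector")
  if (anyDuplicated(names(object@nameTable)) || anyDuplicated(object@nameTable))
    return("region names and labels must be unique")
  present <- unique(as.vector(object@labels))
  missing <- setdiff(object@nameTable, present)
  if (length(missing))
    return(sprintf("labels named in the table but absent from the grid: %s",
                   paste(missing, collapse = ", ")))
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' VesselSpec: ground-truth description of one phantom vessel
#'
#' A straight constant-width segment (capsule footprint) with a scalar blood
#' velocity and an axial flow direction. Coordinates are planar (x, y) in
#' micrometres; x runs along columns, y along rows, y increasing downward
#' (image convention), so "descending" flow points toward increasing row
#' index — the orientation of cortical penetrating arterioles in a coronal
#' image with the cortical surface at the top.
#'
#' @slot from,to numeric (x, y) endpoints in um
#' @slot widthUm full vessel diameter in um (> 0)
#' @slot velocityMmS scalar velocity in [0, 100] mm/s
#' @slot direction `"descending"` (arteriole-like) or `"ascending"`
#'   (venule-like)
#' @seealso [vesselSpec()], [makeScene()]
#' @export
setClass("VesselSpec",
  representation(from = "numeric", to = "numeric", widthUm = "numeric",
                 velocityMmS = "numeric", direction = "character"))

setValidity("VesselSpec", function(object) {
  if (length(object@from) != 2L || length(object@to) != 2L)
    return("endpoints must be (x, y) pairs in um")
  if (all(object@from == object@to)) return("endpoints must be distinct")
  if (object@widthUm <= 0) return("widthUm must be > 0")
  if (object@velocityMmS < 0 || object@velocityMmS > 100)
    return("velocityMmS must lie in [0, 100]")
  if (!object@direction %in% c("descending", "ascending"))
    return("direction must be descending or ascending")
  TRUE
})

#' Construct a VesselSpec
#'
#' @param from,to numeric (x, y) endpoints in um
#' @param widthUm full diameter in um
#' @param velocityMmS velocity in mm/s (0-100)
#' @param direction `"descending"` or `"ascending"`
#' @return a [VesselSpec-class]
#' @export
vesselSpec <- function(from, to, widthUm, velocityMmS = 10,
                       direction = c("descending", "ascending")) {
  new("VesselSpec", from = as.numeric(from), to = as.numeric(to),
      widthUm = widthUm, velocityMmS = velocityMmS,
      direction = match.arg(direction))
}

#' PhantomScene: a ground-truth vessel scene
#'
#' Holds the vessel specifications plus the raster geometry from which all
#' synthetic scanner exports are rendered, so downstream recovery can be
#' checked against exact truth.
#'
#' @slot vessels list of [VesselSpec-class]
#' @slot gridShape integer (rows, cols) in pixels
#' @slot pixelSizeUm micrometres per pixel
#' @slot seed integer seed recorded with the scene
#' @seealso [makeScene()], [renderDensityMap()], [renderSpeedMap()],
#'   [renderDirectionalMap()]
#' @export
setClass("PhantomScene",
  representation(vessels = "list", gridShape = "integer",
                 pixelSizeUm = "numeric", seed = "integer"))

setValidity("PhantomScene", function(object) {
  if (!length(object@vessels)) return("a scene needs at least one vessel")
  if (!all(vapply(object@vessels, is, logical(1), "VesselSpec")))
    return("vessels must all be VesselSpec objects")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    return("gridShape must be positive (rows, cols)")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  lim <- rev(object@gridShape) * object@pixelSizeUm # (x extent, y extent)
  for (v in object@vessels) {
    r <- v@widthUm / 2
    lo <- pmin(v@from, v@to) - r
    hi <- pmax(v@from, v@to) + r
    if (any(lo < 0) || any(hi > lim))
      return("vessel capsule extends outside the grid")
  }
  TRUE
})

#' StimSchedule: the stimulation protocol of an NVC recording
#'
#' Defaults follow the whisker-stimulation protocol: 30 s baseline, 30 s
#' stimulation, 30 s post-stimulation, repeated 7 times, sampled every 0.2 s
#' (the minimal 200 ms pause between scans).
#'
#' @slot baselineS,stimS,postS window durations in seconds
#' @slot nTrials number of stimulation trials
#' @slot dtS sampling interval in seconds
#' @seealso [stimSchedule()], [simulateNvcTrace()], [segmentTrials()]
#' @export
setClass("StimSchedule",
  representation(baselineS = "numeric", stimS = "numeric", postS = "numeric",
                 nTrials = "integer", dtS = "numeric"))

setValidity("StimSchedule", function(object) {
  if (any(c(object@baselineS, object@stimS, object@postS, object@dtS) <= 0))
    return("durations and dt must be > 0")
  if (object@nTrials < 1L) return("nTrials must be >= 1")
  if (object@dtS > object@stimS) return("dtS must not exceed the stimulation window")
  TRUE
})

#' Construct a StimSchedule
#' @param baselineS,stimS,postS window durations in seconds
#' @param nTrials number of trials
#' @param dtS sampling interval in seconds
#' @return a [StimSchedule-class]
#' @export
stimSchedule <- function(baselineS = 30, stimS = 30, postS = 30,
                         nTrials = 7L, dtS = 0.2) {
  new("StimSchedule", baselineS = baselineS, stimS = stimS, postS = postS,
      nTrials = as.integer(nTrials), dtS = dtS)
}

#' NvcTrace: a relative-CBV time series bound to its stimulation schedule
#'
#' @slot samples numeric vector of relative CBV (arbitrary units; the phantom
#'   baseline is 100 so percent-change math is transparent)
#' @slot schedule the [StimSchedule-class] it was recorded under
#' @slot animalId animal identifier
#' @slot group `"young"` or `"aged"` (or `""` when ungrouped)
#' @seealso [simulateNvcTrace()], [segmentTrials()]
#' @export
setClass("NvcTrace",
  representation(samples = "numeric", schedule = "StimSchedule",
                 animalId = "character", group = "character"))

setValidity("NvcTrace", function(object) {
  sch <- object@schedule
  need <- object@schedule@nTrials *
    round((sch@baselineS + sch@stimS + sch@postS) / sch@dtS)
  if (length(object@samples) < need)
    return(sprintf("trace too short: %d samples, %d needed", length(object@samples), need))
  TRUE
})

#' AvrResult: arteriole-to-venule ratio summary
#'
#' The AVR is the arteriole:venule pixel-count ratio in a region; each class
#' is also reported as a percentage of the total classified vasculature so
#' either reading of the biomarker can be reproduced.
#'
#' @slot arteriolePixels,venulePixels,totalVascularPixels pixel counts
#' @slot avr arteriole/venule count ratio
#' @slot arteriolePctOfTotal,venulePctOfTotal percentages of total classified
#'   vascular pixels
#' @seealso [computeAvr()]
#' @export
setClass("AvrResult",
  representation(arteriolePixels = "integer", venulePixels = "integer",
                 totalVascularPixels = "integer", avr = "numeric",
                 arteriolePctOfTotal = "numeric", venulePctOfTotal = "numeric"))

#' TestResult: a two-group comparison
#'
#' @slot statistic t statistic
#' @slot df degrees of freedom (non-integer for Welch)
#' @slot pValue two-sided p-value
#' @slot method `"student"` or `"welch"`
#' @slot groupNames,groupMeans,groupSems,nPerGroup per-group summaries
#' @slot stars significance stars at the 0.05/0.005/0.001/0.0001 thresholds
#' @seealso [studentT()], [welchT()], [compareMetric()]
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character", groupNames = "character",
                 groupMeans = "numeric", groupSems = "numeric",
                 nPerGroup = "integer", stars = "character"))

setValidity("TestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must lie in [0, 1]")
  if (object@df <= 0) return("df must be > 0")
  if (!object@method %in% c("student", "welch")) return("method must be student or welch")
  TRUE
})

# ---- accessors ----

#' @rdname mapValues
#' @export
setMethod("mapValues", "PixelMap", function(x) x@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "RegionSet", function(x) x@labels)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PixelMap", function(x) x@pixelSizeUm)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "RegionSet", function(x) x@pixelSizeUm)

#' @rdname modality
#' @export
setMethod("modality", "IntensityMap", function(x) x@modality)

#' @rdname regionNames
#' @export
setMethod("regionNames", "RegionSet",
  function(x) unique(c(names(x@nameTable), "whole_brain")))

# ---- show methods ----

setMethod("show", "IntensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityMap [%s]: %d x %d px @ %g um/px\n",
              object@modality, d[1], d[2], object@pixelSizeUm))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask: %d x %d px @ %g um/px, %.2f%% foreground\n",
              d[1], d[2], object@pixelSizeUm, 100 * mean(object@values)))
})

setMethod("show", "ThicknessMap", function(object) {
  fg <- object@values[object@values > 0]
  cat(sprintf("ThicknessMap: %d x %d px @ %g um/px\n",
              nrow(object@values), ncol(object@values), object@pixelSizeUm))
  if (length(fg))
    cat(sprintf("  foreground diameters: median %.1f um, max %.1f um; %d px flagged\n",
                stats::median(fg), max(fg), sum(object@flagged)))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d x %d px @ %g um/px\n",
              nrow(object@labels), ncol(object@labels), object@pixelSizeUm))
  for (nm in names(object@nameTable))
    cat(sprintf("  %-14s label %d: %d px\n", nm, object@nameTable[[nm]],
                sum(object@labels == object@nameTable[[nm]])))
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene: %d vessels on %d x %d px @ %g um/px (seed %d)\n",
              length(object@vessels), object@gridShape[1], object@gridShape[2],
              object@pixelSizeUm, object@seed))
})

setMethod("show", "NvcTrace", function(object) {
  sch <- object@schedule
  cat(sprintf("NvcTrace [%s%s]: %d samples @ %g s, %d trials of %g s\n",
              object@animalId, if (nzchar(object@group)) paste0(", ", object@group) else "",
              length(object@samples), sch@dtS, sch@nTrials,
              sch@baselineS + sch@stimS + sch@postS))
})

setMethod("show", "AvrResult", function(object) {
  cat(sprintf("AVR = %.3f (%d arteriole px [%.1f%%], %d venule px [%.1f%%], %d vascular px)\n",
              object@avr, object@arteriolePixels, object@arteriolePctOfTotal,
              object@venulePixels, object@venulePctOfTotal,
              object@totalVascularPixels))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g %s\n",
              if (object@method == "student") "Student's (pooled)" else "Welch's",
              object@statistic, object@df, object@pValue, object@stars))
  for (i in seq_along(object@groupNames))
    cat(sprintf("  %-8s mean %.4g +/- %.4g SEM (n = %d)\n",
                object@groupNames[i], object@groupMeans[i],
                object@groupSems[i], object@nPerGroup[i]))
})
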