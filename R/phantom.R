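# Synthetic scanner-export generator. Every downstream stage of the package
# is validated by recovery against the ground truth recorded here.

#' Derive a stream-specific seed from the master seed
#'
#' All randomness in the phantom module flows from one integer master seed.
#' Sub-streams (per animal, per modality) use the documented splitting rule
#' `(seed * 48271 + k * 1009) mod (2^31 - 1)`, a multiplicative-congruential
#' jump that keeps derived seeds distinct, reproducible and below 2^31.
#'
#' @param seed master integer seed
#' @param k stream index (>= 0)
#' @return derived integer seed
#' @export
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 1009) %% 2147483647)
}

#' Assemble a phantom scene from vessel specifications
#'
#' @param vessels list of [VesselSpec-class] (nonempty)
#' @param gridShape integer (rows, cols) of the raster grid in pixels
#' @param pixelSizeUm micrometres per pixel (default 2)
#' @param seed integer seed recorded with the scene
#' @return a [PhantomScene-class]; errors if any vessel capsule extends
#'   outside the grid
#' @examples
#' v <- vesselSpec(c(100, 256), c(412, 256), widthUm = 20, velocityMmS = 10)
#' makeScene(list(v), gridShape = c(256, 256))
#' @export
makeScene <- function(vessels, gridShape, pixelSizeUm = 2, seed = 1L) {
  if (!length(vessels)) stop("vessels must be a nonempty list of VesselSpec")
  new("PhantomScene", vessels = vessels,
      gridShape = as.integer(gridShape), pixelSizeUm = pixelSizeUm,
      seed = as.integer(seed))
}

# Rasterize one vessel capsule: pixel (i, j) is inside iff the distance from
# its centre ((j - 0.5) s, (i - 0.5) s) to the segment is <= width/2.
rasterizeVessel <- function(vessel, gridShape, pixelSizeUm) {
  s <- pixelSizeUm
  r <- vessel@widthUm / 2
  p0 <- vessel@from; p1 <- vessel@to
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  jlo <- max(1L, floor(lo[1] / s + 0.5)); jhi <- min(gridShape[2], ceiling(hi[1] / s + 0.5))
  ilo <- max(1L, floor(lo[2] / s + 0.5)); ihi <- min(gridShape[1], ceiling(hi[2] / s + 0.5))
  mask <- matrix(FALSE, gridShape[1], gridShape[2])
  if (jhi < jlo || ihi < ilo) return(mask)
  ii <- ilo:ihi; jj <- jlo:jhi
  cx <- (jj - 0.5) * s; cy <- (ii - 0.5) * s
  X <- matrix(cx, length(ii), length(jj), byrow = TRUE)
  Y <- matrix(cy, length(ii), length(jj))
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- X - (p0[1] + t * d[1]); dy <- Y - (p0[2] + t * d[2])
  mask[ii, jj] <- (dx * dx + dy * dy) <= r * r
  mask
}

#' Rasterized footprint of every vessel in a scene
#'
#' @param scene a [PhantomScene-class]
#' @return list of logical matrices, one per vessel, in scene order
#' @export
sceneVesselMasks <- function(scene) {
  lapply(scene@vessels, rasterizeVessel, gridShape = scene@gridShape,
         pixelSizeUm = scene@pixelSizeUm)
}

#' Ground-truth union vessel mask of a scene
#'
#' @param scene a [PhantomScene-class]
#' @return a [BinaryMask-class] — the union of all rasterized capsules
#' @export
sceneMask <- function(scene) {
  masks <- sceneVesselMasks(scene)
  u <- Reduce(`|`, masks)
  binaryMask(u, scene@pixelSizeUm)
}

#' Render the synthetic vascular density export
#'
#' Emulates the greyscale ULM density map: vessel pixels carry a nonzero
#' 8-bit intensity, background is exactly 0. The default renders a uniform
#' 255; `style = "speckle"` draws seeded per-pixel intensities in 60..255
#' for more realistic texture (binarization is unaffected either way).
#'
#' @param scene a [PhantomScene-class]
#' @param style `"uniform"` or `"speckle"`
#' @return an [IntensityMap-class] with modality `"density"`
#' @export
renderDensityMap <- function(scene, style = c("uniform", "speckle")) {
  style <- match.arg(style)
  u <- mapValues(sceneMask(scene))
  img <- matrix(0L, nrow(u), ncol(u))
  if (style == "uniform") {
    img[u] <- 255L
  } else {
    n <- sum(u)
    img[u] <- withr::with_seed(subSeed(scene@seed, 101L),
                               sample(60:255, n, replace = TRUE))
  }
  intensityMap(img, "density", scene@pixelSizeUm)
}

#' Render the synthetic 8-bit speed export
#'
#' Vessel pixels carry `round(velocity * 2.55)`, the 8-bit encoding of the
#' 0-100 mm/s scale; background is 0. Where vessels overlap, the vessel
#' listed later in the scene wins.
#'
#' @param scene a [PhantomScene-class]
#' @return an [IntensityMap-class] with modality `"speed"`
#' @export
renderSpeedMap <- function(scene) {
  masks <- sceneVesselMasks(scene)
  img <- matrix(0L, scene@gridShape[1], scene@gridShape[2])
  for (i in seq_along(masks)) {
    v <- scene@vessels[[i]]@velocityMmS
    if (v < 0 || v > 100) stop("velocity out of the encodable 0-100 mm/s range")
    img[masks[[i]]] <- as.integer(min(255L, max(0L, round(v * 2.55))))
  }
  intensityMap(img, "speed", scene@pixelSizeUm)
}

#' Render the synthetic RGB axial-direction export
#'
#' Descending-flow vessels (arteriole-like) are rendered pure red, ascending
#' (venule-like) pure blue, background black. Where opposite-direction
#' vessels overlap, the vessel listed later in the scene wins.
#'
#' @param scene a [PhantomScene-class]
#' @return an [IntensityMap-class] with modality `"directional"`
#' @export
renderDirectionalMap <- function(scene) {
  masks <- sceneVesselMasks(scene)
  rgb <- array(0L, c(scene@gridShape[1], scene@gridShape[2], 3L))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    ch <- if (scene@vessels[[i]]@direction == "descending") 1L else 3L
    oth <- if (ch == 1L) 3L else 1L
    r <- rgb[, , ch];  r[m] <- 255L; rgb[, , ch]  <- r
    o <- rgb[, , oth]; o[m] <- 0L;   rgb[, , oth] <- o
  }
  intensityMap(rgb, "directional", scene@pixelSizeUm)
}

#' Build a RegionSet from a rectangular-band layout
#'
#' `layout` is a named list; each element is either a length-2 row range
#' (a full-width horizontal band) or a list with `rows` and `cols` ranges.
#' Regions must not overlap and must lie inside the grid. `whole_brain` is
#' implicit: it is the union of all labeled pixels and must not be given as
#' an explicit layout entry.
#'
#' @param gridShape integer (rows, cols)
#' @param layout named list of row ranges or `list(rows =, cols =)` blocks
#' @param pixelSizeUm micrometres per pixel
#' @return a [RegionSet-class]
#' @examples
#' makeRegionSet(c(300, 300), list(cortex = c(1, 100),
#'   hippocampus = c(101, 200), white_matter = c(201, 300)))
#' @export
makeRegionSet <- function(gridShape, layout, pixelSizeUm = 2) {
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    stop("layout must be a named list of regions")
  if ("whole_brain" %in% names(layout))
    stop("whole_brain is implicit (the union of all labeled regions)")
  labels <- matrix(0L, gridShape[1], gridShape[2])
  tab <- integer(0)
  for (k in seq_along(layout)) {
    el <- layout[[k]]
    if (is.list(el)) { rows <- el$rows; cols <- el$cols } else { rows <- el; cols <- c(1L, gridShape[2]) }
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (rows[1] < 1L || rows[2] > gridShape[1] || cols[1] < 1L ||
        cols[2] > gridShape[2] || rows[1] > rows[2] || cols[1] > cols[2])
      stop(sprintf("region '%s' lies outside the grid", names(layout)[k]))
    block <- labels[rows[1]:rows[2], cols[1]:cols[2]]
    if (any(block != 0L))
      stop(sprintf("region '%s' overlaps an earlier region", names(layout)[k]))
    labels[rows[1]:rows[2], cols[1]:cols[2]] <- k
    tab[[names(layout)[k]]] <- k
  }
  new("RegionSet", labels = labels, nameTable = tab, pixelSizeUm = pixelSizeUm)
}

#' HrfParams: parameters of the synthetic hemodynamic response
#'
#' The stimulus-evoked response is a gamma-variate kernel
#' `g(t) = (t/tp)^a exp(a (1 - t/tp))`, which rises from 0, peaks at exactly
#' `latencyS` with unit height, and decays; `riseShape` (a) controls how
#' sharply it rises. The trace is `100 + amplitudePct * g(t - onset)` plus
#' Gaussian noise.
#'
#' @slot amplitudePct peak relative-CBV increase in % of baseline
#' @slot latencyS time from stimulus onset to peak, s
#' @slot riseShape positive gamma-variate shape parameter
#' @slot noiseSdPct additive Gaussian noise SD in % of baseline
#' @seealso [hrfParams()], [simulateNvcTrace()]
#' @export
setClass("HrfParams",
  representation(amplitudePct = "numeric", latencyS = "numeric",
                 riseShape = "numeric", noiseSdPct = "numeric"))

setValidity("HrfParams", function(object) {
  if (object@amplitudePct < 0) return("amplitudePct must be >= 0")
  if (object@latencyS <= 0) return("latencyS must be > 0")
  if (object@riseShape <= 0) return("riseShape must be > 0")
  if (object@noiseSdPct < 0) return("noiseSdPct must be >= 0")
  TRUE
})

#' Construct HrfParams
#' @param amplitudePct peak response in % of baseline
#' @param latencyS time to peak in s
#' @param riseShape gamma-variate shape (default 3)
#' @param noiseSdPct Gaussian noise SD in % (default 0)
#' @return an [HrfParams-class]
#' @export
hrfParams <- function(amplitudePct = 20, latencyS = 5, riseShape = 3,
                      noiseSdPct = 0) {
  new("HrfParams", amplitudePct = amplitudePct, latencyS = latencyS,
      riseShape = riseShape, noiseSdPct = noiseSdPct)
}

# Unit-peak gamma-variate kernel, peak exactly at latencyS.
gammaVariate <- function(t, latencyS, riseShape) {
  g <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / latencyS
  g[pos] <- x^riseShape * exp(riseShape * (1 - x))
  g
}

#' Simulate a stimulus-locked relative-CBV trace
#'
#' Baseline level is fixed at 100 arbitrary units. Each trial adds a
#' gamma-variate response of height `amplitudePct` peaking `latencyS` after
#' the stimulation onset, plus seeded Gaussian noise.
#'
#' @param hrf an [HrfParams-class]
#' @param schedule a [StimSchedule-class]
#' @param seed integer seed for the noise stream
#' @param animalId,group identifiers carried on the trace
#' @return an [NvcTrace-class]; sample `i` is taken at time `i * dtS`
#' @export
simulateNvcTrace <- function(hrf, schedule = stimSchedule(), seed = 1L,
                             animalId = "phantom", group = "") {
  sch <- schedule
  trialLen <- sch@baselineS + sch@stimS + sch@postS
  perTrial <- round(trialLen / sch@dtS)
  n <- sch@nTrials * perTrial
  t <- seq_len(n) * sch@dtS
  y <- rep(100, n)
  for (k in seq_len(sch@nTrials)) {
    onset <- (k - 1) * trialLen + sch@baselineS
    # the response is confined to its own trial window, so every baseline
    # window is exactly at the 100-unit floor in the noiseless case
    idx <- ((k - 1) * perTrial + 1):(k * perTrial)
    y[idx] <- y[idx] + hrf@amplitudePct *
      gammaVariate(t[idx] - onset, hrf@latencyS, hrf@riseShape)
  }
  if (hrf@noiseSdPct > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(n, 0, hrf@noiseSdPct))
  new("NvcTrace", samples = y, schedule = sch,
      animalId = animalId, group = group)
}

#' Cohort generation parameters
#'
#' Defaults define the simulated study conditions: 6 young and 7 aged
#' animals; a 600 x 600 px grid at 2 um/px split into three full-width bands
#' (cortex, hippocampus, white matter); young target coverage fractions
#' 0.12 / 0.10 / 0.08; vessel widths lognormal with median 18 um (sdlog
#' 0.3) truncated to [6, 40] um; regional velocities 12 / 10 / 8 mm/s with
#' per-vessel lognormal jitter (sdlog 0.15); cortical arteriole fraction
#' 0.6; HRF amplitude 20 %, latency 5 s, shape 3, noise SD 2 %. Aged
#' multipliers impose the age contrasts: coverage x0.8, widths x0.8,
#' hippocampal velocity x0.7, cortical velocity x1.15, HRF amplitude x0.6,
#' latency x1.5, arteriole fraction x0.8. Between-animal variability is
#' lognormal with sdlog `animalSdLog` on each scaled attribute.
#'
#' @param nYoung,nAged group sizes (>= 2)
#' @param gridShape raster grid (rows, cols)
#' @param pixelSizeUm micrometres per pixel
#' @param coverage named young coverage fractions per region
#' @param widthMedianUm,widthSdLog width distribution (truncated [6, 40] um)
#' @param velocity named young regional velocities, mm/s
#' @param vesselSdLog per-vessel lognormal velocity jitter
#' @param animalSdLog between-animal lognormal variability
#' @param arterioleFraction young cortical arteriole (descending) fraction
#' @param hrfYoung an [HrfParams-class] for the young group
#' @param aged named list of aged multipliers (`coverage`, `width`,
#'   `velocity` named per region, `hrfAmplitude`, `hrfLatency`,
#'   `arterioleFraction`)
#' @param schedule a [StimSchedule-class]
#' @return a `CohortParams` list
#' @export
cohortParams <- function(
  nYoung = 6L, nAged = 7L,
  gridShape = c(600L, 600L), pixelSizeUm = 2,
  coverage = c(cortex = 0.12, hippocampus = 0.10, white_matter = 0.08),
  widthMedianUm = 18, widthSdLog = 0.3,
  velocity = c(cortex = 12, hippocampus = 10, white_matter = 8),
  vesselSdLog = 0.15, animalSdLog = 0.05,
  arterioleFraction = 0.6,
  hrfYoung = hrfParams(amplitudePct = 20, latencyS = 5, riseShape = 3,
                       noiseSdPct = 2),
  aged = list(coverage = 0.8, width = 0.8,
              velocity = c(cortex = 1.15, hippocampus = 0.7, white_matter = 1),
              hrfAmplitude = 0.6, hrfLatency = 1.5, arterioleFraction = 0.8),
  schedule = stimSchedule()) {
  if (nYoung < 2L || nAged < 2L) stop("need at least 2 animals per group")
  structure(list(nYoung = as.integer(nYoung), nAged = as.integer(nAged),
                 gridShape = as.integer(gridShape), pixelSizeUm = pixelSizeUm,
                 coverage = coverage, widthMedianUm = widthMedianUm,
                 widthSdLog = widthSdLog, velocity = velocity,
                 vesselSdLog = vesselSdLog, animalSdLog = animalSdLog,
                 arterioleFraction = arterioleFraction, hrfYoung = hrfYoung,
                 aged = aged, schedule = schedule),
            class = "CohortParams")
}

# Sample vessels for one band until the analytic capsule area (L*w + pi r^2)
# reaches the target coverage fraction of the band. Cortical vessels are
# near-vertical penetrating segments; other bands draw random orientations.
# Capsules are kept strictly inside the band so regional truth is clean.
sampleBandVessels <- function(rows, gridShape, pixelSizeUm, targetFrac,
                              widthMedianUm, widthSdLog, velocityMmS,
                              vesselSdLog, vertical, arterioleFraction) {
  s <- pixelSizeUm
  x0 <- 0; x1 <- gridShape[2] * s
  y0 <- (rows[1] - 1) * s; y1 <- rows[2] * s
  bandArea <- (x1 - x0) * (y1 - y0)
  target <- targetFrac * bandArea
  vessels <- list(); truth <- list()
  area <- 0; k <- 0
  while (area < target && k < 500) {
    k <- k + 1
    w <- min(40, max(6, stats::rlnorm(1, log(widthMedianUm), widthSdLog)))
    r <- w / 2
    v <- min(80, max(0.5, velocityMmS * stats::rlnorm(1, 0, vesselSdLog)))
    if (vertical) {
      L <- stats::runif(1, 0.3, 0.6) * (y1 - y0)
      theta <- pi / 2 + stats::runif(1, -0.12, 0.12)
    } else {
      L <- stats::runif(1, 80, 180)
      theta <- stats::runif(1, 0, pi)
    }
    hx <- abs(cos(theta)) * L / 2 + r
    hy <- abs(sin(theta)) * L / 2 + r
    if (2 * hx >= (x1 - x0) || 2 * hy >= (y1 - y0)) next
    cx <- stats::runif(1, x0 + hx + 1e-6, x1 - hx - 1e-6)
    cy <- stats::runif(1, y0 + hy + 1e-6, y1 - hy - 1e-6)
    from <- c(cx - cos(theta) * L / 2, cy - sin(theta) * L / 2)
    to <- c(cx + cos(theta) * L / 2, cy + sin(theta) * L / 2)
    vessels[[length(vessels) + 1L]] <-
      vesselSpec(from, to, widthUm = w, velocityMmS = v,
                 direction = "descending") # direction assigned below
    truth[[length(truth) + 1L]] <-
      data.frame(widthUm = w, velocityMmS = v, lengthUm = L,
                 areaUm2 = L * w + pi * r^2)
    area <- area + L * w + pi * r^2
  }
  n <- length(vessels)
  # direction split targets the arteriole fraction of vascular *area* (the
  # quantity the pixel-count AVR measures): greedy balancing over a
  # randomized vessel order keeps the realized area fraction within one
  # vessel footprint of the target without tying direction to placement
  areas <- vapply(truth, function(t) t$areaUm2, 0)
  ord <- sample.int(n)
  dirs <- character(n)
  artArea <- 0; done <- 0
  for (i in ord) {
    if (done == 0 || artArea / done < arterioleFraction) {
      dirs[i] <- "descending"; artArea <- artArea + areas[i]
    } else {
      dirs[i] <- "ascending"
    }
    done <- done + areas[i]
  }
  for (i in seq_len(n)) vessels[[i]]@direction <- dirs[i]
  tr <- do.call(rbind, truth)
  tr$direction <- dirs
  list(vessels = vessels, truth = tr)
}

#' Simulate a full young-versus-aged phantom cohort
#'
#' Generates, per animal, a vessel scene with the three-band region layout,
#' the rendered density/speed/directional exports, an NVC trace, and a
#' ground-truth table. Aged animals receive the multiplicative effects in
#' `params$aged`.
#'
#' @param params a [cohortParams()] list
#' @param seed master integer seed (split per animal via [subSeed()])
#' @return a list with `animals` (list of per-animal bundles: `id`, `group`,
#'   `scene`, `regions`, `density`, `speed`, `directional`, `trace`,
#'   `vesselTruth`, `hrf`) and `truth` (per-animal ground-truth data frame)
#' @export
simulateCohort <- function(params = cohortParams(), seed = 1L) {
  regions <- makeRegionSet(params$gridShape,
    list(cortex = c(1L, params$gridShape[1] %/% 3L),
         hippocampus = c(params$gridShape[1] %/% 3L + 1L,
                         2L * (params$gridShape[1] %/% 3L)),
         white_matter = c(2L * (params$gridShape[1] %/% 3L) + 1L,
                          params$gridShape[1])),
    pixelSizeUm = params$pixelSizeUm)
  bands <- list(cortex = c(1L, params$gridShape[1] %/% 3L),
                hippocampus = c(params$gridShape[1] %/% 3L + 1L,
                                2L * (params$gridShape[1] %/% 3L)),
                white_matter = c(2L * (params$gridShape[1] %/% 3L) + 1L,
                                 params$gridShape[1]))
  groups <- c(rep("young", params$nYoung), rep("aged", params$nAged))
  animals <- vector("list", length(groups))
  truthRows <- vector("list", length(groups))
  for (a in seq_along(groups)) {
    grp <- groups[a]
    id <- sprintf("%s_%02d", grp, if (grp == "young") a else a - params$nYoung)
    aseed <- subSeed(seed, a)
    bundle <- withr::with_seed(aseed, {
      mult <- function(x) x * stats::rlnorm(1, 0, params$animalSdLog)
      agedMul <- params$aged
      isAged <- grp == "aged"
      covMul <- if (isAged) agedMul$coverage else 1
      widMul <- if (isAged) agedMul$width else 1
      artFrac <- params$arterioleFraction *
        (if (isAged) agedMul$arterioleFraction else 1)
      vessels <- list(); vtruth <- list()
      for (rg in names(bands)) {
        velMul <- if (isAged) agedMul$velocity[[rg]] else 1
        bv <- sampleBandVessels(bands[[rg]], params$gridShape,
          params$pixelSizeUm,
          targetFrac = mult(params$coverage[[rg]] * covMul),
          widthMedianUm = mult(params$widthMedianUm * widMul),
          widthSdLog = params$widthSdLog,
          velocityMmS = mult(params$velocity[[rg]] * velMul),
          vesselSdLog = params$vesselSdLog,
          vertical = rg == "cortex",
          arterioleFraction = if (rg == "cortex") artFrac else 0.5)
        bv$truth$region <- rg
        vessels <- c(vessels, bv$vessels)
        vtruth[[rg]] <- bv$truth
      }
      scene <- makeScene(vessels, params$gridShape, params$pixelSizeUm,
                         seed = aseed)
      amp <- mult(params$hrfYoung@amplitudePct *
                  (if (isAged) agedMul$hrfAmplitude else 1))
      lat <- mult(params$hrfYoung@latencyS *
                  (if (isAged) agedMul$hrfLatency else 1))
      hrf <- hrfParams(amplitudePct = amp, latencyS = lat,
                       riseShape = params$hrfYoung@riseShape,
                       noiseSdPct = params$hrfYoung@noiseSdPct)
      list(scene = scene, hrf = hrf, vesselTruth = do.call(rbind, vtruth))
    })
    trace <- simulateNvcTrace(bundle$hrf, params$schedule,
                              seed = subSeed(aseed, 7L),
                              animalId = id, group = grp)
    animals[[a]] <- list(
      id = id, group = grp, scene = bundle$scene, regions = regions,
      density = renderDensityMap(bundle$scene),
      speed = renderSpeedMap(bundle$scene),
      directional = renderDirectionalMap(bundle$scene),
      trace = trace, vesselTruth = bundle$vesselTruth, hrf = bundle$hrf)
    vt <- bundle$vesselTruth
    truthRows[[a]] <- data.frame(
      animalId = id, group = grp,
      trueMeanWidthUm = mean(vt$widthUm),
      trueCoverageFrac = sum(vt$areaUm2) /
        (prod(params$gridShape) * params$pixelSizeUm^2),
      trueHippVelocity = mean(vt$velocityMmS[vt$region == "hippocampus"]),
      trueCortexVelocity = mean(vt$velocityMmS[vt$region == "cortex"]),
      trueArterioleFrac = mean(vt$direction[vt$region == "cortex"] == "descending"),
      trueHrfAmplitude = animals[[a]]$hrf@amplitudePct,
      trueHrfLatency = animals[[a]]$hrf@latencyS)
  }
  list(animals = animals, truth = do.call(rbind, truthRows),
       regions = regions, params = params, seed = as.integer(seed))
}
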