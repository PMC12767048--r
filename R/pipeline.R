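# Desk-scale orchestration: phantom cohort -> all quantification stages ->
# group statistics -> CSV report bundle, deterministic under a fixed
# config + seed.

#' Assemble a pipeline configuration
#'
#' @param outDir output directory for the report bundle (created if needed);
#'   `NULL` returns results in memory only
#' @param seed master integer seed
#' @param cohort a [cohortParams()] list (phantom study conditions)
#' @param flow a [flowModelParams()] list
#' @param policy statistical method policy (see [defaultMethodPolicy()])
#' @param writeRasters also write the per-animal rasters (TIFF) next to the
#'   CSVs (default FALSE; the CSV tables are the report)
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(outDir = NULL, seed = 1L, cohort = cohortParams(),
                           flow = flowModelParams(),
                           policy = defaultMethodPolicy(),
                           writeRasters = FALSE) {
  structure(list(outDir = outDir, seed = as.integer(seed), cohort = cohort,
                 flow = flow, policy = policy, writeRasters = writeRasters),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level fields: `seed`, `outDir`, `writeRasters`, and the
#' scalar cohort overrides `nYoung`, `nAged`, `pixelSizeUm`, `gridRows`,
#' `gridCols`. Unspecified fields keep the package defaults.
#'
#' @param path YAML file
#' @return a `PipelineConfig` list
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  co <- cohortParams(
    nYoung = if (is.null(y$nYoung)) 6L else y$nYoung,
    nAged = if (is.null(y$nAged)) 7L else y$nAged,
    gridShape = c(if (is.null(y$gridRows)) 300L else y$gridRows,
                  if (is.null(y$gridCols)) 300L else y$gridCols),
    pixelSizeUm = if (is.null(y$pixelSizeUm)) 2 else y$pixelSizeUm)
  pipelineConfig(outDir = y$outDir,
                 seed = if (is.null(y$seed)) 1L else y$seed,
                 cohort = co,
                 writeRasters = isTRUE(y$writeRasters))
}

# All quantification stages for one animal bundle.
quantifyAnimal <- function(an, flow, regionNamesUsed) {
  mask <- binarize(an$density)
  tmap <- applyReliabilityFloor(localThickness(mask), flow$floorRadiusUm)
  speedM <- decodeSpeed(an$speed, flow)
  fmap <- flowRateMap(speedM, tmap, flow)
  rows <- do.call(rbind, lapply(regionNamesUsed, function(rg) {
    sel <- regionMask(an$regions, rg) & mapValues(mask)
    eligible <- sel & !tmap@flagged
    data.frame(
      animalId = an$id, group = an$group, region = rg,
      coveragePct = coverage(mask, an$regions, rg),
      meanDiameterUm = if (any(eligible)) mean(mapValues(tmap)[eligible]) else NA_real_,
      medianDiameterUm = if (any(eligible)) stats::median(mapValues(tmap)[eligible]) else NA_real_,
      meanSpeedMmS = if (any(sel)) mean(mapValues(speedM)[sel]) else NA_real_,
      meanFlowMlMin = if (any(eligible)) mean(mapValues(fmap)[eligible]) else NA_real_)
  }))
  dmap <- classifyDirection(an$directional)
  avrRes <- computeAvr(dmap, an$regions, "cortex")
  avrRow <- data.frame(animalId = an$id, group = an$group,
                       arteriolePixels = avrRes@arteriolePixels,
                       venulePixels = avrRes@venulePixels,
                       avr = avrRes@avr,
                       arteriolePctOfTotal = avrRes@arteriolePctOfTotal)
  # pixelwise observations feeding the Welch distribution comparisons
  pixels <- lapply(stats::setNames(nm = regionNamesUsed), function(rg) {
    sel <- regionMask(an$regions, rg) & mapValues(mask)
    eligible <- sel & !tmap@flagged
    list(thickness = mapValues(tmap)[eligible],
         speed = mapValues(speedM)[sel])
  })
  list(regionMetrics = rows, avr = avrRow, pixels = pixels, mask = mask,
       tmap = tmap, speed = speedM, flow = fmap)
}

#' Run the full phantom study pipeline
#'
#' Generates the seeded cohort, quantifies every animal (coverage, diameter,
#' speed, regional CBF, cortical AVR, NVC metrics), runs the group
#' comparisons for every metric under the method policy, and (when `outDir`
#' is set) writes the CSV report bundle plus a run manifest. Reruns with an
#' identical config and seed produce byte-identical CSVs.
#'
#' @param config a [pipelineConfig()] list
#' @return list with `regionMetrics`, `avr`, `nvcTrials`, `comparisons`
#'   data frames, the `cohort`, and `files` (paths written, if any)
#' @export
runPipeline <- function(config = pipelineConfig()) {
  co <- simulateCohort(config$cohort, config$seed)
  regionNamesUsed <- c("whole_brain", "cortex", "hippocampus", "white_matter")
  perAnimal <- lapply(co$animals, quantifyAnimal, flow = config$flow,
                      regionNamesUsed = regionNamesUsed)
  regionMetrics <- do.call(rbind, lapply(perAnimal, `[[`, "regionMetrics"))
  avrTable <- do.call(rbind, lapply(perAnimal, `[[`, "avr"))
  nvcTrials <- nvcMetricsTable(lapply(co$animals, `[[`, "trace"))

  comparisons <- list()
  addCmp <- function(metric, values, groups) {
    res <- compareMetric(data.frame(value = values, group = groups), metric,
                         config$policy, groupOrder = c("young", "aged"))
    comparisons[[length(comparisons) + 1L]] <<- testResultRow(res, metric)
  }
  groupsOf <- vapply(co$animals, `[[`, "", "group")
  pooledPixels <- function(rg, what) {
    vals <- lapply(perAnimal, function(pa) pa$pixels[[rg]][[what]])
    data.frame(value = unlist(vals),
               group = rep(groupsOf, vapply(vals, length, 0L)))
  }
  for (rg in regionNamesUsed) {
    sub <- regionMetrics[regionMetrics$region == rg, ]
    addCmp(paste0("coverage_", rg), sub$coveragePct, sub$group)
    # speed and thickness distributions are compared pixelwise (Welch), the
    # statistical unit the study used for these metrics; per-animal means
    # remain available in regionMetrics
    th <- pooledPixels(rg, "thickness")
    addCmp(paste0("thickness_", rg), th$value, th$group)
    sp <- pooledPixels(rg, "speed")
    addCmp(paste0("speed_", rg), sp$value, sp$group)
    addCmp(paste0("cbf_", rg), sub$meanFlowMlMin, sub$group)
  }
  addCmp("avr_cortex", avrTable$avr, avrTable$group)
  addCmp("nvc_average", nvcTrials$averageResponsePct, nvcTrials$group)
  addCmp("nvc_peak", nvcTrials$peakPct, nvcTrials$group)
  addCmp("nvc_ttp", nvcTrials$timeToPeakS, nvcTrials$group)
  comparisons <- do.call(rbind, comparisons)

  files <- character(0)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(config$outDir, name)
      utils::write.csv(df, p, row.names = FALSE)
      files[[length(files) + 1L]] <<- p
    }
    wr(regionMetrics, "animal_region_metrics.csv")
    wr(avrTable, "avr.csv")
    wr(nvcTrials, "nvc_trials.csv")
    wr(comparisons, "group_comparisons.csv")
    manifest <- list(
      package = "VasculoMap",
      version = as.character(utils::packageVersion("VasculoMap")),
      seed = config$seed,
      nYoung = config$cohort$nYoung, nAged = config$cohort$nAged,
      gridShape = config$cohort$gridShape,
      pixelSizeUm = config$cohort$pixelSizeUm,
      flowK = config$flow$K, floorRadiusUm = config$flow$floorRadiusUm)
    mp <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    files[[length(files) + 1L]] <- mp
    if (config$writeRasters) {
      for (i in seq_along(co$animals)) {
        an <- co$animals[[i]]
        writeRasterMap(an$density,
          file.path(config$outDir, paste0(an$id, "_density.tif")))
        writeRasterMap(an$speed,
          file.path(config$outDir, paste0(an$id, "_speed.tif")))
        writeRasterMap(an$directional,
          file.path(config$outDir, paste0(an$id, "_directional.tif")))
        writeFloatMap(perAnimal[[i]]$tmap,
          file.path(config$outDir, paste0(an$id, "_thickness.tif")))
        writeFloatMap(perAnimal[[i]]$flow,
          file.path(config$outDir, paste0(an$id, "_flow.tif")))
      }
      writeRegionSet(co$regions, file.path(config$outDir, "regions.tif"))
    }
  }
  list(regionMetrics = regionMetrics, avr = avrTable, nvcTrials = nvcTrials,
       comparisons = comparisons, cohort = co, files = files)
}
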