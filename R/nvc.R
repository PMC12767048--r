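# Neurovascular coupling: stimulus-locked epoch analysis of relative-CBV
# traces. Each trial is baseline 30 s -> stimulation 30 s -> post 30 s;
# metrics are the average response and peak (% over baseline) during
# stimulation and the time from stimulus onset to peak.

#' Segment a trace into stimulation trials
#'
#' Sample `i` of a trace is taken at time `i * dtS`. Each trial window is
#' `baselineS + stimS + postS` long; the trace must hold at least `nTrials`
#' full windows (extra trailing samples are ignored).
#'
#' @param trace an [NvcTrace-class]
#' @return list of trials; each trial is a list with `samples`, the index
#'   vectors `baselineIdx`, `stimIdx`, `postIdx` (relative to the trial),
#'   `dtS` and `trial` number
#' @export
segmentTrials <- function(trace) {
  stopifnot(is(trace, "NvcTrace"))
  sch <- trace@schedule
  nb <- round(sch@baselineS / sch@dtS)
  ns <- round(sch@stimS / sch@dtS)
  np <- round(sch@postS / sch@dtS)
  len <- nb + ns + np
  if (length(trace@samples) < sch@nTrials * len)
    stop(sprintf("trace too short: %d samples, %d needed for %d trials",
                 length(trace@samples), sch@nTrials * len, sch@nTrials))
  lapply(seq_len(sch@nTrials), function(k) {
    off <- (k - 1L) * len
    list(samples = trace@samples[off + seq_len(len)],
         baselineIdx = seq_len(nb), stimIdx = nb + seq_len(ns),
         postIdx = nb + ns + seq_len(np), dtS = sch@dtS, trial = k,
         animalId = trace@animalId, group = trace@group)
  })
}

#' Baseline-normalize a trial to percent change
#'
#' dCBV%(t) = 100 * (s(t) - b) / b with b the mean of the trial's baseline
#' window. Scale-invariant: multiplying the raw samples by any positive
#' constant leaves the normalized trial unchanged.
#'
#' @param trial one element of [segmentTrials()] output
#' @return the trial with a `dCbvPct` component added
#' @export
baselineNormalize <- function(trial) {
  b <- mean(trial$samples[trial$baselineIdx])
  if (!is.finite(b) || b <= 0)
    stop("nonpositive baseline mean: cannot normalize")
  trial$dCbvPct <- 100 * (trial$samples - b) / b
  trial$baselineMean <- b
  trial
}

#' Functional-hyperemia metrics of one normalized trial
#'
#' Average response = mean dCBV% over the stimulation window; peak = max
#' over the same window; time-to-peak = time from stimulus onset to the
#' peak sample (the first stimulation sample, at `dtS` after onset, gives
#' time-to-peak `dtS`). The peak search stays within the stimulation window,
#' so time-to-peak always lies in (0, stimS]. If the window maximum is <= 0
#' the peak is reported as 0 and time-to-peak as missing.
#'
#' @param trial a trial from [baselineNormalize()]
#' @return named list: `averageResponsePct`, `peakPct`, `timeToPeakS`
#' @export
trialMetrics <- function(trial) {
  if (is.null(trial$dCbvPct)) stop("trial is not baseline-normalized")
  stim <- trial$dCbvPct[trial$stimIdx]
  avg <- mean(stim)
  mx <- max(stim)
  if (mx <= 0) {
    list(averageResponsePct = avg, peakPct = 0, timeToPeakS = NA_real_)
  } else {
    list(averageResponsePct = avg, peakPct = mx,
         timeToPeakS = which.max(stim) * trial$dtS)
  }
}

#' Per-trial metrics table for a set of traces
#'
#' Convenience wrapper: segments, normalizes and measures every trial of
#' every trace, one row per stimulation response — the statistical unit used
#' for group comparisons.
#'
#' @param traces list of [NvcTrace-class]
#' @return data frame with `animalId`, `group`, `trial`,
#'   `averageResponsePct`, `peakPct`, `timeToPeakS`
#' @export
nvcMetricsTable <- function(traces) {
  rows <- lapply(traces, function(tr) {
    trials <- lapply(segmentTrials(tr), baselineNormalize)
    do.call(rbind, lapply(trials, function(t) {
      m <- trialMetrics(t)
      data.frame(animalId = t$animalId, group = t$group, trial = t$trial,
                 averageResponsePct = m$averageResponsePct,
                 peakPct = m$peakPct, timeToPeakS = m$timeToPeakS)
    }))
  })
  do.call(rbind, rows)
}

#' Aggregate per-trial responses into group summaries and mean curves
#'
#' @param metrics per-trial metrics table ([nvcMetricsTable()] format)
#' @param curves optional matrix of normalized trial curves (samples x
#'   trials, columns aligned with `metrics` rows) from which time-locked
#'   group mean +/- SEM curves are computed
#' @param dtS sampling interval of the curves, s
#' @return list with `summary` (per group x metric: mean, SEM, n; missing
#'   time-to-peak values excluded pairwise) and, when curves are given,
#'   `meanCurves` (data frame: `timeS`, `group`, `mean`, `sem`)
#' @export
aggregateResponses <- function(metrics, curves = NULL, dtS = 0.2) {
  if (!nrow(metrics)) stop("empty metrics table")
  metricCols <- c("averageResponsePct", "peakPct", "timeToPeakS")
  summ <- do.call(rbind, lapply(split(metrics, metrics$group), function(g) {
    do.call(rbind, lapply(metricCols, function(mc) {
      x <- g[[mc]][is.finite(g[[mc]])]
      data.frame(group = g$group[1], metric = mc, mean = mean(x),
                 sem = stats::sd(x) / sqrt(length(x)), n = length(x))
    }))
  }))
  rownames(summ) <- NULL
  out <- list(summary = summ)
  if (!is.null(curves)) {
    out$meanCurves <- do.call(rbind, lapply(unique(metrics$group), function(gr) {
      cc <- curves[, metrics$group == gr, drop = FALSE]
      data.frame(timeS = seq_len(nrow(cc)) * dtS, group = gr,
                 mean = rowMeans(cc),
                 sem = apply(cc, 1, stats::sd) / sqrt(ncol(cc)))
    }))
  }
  out
}
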