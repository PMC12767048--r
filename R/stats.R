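# Two-group comparison layer: unpaired Student's t-test (pooled variance)
# and Welch's t-test (no equal-variance assumption), with the per-metric
# method policy used throughout the study: Welch for the pixelwise speed and
# thickness distributions (unequal variances, skewed), Student for coverage,
# regional CBF, AVR and the NVC metrics.

#' Significance stars
#'
#' Thresholds follow the figure-legend convention:
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p p-value
#' @return star string (`"ns"` when p >= 0.05)
#' @export
starsFor <- function(p) {
  if (p < 0.0001) "****" else if (p < 0.001) "***" else if (p < 0.005) "**"
  else if (p < 0.05) "*" else "ns"
}

buildTestResult <- function(ht, method, a, b, groupNames) {
  new("TestResult",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      pValue = ht$p.value, method = method, groupNames = groupNames,
      groupMeans = c(mean(a), mean(b)),
      groupSems = c(stats::sd(a) / sqrt(length(a)),
                    stats::sd(b) / sqrt(length(b))),
      nPerGroup = c(length(a), length(b)),
      stars = starsFor(ht$p.value))
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Assumes equal SDs in the two groups and uses the pooled variance
#' estimate; df = n1 + n2 - 2; two-sided p.
#'
#' @param a,b numeric samples (n >= 2 each)
#' @param groupNames labels for the two samples
#' @return a [TestResult-class]
#' @export
studentT <- function(a, b, groupNames = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (stats::var(a) + stats::var(b) == 0)
    stop("degenerate: pooled variance is zero")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  buildTestResult(ht, "student", a, b, groupNames)
}

#' Welch's t-test
#'
#' No equal-variance assumption; Welch-Satterthwaite degrees of freedom;
#' two-sided p.
#'
#' @param a,b numeric samples (n >= 2 each, at least one with nonzero
#'   variance)
#' @param groupNames labels for the two samples
#' @return a [TestResult-class]
#' @export
welchT <- function(a, b, groupNames = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate: both variances are zero")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  buildTestResult(ht, "welch", a, b, groupNames)
}

#' Default per-metric test policy
#'
#' Welch for the pixelwise `speed` and `thickness` distributions; Student
#' for `coverage`, `cbf`, `avr` and the NVC metrics.
#'
#' @return named character vector metric -> method
#' @export
defaultMethodPolicy <- function() {
  c(coverage = "student", thickness = "welch", speed = "welch",
    cbf = "student", avr = "student",
    nvc_average = "student", nvc_peak = "student", nvc_ttp = "student")
}

#' Compare one metric between two groups under the method policy
#'
#' @param table data frame with columns `value` and `group` (exactly two
#'   groups); rows with missing values are dropped
#' @param metric metric name looked up in the policy (a name containing
#'   `thickness` or `speed` falls back to the Welch entry; unknown names
#'   error)
#' @param policy named method policy (see [defaultMethodPolicy()])
#' @param groupOrder optional order of the two group labels (first = first
#'   sample)
#' @return a [TestResult-class]
#' @export
compareMetric <- function(table, metric, policy = defaultMethodPolicy(),
                          groupOrder = NULL) {
  table <- table[is.finite(table$value), , drop = FALSE]
  groups <- unique(table$group)
  if (length(groups) != 2L)
    stop(sprintf("need exactly two groups, got %d", length(groups)))
  if (!is.null(groupOrder)) groups <- groupOrder
  key <- if (metric %in% names(policy)) metric
         else if (grepl("thickness|diameter", metric)) "thickness"
         else if (grepl("speed|velocity", metric)) "speed"
         else if (grepl("coverage", metric)) "coverage"
         else if (grepl("cbf|flow", metric)) "cbf"
         else if (grepl("avr", metric)) "avr"
         else if (grepl("ttp|time", metric)) "nvc_ttp"
         else if (grepl("nvc|response|peak", metric)) "nvc_peak"
         else stop(sprintf("no method policy for metric '%s'", metric))
  method <- policy[[key]]
  a <- table$value[table$group == groups[1]]
  b <- table$value[table$group == groups[2]]
  if (method == "student") studentT(a, b, groupNames = as.character(groups))
  else welchT(a, b, groupNames = as.character(groups))
}

#' Format a TestResult as a one-row summary data frame
#'
#' @param res a [TestResult-class]
#' @param metric metric label carried into the row
#' @return data frame: metric, method, per-group mean/SEM/n, t, df, p, stars
#' @export
testResultRow <- function(res, metric = "") {
  data.frame(metric = metric, method = res@method,
             group1 = res@groupNames[1], mean1 = res@groupMeans[1],
             sem1 = res@groupSems[1], n1 = res@nPerGroup[1],
             group2 = res@groupNames[2], mean2 = res@groupMeans[2],
             sem2 = res@groupSems[2], n2 = res@nPerGroup[2],
             t = res@statistic, df = res@df, p = res@pValue,
             stars = res@stars)
}
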