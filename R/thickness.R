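# Vessel diameter by the model-independent local-thickness transform: each
# foreground pixel receives the diameter of the largest circle that fits
# entirely within the binary structure and contains that pixel.
#
# Digitization rule (shared by the fast path and the brute-force oracle): a
# circle of radius rho centred at pixel c contains pixel p iff the
# centre-to-centre distance is <= rho; radii live on the half-pixel lattice,
# so diameters are integer pixel counts; pixels outside the image grid count
# as background. The reference plugin's sub-pixel interpolation is
# approximated by this explicit rule, not cloned.

#' Local-thickness transform
#'
#' Fast path: exact integer squared Euclidean distance transform, largest
#' inscribed-circle radius per centre, then thickness propagation by circle
#' painting (compiled). Agrees pixel-for-pixel with [thicknessOracle()].
#'
#' @param mask a [BinaryMask-class]
#' @return a [ThicknessMap-class] with diameters in micrometres (0 on
#'   background); an empty mask warns and returns an all-zero map
#' @examples
#' m <- matrix(FALSE, 21, 21); m[9:13, 3:19] <- TRUE # 5-px-wide strip
#' tm <- localThickness(binaryMask(m, pixelSizeUm = 2))
#' mapValues(tm)[11, 11] # 5 px * 2 um = 10 um
#' @export
localThickness <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mapValues(mask)
  if (!any(v)) {
    warning("empty mask: all-zero thickness map")
    px <- matrix(0L, nrow(v), ncol(v))
  } else {
    px <- .cppLocalThickness(v)
  }
  new("ThicknessMap", values = px * pixelSize(mask),
      pixelSizeUm = pixelSize(mask), floorRadiusUm = NA_real_,
      flagged = matrix(FALSE, nrow(v), ncol(v)))
}

#' Brute-force local-thickness oracle
#'
#' Independent verification path: for every foreground centre it grows the
#' candidate radius ring by ring, checking containment of each disk pixel
#' directly against the mask (out-of-grid pixels count as background), then
#' propagates the maximal diameter to every covered pixel. Same digitization
#' rule as [localThickness()], so agreement is exact, but no distance
#' transform is involved.
#'
#' @param mask a [BinaryMask-class]
#' @param maxPixels refuse masks larger than this many pixels (exhaustive
#'   search guard, default 64 x 64)
#' @return a [ThicknessMap-class]
#' @export
thicknessOracle <- function(mask, maxPixels = 4096L) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mapValues(mask)
  if (length(v) > maxPixels)
    stop(sprintf("mask has %d pixels; oracle guard is %d", length(v), maxPixels))
  nr <- nrow(v); nc <- ncol(v)
  kmaxAll <- ceiling(2 * sqrt(nr^2 + nc^2)) + 1L
  # ring offsets: offsets with k-1 < 2*dist <= k, cumulative disks
  ring <- vector("list", kmaxAll)
  rad <- (kmaxAll %/% 2L) + 1L
  off <- expand.grid(di = -rad:rad, dj = -rad:rad)
  d2x4 <- 4L * (off$di^2 + off$dj^2)
  kbin <- ceiling(sqrt(d2x4)) # smallest k with k^2 >= 4 d^2, i.e. 2d <= k
  for (k in seq_len(kmaxAll)) ring[[k]] <- off[kbin == k, , drop = FALSE]
  kmat <- matrix(0L, nr, nc)
  fg <- which(v, arr.ind = TRUE)
  for (idx in seq_len(nrow(fg))) {
    i <- fg[idx, 1]; j <- fg[idx, 2]
    k <- 0L
    repeat {
      kk <- k + 1L
      rg <- ring[[kk]]
      if (nrow(rg)) {
        pi_ <- i + rg$di; pj <- j + rg$dj
        bad <- pi_ < 1L | pi_ > nr | pj < 1L | pj > nc
        if (any(bad) || !all(v[cbind(pi_[!bad], pj[!bad])])) break
      }
      k <- kk
    }
    kmat[i, j] <- k
  }
  out <- matrix(0L, nr, nc)
  for (idx in seq_len(nrow(fg))) {
    i <- fg[idx, 1]; j <- fg[idx, 2]
    k <- kmat[i, j]
    if (k <= 0L) next
    for (kk in seq_len(k)) {
      rg <- ring[[kk]]
      if (!nrow(rg)) next
      pi_ <- i + rg$di; pj <- j + rg$dj
      cells <- cbind(pi_, pj)
      cur <- out[cells]
      out[cells] <- pmax(cur, k)
    }
    if (out[i, j] < k) out[i, j] <- k
  }
  new("ThicknessMap", values = out * pixelSize(mask),
      pixelSizeUm = pixelSize(mask), floorRadiusUm = NA_real_,
      flagged = matrix(FALSE, nr, nc))
}

#' Flag diameters below the reliability floor
#'
#' ULM lateral resolution limits how small a vessel can be measured
#' reliably; a conservative minimum reliable vessel radius of about 5 um is
#' the default. Pixels with diameter < 2 x floor radius are flagged; they
#' stay in the map but are excluded from distributions and flow maps when
#' the filter is enabled (the default).
#'
#' @param tmap a [ThicknessMap-class]
#' @param floorRadiusUm reliability floor radius in um (default 5)
#' @return the map with its `flagged` slot and `floorRadiusUm` set
#' @export
applyReliabilityFloor <- function(tmap, floorRadiusUm = 5) {
  stopifnot(is(tmap, "ThicknessMap"))
  v <- mapValues(tmap)
  tmap@flagged <- v > 0 & v < 2 * floorRadiusUm
  tmap@floorRadiusUm <- floorRadiusUm
  tmap
}

# shared histogram builder: relative frequencies over fixed-width bins
buildHistogram <- function(x, binWidth, origin = 0) {
  if (!length(x)) stop("no eligible pixels: empty distribution")
  lo <- origin + floor((min(x) - origin) / binWidth) * binWidth
  hi <- origin + ceiling((max(x) - origin) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  edges <- seq(lo, hi, by = binWidth)
  cnt <- graphics::hist(x, breaks = edges, plot = FALSE, right = FALSE)$counts
  data.frame(binLower = edges[-length(edges)], binUpper = edges[-1],
             count = cnt, relFreq = cnt / length(x))
}

#' Regional vessel-diameter distribution
#'
#' Pixelwise relative-frequency histogram of local thickness over unflagged
#' foreground pixels in a region.
#'
#' @param tmap a [ThicknessMap-class] (run [applyReliabilityFloor()] first if
#'   filtering is wanted)
#' @param regions a [RegionSet-class]
#' @param name region name
#' @param binWidthUm bin width in um (default 2, one pixel at the 2 um/px
#'   export resolution)
#' @param useFloor exclude flagged pixels (default TRUE)
#' @return data frame with `binLower`, `binUpper`, `count`, `relFreq`
#'   (summing to 1) and attribute `n`
#' @export
diameterDistribution <- function(tmap, regions, name, binWidthUm = 2,
                                 useFloor = TRUE) {
  sel <- regionMask(regions, name)
  v <- mapValues(tmap)
  keep <- sel & v > 0
  if (useFloor) keep <- keep & !tmap@flagged
  h <- buildHistogram(v[keep], binWidthUm)
  attr(h, "n") <- sum(keep)
  h
}

#' Regional diameter summary
#'
#' @param tmap a [ThicknessMap-class]
#' @param regions a [RegionSet-class]
#' @param name region name
#' @param useFloor exclude flagged pixels (default TRUE)
#' @return named vector: mean, median, n (pixelwise, um)
#' @export
diameterSummary <- function(tmap, regions, name, useFloor = TRUE) {
  sel <- regionMask(regions, name)
  v <- mapValues(tmap)
  keep <- sel & v > 0
  if (useFloor) keep <- keep & !tmap@flagged
  x <- v[keep]
  if (!length(x)) stop("no eligible pixels in region")
  c(mean = mean(x), median = stats::median(x), n = length(x))
}
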