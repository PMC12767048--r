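# Fixture builders shared across test files. Everything is generated in
# code; no stored binary fixtures.

# Random blob mask: union of random digital disks and rectangles.
randomBlobMask <- function(nr = 48, nc = 48, nBlobs = 4) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(nBlobs)) {
    if (runif(1) < 0.7) {
      ci <- sample.int(nr, 1); cj <- sample.int(nc, 1); r <- sample(1:8, 1)
      ii <- pmax(1, ci - r):pmin(nr, ci + r)
      jj <- pmax(1, cj - r):pmin(nc, cj + r)
      sub <- outer(ii - ci, jj - cj, function(a, b) a^2 + b^2 <= r^2)
      m[ii, jj] <- m[ii, jj] | sub
    } else {
      i0 <- sample.int(nr, 1); j0 <- sample.int(nc, 1)
      i1 <- min(nr, i0 + sample(1:10, 1)); j1 <- min(nc, j0 + sample(1:10, 1))
      m[i0:i1, j0:j1] <- TRUE
    }
  }
  m
}

# A single straight horizontal phantom vessel centred in the grid. The
# centerline sits on a pixel-centre row so recovery tests measure estimator
# bias rather than the half-pixel placement parity (see the vignette).
horizontalVesselScene <- function(widthUm = 20, velocityMmS = 10,
                                  gridPx = 256, pixelSizeUm = 2,
                                  marginUm = 60,
                                  direction = "descending") {
  ext <- gridPx * pixelSizeUm
  yC <- (floor(gridPx / 2) - 0.5) * pixelSizeUm
  v <- vesselSpec(c(marginUm, yC), c(ext - marginUm, yC),
                  widthUm = widthUm, velocityMmS = velocityMmS,
                  direction = direction)
  makeScene(list(v), gridShape = c(gridPx, gridPx), pixelSizeUm = pixelSizeUm)
}

# RegionSet covering the whole grid with a single "cortex" band.
fullCortexRegions <- function(gridPx = 256, pixelSizeUm = 2) {
  makeRegionSet(c(gridPx, gridPx), list(cortex = c(1, gridPx)),
                pixelSizeUm = pixelSizeUm)
}

# Scaled-down cohort for fast structural tests.
smallCohortParams <- function(...) {
  cohortParams(nYoung = 2L, nAged = 2L, gridShape = c(150L, 150L), ...)
}
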