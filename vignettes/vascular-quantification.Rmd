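---
title: "Quantifying cerebrovascular structure and function from ULM exports"
author: "VasculoMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebrovascular structure and function from ULM exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VasculoMap)
```

## The measurement problem

Super-resolution ultrasound localization microscopy traces intravenously
injected microbubbles through the brain vasculature and exports, per
coronal slice, three 8-bit rasters at roughly 2 µm/pixel: a vascular
density map, a speed map, and an RGB axial-direction map. Functional
ultrasound adds region-averaged time series of relative cerebral blood
volume (CBV) during sensory stimulation. None of these products is itself a
biomarker; VasculoMap implements the post-acquisition chain that turns them
into regional vascular coverage, vessel-diameter distributions, blood
velocity, Poiseuille-derived resting cerebral blood flow (CBF), the
cortical arteriole-to-venule ratio (AVR), and neurovascular-coupling (NVC)
response metrics, together with the two-group statistical layer used to
contrast young and aged cohorts.

Everything upstream of the exports — beamforming, microbubble localization
and tracking, atlas registration — is scanner- or vendor-side and out of
scope; the package consumes the exported rasters plus a user-supplied
region label map.

## Coordinate and calibration conventions

Rasters are row-major matrices with the row index increasing downward, the
standard image convention; a coronal slice is assumed oriented with the
cortical surface at the top, so *descending* axial flow (increasing row)
corresponds to penetrating arterioles and *ascending* flow to venules.
Physical calibration (`pixelSizeUm`, default 2 µm) is always supplied
explicitly — export metadata is not standardized enough to trust — and all
quantitative outputs are in physical units (µm, mm/s, mL/min).

## Vascular coverage

The density export is binarized at a threshold of 1: any nonzero pixel
counts as vessel, mirroring the "every colored pixel becomes white"
conversion of the original MATLAB workflow. No morphological cleanup is
applied — none is described for the reference workflow, and cleanup would
silently change coverage. Coverage of a region is then
`100 · (vessel pixels) / (region pixels)`. The threshold is exposed for
sensitivity analysis. One thresholded mask serves both coverage and the
thickness analysis below; the original workflow used a trainable
segmentation for the diameter masks, which is not reproducible from its
description, so a single deterministic rule is used for both and stated
here openly.

## Local thickness: the diameter estimator

The vessel-diameter map uses the model-independent *local thickness*
definition: the value at a pixel is the diameter of the largest circle that
fits entirely within the binary structure and contains that pixel. Two
implementations are shipped on purpose:

* **Fast path** (`localThickness`): an exact integer squared Euclidean
  distance transform (two-pass envelope algorithm), conversion of each
  foreground pixel's clearance into the largest admissible half-pixel
  radius, and thickness propagation by painting each circle onto the pixels
  it covers (compiled code).
* **Oracle** (`thicknessOracle`): a brute-force search that grows each
  candidate circle ring by ring, testing containment pixel by pixel, with a
  size guard of 64 × 64.

Both share one explicit digitization rule: a circle of radius ρ centred at
pixel *c* contains pixel *p* iff the centre-to-centre distance is ≤ ρ;
radii live on the half-pixel lattice (so diameters are whole pixels);
pixels outside the grid count as background. Because the rule is shared,
"agreement" is well defined and the test suite demands *exact* pixel-level
equality on hundreds of random masks — this is what catches boundary-case
bugs that plague reimplementations of thickness transforms. The reference
ImageJ plugin performs sub-pixel interpolation whose formula is not
published; the half-pixel lattice is a documented substitute, and absolute
agreement with the plugin is not claimed. All arithmetic that decides a
radius is integer arithmetic (squared distances, integer square roots), so
the fast path cannot drift from the oracle through floating-point rounding.

Because transcranial ULM resolution is limited (≈13 µm in the worst case,
better through a cranial window), a conservative minimum reliable vessel
radius of 5 µm is applied: pixels with diameter < 10 µm are *flagged*, kept
in the map, and excluded from distributions, summaries and flow maps by
default. Diameter histograms default to 2 µm bins — one pixel at the export
resolution; finer bins would manufacture empty-bin structure out of raster
quantization.

## Speed decoding and Poiseuille flow

The speed export encodes 0–100 mm/s linearly in 0–255, so decoding divides
by 255/100 = 2.55; decoded values are clipped defensively to [0, 100]. The
per-pixel flow estimate fuses speed with local diameter through the
operational Poiseuille form

\[ Q = v \cdot A \cdot K = v \cdot \pi r^2 \cdot K, \qquad K = 6\times10^{-8}, \]

with *v* in mm/s and *r* in µm. K is not a free parameter: 1 mm/s · µm² =
10⁻¹⁵ m³/s = 10⁻⁹ mL/s = 6×10⁻⁸ mL/min, and the package derives it by
dimensional analysis (`deriveFlowConstant`) rather than hard-coding a
magic number into the formula. The full pressure-gradient Poiseuille
relation (ΔP, viscosity, length) is intentionally not implemented — those
quantities are unobservable in this data and the operational form above is
the one actually applied pixel-by-pixel.

Regional CBF is reported as the mean Q over *vessel-positive, unflagged*
pixels. "Average Q in the selected area" is ambiguous between vessel-pixel
and all-pixel averaging; Q is undefined off-vessel, so vessel-pixel
averaging is the default and the all-pixel (density-weighted) reading is
available via `domain = "all"`. Speed values are treated as scalar per-pixel
speeds without vessel-axis projection, matching how the export is defined.
Speed histograms use 2 mm/s bins; flow histograms use logarithmic bins
because Q spans orders of magnitude across the diameter range.

## Arteriole-to-venule ratio

The RGB direction export is channel-split; a pixel is arteriolar where red
dominates blue, venular where blue dominates red, and unclassified
otherwise — exact ties included, which keeps the rule deterministic and
conservative rather than splitting pixels fractionally. The AVR is the
arteriole:venule pixel-count ratio; because "as a % of the total
vasculature" admits a second reading, the result object also carries each
class as a percentage of classified vasculature, so either convention can
be reported. Analysis defaults to a cortical region: axial (vertical) flow
sensitivity aligns with penetrating arterioles and venules there, and is
unreliable for deeper, obliquely oriented vessels. The descending = red =
arteriole convention follows the coronal orientation above and is a
property of the renderer and classifier pair, not of the mathematics;
swapping channels inverts the ratio exactly, which is tested.

## NVC epoch analysis

Traces follow a 30 s baseline / 30 s stimulation / 30 s post schedule
repeated 7 times at dt = 0.2 s (the scanner's minimal inter-scan pause).
Sample *i* is taken at time *i·dt*. Each trial is normalized to percent
change over its own baseline mean; metrics are the stimulation-window mean
(average response), the window maximum (peak), and the time from onset to
the peak sample. The peak search is restricted to the stimulation window —
the quantity of interest is stimulus-evoked hyperemia — with a documented
option to extend into the post window for delayed responders; consequently
time-to-peak always lies in (0, 30] s. Nonpositive window maxima report a
peak of 0 with missing time-to-peak, excluded pairwise from statistics.
The per-trial response (not the per-animal mean) is the statistical unit,
matching the study design this pipeline reproduces (38 vs 33 recorded
responses). No detrending is applied by default.

## Statistics

`studentT` and `welchT` wrap the standard pooled-variance and
Welch–Satterthwaite tests (two-sided throughout) and are validated in the
test suite against independent closed-form computation and a Monte-Carlo
type-I-error calibration. The per-metric policy applies Welch to the
pixelwise speed and thickness distributions — where unequal variances and
skew are expected — and Student's t elsewhere (coverage, regional CBF, AVR,
NVC). Treating pixels as observations for the distribution comparisons is a
*faithful-reproduction* choice, not a statistical endorsement: pixels
within an animal are strongly dependent, and the per-animal means are
retained in the output tables for anyone preferring the conservative unit.
No multiple-testing correction is applied, matching the reproduced
workflow. Stars follow the 0.05/0.005/0.001/0.0001 convention.

## The phantom generator

The generator replaces the scanner with explicit ground truth. Vessels are
straight constant-width capsules (segment dilated by its radius) — the
simplest geometry with an analytic area `L·w + π(w/2)²`, which makes
coverage, diameter and AVR recovery checkable in closed form. Rasterization
marks a pixel as vessel iff its centre lies within the capsule. Where
vessels overlap, the later-listed vessel wins in the speed and direction
renders (deterministic and documented). The density render puts 255 on
vessel pixels (optionally seeded speckle in 60–255); the speed render
encodes `round(v·2.55)`; the direction render colors descending vessels
pure red and ascending pure blue.

NVC traces use a gamma-variate kernel
\(g(t) = (t/t_p)^a e^{a(1 - t/t_p)}\), which rises from zero, peaks at
exactly the programmed latency \(t_p\) with unit height, and decays;
baseline is fixed at 100 arbitrary units so percent-change math is
transparent. Gaussian noise is added on top. All randomness flows from one
integer master seed via the documented splitting rule
`(seed·48271 + k·1009) mod (2³¹−1)`.

### Simulated study conditions

The cohort defaults are the package's fixed study conditions, chosen once
to emulate a small-animal aging study at desk scale:

| parameter | value | rationale |
|---|---|---|
| group sizes | 6 young, 7 aged | the reproduced study design |
| grid | 600 × 600 px at 2 µm (1.2 × 1.2 mm) | three 400-µm bands (cortex, hippocampus, white matter); enough vessels per animal (~40–60) for stable per-animal summaries at seconds-scale runtime |
| young coverage | 12 / 10 / 8 % per band | cortical density highest, white matter lowest |
| widths | lognormal, median 18 µm, sdlog 0.3, truncated [6, 40] µm | capillary-to-arteriole range sitting mostly above the 10 µm reliability floor |
| velocities | 12 / 10 / 8 mm/s per band, per-vessel sdlog 0.15 | microvascular ULM speed range |
| arteriole fraction | 0.6 of cortical vascular area | penetrating-arteriole dominance; assigned by greedy area balancing so the realized area fraction tracks the parameter within one vessel footprint |
| HRF | 20 % amplitude, 5 s latency, shape 3, 2 % noise | typical whisker-evoked hyperemia |
| between-animal variability | lognormal, sdlog 0.05 | biological spread without swamping n = 6–7 designs |
| aged multipliers | coverage ×0.8, width ×0.8, hippocampal velocity ×0.7, cortical velocity ×1.15, HRF amplitude ×0.6, latency ×1.5, arteriole fraction ×0.8 | the six aging contrasts the pipeline must recover in direction |

Cortical vessels are near-vertical penetrating segments (30–60 % of the
band height); deeper bands draw random orientations, 80–180 µm lengths.
Vessels are added until the analytic capsule area reaches the target
coverage, so "coverage ×0.8" holds by construction rather than by hoping
the rasterizer cooperates.

### What the phantom does and does not show

The phantom has straight, non-tortuous, in-plane vessels, exactly known
directions, no point-spread function, no localization noise, no motion, no
atlas misregistration. Passing recovery tests therefore validates the
*quantification chain* — binarization, thickness transform, unit
conversions, flow fusion, epoch metrics, statistics — not the robustness of
ULM imaging itself. The noise model (uniform speckle, Gaussian trace noise)
is a stand-in, not a claim about scanner statistics. Results on real
exports inherit whatever segmentation and registration quality the
upstream produced.

## Numerical choices and degenerate inputs

* Thickness radii are decided in exact integer arithmetic; `k = isqrt(4d²−1)`
  gives the largest half-lattice diameter strictly inside the clearance.
* Placement parity: because circle centres live on the pixel lattice, a
  straight structure whose medial axis falls midway *between* pixel rows
  rasterizes to an even-height strip whose largest inscribed circle is one
  pixel narrower than the strip; stacked with rasterization quantization the
  worst-case diameter error is 1.5 px. The recovery tests therefore place
  phantom centerlines on pixel-centre rows, measuring estimator bias (≤ 1 px)
  without the placement artifact; on arbitrary real masks the extra half
  quantum is part of the measurement, exactly as for the reference plugin
  before its sub-pixel interpolation.
* Empty masks warn and return all-zero maps; empty regions, all-flagged
  selections, zero venule counts, and nonpositive baselines are errors, not
  silent NaNs.
* Decoded speeds are clipped to [0, 100] mm/s although 8-bit input cannot
  exceed it.
* Histogram frequencies always sum to 1 over the eligible pixels actually
  used; the pixel count is attached as an attribute.
* Ties in the direction classifier go to "none"; ties in `which.max` for
  time-to-peak resolve to the earliest sample, the standard convention.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the thickness oracle on
masks up to 64 × 64, phantom recovery on 128–256 px grids, the Monte-Carlo
calibration at 1000 null replicates, and the full cohort at the 600 px
default — sizes chosen so the whole validation suite completes in a few
minutes on one CPU while every stage still operates well above its
degenerate regime.

## Known limitations

* 2-D only; no 3-D sphere-based thickness, no out-of-plane flow.
* No vessel-type stratification of the diameter distributions.
* The AVR axis convention is configurable but cannot be validated against
  an absolute anatomical standard from the exports alone.
* Pixel-level Welch comparisons inherit pseudo-replication (see above).
* Atlas registration is replaced by user-supplied label rasters.
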