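---
title: "Methods: quantifying stress-granule state from fluorescence microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stress-granule state from fluorescence microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sgquant)
```

## The scientific problem

Stress granules (SGs) are liquid-like RNP condensates. Their healthy state
is defined operationally by four quantitative signatures: rapid FRAP
recovery of their components, frequent fusion and fission, near-complete
dissolution on RNase injection, and prompt disassembly after stress.
Accumulation of misfolded protein flips each signature: the mobile fraction
collapses, fusion/fission stop, most of the granule area survives RNase,
and disassembly is delayed. `sgquant` turns each signature into a tested
estimator and, because public imaging data for this assay class are
scarce, ships a simulator that generates every input with known ground
truth. This vignette documents the models, the defaults and their
rationale, the numerical choices, and what the synthetic validation does
and does not demonstrate.

## The enrichment statistic

For each segmented granule the package computes

\[ R = \frac{\overline{I}_{\text{inside}} - b}{\overline{I}_{\text{surround}} - b}, \]

the mean fluorescence inside the granule over the mean in a surrounding
region, optionally background-corrected by a scalar \(b\). A granule is
"enriched" for a probe when \(R\) strictly exceeds a threshold \(\tau\);
the assay's conventional thresholds are 1.4 (general classification) and
1.5 (time-course classification), both exposed as parameters.

Design choices the ratio definition leaves open:

- **Surround geometry.** An annulus from 2 px outside the granule boundary
  to 6 px, clipped to the cell mask and excluding *all* granule pixels.
  The 2 px gap keeps PSF bleed from the granule rim out of the denominator;
  excluding neighbouring granules keeps bright neighbours from inflating
  it. Both distances are parameters (`surround_gap_px`,
  `surround_width_px`).
- **Background.** Default `"auto"`: the kernel-density mode of the pixels
  outside the cell mask, i.e. the camera offset. Without subtraction an
  additive offset biases \(R\) toward 1; with it, \(R\) is invariant to
  offsets and (by construction) to multiplicative gain. Tests assert both
  properties.
- **Degenerate surrounds** (empty annulus, or non-positive mean after
  background subtraction) mark the granule "unmeasurable" rather than
  failing the pipeline.

## Segmentation

The granule detector is a difference-of-Gaussians band-pass (defaults
\(\sigma = 1\) and \(8\) px, bracketing the granule radius scale) followed
by an Otsu threshold computed on the min-max-normalised response inside the
cell mask, hole filling, 4-connected labelling, and an area gate
(4 px to 5% of the cell area). Components whose peak band-pass response is
below 25% of the global peak are dropped; this suppresses correlated-noise
specks and, being a ratio of responses, preserves gain invariance. Labels
are renumbered in raster-scan order of each component's first pixel, so
segmentation is deterministic. The cell mask comes from the same channel
(smooth, Otsu, largest component, fill holes) or is supplied by the user.

Perimeter uses a 4-direction Crofton estimate,
\(P = \tfrac{\pi}{8}\,(n_h + n_v + (n_{d1} + n_{d2})/\sqrt{2})\) over
boundary transition counts. On a digitised disk of radius 10 it yields
circularity \(C = 4\pi A/P^2 \approx 0.94\); on an axis-aligned square,
\(C \approx 0.90\) against the continuum \(\pi/4 \approx 0.785\). No
discrete estimator reproduces both the square's edge-length convention and
an unbiased disk perimeter simultaneously (an exposed-edge count gives the
square exactly but drives the disk to \(C \approx 0.62\)); we prefer the
estimator that is nearly unbiased on blob-like shapes, and the tests state
the digitisation tolerance explicitly.

## FRAP

Raw traces carry three signals per frame: the bleach ROI, a reference
region (for whole-field acquisition bleaching), and background. Double
normalization computes, on background-subtracted signals,

\[ F(t) = \frac{\overline{ref}_{pre}}{ref(t)} \cdot
          \frac{roi(t)}{\overline{roi}_{pre}}, \]

which is ~1 pre-bleach and exactly 1 for a trace whose ROI and reference
decay identically. Recovery is fit on post-bleach frames by single
exponential \(F(t') = F_0 + (F_\infty - F_0)(1 - e^{-kt'})\) with
\(t' = 0\) at the first post-bleach frame, and the mobile fraction is
\(M_f = (F_\infty - F_0)/(1 - F_0)\), clipped to \([0, 1.05]\) with the
raw value retained. A single-exponential model is used throughout — the
fit exposes its SSE so users can judge adequacy; reaction–diffusion
modelling is out of scope. Initialisation is deterministic
(\(F_0\) = first post-bleach point, \(F_\infty\) = mean of the last three,
\(k = \ln 2 /\) time-to-half-recovery, bounded positive), and a perfectly
flat post-bleach curve short-circuits to the analytic \(M_f = 0\)
(undefined if nothing was bleached). Group summaries default to
fit-then-average; curves are also averaged pointwise (interpolating onto a
common grid when needed) with SEM reported as absent, never 0, for a
single trace.

## Costes block randomization

Colocalization inside a granule ROI is the Pearson coefficient over ROI
pixels. Its significance comes from shuffling one channel in square blocks
of physical size 0.12 µm (the PSF scale; converted to pixels via the
plane's pixel size, minimum 1 px) and recomputing \(r\) each round, with
the add-one p-value \(p = (1 + \#\{r_{rand} \ge r_{obs}\})/(N + 1)\),
default \(N = 1000\). Blocks are anchored at the ROI bounding-box origin;
blocks with under 50% ROI coverage are excluded, and both the observed and
randomized coefficients are computed on the same pixel set (ROI pixels in
included blocks) so the null matches the statistic. Calibration is
verified empirically: on independent-noise channels the rejection rate at
\(p \le 0.05\) is ~0.05 over 500 repetitions.

## Dynamics, RNase sensitivity and disassembly survival

Tracking is greedy nearest-neighbour linking between consecutive frames,
resolved globally in ascending distance (ties broken by track id, then
position — deterministic and invariant to detection order), gated by
`max_link_px` (default 3× the median granule radius). There is no motion
model and no gap closing; a granule missed in one frame starts a new
track.

The original assays scored fusion and fission by eye; the package
operationalises them: a fusion is a detection whose neighbourhood (within
`merge_dist_px`, default 10 px) contains ≥ 2 granules from the previous
frame — terminating tracks plus at most one continuing as the child — with
the child's area matching the summed parent areas within 30%; fission is
the mirror image. Both parameters are exposed. Prevalence is reported in
both circulating conventions (events per cell per hour, and fraction of
cells with ≥ 1 event), with Welch t statistics between groups.

RNase sensitivity is the fraction of total segmented granule area
remaining across a pre/post injection pair. Complete disassembly is the
first frame with zero detections sustained for ≥ 2 frames (debouncing
segmentation flicker); cells whose granules persist to the movie end are
censored. Survival uses the product-limit estimator with Greenwood
confidence intervals on the log scale, and the two-group log-rank test,
via the `survival` package — tests pin the estimator to hand-computed
product-limit values and to the empirical survival function on uncensored
data.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions under which everything is validated.

- **Optics and camera.** Granules are uniform disks convolved with a
  Gaussian PSF (\(\sigma = 1\) px) in a 256×256 px field at 0.135 µm/px —
  the pixel size that makes a 20 px bleach square span 2.7 µm. Noise is
  Poisson shot noise on photon counts (gain 2 a.u./photon) plus Gaussian
  read noise (sd 2 a.u.) and a constant offset (10 a.u.). Camera
  statistics are not dictated by the assay; this is the standard
  fluorescence-camera model with a controllable SNR.
- **Ground truth in the image plane.** Blur moves flux across the disk
  rim, so a disk whose *pre-blur* amplitude encodes ratio 3 measures ~2.6
  after a realistic PSF. The generator therefore calibrates each disk's
  amplitude so that the *post-blur* mean over the true disk equals the
  requested enrichment exactly; "true ratio" means the ratio an ideal
  measurement of the optical image would return. Recovery tests then probe
  noise, segmentation and surround estimation — not an optics bias that no
  estimator could remove.
- **Scene geometry.** One elliptical cell, granule radii ~N(5, 1) px
  truncated at 2 (≈1.35 µm diameter — typical SG scale), placed without
  overlap and with margins that keep surround annuli inside the cell. SG
  size and SNR distributions are free parameters of the config, not claims
  about any particular dataset.
- **Scripted movies** carry per-frame waypoints and an event list; fusion
  conserves disk area (\(r_c^2 = \sum r_p^2\)), validated at script
  construction. Builders keep approaching granules ≥ 4 px apart
  edge-to-edge until the scripted frame so segmentation cannot merge them
  early. Time-lapses render the marker channel only.
- **FRAP traces** follow the closed form
  \(roi(t) = L(t)[P(1-d) + d\,M_f(1 - e^{-kt'})P] + B\) with
  \(L(t) = (1-\ell)^{\text{frame}}\); the reference carries \(L(t)\) only.
- **Survival cohorts** are exponential (constant hazard) with right
  censoring at the observation window.
- Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; identical (spec, seed) pairs are bit-identical.

**What passing these tests shows — and what it does not.** The synthetic
scenes have flat cytoplasm, disk-shaped granules, a single cell, and exact
knowledge of the background. Real SGs are irregular, sit on textured
cytoplasm next to nuclei, and drift in z. Validation here demonstrates
that the estimators are unbiased and calibrated under a controlled imaging
model at realistic SNR; it does not certify performance on any particular
microscope's data, and segmentation parameters (band-pass scale, area
gates) should be reviewed against real granule sizes before use.

## Benchmark problem sizes

The packaged benchmarks (also run by `scripts/acceptance.R`) use: 25
scenes × 40 granules (1,000 granules over ratio classes 1, 1.2, 1.5, 2, 3);
100 FRAP traces at each of \(M_f \in \{0.2, 0.6, 0.9\}\) at 2% noise, plus
a 5-truth × 20-replicate monotonicity grid for the truth–recovery Spearman
correlation (with only three tied truth levels the attainable Spearman is
capped at ~0.943 by rank ties, so the monotonicity grid is the meaningful
design); 500 Costes repetitions × 200 rounds; a 20-movie event cohort (10
fusions, 10 fissions); 1,000 null and 200 alternative log-rank replicates;
and one rendered RNase pair at target fraction 0.88. These sizes give
sampling error comfortably below each check's tolerance.

## Numerical and interface choices

- Coordinates are R-native: 1-based (row, col), pixel centres at integer
  coordinates; areas in pixels, converted to µm² via the pixel size.
- Thresholding at \(\tau\) is strictly `>`, matching the assay convention
  (1.40 does not count at \(\tau = 1.4\)).
- SEM over fewer than two replicates is reported as `NA` (absent), never 0.
- TIFF output: 8/16-bit integer rasters error on saturation instead of
  clipping; float pages are IEEE float32 restricted to [0, 1] (the range
  the TIFF reader maps floats onto) — arbitrary-scale intensities belong
  in 16-bit.
- Area of near-resolution-limit remnants (radius ≲ 2 px) is PSF-limited:
  segmentation reports the blurred footprint, which overestimates the true
  disk area; the RNase benchmark therefore targets the high-retention
  regime where granules stay well above the resolution limit.
- The pipeline writes a resolved-config YAML and a version/seed log with
  every run; deterministic stages are byte-identical on rerun.

## Known limitations

Single-cell scenes (multi-cell instance separation is out of scope); no
gap closing or motion model in tracking (a fast granule beyond
`max_link_px` fragments into two tracks, by contract); single-exponential
FRAP only; no 3D rendering, spectral bleed-through or motion blur in the
simulator; Manders coefficients and Costes automatic thresholding are not
implemented.
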