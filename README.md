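# sgquant

Quantitative imaging analysis of stress granules (SGs) and their
conversion into an aberrant, misfolded-protein-containing state.

Stress granules are membrane-less RNP compartments that assemble under
stress and normally behave like liquid droplets: their components exchange
rapidly with the cytosol, the granules fuse and divide, and they dissolve
within minutes when their RNA scaffold is degraded. When misfolded proteins
(e.g. mutant SOD1 or a destabilised Ubc9) accumulate inside them, SGs turn
into something else — component mobility collapses, fusion and fission
stop, the granules resist RNase, and disassembly after stress is delayed.
`sgquant` implements the full quantitative readout used to establish that
transition from multi-channel fluorescence microscopy:

- **Segmentation** — granule detection on the marker channel
  (difference-of-Gaussians band-pass, Otsu threshold inside the cell mask,
  4-connected labelling), plus area, perimeter (Crofton) and circularity
  `C = 4πA / P²`.
- **Enrichment** — the per-granule relative enrichment ratio
  `R = mean(inside) / mean(surround)`, the fraction of granules with
  `R > τ` (thresholds 1.4 and 1.5), enrichment time courses, and Pearson
  correlation of enrichments across channels.
- **FRAP** — double normalization
  `F(t) = [ref_pre / ref(t)] · [roi(t) / roi_pre]`, single-exponential
  recovery fits `F(t') = F₀ + (F∞ − F₀)(1 − e^(−k t'))`, and the mobile
  fraction `Mf = (F∞ − F₀)/(1 − F₀)`.
- **Colocalization** — ROI-restricted Pearson correlation with a Costes
  block-randomization null (default 1,000 rounds, 0.12 µm blocks) and an
  add-one permutation p-value.
- **Dynamics** — nearest-neighbour tracking, fusion/fission event calling
  with area conservation, per-group event prevalence, and the fraction of
  SG area remaining after RNase microinjection.
- **Survival** — Kaplan–Meier curves of per-cell time to complete SG
  disassembly (Greenwood 95% CIs) and the two-group log-rank test.
- **Synthetic data** — a fully ground-truthed microscopy simulator
  (PSF-blurred granules with controlled enrichment, Poisson + Gaussian
  camera noise, scripted time-lapse fusion/fission/disassembly, FRAP traces
  with known mobile fraction, exponential disassembly cohorts) against
  which every stage is validated.

Everything is tidyverse-native: tables in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, `autoplot()` for each result type.

## Worked example

Render a synthetic cell whose granules all recruit the marker, with one in
five also enriching the probe threefold, then quantify it:

```r
library(sgquant)

sc <- render_scene(scene_spec(n_granules = 10,
                              probe_enrichment_ratios = c(1, 1, 1, 1, 3),
                              seed = 7))
gl <- segment_granules(sc$marker, sc$cell_mask)
gl
#> <granule_labels> 10 granules in 256 x 256 px

granules <- measure_granules(gl, list(marker = sc$marker, probe = sc$probe))
dplyr::select(granules, granule, area_um2, circularity, marker_ratio, probe_ratio)
#> # A tibble: 10 × 5
#>    granule area_um2 circularity marker_ratio probe_ratio
#>      <int>    <dbl>       <dbl>        <dbl>       <dbl>
#>  1       1    1.26        1.02          4.00       1.01
#>  2       2    1.00        1.03          3.91       2.94
#>  3       3    0.984       1.06          4.04       1.00
#>  4       4    2.70        0.976         4.12       3.02
#>  ...

classify_enriched(granules, threshold = 1.4)
#> # A tibble: 1 × 4
#>   threshold n_granules n_enriched fraction_enriched
#>       <dbl>      <int>      <int>             <dbl>
#> 1       1.4         10          2               0.2
```

Two of ten granules exceed the enrichment threshold `τ = 1.4`, matching the
scene's design (every fifth granule was rendered at true ratio 3, the rest
at 1). The per-granule circularities sit near 1, as they should for
disk-shaped granules, and the marker ratio is ~4 everywhere because the
marker defines the granules.

FRAP analysis of a simulated trace with a known mobile fraction of 0.6:

```r
tr  <- simulate_frap(frap_spec(true_mobile_fraction = 0.6, seed = 7))
fit <- frap_fit(frap_normalize(tr))
fit
#> <frap_fit> Mf = 0.606, k = 0.1116 /s, F0 = 0.213, Finf = 0.690 (converged)
autoplot(fit)   # recovery curve with the fitted exponential
```

Disassembly survival of two cohorts with different hazards (e.g. vehicle
vs an HSP70 inhibitor that delays disassembly):

```r
a <- sample_survival_cohort(34, 0.030, 120, "DMSO", seed = 7)
b <- sample_survival_cohort(29, 0.008, 120, "VER",  seed = 8)
logrank_test(a, b)
#> # A tibble: 1 × 5
#>   chisq    df p_value   n_a   n_b
#>   <dbl> <dbl>   <dbl> <int> <int>
#> 1  8.76     1 0.00307    34    29
autoplot(kaplan_meier(dplyr::bind_rows(a, b)))
```

The end-to-end still-image pipeline (simulate or load → segment → measure →
classify → write CSV/JSON under a stable layout) runs from a single config:

```r
res <- run_pipeline(run_config(
  simulate = list(n_granules = 12, probe_enrichment_ratios = c(1, 1, 3)),
  seed = 1, out_dir = "out/run1"
))
```

A thin command-line front end (`inst/cli/granule-qc.R`) exposes
`pipeline`, `simulate`, `frap`, `coloc` and `survival` subcommands over the
same functions.

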