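# flimfret

Quantifying drug–target engagement in living tissue from fluorescence
lifetime imaging (FLIM) acquired through a fiber-bundle confocal
endomicroscope.

## The problem

Doxorubicin intercalates into DNA. When the chromatin nearby carries a
histone–EGFP fusion (H1-EGFP), the intercalated drug sits within Förster
distance of the donor and quenches it by FRET, shortening the EGFP
fluorescence lifetime. A time-correlated single photon counting (TCSPC)
endomicroscope can therefore read out how much drug is actually engaged
with its chromatin target, nucleus by nucleus, in vivo — but only after a
chain of non-trivial processing: the tissue breathes, single 8.5 Hz
frames hold too few photons to fit, the fiber bundle adds strong
background, and doxorubicin's own emission bleeds into the donor channel.

`flimfret` implements that chain end to end:

1. **Motion gating** — frames are registered to a reference by
   normalized cross-correlation (NCC) template matching; frames scoring
   below 0.9 (0.8 for low-SNR data) are rejected as breathing-distorted,
   and the photon events of the surviving frames are re-accumulated onto
   a common grid (85 frames ≈ 10 s at 8.5 Hz).
2. **Nucleus segmentation** — background subtraction, smoothing, locally
   adaptive thresholding, erosion (3 px square) / dilation (2 px-radius
   disc), rejection of objects under 20 px, and distance-transform
   watershed to split touching nuclei.
3. **Decay fitting** — Poisson maximum-likelihood fits of the per-pixel
   and per-nucleus decay histograms. The donor decay is modelled as a
   two-component mixture,

   I(t) ∝ (1 − f)·e^(−t/τ_long) + f·e^(−t/τ_short),

   where `f` is the FRETing population fraction, τ_long the non-FRETing
   donor lifetime (2460 ps for the endomicroscope; 2330 ps on the
   laser-scanning microscope) and τ_short = 770 ps the FRET-quenched
   lifetime. τ_short is either fixed or profiled globally across all
   nuclei; the model includes the instrument response and the
   incomplete-decay wrap-around of the 12.5 ns (80 MHz) excitation
   period. Intensity-weighted mean lifetimes are τ_m = Σαᵢτᵢ²/Σαᵢτᵢ.
4. **Concentration calibration** — doxorubicin emission bleeds into the
   donor channel at ≈1 % of detected photons per µM; a monotone
   interpolated look-up table between `f` and the in-vitro dose ladder
   (0, 0.18, 0.9, 1.8, 9, 18 µM) converts fitted fractions into
   equivalent intracellular concentrations, censored outside the
   calibrated range.
5. **Cohort statistics** — per-nucleus records, normalized
   FRET-fraction and concentration histograms per group, and Welch
   (unequal-variance) two-tailed t-tests.

A fully synthetic TCSPC scene generator reproduces the statistical
structure of the real acquisitions (118 × 172 px frames, 256 micro-time
bins, 400–1000 photons per pixel per 10 s, Poisson counting noise,
breathing-like motion with sporadic non-rigid distortions), so every
stage is testable without instrument data.

## Worked example

Simulate a default in-vivo-like acquisition (12 nuclei, 85 frames,
20 % breathing-distorted), run the full chain, and read the per-nucleus
engagement estimates:

```r
library(flimfret)
res <- runPipeline(list(seed = 7, out_dir = "run1"))
#> simulate: 2108217 events, 12 nuclei
#> align: 73/85 frames accepted
#> accumulate: 1810987 photons pooled, 3020 dropped out-of-bounds
#> segment: 12 nuclei
#> fit: tau = 2460/770 ps, median f = 0.32
#> summarize: 12 nucleus records

head(res$records[, c("nucleus_id", "n_photons", "fret_fraction",
                     "tau_mean_iw_ps", "concentration_uM", "censoring")])
#>   nucleus_id n_photons fret_fraction tau_mean_iw_ps concentration_uM censoring
#> 1          1    242143     0.3078234       2253.497        0.7769456     exact
#> 2          2    180303     0.1136906       2394.764        0.1934541     exact
#> 3          3    144516     0.2527634       2298.195        0.5510410     exact
#> 4          4    127724     0.3274102       2236.544        0.8772541     exact
#> 5          5     97661     0.3228644       2240.531        0.8529877     exact
#> 6          6    164462     0.1950650       2340.846        0.3774599     exact
```

Each record is one segmented nucleus: its pooled photon count (all well
above the ~10⁴ photons a two-component fit needs), the fitted FRETing
population fraction `f`, the implied intensity-weighted mean lifetime,
and the equivalent doxorubicin concentration from the calibration table
(`censoring` marks estimates outside the calibrated range). The twelve
distorted frames were rejected by the 0.9 NCC gate; the remaining 73
frames contributed 1.8 M photons to the pooled image.

`res$summary$summary` aggregates the cohort (here one mouse, IP route):

```r
#>   group  n  f_median     f_q25     f_q75 conc_median_uM conc_median_is_bound
#> 1 M1/IP 12 0.3201915 0.2691027 0.3759851      0.8390953                FALSE
```

Because the scene is synthetic, `sceneNuclei(res$scene)` holds the
ground truth; on this run every fitted `f` lies within ±0.05 of its true
value.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/flim-pipeline.R --out run1 --seed 7
```

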