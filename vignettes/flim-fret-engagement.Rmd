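---
title: "Methods: FLIM-FRET drug-target engagement from TCSPC endomicroscopy"
author: "flimfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLIM-FRET drug-target engagement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `flimfret`, in the spirit of the methods sections of
mature analysis packages. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The physical model

A chromatin-tethered EGFP donor in a doxorubicin-treated nucleus is a
mixture of two populations: donors with an intercalated acceptor within
Förster distance, decaying with a short quenched lifetime
$\tau_s$ (770 ps), and unquenched donors at $\tau_l$ (2460 ps for the
endomicroscope channel, 2330 ps for the laser-scanning microscope).
The donor decay is

$$ I(t) \propto (1-f)\,e^{-t/\tau_l} + f\,e^{-t/\tau_s}, $$

with $f$ the **FRETing population fraction** — an amplitude (molecule)
fraction. Detected photons split differently: the photon share of the
short component is $f\tau_s / (f\tau_s + (1-f)\tau_l)$, because each
population contributes photons in proportion to (fraction x lifetime).
The package is explicit about this distinction: `expectedDecay()` takes
*photon*-fraction weights of individually normalized component curves
(so equal weights give the average of the component curves), while every
user-facing $f$ — simulation truth, fit results, calibration tables,
nucleus records — is a population fraction, converted internally. The
intensity-weighted mean lifetime uses the standard amplitude weighting
$\tau_m = \sum_i \alpha_i\tau_i^2 / \sum_i \alpha_i\tau_i$.

Two instrument effects are modelled exactly:

* **Incomplete decay.** At an 80 MHz repetition rate the 12.5 ns period
  is only ~5 lifetimes of the slow component; fluorescence excited by
  earlier pulses wraps into the observation window. The per-bin
  probabilities integrate the wrapped exponential in closed form
  (a geometric series), so a 2460 ps component carries its ~0.4%
  carry-over correctly instead of biasing the fit.
* **Instrument response.** Model curves are circularly convolved with a
  measured IRF histogram; the IRF temporal offset is calibrated from a
  reference dye of known lifetime by a bounded grid search of the
  Poisson likelihood (`estimateIrfOffset()`, default grid ±1 ns in
  10 ps steps), with a warning if the optimum sits on the grid edge.

## Estimators

All fits of raw histograms are **Poisson maximum likelihood**, not
least squares: TCSPC bins are Poisson counts and per-pixel counts are
low, where unweighted least squares is biased. The total amplitude is
profiled exactly (its MLE is the observed total), background enters as
a uniform mixture weight, and the remaining one- or two-dimensional
problems are solved by deterministic bounded golden-section searches
(`stats::optimize`, lifetime tolerance 0.05 ps, weight tolerance 1e-5).
The mixture log-likelihood is concave in the weight simplex, so the
nested one-dimensional searches converge; fits whose lifetime lands on
the search boundary are flagged `converged = FALSE` and excluded
downstream rather than silently kept. We chose bounded golden-section
search over a tail-regression initialization because it is equally
deterministic and cannot be misled by a poor starting bracket.

The **global bi-exponential fit** (`fitGlobalBiexp()`) profiles the
shared short lifetime on an outer one-dimensional search; for each
candidate $\tau_s$ the per-histogram fraction/background weights are
fitted independently (a variable-projection-like separation). With both
lifetimes fixed this reduces to independent per-histogram fraction
fits, which the test suite checks against a brute-force likelihood grid
(step $10^{-3}$). A fitted $\tau_s$ within 10 ps of $\tau_l$ raises a
degeneracy error advising a single-exponential model.

**Background correction** (`correctBackground()`) subtracts the scaled
blank (probe-in-water) histogram bin-wise and attaches first-order
counting-statistics variances, $\mathrm{var}_i = \mathrm{raw}_i +
r^2\,\mathrm{blank}_i$. Corrected histograms may hold negative bins;
they are fitted by variance-weighted least squares, since their bins
are no longer Poisson.

**Pixel maps** (`pixelFractionMap()`) box-sum the per-pixel histograms
over a 3 x 3 neighbourhood before fitting. Summing histograms (rather
than smoothing fitted maps) was chosen because it conserves photons and
keeps the Poisson model exact. Only pixels with strictly more than 300
photons after summing are fitted; per-nucleus values average the
qualifying pixels.

## Motion gating

Registration is exhaustive integer-shift normalized cross-correlation
(Pearson correlation of the template against every displaced patch in a
±15 px window). Integer shifts suffice because photon events are
re-binned, not interpolated; NCC ties are broken by smallest shift
magnitude, then row-major order, for determinism. Frames scoring below
the gate (default 0.9, configurable down to 0.8 for low-SNR data) are
rejected outright — distorted frames are discarded, never warped back.

Two defaults required decisions the acquisition convention leaves open:

* **Template**: the central sub-region covering 50% of the frame area,
  cut from the reference frame; user-overridable.
* **Reference frame**: the first *good-quality* frame. Quality cannot
  be known before alignment, so frames are pre-screened against a
  template cut from the pixel-wise median image (robust to the minority
  of distorted frames); the first frame scoring at or above the gate
  becomes the reference. Taking frame 0 unconditionally poisons the
  whole acquisition whenever the first frame happens to fall in a
  breathing event.

Per-frame registration images are photon-count images smoothed with a
σ = 1 px Gaussian: single frames at 8.5 Hz hold ~1 photon per pixel and
raw-count NCC is noise-dominated.

## Segmentation

The chain is: background subtraction → Gaussian smoothing (σ = 1 px; the
convention states "smoothed" without parameters) → locally adaptive
threshold → erosion by a 3 px square → dilation by a 2 px-radius disc →
removal of objects under 20 px (strict) → watershed on the inverted
Euclidean distance transform, with shallow basins merged below a 1 px
depth tolerance to prevent over-segmentation from pixel-level minima.
Label maps are renumbered 1..N and the area rule re-applied after
splitting.

The adaptive threshold subtracts the local box mean (window 31 px,
optionally plus *k* local standard deviations, default *k* = 0) and
splits the residual by Otsu's criterion. Every step is linear in the
image, so masks are invariant to global multiplicative rescaling, and
the local mean removes the illumination gradients across the fiber
bundle that defeat a global threshold. The literature method cited for
this step (a minimax-optimized threshold) is replaced by this rule
deliberately: the pipeline's guarantees are segmentation-recovery
properties on truth-known fixtures, not method identity, and the rule
used is recorded in the run configuration. One guard was added during
development: the threshold never falls below five robust noise units
(MAD of adjacent-pixel differences, which ignores smooth structure), so
a field of pure counting noise yields an empty mask instead of speckle.

## Calibration

Doxorubicin emission in the donor channel is modelled as a linear
bleed-through of `bleed_coeff` (default 0.01) of detected photons per
µM, capped at 0.5 with a warning since the linear law is an in-range
approximation. The dose-response look-up table maps concentration to
the FRETing population fraction by shape-preserving monotone (Hyman)
spline interpolation, exact at the knots; the inverse is found by
bisection to 1e-4 µM. Fractions outside the calibrated span are
censored (`below_range` at 0, `above_range` at the top dose —
the binding-saturation plateau makes higher doses indistinguishable).

The packaged table `inst/extdata/calibration_synthetic.csv` is a
**synthetic** logistic-saturation stand-in, $f(C) = 0.7\,C/(C+1\,\mu M)$
over the standard dose ladder: the measured calibration values are not
published as numbers. It reproduces the qualitative shape that matters
— steepest response at sub-micromolar doses, plateau at high doses —
and is labelled synthetic wherever it appears.

`forwardMeanLifetimeCurve()` predicts the measured mean lifetime versus
dose with and without FRET; the gap between the curves is what
separates genuine donor quenching from the bleed-through artefact. The
doxorubicin emission lifetime entering that mixture is not published;
it is an explicit parameter (default 1.0 ns), flagged as an assumption.

## The synthetic scene generator

`makeScene()` / `samplePhotonEvents()` emulate the acquisition's
statistical structure with defaults equal to the real conditions:
118 x 172 px frames at 8.5 Hz, 256 micro-time bins over 12.5 ns, 85
frames (10 s), nuclei of radius 5-10 px bright enough for 400-1000
photons per pixel per window, uniform instrument background (default
0.1 photons/px/frame), 1%/µM bleed-through, and per-pixel Poisson
counts. True FRET fractions default to the 0.1-0.6 span observed in
dosed tissue, and each nucleus' true concentration is derived from its
fraction through the same calibration used for inversion, keeping truth
and estimate commensurable. Motion is a bounded integer random walk
(reflecting bound 3 px); a configurable fraction of frames (default
20%) receives a random affine warp whose translation and edge-of-field
differential displacement are drawn from ±(4-8) px, plus 1 px of local
scatter — large enough that a flagged frame is genuinely unalignable,
producing both alignable and reject-able frames as in vivo. All
randomness flows through one seed with fixed substream labels, so every
object is bit-reproducible.

What the generator does **not** model — and hence what passing tests do
not show about real data: the fiber-core mosaic and optical PSF,
chromatin texture within nuclei (discs with a Gaussian rim of σ = 1 px),
detector afterpulsing and pile-up (acquisition is assumed kept at ≤1%
of the repetition rate), non-uniform fiber autofluorescence (background
is uniform), and genuinely non-rigid slow tissue drift between
accepted frames.

## File formats

Photon event streams are stored as an open columnar text format —
`#key=value` metadata lines followed by CSV columns
`frame,row,col,tbin`, all 0-based, written in (frame,row,col,tbin) sort
order so write/read round-trips are bit-exact. Pixel coordinates are
0-based row-major `(row, col)`; micro-time bins are 0-based half-open.
Intensity stacks and label maps are 16-bit multi-page TIFF (values
above 65535 clip with a warning); calibration tables are CSV with
optional `#key=value` headers; run configurations are YAML, resolved
and logged verbatim into every output directory. Vendor binary TCSPC
formats are out of scope; converting them is a user-supplied step.

## Problem sizes used by the test suite

The suite exercises the chain at sizes chosen to make statistical
assertions sharp while staying lightweight: 2000 Monte-Carlo decays for
the 100-photon precision law (with 500-replicate checks of the
$N^{-1/2}$ scaling at 400 and 1600 photons); 100 random histograms for
the likelihood-grid equivalence; 50 simulated nuclei at ≥10⁴ photons
for global-fit recovery; 50 synthetic scenes (96 x 96 px, 6 nuclei) for
the segmentation benchmark; and one full default acquisition
(118 x 172 px, 85 frames, 12 nuclei, 20% distorted) for the end-to-end
recovery check.

## Known limitations

* The two-component donor model absorbs unmodelled bleed-through
  photons partly into the short component, biasing $f$ upward by a few
  hundredths at high doses; in practice the effect is folded into the
  empirical calibration, but simulation truth and fit differ by it.
* Censored concentration estimates make the method semi-quantitative
  above the top calibrated dose.
* No sub-pixel registration: shifts are integer pixels by design.
* No ≥3-component or stretched-exponential decay models, and no phasor
  analysis.
* Welch-Satterthwaite degrees of freedom are always reported for group
  comparisons, whatever convention other software uses.
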