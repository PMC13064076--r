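---
title: "Methods: ratiometric astrocyte Ca2+ analysis with multi-threshold event detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric astrocyte Ca2+ analysis with multi-threshold event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromted)
```

## The measurement model

The sensor is a tandem construct: the Ca2+-sensitive green fluorophore
(GCaMP6s) is covalently linked 1:1 to a Ca2+-insensitive red fluorophore
(tdTomato). Both channels therefore scale with the same local indicator
concentration, which in turn scales with how much of the optical voxel the
cell occupies (the volume fraction, VF). Per pixel and frame the noiseless
model is

* green: `F = g · vf · (1 + (R − 1) · θ(ca))`
* red:   `F_red = g · vf · c`

with expression gain `g`, red/green brightness ratio `c`, sensor dynamic
range `R` (brightness at saturating vs zero Ca2+) and Hill saturation
`θ(ca) = ca^n / (Kd^n + ca^n)`, `Kd = 144 nM`, `n = 2.45`. Resting Ca2+ in
these cultures is taken as 50 nM.

The activity signal is the ratiometric `ΔF/F_R = (F − F_R)/F_R`, where `F_R`
is the tdTomato image rescaled so that it equals the *zero-Ca2+* green
fluorescence. Because the measurable per-pixel baseline `F0` reflects green
brightness at *resting* (not zero) Ca2+, the scaling factor divides the
baseline ratio by the Hill-model resting brightness:

`scale_k = median(F0_green / F0_red over cell pixels) / (1 + (R − 1)·θ(ca_rest))`.

One `scale_k` is calibrated on designated control recordings and reused for
every measurement of a dataset, so basal levels stay comparable across
recordings; per-recording recalibration is available by simply calling
`compute_scale_factor()` per movie. The reference is static per pixel —
tdTomato is assumed photostable over a 10-minute recording; per-frame
referencing is deliberately out of scope.

### Assumptions

* channels are registered and the 2×2 spectral mixing matrix is known and
  invertible (diagonally dominant in any sane optical configuration);
* no sample drift or photobleaching correction is needed (monolayer
  cultures on a thermally stabilized stage);
* the resting ΔF/F_R lies below the lowest detection threshold — see the
  discussion of the dynamic range below.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `kd`, `hill_n` | 144, 2.45 | nM, – | published GCaMP6s constants |
| `basal_ca` | 50 | nM | assumed resting level in these cultures |
| `dyn_range` | 50 (`hill_params()`), 6 (simulated recordings) | – | see below |
| F0 `window`, `percentile` | 100 frames, 8th | – | robust minimal-brightness proxy |
| ladder | 0.5, 1, 2, 3, 4, 5, 7, 10, 15, 20 | ΔF/F_R | spans the analysis range; includes the focal levels 2, 5, 10 |
| `min_area`, `min_frames` | 4 px, 2 frames | – | rejects single-voxel noise, keeps microdomain events |
| `connectivity` | 26 | – | events are contiguous spatiotemporal volumes; 6/18 selectable |
| `vf_max` | 12.5 | % | peripheral band of the basal analysis |
| histogram bins | 32 log-spaced per feature | feature units | heavy-tailed features |
| NMF `k`, `restarts` | 3, 10 | – | three interpretable components; best-of-restarts reproducibility |
| LDA `shrinkage` | 0.1 | – | within-class covariance ridge for wide feature spaces |

### The sensor dynamic range

The in-situ dynamic range of GCaMP6s is not fixed by the calibration
constants, so it is an explicit free parameter everywhere (`dyn_range`,
must only exceed 1). The package-wide default of 50 reflects purified-protein
measurements. For *simulated validation recordings* the default is 6, for a
self-consistency reason: with the zero-Ca2+-referenced definition, the
resting signal is `ΔF/F_R = (R − 1)·θ(50 nM) = 0.0697·(R − 1)`. A
threshold ladder that starts at 0.5 is only meaningful when rest sits below
it, i.e. `R < 8.2`; at `R = 6` rest is 0.35. This choice was made once, on
that argument, and all analysis code remains valid for any `R > 1`.

## Baseline estimation (F0)

`estimate_f0()` computes, per pixel, a low percentile (default 8th) within
windows of 100 frames advancing by half a window, smooths that envelope with
a 3-point moving average, and takes the temporal minimum. The half-window
stride keeps the estimator `O(T/w)` quantile evaluations per pixel with no
practical accuracy cost: a constant trace returns exactly the constant, and
a step trace (100 → 300 halfway) returns exactly 100 because some window
always lies inside the low regime. Transients shorter than ~92 % of a window
cannot drag the low percentile up, which is why sparse Ca2+ events do not
bias the baseline.

## Event detection and features

At each ladder level the stack is binarized at `ΔF/F_R ≥ level` and
connected components are labeled in (x, y, t) under 26-connectivity (the
adjacency graph is handed to igraph; a brute-force flood fill in the test
suite serves as the independent oracle). Components never reaching
`min_area` pixels in any frame, or spanning fewer than `min_frames` frames,
are discarded. Per event:

* **max size** — peak instantaneous suprathreshold area, µm²;
* **duration** — frames spanned × frame interval, s;
* **distance** — maximal displacement of the intensity-weighted centroid
  from its position in the first event frame (not path length), µm;
* **max slope** — maximal frame-to-frame increase of the footprint-mean
  ΔF/F_R, s⁻¹. The footprint mean (not the single-pixel maximum) is used for
  robustness to pixel noise. The onset frame is compared against the same
  pixels one frame earlier, so the rise from baseline belongs to the event;
  without this the steepest part of a fast-rising event would be invisible
  to the detector. Single-frame components report 0 with
  `slope_defined = FALSE`.

Event counts are reported per cell (cell count is supplied metadata — known
in simulations, manually counted in real fields of view; automated
segmentation is out of scope) and rescaled to a common 600-s recording
equivalent.

A deliberate property of multi-threshold segmentation: a component at a
higher threshold is always spatially and temporally contained in a component
at any lower threshold. Counts are non-increasing in the threshold for
well-separated single-peak events; multi-peak components can legitimately
split as the threshold rises, which is a feature of the representation, not
a bug.

## Histograms and group statistics

Per recording, events are binned per (threshold, feature) into 32 log-spaced
bins, divided by the cell count, rescaled to 600 s, and then averaged across
the recordings of a group with equal weight — the recording is the
statistical unit. Pooling all events before scaling is the natural
alternative; averaging was chosen because group sizes are given in
recordings and it keeps one noisy recording from dominating, and the choice
is confined to `accumulate_histograms()` (a pooled variant is a three-line
change). Out-of-range events are clamped into the edge bins and counted.

## Volume-fraction basal analysis

Within each cell the reference `F_R` is normalized to that cell's 99th
percentile (the soma anchor) and expressed in percent. The percentile (not
the maximum) makes the anchor robust to isolated bright pixels; per-cell
(not global) normalization makes VF a within-cell morphological quantity
independent of expression level. In the peripheral band (VF ≤ 12.5 %), the
per-cell mean of `F0_green / F_R` is the basal ratio: exactly 1 at zero
Ca2+, increasing monotonically with resting Ca2+, and independent of any
common gain on both channels. Hill inversion maps the mean ratio to nM; the
dimensionless ratio remains the primary readout because the inversion —
unlike the ratio — depends on the assumed dynamic range.

## Decomposition

The four per-threshold histograms of each recording are concatenated into
one non-negative row of X. Per-feature-block max normalization (default)
stops large-magnitude blocks from dominating the factorization; raw
frequencies are available (`normalization = "none"`). NMF minimizes the
Frobenius error with alternating nonnegative coordinate descent (HALS),
starting from a deterministic nonnegative-double-SVD initialization plus
seeded random restarts, keeping the best fit — reproducible for a fixed
seed. Recovery tests match components by exhaustive assignment on cosine
similarity, since NMF is identifiable only up to permutation and scale.

LDA runs in the principal-component span of the centered matrix with a
trace-scaled ridge on the within-class scatter
(`(1 − λ)S_w + λ·tr(S_w)/p·I`, λ = 0.1); this keeps the projection defined
when features far outnumber recordings and leaves the separation statistic
invariant under common affine rescaling of the features. Whether the
discriminant should be fit on the same concatenated histogram space as NMF
is an open design point; the package does so, which keeps the two analyses
comparable on identical inputs.

## What the simulator does and does not emulate

`simulate_recording()` generates: soma discs (VF 1) with processes decaying
linearly from VF 0.6 to 0.05 (guaranteeing pixels in the ≤ 12.5 % band);
planted events with linear Ca2+ rise and exponential decay (τ = 1.5 s,
truncated at the planned offset); Hill-model rendering with channel
crosstalk; optional Poisson shot noise and Gaussian read noise (off by
default, so algorithmic correctness is tested separately from robustness).
Ground-truth features are computed analytically from the plant parameters
through the same Hill model, never from the rendered movie — the test
suite's brute-force feature computations on the concentration movie confirm
the two agree.

The generator is a correctness oracle, not a tissue model: it makes no
attempt to reproduce realistic event-rate statistics, event morphology
(plants are squares), Ca2+ buffering or diffusion, bleaching, or motion.
Passing its tests demonstrates that the algorithms compute what they claim
on data obeying the stated model — not that the biological numbers of any
real condition would be reproduced.

## Problem sizes and numerical choices

Validation recordings default to 128×128 px, 600 frames at 5 frames/s
(2 minutes), 1–3 cells — the full 10-minute, full-field scale is supported
by the same code paths. Event kinetics in the planted defaults (peak
1000 nM, 15 frames) keep the whole planted span above threshold 2, so
detected durations are exactly comparable to ground truth. Negative
intensities after unmixing are clipped to 0 (count reported); pixels whose
reference falls below the configurable floor are masked out; θ = 1 is an
error in the Hill inversion rather than `Inf`, so saturation must be handled
explicitly by the caller.

## Known limitations

* No motion or bleaching correction; recordings must be stable.
* No subcellular compartment assignment — activity is analyzed over the
  complete cell.
* Cell counts and cell label maps are inputs, not outputs.
* Inferential statistics on the resulting curves (ANOVA and friends) are
  intentionally not reimplemented; the tidy tables are the export surface.
* The nM basal estimates inherit the uncertainty of the assumed dynamic
  range; ratios of estimates between conditions are far more trustworthy
  than absolute concentrations.
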