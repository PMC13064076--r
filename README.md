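# astromted

Analysis of endogenous astrocyte Ca²⁺ activity from two-channel
(GCaMP6s/tdTomato) time-lapse recordings, for labs using ratiometric
genetically encoded Ca²⁺ indicators in cultured astrocytes. The package
covers the whole path from raw dual-channel movies to condition-level
activity patterns:

1. **Ratiometric normalization.** The activity signal is
   ΔF/F_R = (F − F_R)/F_R, where F is the GCaMP6s fluorescence and F_R the
   scaled tdTomato reference. Spectral unmixing undoes channel crosstalk; a
   sliding-window low-percentile filter estimates the per-pixel baseline F₀;
   and the global scaling factor
   k = median(F₀ᵍ/F₀ʳ) / (1 + (R − 1)·θ(Ca²⁺_rest)) places F_R at the green
   fluorescence expected at zero Ca²⁺, using the GCaMP6s Hill model
   θ(c) = cⁿ/(K_dⁿ + cⁿ) with K_d = 144 nM and n = 2.45.
2. **Multi-threshold event detection (MTED).** ΔF/F_R is binarized at a
   ladder of thresholds (default 0.5–20); spatiotemporal connected
   components at each level become Ca²⁺ events, each described by its
   maximal size (µm²), duration (s), center displacement (µm) and maximal
   ΔF/F_R slope (s⁻¹).
3. **Feature statistics.** Per-cell-scaled, per-recording frequency
   histograms across the threshold ladder, cumulative size curves, and
   simple proportion summaries.
4. **Volume-fraction (VF) basal analysis.** The reference channel maps the
   fraction of each optical voxel occupied by the cell; in thin peripheral
   processes (VF ≤ 12.5 %) the ratio F₀ᵍ/F_R reads out relative basal Ca²⁺,
   and Hill inversion converts it to nM.
5. **Pattern decomposition.** Recording-level feature histograms are
   concatenated into a non-negative matrix X and factorized as X ≈ WH
   (NMF, k = 3 by default, best-of-restarts coordinate descent), and
   projected by shrinkage LDA to separate treatment conditions
   (e.g. Ctrl / 3 h LPS / 24 h LPS).

A synthetic-movie generator with fully known ground truth (cell geometry,
planted events, Hill-model rendering, optional shot/read noise) backs every
stage with an oracle, so the pipeline is validated end-to-end without any
proprietary imaging data.

## Worked example

```r
library(astromted)

# a 2-minute, 128x128 px validation recording: 2 cells, 10 planted events
sim  <- simulate_recording(n_cells = 2, fov = 128, n_frames = 600,
                           n_events = 10, seed = 3)
norm <- normalize_movie(sim$movie, hill = sim$hill,
                        cell_mask = sim$geometry$cell_labels > 0)
ev   <- detect_events(norm$dff, n_cells = 2)
threshold_profile(ev)[1:5, 1:4]
#>   threshold n_events events_per_cell events_per_cell_600s
#> 1       0.5       10               5                   25
#> 2       1.0       10               5                   25
#> 3       2.0       10               5                   25
#> 4       3.0       10               5                   25
#> 5       4.0       10               5                   25
```

All ten planted events are recovered at every threshold they reach: 5 events
per cell in the 2-minute recording, i.e. 25 events/cell when rescaled to the
common 600-s recording equivalent. At threshold 2 the recovered features
match the analytic ground truth exactly (e.g. `max_size_um2` 81 = the 9×9 px
planted square at 1 µm/px; `duration_s` 3 = 15 frames at 5 frames/s).

Downstream, per-recording histograms feed the decomposition:

```r
hists <- list(r1 = accumulate_histograms(ev))      # one per recording
fm    <- build_feature_matrix(hists, labels = "Ctrl")
fit   <- run_nmf(fm, k = 3, seed = 1)              # X ~ WH
glance(fit)                                        # error, iterations, ...
autoplot(fit)                                      # condition-wise weights
```

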