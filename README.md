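# nmjquant

Quantitative analysis of *Drosophila* larval neuromuscular-junction (NMJ)
presynapses, packaged as one tested pipeline:

* **Confocal punctum quantification** — HRP-mask construction, per-slice
  muscle-signal exclusion, maximum projection, prominence-based spot
  detection (Fiji *Find Maxima* semantics), seeded-watershed splitting of
  touching puncta, and the standard NMJ metrics (mean active-zone area,
  density per µm² of HRP area, per-spot mean intensity, integrated
  density, NMJ length by mask skeletonization).
* **Colocalization** — Pearson's coefficient above Costes auto-thresholds
  (orthogonal regression + descending threshold scan), with the
  horizontally-flipped-channel negative control.
* **Nanoscale STED analyses** — active-zone ring centers of mass in
  53 × 53-px ROIs, ranked spot-to-center distances (k1…k5), AZ size bins,
  counts within 400 nm, and radial intensity profiles around cluster
  centers found by Tsai's moments-preserving auto-threshold.
* **Electrophysiology** — 500-Hz Gaussian filtering, Clements–Bekkers
  scaled-template miniature-event detection, evoked averaging with
  stimulus-artifact excision, 10–90 % rise time, exponential decay τ,
  charge, quantal content, paired-pulse ratios, and readily-releasable-pool
  (RRP) estimation by back-extrapolating cumulative quantal content of a
  100-Hz / 61-stimulation train: an OLS line through the last 20 cumulative
  points whose y-intercept is the RRP (quanta) and slope the refill rate.
* **Behavior & statistics** — T-maze choice/performance indices,
  D'Agostino–Pearson omnibus normality, the normality-gated decision tree
  (t test / ANOVA + Tukey / Mann–Whitney), and iterated two-sided Grubbs
  outlier screening.
* **Synthetic data with ground truth** — generators for every input the
  pipeline consumes (bouton-chain NMJ stacks with muscle distractors,
  annular STED scaffolds with partner dots at exact offsets, correlated
  image pairs, mini/evoked/train traces from a depressing-release model,
  reciprocal T-maze counts), so every stage is testable end to end without
  any external download.

## Worked example

Simulate an NMJ with 50 puncta plus muscle distractors, run the full
confocal chain, and estimate the RRP from a synthetic train:

```r
library(nmjquant)

sim     <- make_nmj_stack(nmj_sim_params(n_spots = 50, seed = 1))
cleaned <- clean_stack_per_slice(sim$stack, "spots", "HRP", threshold = 50)
proj    <- max_project(cleaned, "spots")
maxima  <- find_maxima(proj, prominence = 150)
labels  <- segment_spots(proj, threshold = 300, maxima)
spots   <- measure_spots(labels, proj, pixel_pitch_um = 0.1)
hrp     <- make_mask(max_project(sim$stack, "HRP"), 50, pixel_pitch_um = 0.1)
nmj_metrics(spots, hrp, proj,
            nmj_length_um = skeleton_length(hrp$data, 0.1))
#> $total_spot_count     50          # every simulated punctum, none missed
#> $mean_spot_area_um2   0.0978      # supra-threshold punctum footprint
#> $mean_spot_intensity  434
#> $spot_density_per_um2 0.539       # 50 puncta / 92.8 um2 of HRP area
#> $total_intensity      436018      # integrated density inside the mask
#> $nmj_area_um2         92.8
#> $nmj_length_um        27.3

p     <- release_model_params(N0 = 500, p_release = 0.3,
                              refill_per_stim = 3, q = 0.7, seed = 1)
train <- make_train_trace(p)
estimate_rrp(train$trace, mean_mini_amp = -0.7, artifact_s = 3e-4)
#> RRP 483.3 quanta, refill 2.96 quanta/stim, R^2 1.0000
```

The recovered intercept sits ~3 % below the true pool of 500: the
refill-corrected expectation of the depletion recurrence is
N0 − refill/p = 490, and the pre-artifact baseline rule under 100-Hz
response overlap accounts for the remainder (see the methods vignette).

The quantal content of the printed control amplitudes, −55.43 nA evoked
over −0.70 nA miniature, is `quantal_content(-55.43, -0.70)` → **79.2**.
A reciprocal T-maze pair with 90 % avoidance gives

```r
counts <- make_tmaze_counts(n_flies = 45, p_avoid_cs_plus = 0.9, seed = 1)
performance_index_from_counts(counts)
#> 0.844
```

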