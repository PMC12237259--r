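---
title: "Quantifying NMJ presynapses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NMJ presynapses: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

`nmjquant` re-implements, as a single tested pipeline, the quantitative
analyses that underlie presynapse studies at the Drosophila larval
neuromuscular junction (NMJ): punctum quantification in confocal stacks
restricted to an HRP-derived neuronal mask, Pearson colocalization with an
automatic threshold, nanoscale distance and radial-profile analyses of
STED images, electrophysiological trace metrics up to
readily-releasable-pool (RRP) estimation, and T-maze behavioral indices
with the accompanying statistical decision tree. Because the raw microscope
and electrode data behind such studies are rarely deposited, the package
ships a synthetic-data module that generates every input with known ground
truth; all recovery claims below refer to that synthetic regime.

## Confocal punctum quantification

The imaging unit is a two-channel z-stack: a membrane channel (anti-HRP,
labeling the neuronal surface) and a punctum channel (e.g. the active-zone
scaffold BRP, early endosomes, or mitochondria). The analysis chain is:

1. **Masking.** The HRP channel defines a binary mask (`make_mask`); all
   quantities are restricted to it. For proteins with a muscle-tissue
   contribution, `clean_stack_per_slice` builds an HRP mask *per optical
   slice* and zeroes all punctum signal outside it before projection, so
   out-of-terminal structures directly below or above the NMJ do not leak
   into the maximum projection.
2. **Projection and background.** `max_project` collapses z by per-pixel
   maximum; `subtract_background` removes a scalar estimate (fixed value,
   histogram mode, or the mean of an empty ROI) with clamping at zero. The
   estimate and strategy are recorded on the result, since a manual
   threshold choice is otherwise irreproducible.
3. **Segmentation.** `find_maxima` detects punctum seeds as 8-connected
   local maxima whose prominence above the surrounding saddle exceeds a
   noise tolerance — the semantics of the Fiji *Find Maxima* command. The
   plateau rule had to be pinned down explicitly: the representative point
   is the plateau centroid rounded to the nearest pixel, exact halves
   toward the smaller index. `segment_spots` then splits the
   supra-threshold mask (same threshold as the NMJ mask) into one region
   per seed by a marker-seeded watershed (descending-intensity priority
   flood). This replaces the manual pencil-tool splitting of touching
   puncta with its automated equivalent; touching puncta are divided at
   their intensity saddle.
4. **Measurement.** `measure_spots` reports per-punctum area, centroid,
   mean and integrated intensity, measured on the original unmodified image
   restricted to the label support (the "min" image-calculator idiom).
   Labels below an area cut-off are removed *before* any statistic; the
   early-endosome analyses use 0.0202 µm². `nmj_metrics` aggregates: mean
   punctum area, density (count / HRP-mask area), unweighted mean of
   per-punctum mean intensities (not area-weighted), total count, and
   integrated density over the mask.

NMJ length is the one place where a manual step is replaced by a
surrogate rather than an equivalent: instead of hand-drawn branch lines,
`skeleton_length` thins the HRP mask (Zhang–Suen) and sums skeleton edge
lengths with axial steps of one pixel and diagonal steps of √2, skipping
diagonals short-cut by an axial neighbor. On thick masks the skeleton ends
retract by roughly half the local width; only length-normalized metrics are
affected, and the tests therefore exercise thin analytic shapes.

Coordinates follow R's 1-based, (y, x), pixel-center convention throughout;
areas are pixel counts × pitch². Group comparisons are reported as percent
of control via `normalize_to_control` (control mean ↦ 100 exactly); rescue
assays with an unspecific driver background subtract the background group's
mean first, which maps that group to 0.

## Colocalization

`pearson_above_threshold` computes the Pearson coefficient over mask
pixels where at least one channel exceeds its automatic threshold — pixels
sub-threshold in *both* channels are excluded, the colocalization-plugin
convention. Thresholds come from `costes_thresholds`: candidate levels for
channel 1 walk downward along the orthogonal (total-least-squares)
regression line, and the first (highest) pair at which the sub-threshold
pixels' correlation is ≤ 0 (or undefined) is kept. Before thresholding,
images are rescaled so their maximum is 256 exactly (`normalize_to_256`);
the pipeline applies this normalization before thresholding, which is the
order the procedure implies. The negative control mirrors channel 2
horizontally and repeats the whole procedure. A documented caveat: a
left-right symmetric image correlates perfectly with its own mirror, so
the control is only meaningful for asymmetric content — the test suite
asserts this failure mode explicitly rather than hiding it.

## Nanoscale (STED) analyses

At STED resolution the BRP C-terminal label resolves planar active zones
(AZs) as rings. `kneighbor_analysis` reproduces the K-neighbor recipe:
53 × 53-px regions of interest (1.06 µm at the 20-nm default pitch) are
cropped around each AZ; the ring center is the intensity-weighted center
of mass after subtracting the ROI minimum (subpixel, the XM/YM
convention); partner-channel spots are Find-Maxima points (integer pixel
coordinates, the ImageJ convention); `kneighbor` ranks the Euclidean
center-to-spot distances in nm, k1 being the minimum. AZ areas in px² are
binned small [1, 159], middle [160, 215], big > 215 — the printed upper
bin label is internally inconsistent with the middle bin's edges, so the
bin is implemented as "> 215" and flagged here. `count_within_radius`
counts spots within 400 nm (inclusive boundary). Since ring centers are
subpixel but spot coordinates are integer pixels, recovered k1 values are
accurate to half a pixel (10 nm at 20-nm pitch) by construction; that is
the bound the acceptance suite asserts.

`radial_profile` measures annulus-mean intensity versus radius in both
channels around cluster centers obtained by Moments auto-thresholding plus
Find Maxima (`radial_profile_centers`). `moments_threshold` is the Tsai
moments-preserving threshold: the below-fraction is solved in closed form
from the first three gray-level moments of a 256-bin histogram and the
threshold is the corresponding histogram p-tile, so adding a constant to
the image shifts the threshold by that constant. Radial bins are centered
on multiples of the bin width (default 20 nm, one STED pixel), so a ring
of radius 120 nm peaks in the bin labeled 120. Aggregation follows the
published hierarchy: per-cluster profiles → per-image median → group mean
with a Student-t 95 % confidence interval on n − 1 degrees of freedom
(the paper states only "95 % confidence intervals"; t-based is the choice
made here, and "normalized" group profiles divide by the maximum mean
bin, which is likewise not defined in the source and declared here).

## Electrophysiology

Traces are uniformly sampled sweeps (10 kHz by default) with stimulus
annotations; inward currents are negative. `gaussian_lowpass` implements
the 500-Hz Gaussian filter with the convention |H(f~c~)| = ½, fixing the
kernel sd at √(ln 2 / 2)/(π f~c~); conventions differ between packages, so
this one is stated rather than assumed.

**Miniature events.** `detect_minis` is a sliding scaled-template
(Clements–Bekkers) detector: at each offset the template is optimally
scaled and offset in least squares, and the detection criterion is the
scale divided by the *fitting-error* standard error √(SSE/(N−1)). With a
realistic-amplitude template the criterion reads "fitted event amplitude
in units of residual noise", and the conventional threshold of 3.5 applies.
Two consequences are documented rather than hidden: (i) the template must
carry a physically sensible amplitude (a unit-peak kernel times the
expected mini size); (ii) the calibration assumes residuals uncorrelated
at the sampling rate, so for band-limited data the matching should run on
a decimated copy (the `decimate` argument; event times are reported on the
original clock). Events are criterion-peak points of contiguous
above-threshold excursions with a refractory merge; events closer than one
template length fuse into a single excursion and are counted once — an
inherent limitation of single-template matching that bounds recall near
(1 − rate × template length). At the synthetic study conditions (90-s
traces, 1 Hz, SNR 5, threshold 3.5) pooled recall is ≈ 0.96 with a
false-positive rate well under 0.1 Hz.

**Evoked metrics.** `average_evoked` aligns sweeps on stimuli (20 sweeps
for 0.2-Hz and 10-ms paired-pulse data, 10 for 30-ms paired pulse),
subtracts per-sweep pre-stimulus baselines, and excises the stimulus
artifact over a configurable window (default 1 ms; the width is not
recorded in the source procedure) by linear interpolation. `rise_time` is
the interpolated 10–90 % time before the peak (last 10 % crossing, first
90 % crossing — the tie-break for non-monotonic rises). `decay_tau` fits
A·e^(−t/τ) on the magnitude trace between the 60 % and 5 % post-peak
crossings (nonlinear least squares started from the log-linear fit;
magnitude fitting keeps A > 0 regardless of sign convention). `charge` is
the trapezoidal integral (nA·ms = pC). `quantal_content` divides evoked by
mean mini amplitude; `paired_pulse_ratio` takes the second amplitude from
the last point before the second artifact onset, the first from the sweep
baseline.

**RRP back-extrapolation.** For a 100-Hz train of 61 stimuli,
`estimate_rrp` extracts per-stimulus amplitudes with the pre-artifact
baseline rule, converts to quanta, accumulates, and fits an ordinary
least-squares line to the last 20 cumulative points; the y-intercept is
the RRP in quanta and the slope the refill rate per stimulus. The
amplitude-extraction window must start after the artifact ends; with the
synthetic 2-sample artifact, an 0.3-ms window retains the response peak.
Residual bias of the baseline rule under 100-Hz overlap (each response
rides the previous decay) leaves the recovered intercept ≈ 3 % below the
true pool at the default kernel (τ = 3 ms), within the 5 % recovery target;
the refill/release correction N₀ − R/p of the deterministic recurrence
accounts for most of the remaining offset.

**Homeostatic-plasticity normalization.** `php_normalize` divides each
genotype's treated and untreated values by that genotype's own untreated
mean; genotypes never share reference values.

## Behavior and statistics

`choice_index` is (flies avoiding CS+ − flies approaching CS+)/total, so 1
is complete learning and 0 a 50:50 split; `performance_index` averages the
two reciprocal runs, which cancels any fixed additive arm bias (the tests
verify the algebraic identity). `dagostino_pearson` implements the omnibus
normality test from the transformed skewness and kurtosis z-scores
(K² ~ χ²₂, n ≥ 8). `choose_and_run_test` encodes the decision tree:
all-groups-normal → unpaired two-tailed t test (two groups, classic
equal-variance form) or one-way ANOVA with Tukey HSD (more); otherwise
Mann–Whitney U (two) or Kruskal–Wallis (more — a fallback route, since the
source procedure never faced that case). "Normal" requires *every* group to
pass at α = 0.05; groups too small for the omnibus test route to the
nonparametric branch. `grubbs_outliers` is the iterated two-sided
single-outlier Grubbs screen at α = 0.05 (at most one removal per pass),
the behavior of the Prism outlier calculator; its empirical type-I rate on
clean normal samples is ≈ 5 %.

## The synthetic-data module

Every generator is a pure function of its parameters including the seed,
and emits integer photon-count-like intensities so that 16-bit TIFF
round-trips (`write_stack_tiff`/`read_stack_tiff`) are bit-exact.

* `make_nmj_stack` draws a bouton chain (default six boutons of 2-µm
  radius along a 20-µm arc — proportions of a type-1b NMJ on muscle 4,
  imaged at 100-nm pitch with five 0.25-µm slices), renders Gaussian
  puncta (PSF sd 0.15 µm) at rejection-sampled positions inside the
  envelope (default minimum separation 6 σ, the well-separated regime,
  kept clear of the envelope boundary), plus distractor puncta outside the
  envelope at 0.05 µm⁻² — the muscle contribution the per-slice cleaning
  is designed to remove. Optional Poisson-then-Gaussian noise. Geometry
  that cannot fit the frame is an error, never a silent crop.
* `make_sted_frame` places annular AZ scaffolds (default ring radius
  120 nm, Gaussian cross-section 40 nm) on non-overlapping 53 × 53-px ROI
  cells at 20-nm pitch, with partner dots at exact stored offsets.
* `make_mini_trace` / `make_train_trace` build sweeps from a
  difference-of-exponentials kernel normalized to unit peak (rise 0.8 ms,
  decay 6 ms for minis; 0.3/3 ms for train responses — the source states
  no waveform, so these are declared defaults, not inferences), Poisson
  event times, a depressing-release recurrence
  (released = p·pool, pool ← pool − released + refill; optional binomial
  sampling), a 2-sample rectangular artifact at each stimulus onset so
  artifact-exclusion logic is genuinely exercised, and Gaussian noise. The
  default protocol is 61 stimuli at 100 Hz.
* `make_tmaze_counts` splits flies binomially between arms for a
  reciprocal run pair.
* `interval_length_aa` is the inclusive residue-interval length used to
  annotate simulated domain-deletion metadata.

What the generators deliberately do **not** model: optics-accurate PSFs,
deconvolution, detector gain structure, pink/line noise, electrode series
resistance, biological variability beyond the stated distributions, or
hardware anti-alias filtering. Passing recovery tests therefore
demonstrates the correctness of the analysis logic under controlled
conditions — not robustness to every artifact of real recordings.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 288-px five-slice stacks
with 50 puncta (10 seeds), 1000 random AZ configurations plus 5 generated
STED frames, 10⁵-pixel correlation images, 90-s 10-kHz mini traces
(10 seeds), 61-stimulation trains (1 deterministic + 50 binomial seeds),
and 2000 Grubbs replicates — sizes chosen so the whole suite completes in
well under a minute per stage on one core while keeping Monte-Carlo
standard errors far below the asserted tolerances. All randomness flows
through explicit seeds; generators restore the caller's RNG state.
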