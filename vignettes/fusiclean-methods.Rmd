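---
title: "Motion-artifact removal for awake fUSI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-artifact removal for awake fUSI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Functional ultrasound imaging (fUSI) estimates cerebral blood volume (CBV)
from the power of blood echoes in beamformed I/Q data. Tissue ("clutter")
echoes are several orders of magnitude stronger than blood echoes; clutter
filtering exploits their higher spatiotemporal correlation to remove them.
In head-fixed but awake animals, residual tissue motion during movement
bouts produces abrupt power Doppler surges across much of the field of
view. These surges inflate or distort voxel-to-voxel correlations and can
dominate seed-based functional connectivity (FC). This package implements
the full chain — velocity estimation, clutter filtering, quality control
(QC), denoising, FC — together with metrics that quantify how well a
denoising strategy suppresses motion artifacts while preserving
connectivity structure.

# Models and procedures

## Axial velocity (Kasai autocorrelation)

Writing the beamformed signal as `IQ = A·exp(iφ)`, the phase advance
between adjacent frames maps to axial scatterer velocity:

    v_z = arg( IQ(t+1) · IQ*(t) ) · c · f_IQ / (4π · f_pulse)

Taking the argument of the complex product, rather than differencing
phases, avoids 2π wrap errors. Defaults: a temporal Butterworth low-pass
(30 Hz, order 6) on the I/Q data before estimation and a 3×3(×3) median
filter on each velocity volume, both reducing estimator noise. Per-block
averages of `|v_z|` over all adjacent frame pairs give one absolute
velocity volume per power Doppler frame. The estimate saturates at the
Nyquist velocity `c·f_IQ/(4·f_pulse)` (12.3 mm/s at 15.625 MHz / 500 Hz).
The low-pass is applied per block: the block is the processing unit
throughout, and filtering across block boundaries would couple otherwise
independent units.

## Clutter filtering

For each block, let `X` be the (time × voxels) matrix and `M` its
restriction to a voxel mask (the whole field of view, or a brain mask to
avoid biasing the basis with extra-cerebral outliers). The eigenvectors of
the Gram matrix `M·Mᴴ` are the temporal singular vectors of `M`, and the
eigenvalues are component energies. Clutter components are removed by
subspace regression applied to the full block:

    X_filtered = X − U_c · U_cᴴ · X

Selection variants:

* **static SVD_T** — remove the `T` most energetic components in every
  block (`T ∈ {20, 40, 60}` in the benchmark grid);
* **static SVD_T + high-pass** — additionally apply a zero-phase 20 Hz
  order-8 temporal high-pass after the regression (at 15.625 MHz and
  1540 m/s, 20 Hz corresponds to ≈ 1 mm/s axial blood velocity, just above
  capillary speeds);
* **constant-energy SVD_T** — remove, per block, the smallest number of
  top components such that the residual energy does not exceed a threshold
  `C`, computed per acquisition as the minimum static-`T` residual across
  its blocks.

The constant-energy filter adapts to motion (blocks with energetic
artifacts lose more components), but by construction it also clamps the
block-to-block energy profile: slow CBV fluctuations that express as
global energy changes are partially clipped. This is why combining it with
scrubbing based on the relative global signal is forbidden in the strategy
grid — the global signal becomes uninformative — and why recovery of slow
CBV time courses is only guaranteed for the static filter in our tests.

Power Doppler is then the time-average of `|X_filtered|²` per voxel.
Numerical choices: eigenvalues are clamped at zero (Gram matrices are
positive semidefinite; tiny negative values are floating-point noise),
ties keep the decomposition order, and eigenvector phase is irrelevant
because the projector depends only on the span. A trailing partial block
is dropped. For `static_highpass` the regression runs first and the
high-pass second.

## Quality control

Spatial: temporal mean power Doppler (also rendered in dB for display),
temporal coefficient of variation, temporal mean velocity. Temporal, per
frame:

* **rGS** `= 100·(GS − D1)/D1`, the global (brain-mean) power Doppler
  signal as percent excursion over its first decile — a robust baseline;
* **GV**, the brain-mean absolute axial velocity (mm/s) — a direct motion
  measure independent of intensity;
* **rDVARS**: DVARS is the RMS backward frame difference over brain
  voxels; it is standardized by the null level expected from temporal
  noise alone, `μ₀ = mean_v 2(1−ρ_v)σ_v²`, with `σ_v = IQR/1.349` and
  `ρ_v` the per-voxel lag-1 autocorrelation. The identity
  `Var(x_t − x_{t−1}) = 2(1−ρ₁)σ²` holds for any stationary series, so the
  baseline is near 1 well beyond strict AR(1) noise.

Two deliberate choices here. First, we report `DVARS/√μ₀` (not
`DVARS/μ₀`): `μ₀` carries squared signal units, so only the square-root
form is dimensionless, sits at a stable baseline of 1 on quiet data and
matches a scrubbing threshold of 2. Second, `ρ_v` is the sample lag-1
Pearson autocorrelation clipped to `[0, 0.99]`; the estimator is not
prescribed by the QC literature we follow, so it is configurable in
spirit: the clipping only guards degenerate series. All quantiles
(deciles, IQR) use linear interpolation between order statistics
(type 7), uniformly across the package. The first rDVARS sample has no
backward difference and is emitted as missing (`n/a` in TSV output).

Because rDVARS reacts to *transitions*, an isolated one-frame surge is
flagged at the surge and at the recovery frame after it, and a run of
consecutive surge frames is flagged at its entry and exit. GV, which
tracks the motion itself, flags exactly the event frames. Tests and the
synthetic benchmark assert exactly these semantics.

## Denoising pipeline

Stages run in a fixed order; each matters to the next:

1. **Spatial smoothing**, Gaussian, 0.3 mm full width at half maximum
   (σ = FWHM/2.355 converted to voxels; edges replicated).
2. **Scrubbing by replacement**: frames exceeding the chosen metric's
   threshold (rGS 10 %, rDVARS 2.0, or GV above its first decile +
   0.01 mm/s) are replaced per voxel by the mean of quiet frames, so the
   subsequent filter sees regular sampling and surges cannot ring through
   it.
3. **Frequency filtering**: zero-phase (forward–backward) Butterworth,
   order 6; 0.01 Hz high-pass or 0.01–0.1 Hz band-pass.
4. **Deletion** of the replaced frames. Acquisitions retaining less than
   5 minutes are rejected (a typed condition carrying the retained
   duration).
5. **Confound regression**: ordinary least squares per voxel,
   `X − C·β`, with an intercept always included (the data are censored
   after filtering, so they are not exactly zero-mean; the intercept
   stabilizes β at no cost). Confound sets: the global brain signal, or
   five principal components of voxel series from a source mask — top-5 %
   temporal-variance voxels (tCompCor), white matter + CSF (aCompCor), a
   random brain mask of the same cardinality as WM+CSF (drawn once per
   dataset from the seed), or the lowest-variance voxels of that
   cardinality. Confounds are estimated from the raw series before any
   denoising (smoothing would leak gray-matter signal into thin anatomical
   masks) and then pass through the same replace–filter–delete sequence as
   the data. PCA uses mean-centering only (no variance normalization);
   component signs follow a deterministic largest-|loading|-positive
   convention. Voxel-selection ties break by linear index; mask
   cardinalities use `floor(fraction·N)`.

## Seed-based FC and benchmark metrics

Seed signals average the denoised series over spheres of radius 0.3 mm
(voxel-center inclusion); seed maps are Pearson correlations with every
brain voxel, with zero-variance voxels assigned r = 0 (flagged) so that
thresholding and overlap metrics stay defined. Group maps average in
Fisher-z space. Two metrics score a strategy:

* **Motion robustness**: mean squared difference, over brain voxels and
  the six seeds, between maps computed without scrubbing and with
  GV-based scrubbing; small values mean motion frames barely influence
  the maps. Computed on raw correlations (not Fisher z), since the maps
  themselves hold correlations.
* **FC similarity**: Dice overlap of top-10 % (by absolute correlation,
  ties by voxel index) masks between each acquisition's maps and
  ground-truth group maps computed with the standard strategy
  (static SVD_60, rGS scrubbing, 0.01–0.1 Hz band-pass, global-signal
  regression). Both modes of thresholding (absolute and signed) are
  available; the benchmark uses absolute.

Both metrics average within subject before averaging across subjects, so
subjects with more acquisitions are not over-weighted; strategies
retaining fewer than two thirds of subjects after the 5-minute rule are
flagged invalid rather than silently dropped. `tDOF` reports the percent
of frames surviving censoring. The per-acquisition MSE averages over all
(voxel, seed) pairs jointly; averaging per seed first would weight seeds
by brain coverage, which the joint average avoids.

## FIR motion-response model

The power Doppler signal at each voxel is regressed on all delayed copies
of GV between −12 and +12 s on the acquisition's lag grid
(61 columns at 2.5 Hz), plus an intercept and a linear drift. Shifted
samples beyond the record are zero-padded and the affected rows flagged;
zero-padding keeps the designs aligned across lags, which trimming would
not. Plain OLS is used — no prewhitening; the estimates stay unbiased
under stationary noise and the second level absorbs subject variance.
Group maps are one-sample t statistics over subject betas converted to
z-scores through the normal quantile of the t distribution function
(computed on the log scale for tail accuracy).

# The synthetic-data generator

`simulate_iq()` emulates, at the I/Q level: (a) clutter as a rank-4 sum of
smooth complex spatial patterns times slowly varying temporal envelopes,
scaled to a clutter-to-blood energy ratio of 100 (the ratio is not
quantified in vivo; 100 keeps the subspaces separable and is a modeling
choice, not a measured value); (b) blood as per-voxel random-phase
scatterers with Doppler shifts drawn uniformly in ±[2, 10] mm/s — above
the ≈ 1 mm/s clutter cutoff so high-pass variants retain them — amplitude
modulated by slow network CBV signals; (c) motion events that multiply
clutter energy by a surge factor and impose the axial phase ramp
`exp(i·4π·f_pulse·v·t/(c·f_IQ))` corresponding to a uniform tissue
velocity (one scalar per event; a spatial velocity gradient would be a
straightforward extension but is not needed by any test); (d) complex
white noise at 1 % of blood energy. One root seed feeds independent
substreams per component, so adding a component never perturbs the
others.

`simulate_power_doppler()` works directly at the Doppler frame rate:
a smooth positive baseline map times
`1 + networks + global + AR(1) noise`, with multiplicative surges at
events and a matching velocity series (0.02 mm/s quiet baseline, the
event velocity during events). Defaults, chosen once as plausible
awake-mouse values and then frozen: network amplitude 5 % (slow
hemodynamic fluctuations are a few percent of CBV), a brain-wide
physiological fluctuation of 2 % with smooth spatial loading (this is the
component global-signal regression chiefly removes in vivo), AR(1) noise
of 2 % with ρ = 0.3, surges of +100–400 % at events. The benchmark cohort
(`synthetic_benchmark_dataset`) uses 8 subjects × 1000 frames with 12
events each and surge factors log-uniform in [1.05, 5]: real artifact
amplitudes span a wide range, and the smaller ones sit below the 10 % rGS
scrubbing threshold while velocity- and rDVARS-based detection still
resolves them — the regime in which scrubbing metrics genuinely differ.

What the generator does *not* emulate: speckle statistics, acoustic
propagation and skull effects, spatially structured artifact topographies
(inferior veins, muscle proximity), slow drifts, breathing and heart-rate
bands, and between-session registration error. Passing tests therefore
show correctness of the algorithms and the direction of the benchmark
orderings under a controlled signal model — not in-vivo effect sizes. In
particular the FC-similarity margin between the optimized and standard
strategies is small on synthetic data (the standard strategy's maps are
compared against ground truth derived from itself, which favors it),
while the motion-robustness margin is large and stable; on real data both
margins are driven by artifact heterogeneity that the generator only
partially reproduces.

# Numerical choices

* **Zero-phase Butterworth filtering** is implemented as cascaded
  second-order sections obtained by bilinear transform of the analytic
  Butterworth prototype. At 0.01 Hz cutoff and 2.5 Hz sampling the
  expanded polynomial form is numerically unstable; the cascade is the
  standard remedy. Forward–backward application uses odd-reflection
  padding of three times the filter's impulse-response scale
  (`3·fs/f_c` samples, capped at the record length) and steady-state
  initial conditions per section, so a constant input maps to a constant
  (then removed) output and edge transients stay out of the record.
  Series too short for meaningful padding raise an input error.
* **Quantiles** are type 7 everywhere (D1 baselines, IQR, GV scrub
  baseline).
* **Degenerate inputs**: all-flagged acquisitions, empty masks, constant
  seed signals and non-finite samples raise typed errors naming the
  problem; constant series yield rDVARS 0 with a guarded null level.
* **Rank deficiency** in confound or FIR designs drops dependent columns
  with a warning rather than failing.
* **Determinism**: simulations are bit-reproducible from their seed; the
  random CompCor mask is drawn once per dataset from an explicit seed;
  the end-to-end pipeline writes identical checksums on reruns.

# Problem sizes

The test suite runs the full property checks at desk scale: random
200×500 blocks for the eigen/SVD oracles, 2000×500 Monte-Carlo nulls for
rDVARS (ρ ∈ {0, 0.5}), n = 3000 for FIR gain recovery, and the benchmark
cohort of 8 subjects × 1000 frames × 16×16 voxels for the end-to-end
orderings. These sizes were chosen so the whole suite completes in about
a minute while keeping every statistical check comfortably powered.

# Known limitations

Atlas registration, slice-timing correction and template construction are
out of scope (synthetic fixtures carry their own coordinates). The
benchmark operates on power-Doppler-level simulations, so clutter-filter
variants enter the strategy labels but differentiate only on I/Q-level
data. Group-level inference beyond one-sample z-maps (FWER-controlled
displays) is not provided. ICA-family confound methods and spline
interpolation of censored frames are deliberately excluded; the latter is
known to bias long censored stretches.
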