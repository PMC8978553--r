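# msdrift

Mean-shift drift correction for single-molecule localization microscopy
(SMLM) in 2D and 3D.

## The problem

SMLM techniques (STORM, PALM, PAINT) build super-resolved images by
localizing sparse, stochastically activated emitters over many thousands
of camera frames. Acquisitions run for minutes, over which thermal and
mechanical stage drift typically exceeds the localization precision
(σ ≈ 5–30 nm), smearing the pooled localization map. `msdrift` estimates
the drift trajectory directly from the localizations — no fiducial
markers, no image reconstruction, no Fourier transforms — and subtracts
it.

## The method

**Pairwise-displacement mean shift.** For two sets of localizations *A*
and *B* sampling the same structure with a relative shift
**r**<sub>shift</sub>, the displacements *b − a* between localizations of
the *same* emitter cluster tightly around **r**<sub>shift</sub>, while
displacements between *different* emitters form a diffuse background.
The estimator iterates a flat observation window (radius 100 nm for
experimental data, 150 nm for the simulated benchmarks): extract all
displacements inside the window centered on the current guess μ, move μ
to their centroid, redraw the window, and repeat until the mean moves by
less than a tolerance — i.e. until the peak is centered in the window.
The per-axis standard error of that centroid, SD/√n over the in-window
displacements, serves both as the least-squares weight and as a
data-driven reliability proxy: estimates are trustworthy while the error
stays below about σ/4.

**Redundant weighted trajectory fit.** Frames are partitioned into *K*
non-overlapping temporal bins of equal frame count. Mean shift is run
between *every* pair of bins (*i* < *j*), giving shifts Δ<sub>ij</sub>
with errors ε<sub>ij</sub>. Per axis, the control-point drifts
*d*<sub>1..K</sub> (with *d*<sub>1</sub> = 0) minimize

    Σ_{i<j}  (Δ_ij − (d_j − d_i))² / ε_ij²

an overdetermined system — K(K−1)/2 measurements for K−1 unknowns — whose
redundancy sharpens every control point; 68% confidence half-widths come
from the inverse weighted normal matrix. The trajectory is linearly
interpolated to every frame and subtracted.

Close-pair extraction uses a C++ cell-list (grid hash) query, so the
cost is near-linear in the number of localizations, and the whole method
is dimension-generic: in 3D the window is a sphere (optionally an
axis-scaled ellipsoid for anisotropic axial precision) and everything
else is unchanged.

## Worked example

```r
library(msdrift)

# simulate a 15,000-frame acquisition of a 5 um test cell drifting at
# 5 pm/frame in x and y (75 nm accrued), with blinking emitters
cfg <- sim_config(mean_locs = 30, n_frames = 15000, blink_corr = 3,
                  seed = 11)
sim <- simulate_drift_series(cfg, function(f) cbind(0.005 * f, 0.005 * f))

# estimate the drift from 1,500-frame bins and correct
traj <- estimate_drift(sim$table, bin_width = 1500,
                       params = ms_params(min_pairs = 5))
traj
#> <drift_trajectory> 10 control points, 2D, net drift 93.19 nm

corrected <- apply_drift_correction(sim$table, traj)

# score the correction by Fourier ring correlation (1/7 threshold)
frc_resolution(sim$table, pixel_nm = 10, n_replicates = 20, seed = 9)
#> <frc_result> resolution = 62.5 +/- 1.6 nm (threshold 0.143, 20 replicates)
frc_resolution(corrected, pixel_nm = 10, n_replicates = 20, seed = 9)
#> <frc_result> resolution = 45.7 +/- 0.9 nm (threshold 0.143, 20 replicates)
```

The trajectory spans the first to last bin centers (frames 750–14,250),
over which the simulated drift accrues 0.005 × 13,500 × √2 ≈ 95 nm; the
reported 93.2 nm net drift matches to a few nm, and removing it recovers
most of the resolution lost to drift.

A shell front end wraps the same functions
(`inst/cli/msdrift <simulate|drift|frc> [options]`), reading an optional
YAML config and writing a JSON run manifest next to its outputs.

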