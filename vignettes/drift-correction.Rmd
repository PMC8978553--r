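---
title: "Mean-shift drift correction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-shift drift correction: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdrift)
```

## The model

An SMLM acquisition yields localizations $(t_i, \mathbf{x}_i)$: a frame
index and a fitted emitter position with precision $\sigma$. Stage drift
adds a slowly varying translation $\mathbf{d}(t)$ to every position.
`msdrift` models drift as piecewise linear between control points, one
per temporal bin, and estimates the control points from the data alone.

**Shift between two point sets.** Consider localization sets $A$ and $B$
of the same structure separated by a shift $\mathbf{r}$. Among all
pairwise displacements $\mathbf{b}-\mathbf{a}$, same-emitter pairs are
distributed as $\mathcal{N}(\mathbf{r}, 2\sigma^2 I)$ while
different-emitter pairs follow the (broad) autocorrelation of the emitter
pattern. The mean-shift iteration

$$\mu \leftarrow \mathrm{mean}\{\,\mathbf{b}-\mathbf{a} :
   \|\mathbf{b}-\mathbf{a}-\mu\| \le r_w \,\}$$

converges to a point where the in-window displacement distribution is
balanced around $\mu$; with a distinct same-emitter peak this is, to
excellent approximation, $\mathbf{r}$. No assumption of spatially uniform
emitters is required: clustered structures concentrate the background at
short displacements but leave the same-emitter peak dominant.

**Trajectory fit.** With bins $1..K$ and pairwise estimates
$\Delta_{ij}$ weighted by $1/\varepsilon_{ij}^2$, each axis solves an
overdetermined linear system $\Delta_{ij} = d_j - d_i$ anchored at
$d_1 = 0$ (the model is invariant under a common translation of all
$d_k$, so the gauge must be fixed; the data constrain only differences).
The axes decouple because the model is separable. 68% confidence
half-widths are $\sqrt{\mathrm{diag}[(X^\top W X)^{-1}]}$, treating the
$\varepsilon_{ij}$ as absolute standard deviations.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r_initial` | 150 nm | first-iteration window radius; shifts up to roughly this magnitude are captured from a cold start at zero. 100 nm suits typical experimental data, 150 nm the simulated benchmarks |
| `r_window` | = `r_initial` | radius after the first iteration; the window is redrawn at each step, not shrunk |
| `tol` | 0.1 nm | convergence tolerance on the movement of the mean; well below any relevant precision |
| `max_iter` | 50 | iteration cap; typical convergence takes 2–6 iterations |
| `min_pairs` | 10 | windows with fewer displacements yield estimates flagged invalid rather than errors, so the trajectory fit can drop them |
| `bin_width` | (per run) | frames per temporal bin. Short bins resolve fast drift but starve the estimator (few localizations per emitter per bin); long bins average the drift away. The estimated error offers a data-driven guide: keep it below about $\sigma/4$ |
| FRC `pixel_nm` | 5 nm | reconstruction pixel; choose below the localization precision (10 nm is used for the σ = 15 nm simulations) |
| FRC `threshold` | 1/7 | standard fixed-threshold resolution criterion |
| FRC `block_frames` | 50 | frames per split block; splitting whole blocks keeps a fluorophore's blinking run on one side of the split |

The error estimator attached to each shift is the per-axis standard
error of the in-window centroid, $\mathrm{SD}/\sqrt{n}$. It captures the
two qualitative drivers — more same-emitter pairs shrink it, more
background pairs inflate it — and it is the least-squares weight. It is
deliberately simple and is exposed as a swappable strategy: it treats
in-window displacements as independent, while in reality pairs sharing a
localization are correlated and the background arrives in per-emitter
lumps, so it understates the true spread by a factor of roughly 2–3 in
dense conditions. Consequently the default (absolute-weight) confidence
intervals are optimistic on real pipelines; `chisq_rescale = TRUE`
rescales them by the reduced chi-square of the fit when calibrated
intervals matter more than propagating the physical error model.

## The synthetic benchmark

The generator emulates the standard simulation benchmark for shift
estimators: a circular test cell of radius 5 µm (2D) or a cylinder of
radius 5 µm and height 1 µm (3D) with emitters placed uniformly at a
chosen density; each data set samples every emitter
$\mathrm{Poisson}(\bar\ell)$ times with isotropic-per-axis Gaussian
noise ($\sigma_{xy}$ = 15 nm; $\sigma_z = 2\sigma_{xy}$ in 3D); the
second set is translated by a shift of magnitude
$\mathrm{Uniform}(0, 150\,\mathrm{nm})$ — ten times the precision — in a
uniformly random direction. The easy condition is 5 molecules/µm² with
$\bar\ell = 2$; the hard condition 20/µm² with $\bar\ell = 0.05$.
Scoring follows the benchmark conventions: *precision* is the SD of a
Gaussian fitted to the central peak of the signed per-axis error
histogram (robust to the heavy tails of failed runs), and the *failure
rate* is the fraction of replicates with any-axis error above $2\sigma$.

For drifting series, emitters blink in runs of consecutive frames with
geometric run lengths (mean `blink_corr` frames), emitting one
localization per active frame at the emitter position plus the drift at
that frame plus noise; `mean_locs` is the expectation over the whole
series. This reproduces the time-correlated localizations that real
fluorophore off-rates produce, which is what makes naive temporal
schemes biased.

What the generator does *not* model: camera image formation and PSF
fitting, spatially structured or clustered emitter layouts (generally
*favorable* cases for these estimators), emitters entering or leaving
the field of view, and localization-precision heterogeneity. Passing
benchmarks here therefore demonstrates the estimator's statistical
behavior under controlled conditions, not end-to-end performance on any
particular instrument.

## Numerical and design choices

- **Window boundary** is a closed ball ($\le r$); a measure-zero choice
  fixed so the grid query and the brute-force oracle agree exactly.
- **Cell-list close pairs**: the C++ kernel hashes points into cells of
  side $r$ and inspects $3^d$ neighbor cells per query point. A
  pathological extent-to-radius ratio (where grid keys could overflow)
  falls back to the quadratic scan.
- **Centroid, not kernel**: the window is flat; no Gaussian/Epanechnikov
  weighting, no multi-start mode enumeration.
- **Iteration radius** stays at `r_window` after the first iteration
  (`r_initial` may be larger to capture big shifts); both radii are
  exposed because shrinking is a legitimate variant.
- **Non-convergence policy**: an underpopulated window returns an
  estimate flagged invalid instead of throwing, so one starved bin pair
  cannot abort a whole trajectory; the fit drops invalid entries and
  verifies that the remaining pair graph is connected before solving.
- **Remainder frames** fold into the last bin rather than being
  discarded (at most one bin deviates from equal frame counts).
- **Error floor**: per-axis $\varepsilon$ is floored at $10^{-6}$ nm so
  noiseless (exact) estimates keep finite weight.
- **Interpolation** between control points is linear with clamped
  (constant) extrapolation beyond the first and last bin centers; the
  drift model has no information outside that range.
- **Overlapping bins** are implemented only as a diagnostic
  (`bin_frames(..., overlap = 0.5)`). Shared localizations between
  overlapping bins contribute exact-zero self-displacements that drag
  shift estimates toward zero; the resulting trajectories
  systematically underestimate accrued drift. Redundancy partially
  repairs the total when many disjoint long-lag pairs are available, so
  the diagnostic is sharpest at small $K$ and sparse per-bin sampling —
  the regression test uses $K=3$ half-overlapping bins against $K=3$
  disjoint bins on blinking data.
- **Adjacent-bin exclusion** (`exclude_adjacent`) exists to probe
  blinking-induced bias in non-overlapping binning; on simulated data
  without long blink correlations it changes fits by less than the
  confidence intervals.
- **FRC details**: reconstructions are 2D count histograms zero-padded
  to a power-of-two square; ring width is one frequency sample with a
  3-ring moving average; the 1/7 crossing is linearly interpolated
  between rings; 3D tables are evaluated in-plane. The half-split
  assigns whole 50-frame blocks rather than individual localizations,
  which blunts (but cannot fully remove) blinking-induced spurious
  correlation between halves.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use: 250–500 replicates per
benchmark cell (2D and 3D), a 3×3 condition grid at 100 replicates per
cell for the σ/4 robustness relation, 15,000-frame drifting series
(~10⁴ localizations) for the trajectory and FRC checks with 20 FRC
replicates at 10 nm pixels, and six replicate simulations for the
overlapping-bin diagnostic. These sizes give stable statistics (binomial
error on a 500-replicate failure rate is about 2 percentage points at
worst) while keeping a full run in the minutes range on one CPU.

## Known limitations

- The SEM-based error underestimates true scatter in dense or heavily
  blinking data (see above); treat default CIs as lower bounds there.
- Drift between bin centers is assumed linear; fast oscillatory drift
  within a bin is averaged, not corrected. No spline or Gaussian-process
  smoothing is offered.
- Estimates degrade when the expected same-emitter pair count per bin
  pair falls toward `min_pairs`, and fail (flagged) below it; the σ/4
  guide is the practical defense.
- Emitters drifting out of the field of view bias shifts by at most
  ~σ × (σ / field size) — negligible for typical fields — and are not
  modeled.
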