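---
title: "Methods: simulating and measuring motor-protein traffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring motor-protein traffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(motortraffic)
```

This vignette documents the modelling and estimator choices behind
`motortraffic`: the lattice-gas traffic model and its numerical
realisation, what the synthetic imaging emulates (and does not), how the
correlation-imaging and single-particle estimators are constructed and
validated, and the staged fitting procedure. Empirical statements below
are the ones computed by the package's test suite and acceptance script;
nothing else is claimed.

## The traffic model

Motors on a microtubule are modelled as a multi-lane exclusion process
with Langmuir kinetics. Each of `n_lanes` protofilaments (1–13; lanes are
independent, no side-stepping) is a 1-D lattice whose site length is one
motor step (`motor_step_nm`, default 8 nm). A motor occupies
`motor_size_nm / motor_step_nm` consecutive sites (16/8 = 2 by default)
and carries three elementary rates, all first-order:

* **attachment** at `omega_A0 * c` per site per lane (`omega_A0` in
  um^3/s, `c` the bulk concentration in motors/um^3), succeeding only if
  the whole footprint is empty;
* **stepping** by one site towards the plus end at `step_rate`, allowed
  when the target site is empty and the gap to the motor ahead after the
  step is at least `interaction_range` motor sizes (`interaction_range =
  0` is plain hard-core exclusion);
* **detachment** at `omega_D` while free to step, and at `omega_DC`
  *instead* (the rates are not additive) while the step is blocked — the
  "constrained" state. A motor whose front sits on the last site of an
  open lattice can always step (off the lattice), so it is never
  constrained by the boundary; its run is recorded as censored.

Two calibration conventions had to be fixed because they are not implied
by the rates alone. First, candidate binding positions are counted per
8-nm *site*, not per 16-nm footprint position; with this convention the
dilute-limit density per um is `omega_A0 * c / omega_D * n_lanes *
(1000/motor_step_nm)`, which is the identity the stage-1 fit inverts.
Second, the interaction range is measured *after* the step, so range 0
reduces exactly to hard-core exclusion. Both conventions are echoed in
all outputs.

Useful closed forms (`analytic_low_density()`): dilute velocity
`v0 = motor_step x step_rate` (0.3 um/s at defaults, the quantity the
zero-density run length `v0/omega_D = 1.2 um` follows from), and a
packing capacity of `floor(1000/motor_size_nm)` = 62 motors/um per
protofilament. `mean_field_velocity()` gives the uncorrelated-occupancy
reference `v0 (1 - rho_site)` — a 50% drop at half occupancy — against
which the simulated decorrelation is judged.

## Numerical realisation

Time evolution is an exact continuous-time (Gillespie) chain, implemented
with *thinning*: every bound motor carries the rate bound
`step_rate + max(omega_D, omega_DC)` and every binding position the bound
`omega_A0 * c`; a candidate event is drawn from the bound process and
accepted with the ratio of true to bound rate. Rejected candidates only
advance time, so the law of the process is unchanged while each attempt
costs O(1) — this is what makes the high-density concentration sweeps
affordable on a single core. The RNG is R's own stream, seeded once per
simulation (`seed` in `lattice_config()`), so identical seeds give
bit-identical event sequences; derived per-stage seeds
(`derive_seed()`) keep pipeline stages independently reproducible.

The default burn-in is `max(5/omega_D, lattice_length/v0)` (capped at
half the duration): five unbinding times to equilibrate occupancy, or one
full transit so the lattice fills from an empty start. Density is the
time-average of the bound count after burn-in (batch-means SE over 10
batches); velocity is the displacement-weighted ensemble mean (total
displacement over total attached time — the quantity image correlation
measures); the run length is the censored-exponential MLE, `sum(lengths)
/ n_uncensored`, in which runs ended by the lattice end or the end of the
simulation enter as survival terms only. Ring boundaries (used by the
stationary-state oracles) support a fixed motor number without Langmuir
exchange; their velocity comes from exact step counters
(`ensemble_velocity()`), since every run on a ring is censored.

The simulator is tested against independent stationary oracles rather
than against itself: the ring exclusion process with single-site motors,
whose stationary measure is uniform over configurations (mean stepping
rate `p (L-N)/(L-1)`, confirmed by brute-force enumeration of all
configurations for L ≤ 8), and the Langmuir isotherm `k/(k + omega_D)` in
the no-stepping limit.

## Synthetic imaging

`parametric_trajectories()` generates exclusion-free ground truth: a
Poisson process of binding events in space-time, exponential lifetimes,
exactly constant velocity. It exists so the analysis estimators can be
validated independently of the traffic simulator. `render_stack()` turns
either trajectory source into a TIRF-like movie: each labeled, unbleached
motor contributes an isotropic 2-D Gaussian (sigma 130 nm, about the
diffraction limit for GFP emission at high NA) integrated over 80-nm
pixels, with motion blur as the average of 10 sub-exposure positions,
Poisson shot noise per pixel on top of a uniform background, and linear
camera digitization clipped to 16 bits. Defaults (1000 frames, 200 ms
exposure, 80-nm pixels, peak-pixel SNR ~10) emulate the motility-assay
movies this pipeline is meant for.

Deliberately not modelled: EMCCD excess noise (a multiplicative variance
factor would scale the shot-noise spike that the FCS estimator already
discards), microtubule curvature, stage drift, and depth-dependent
excitation. Lattice trajectories are rendered as one straight space-time
segment per run; at the dilute densities where stacks are analysed this
differs from the stepwise path by less than a pixel. Tests passing on
these movies therefore validate the estimators under idealised optics;
they do not certify robustness to curvature, drift or non-Poisson camera
noise.

`make_kymograph()` samples the intensity along the annotated microtubule
axis at pixel spacing (bilinear interpolation, averaged over
`width_pixels` perpendicular offsets) and records per-frame background
statistics from two parallel off-axis bands (default offset 5 px, where
the PSF leak is < 1%); `background_subtract()` removes the per-frame
band mean without clipping negatives.

## Correlation imaging

**Density (FCS).** The spatially summed intensity `F(t)` of a segment
fluctuates with the labeled-motor number `N(t)`, so `G(tau) =
<dF dF>/<F>^2` has amplitude `1/<N>`. The amplitude is the linear
extrapolation of G at lags 1–3 frames to lag zero, which excludes the
shot-noise variance confined to lag 0; the decay of G over those lags
(`~(omega_D + v/L) * dt` per frame, about 1% here) makes the linear
extrapolation accurate to well under a percent. Labeled density scales to
total density by the total:labeled concentration ratio of the spiking
scheme. Because `N(t)` decorrelates in `1/omega_D` (~4 s), a 200-s record
holds only ~50 independent samples and a single-stack estimate scatters
by ~20%; the estimator is unbiased, so replicate averaging converges
(the linearity test holds R^2 ≥ 0.98 over a decade of N).

**Velocity and run length.** The spatiotemporal correlation
`C(xi, tau)` is computed by zero-padded FFT with per-position temporal
means removed, no wraparound, every lag pair normalized by its overlap
count. Per time lag, a Gaussian plus constant offset is fitted in a
±10-pixel window around the maximum (refit once re-centered; lags with
R^2 < 0.8 are flagged and excluded). The peak position `x_p(tau)` drifts
at the ensemble velocity — recovered by an SE-weighted line — and the
Gaussian area `A(tau) = amplitude x sigma x sqrt(2 pi)` decays with the
effective unbinding rate, recovered by weighted nonlinear least squares
(a semi-log linear fit is reported alongside). Run length =
velocity/decay rate. Non-decaying areas flag the run length as
undetermined rather than returning a negative rate.

Two properties of this estimator were established on synthetic ground
truth and shaped defaults. First, the overlap-count normalization exactly
compensates motors drifting out of a finite segment (the surviving-pair
count and the normalization share the factor `L - v tau`), so segment
ends do not bias the decay. Second, at late lags the peak sinks into the
correlated noise floor of a finite record and the fitted areas flatten
(the positivity-constrained amplitude cannot average to zero), which
biases the decay rate low; the exponential fit is therefore restricted,
self-consistently, to lags within 1.5 fitted decay times (iterated,
`decay_window` argument). With this window the 1000-frame fixture
recovers the generating run length with ~+5% residual bias and ~3%
scatter across seeds, and velocity within ~1%.

Photobleaching adds to the fitted decay (`~omega_D + bleach_rate`), as
the bleaching test verifies; no bleaching correction is estimated from
the data — a known rate must be supplied by the user.

## Single-particle tracking

Detection: per frame, candidate pixels above the robust background
(median + 5 MAD by default) that are 3x3 local maxima (ties allowed —
integer counts tie frequently, and rejecting ties silently drops real
spots) are refined by a 2-D Gaussian fit on a 7x7 patch, falling back to
a centroid when the fit fails. Detections closer than 2 pixels after
refinement are deduplicated (brightest wins): flank pixels of a bright
spot can pass the local-max test and their fits migrate onto the same
molecule, and such duplicates were the dominant cause of broken tracks.
Linking is greedy mutual-nearest-neighbour with a displacement gate
(default 0.25 um/frame) and no gap closing or merge/split handling — a
declared simplification adequate below ~0.5 motors/um, which is why the
single-molecule fixtures sit at the ~0.1 motors/um of a 200 pM assay.
Tracks shorter than 5 frames are discarded to keep noise detections out
of the statistics.

Velocity is the SE-weighted through-origin fit of mean along-axis
displacement versus time lag; localization noise is zero-mean and cancels
there. Run lengths are net along-axis displacements fitted via the
empirical CDF with a shifted exponential `1 - exp(-(x - x0)/lambda)`,
`x0` the shortest observable run (set by the 5-frame minimum); by
memorylessness the fitted `lambda` is the mean run length, and the SE
comes from 200 bootstrap refits. Because censored tracks cannot enter a
CDF as survival terms, unbiasedness requires excluding censored runs in a
way independent of their length: the fixtures restrict the sample to
tracks born at least five mean run lengths before the track's plus end
and finished before the last frame. (Simply dropping censored tracks
selects against long runs and biases `lambda` low by ~6% on a 20-um
track — measured on ground truth.)

## Staged fitting

Stage 1 (`fit_low_density()`): in the linear regime, the velocity and
run-length plateaus give `step_rate = v0/motor_step` and `omega_D =
v0/RL0`, and the through-origin slope of density versus concentration
gives `omega_A0` through the per-site attachment convention. A curvature
check (quadratic term vs linear prediction at the largest concentration,
10% threshold) refuses series that leave the linear regime and reports
the admissible concentration range.

Stage 2 (`grid_search_fit()`): with stage-1 rates fixed, every integer
triple (lanes 1–13, interaction range 0–20 motor sizes,
`omega_DC/omega_D` 0–10) is simulated at the observed concentrations
(default 3 replicates per point, derived seeds) and scored by the sum
over density, velocity and run length of SE-weighted squared
log-residuals; log scale puts the three observables on comparable
footing, and zeros are offset by the smallest positive SE of each
observable. Ties break towards smaller lanes, then range, then ratio.
The self-consistency test generates a series at (13, 0, 3) with 5%
noise and recovers the triple exactly on a 3x3x4 sub-grid, with the
true triple's loss well separated from its neighbours.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations to single-
core runs: zero-density checks use a 20-um lattice for ~1600 s (~2000
completed runs); correlation fixtures render 500–1000 frames on 12–40 um
segments at ~3 motors/um; the single-molecule fixture renders 6000 frames
at ~0.1 motors/um (~500 tracks); the grid-search check uses a 5-um
lattice, 80-s runs, 2 replicates over 36 triples. These sizes give the
standard errors quoted in the tests; all scale linearly if more precision
is wanted.

## Known limitations

* With an elevated constrained-motor detachment ratio `r =
  omega_DC/omega_D`, crowding hits the run length much earlier than the
  velocity: at blocked fraction `f` the velocity falls by the factor
  `1 - f` while the effective unbinding rate rises by `(r - 1) f`, so the
  run length falls roughly `r` times faster; at `r = 3` it leaves any
  tolerance band about three times earlier (in density) than the
  velocity does. The
  kinesin-II parameter set therefore shows run length ~20% below its
  dilute value already near 130 motors/um while velocity is still within
  10%; a requirement that *both* observables hold a 10% band up to ~200
  motors/um is not satisfiable with these rates, and the corresponding
  acceptance check documents this by failing.
* The tracker is not a full multi-hypothesis tracker: above ~0.5
  motors/um merged spots split tracks, and run-length estimates degrade
  before velocity estimates do.
* FCS density assumes Poisson number statistics of *labeled* motors;
  strong exclusion at high total density narrows the number distribution
  of labeled motors only mildly at the 1:10–1:250 spiking ratios the
  design targets, but the estimator has no correction for it.
* The correlation run-length estimator carries a small (+~5%) residual
  bias from the finite-record noise floor even with the truncated fit
  window; records longer than ~10 decay times would remove it.
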