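---
title: "Coverage of intraprostatic lesion boosts under intrafraction motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage of intraprostatic lesion boosts under intrafraction motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplmotion)
```

## The problem

A simultaneous integrated boost (SIB) escalates dose to a macroscopic
intraprostatic lesion (IPL) inside the prostate's main treatment volume.
Because the boost volume is small — lesion radii of 3–7 mm are typical —
intrafraction motion of the prostate after image-guided setup can move the
lesion partly or wholly out of the boosted region, and the central clinical
question is how much safety margin `m` around the lesion is needed so that
the lesion still receives an acceptable dose.

`iplmotion` answers this with a deliberately simple, fully analysable
idealization: the IPL is a sphere of radius `r`, the boost dose is constant
inside a concentric sphere of radius `r + m` and zero outside, and motion
rigidly translates the prostate (and the lesion with it) by a recorded
displacement vector while the dose stays where it was planned.  For each
recorded displacement of Euclidean length `d`, the geometric overlap of the
two spheres determines everything.

## The coverage model

The lens-shaped intersection of the lesion sphere (radius `r`) and the
boost sphere (radius `r + m`) with centres a distance `d` apart has
closed-form volume

$$V_{\mathrm{overlap}} = \frac{\pi}{12\,d}\,(2r + m - d)^2\,
  \bigl(d^2 + 2d(2r + m) - 3m^2\bigr),
  \qquad m < d < 2r + m,$$

with the limiting branches $V = \tfrac{4}{3}\pi r^3$ for $d \le m$ (the
lesion is wholly inside the boost) and $V = 0$ for $d \ge 2r + m$ (the
spheres are disjoint).  The expression is continuous at both branch points;
boundary ties go to the closed branches, which agree with the open-window
limits, so the choice is cosmetic but fixed.  Because the lens window is
open at `d = m`, the formula's `1/d` factor is never evaluated at `d = 0`.

Two normalizations of the overlap matter:

* `coverage_ipl()` — $c_{\mathrm{IPL}} = V_{\mathrm{overlap}} / \tfrac{4}{3}\pi r^3$,
  the fraction of lesion volume receiving boost dose.  Non-increasing in
  `d`, non-decreasing in `m`.
* `coverage_sib()` — $c_{\mathrm{SIB}} = V_{\mathrm{overlap}} / \tfrac{4}{3}\pi (r+m)^3$,
  the fraction of the boost dose bath occupied by lesion, i.e. the dose
  efficiency.  The identity
  $c_{\mathrm{SIB}} = \frac{r^3}{(r+m)^3}\,c_{\mathrm{IPL}}$ holds exactly
  for every displacement, so even a perfectly centred lesion fills only the
  cubic volume ratio: 36% for `r = 5, m = 2`, 20% for `r = 7, m = 5`.
  Margins buy lesion coverage at a steep price in dose efficiency.

Report tables print these fractions rounded half away from zero to integer
percent (`percent_half_up()`): `0.125` prints as 13%, where R's default
banker's rounding would print 12%.

## The motion model

Real-time tracking of the prostate during treatment shows that, unlike
inter-fraction setup error, the variance of intrafraction displacement
grows roughly linearly in elapsed time — the gland drifts rather than
jitters around a fixed point.  The generator therefore models each axis as
Brownian motion with drift: over a sampling step $\Delta t$ (minutes) the
displacement increment on axis $a$ is Gaussian with mean
$\mu_a \Delta t$ and variance $\sigma_a^2\,\Delta t\, \kappa^2$, where
$\kappa$ is a per-patient motility multiplier.  The first sample of every
fraction is exactly $(0,0,0)$: displacements are defined relative to the
start-of-fraction position established by image guidance.  No
mean-reversion term is included — tracked cohorts give no evidence for one
on the few-minute timescale of a fraction — and periodic respiratory or
peristaltic components are out of scope.

### Defaults and their calibration

All defaults were fixed once, from the published summary statistics of a
tracked cohort (28 patients, 720 fractions, 53.5 h of recording), before
any downstream result was computed:

* **Cohort shape** — 28 patients × 26 fractions of 4.46 min sampled every
  5 s (53.5 h / 720 fractions ≈ 4.46 min; ≈ 39,000 samples at ≈ 4.9 s
  spacing motivate the 5 s default).
* **Diffusion scales** — a Brownian path of duration $T$ sampled uniformly
  in time has pooled displacement variance $\sigma^2 T/2$.  Inverting this
  with $T = 4.46$ min against pooled per-axis standard deviations of
  0.76 / 1.15 / 1.64 mm (lateral / longitudinal / vertical) gives
  $\sigma = 0.509 / 0.770 / 1.098$ mm per $\sqrt{\text{min}}$.  The axis
  ordering lateral < longitudinal < vertical is a robust feature of
  prostate tracking and is preserved by construction.
* **Drifts** — small deterministic drifts of −0.058 mm/min
  (longitudinal) and +0.049 mm/min (vertical) reproduce the nonzero pooled
  per-axis means (−0.13 and +0.11 mm) at the mean sample time $T/2$; the
  lateral axis is symmetric.
* **Between-patient motility** — multipliers are log-normal with
  `sdlog = 0.45` and `meanlog = -sdlog^2`, so the mean *squared* multiplier
  is 1 and the cohort-pooled variance is unaffected by the spread.  A
  spread of 0.45 makes per-patient mean radial displacement span roughly a
  factor of five across a 28-patient cohort (≈ 0.5–2.5 mm), matching the
  patient variability seen in tracked data.

With these defaults a simulated cohort pools to a mean radial displacement
of ≈ 1.5 mm against the ≈ 1.3 mm of the tracked cohort; the per-axis
standard deviations come out some 10–15% low in a typical 28-patient
realization because the skewed multiplier distribution rarely attains its
population mean square in a cohort that small.  We accept this: the
generator is calibrated to the *population* model, not tuned to any one
realization.

### Seeding

One root seed defines the whole cohort.  Patient-level and fraction-level
streams are derived by a fixed counter scheme
(`derive_stream_seed(seed, patient, fraction)`, with `fraction = 0`
addressing the patient's motility draw), so any single fraction can be
regenerated in isolation and byte-identical trajectory files result from
identical configurations.  All generator functions restore the global RNG
state on exit.

## Displacement statistics

`displacement_table()` pools every sample with equal weight over all
fractions and patients — fraction lengths are equal by design, and tracked
cohorts are pooled the same way — and reports mean, standard deviation,
min/max, the 5/25/50/75/95% quantiles and the root mean square for the
three signed axes and the radial (Euclidean) distance.  Quantiles use
linear interpolation between order statistics (type 7); the convention is
fixed purely so that results are bit-for-bit reproducible.  The `t = 0`
anchor samples are recorded positions and are included by default;
`include_anchor = FALSE` drops them, since whether tracked-cohort tables
include them is ambiguous.

## Dose–volume histograms

`compute_dvh()` estimates the lesion DVH by Monte Carlo: `n = 5000` points
(the conventional size; configurable) are sampled uniformly in the lesion
sphere via an isotropic Gaussian direction and radius $rU^{1/3}$ — a fixed
scheme, so seeds are portable — and each point receives one unit of dose
for every displacement sample under which it remains inside the shifted
boost sphere, the inclusion test being
$(a+x)^2 + (b+y)^2 + (c+z)^2 \le (r+m)^2$.  Dividing by the number of
displacement samples (always the actual sample count) gives per-point dose
fractions; the cumulative curve is built from these exact values without
binning, and `dvh_curve_table()`'s 1%-step grid is presentation only.

`dvh_query_D(curve, v)` returns the lower order statistic (the
$\lceil vn \rceil$-th largest per-point dose): a conservative rule that
guarantees at least the stated volume fraction truly receives the reported
dose.  `dvh_query_V(curve, D)` is the plain exceedance fraction.

The mean per-point dose and the trajectory-mean of `coverage_ipl()` are two
estimators of the same volume integral — the expected covered fraction of
the lesion — and the test suite holds them to agreement within Monte Carlo
error.  This cross-check ties the stochastic DVH engine to the closed-form
geometry and would catch an error in either.

## Numerical and design choices

* Displacement `d` enters all geometry only through the Euclidean norm;
  axis sign conventions (+left, +cranial, +anterior) matter only for file
  stability.
* The coverage formula's applicability window is `m < d < 2r + m`, the
  window of the piecewise definition itself; statements of the lens
  formula elsewhere with a `r + m` upper bound are typographic slips, as
  the formula is plainly continuous and correct up to `2r + m`.
* The DVH engine processes displacement samples in chunks of 2000 so the
  points × samples distance matrix never materializes whole; memory stays
  below a few hundred MB for the default problem size.
* Degenerate inputs fail loudly: empty trajectory sets, negative
  distances, mismatched point-set/geometry radii, and out-of-range DVH
  queries are errors, not silent zeros.

## What the tests show — and what they cannot

The test suite runs on synthetic cohorts only.  Problem sizes were chosen
so the full suite completes in about a minute: variance-law recovery uses
10,000 replicate fractions; the coverage oracle sweeps 1,000 random
geometries against 200,000-point inclusion sampling; DVH consistency uses
a 10-patient cohort at the default 5,000 points.

Passing tests therefore demonstrate that the geometry is exact, the DVH
estimator is consistent with it, and the generator has the statistical
structure it claims (linear-in-time variance, anchored starts, calibrated
scales, reproducibility).  They cannot validate the motion model against
real prostates: real trajectories include transient events (gas passage,
muscle contraction), possible mean reversion, measurement noise, and
rotations and deformations of the gland, none of which the generator
emulates.  Coverage tables computed from a synthetic cohort consequently
resemble, but do not reproduce, tables computed from any particular
tracked cohort — only the zero-displacement occupancy ratios
$r^3/(r+m)^3$ are cohort-independent.

## Known limitations

The dose is ideally spherical and binary; there is no beam/apparatus
interplay, no fraction-wise dose accumulation across differing geometries,
no organ-at-risk dosimetry, and no target rotation or deformation.  These
are simplifications inherited from the center-of-gland tracking data the
model emulates, not implementation shortcuts.
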