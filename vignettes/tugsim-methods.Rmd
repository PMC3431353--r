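---
title: "Methods: the tug-of-war transport model and its trajectory analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tug-of-war transport model and its trajectory analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tugsim` simulates a cargo (an organelle such as a melanosome, radius
`r` = 500 nm) transported along a microtubule by two teams of molecular
motors of opposite polarity: `N_f` plus-end-directed (kinesin-2-like)
and `N_b` minus-end-directed (cytoplasmic-dynein-like) steppers, each
permanently tethered to the cargo through its own elastic linker.

The cargo position `x_c` obeys an overdamped Langevin equation

    dx_c/dt = (1/gamma) * sum_i f_i + xi(t)

where `gamma = 6 pi eta r` is the Stokes drag (`eta = n_gamma *
eta_water`; the cytoplasm is modelled as ~500x more viscous than water)
and `xi` is white thermal noise of intensity `k_B T / gamma`, so the
fluctuation-dissipation relation holds: a free cargo diffuses with
`D = k_B T / gamma` (about 880 nm^2/s for the reference conditions).

Each motor-linker is slack within a distance `x0` = 110 nm of the cargo
and Hookean beyond it,

    f_i = k (d_i - x0)  for d_i >= x0,   k (d_i + x0)  for d_i <= -x0,
    f_i = 0 otherwise,   with d_i = x_i - x_c,

always pulling the cargo toward the motor. Motors whose linker is taut
are called *pulling*; the pulling state `(q_f, q_b)` controls the
instantaneous velocity while the attachment state `(n_f, n_b)` controls
run lengths.

Attached motors step by `dx` = 8 nm toward their polarity, never
backward, with probability per unit time `v(L)/dx`, where the
load-velocity relation is

    v(L) = v0 (1 - (L/Fs)^w),  0 <= L <= Fs,

`v = 0` at and beyond the stall force `Fs`, and `v = v0` for assisting
loads (`L < 0`; the minimal capped extension consistent with the
no-back-steps rule). The load is the reaction to the linker force:
`L = f` for forward motors, `L = -f` for backward ones. Attached motors
detach with rate `eps * exp(|f|/Fd)` (Kramers-type escape over a
load-lowered barrier; the magnitude is used so assisting and opposing
loads destabilize the bond alike). Detached motors re-engage with rate
`pi_att`, uniformly on the lattice sites strictly inside the slack zone,
so a new engagement starts force-free.

A consequence worth naming: a backward motor left behind by a
forward-moving cargo keeps stepping away until its load reaches `Fs` at
distance `x0 + Fs/k`; past that point it cannot advance and acts as an
elastic anchor until it detaches. With loose linkers (`k` = 0.02 pN/nm)
that anchor distance is 410 nm and anchors persist for hundreds of
milliseconds; with stiff linkers (`k` = 0.3 pN/nm) it is 130 nm and
force builds an order of magnitude faster, which is what removes the
low-velocity tug-of-war mode and sharpens reversions.

### Reference conditions

`referential_set()` returns the canonical symmetric parameterization:

| parameter | value | meaning |
|---|---|---|
| `N_f = N_b` | 2 | motors per team |
| `n_gamma` | 500 | viscosity relative to water |
| `r` | 500 nm | cargo radius |
| `T` | 300 K | temperature |
| `x0` | 110 nm | linker slack half-width |
| `k` | 0.02 pN/nm | linker stiffness (in-vivo scale) |
| `v0` | 500 nm/s | zero-load velocity |
| `w` | 2 | load-velocity nonlinearity |
| `Fs` | 6 pN | stall force |
| `eps` | 0.2 /s | zero-load detachment rate |
| `Fd` | 3 pN | detachment force |
| `pi_att` | 2 /s | attachment rate |

`canonical_config()` also provides the stiff-linker variant (`k` = 0.3
pN/nm, the value measured for kinesin in vitro), two asymmetric
attachment/detachment sets emulating dispersion- and aggregation-like
conditions (`pi_f` = 3.5 vs 1.8 /s against `pi_b` = 2.2 /s, `eps` near
0.08 /s, `n_gamma` = 300), and a team-size imbalance (`N_f` = 2,
`N_b` = 3). `scale_parameters()` implements the approximate dynamical
invariance `Fs -> lambda Fs`, `Fd -> beta Fd`, `k -> lambda k`,
`gamma -> lambda gamma` (with `beta ~ sqrt(lambda)`) used to study
lower stall forces.

## Numerical scheme

The cargo update is first-order Euler-Maruyama; motor events are
independent Bernoulli draws with per-step probabilities `rate * dt`.
The default `dt` = 1e-5 s keeps every event probability below ~1e-3
(the engine enforces a hard 0.1 guard and reruns a trajectory at
`dt/10` if it ever trips, to at most 1e-7 s). The spring relaxation
time `gamma/k` is 236 ms (16 ms for the stiff variant), three to four
orders above `dt`. Trajectories start with all motors engaged at
relaxed positions, run 20 s or until every motor is detached, and are
sampled every 0.01 s.

The compiled inner loop uses one xoshiro256++ stream per trajectory,
seeded by scrambling `(base_seed, trajectory index)` through
splitmix64, so ensembles are bit-reproducible and independent of
execution order, and extending an ensemble preserves its prefix.

## Trajectory analysis

The analysis mirrors the segmental-velocity methodology of
single-particle tracking studies and runs equally on simulated
trajectories or plain (t, x) tables from tracking software (state
channels are then unavailable).

**Processive periods.** The path is smoothed with a 0.1-s moving
average and split into maximal single-direction runs; a run ends when
the cargo retraces more than 60 nm from its running extremum, runs are
trimmed to their extrema, and only runs with net displacement of at
least 100 nm are kept. The original selection procedure for processive
periods is not fully specified in the available text; this rule is the
package's own deterministic concretization and all three thresholds
are exposed as arguments.

**Segments.** Each period is cut into consecutive non-overlapping
40-point windows (0.4 s). The segmental velocity is the OLS slope of
position on time; windows with speed below 100 nm/s or |Pearson r|
below 0.98 are discarded. Each accepted segment carries the fractional
occupancy of every `(q_f, q_b)` and `(n_f, n_b)` state over its 40
samples, so state-resolved histogram curves sum bin-exactly to the
total — occupancy weighting, rather than a majority vote, is what makes
that partition exact.

**Histograms.** Default bin width 55 nm/s (4-5 bins per 250 nm/s mode;
the upstream bin-size criterion is not reproduced in the available
text, and every quantity reported here is insensitive to the choice);
25 nm/s is used for the stiff system, whose distribution is a single
~100-nm/s-wide peak that would otherwise occupy too few bins for a
four-component fit. Normalization sets the global maximum to 1.

**Spatial distributions and mu.** For forward-moving accepted segments
in a velocity window, motor positions relative to the cargo are pooled
over every sample of every segment; `mu` is the ratio of pulling
forward (`d > x0`) to pulling backward (`d < -x0`) motor counts. Both
per-team histograms are normalized by the same constant so the area
quotient beyond the slack boundaries equals the count ratio.

**Reversions.** Long-term reversions are extrema of the 0.05-s-smoothed
path followed by an opposite excursion of at least 250 nm lasting more
than 1 s. The slowing-down phase before a reversal is fitted over the
last 1 s of approach with a changepoint model: constant-velocity motion
rolling off into the saturating exponential
`x(t) = A (1 - exp(-(t - t0)/t_r)) + c`, continuous in value and slope
at the free onset `t0`. Fitting the onset jointly, instead of
detecting it with a residual-band rule and fitting only past it,
proved necessary: on synthetic ground-truth curves the two-stage
variant returned time constants that tracked the analysis-window
length, while the joint fit recovers `t_r` from 50 to 750 ms to a few
percent with 10-30 nm of localization noise. Fits with `t_r` longer
than the post-onset span, or with fewer than 10 post-onset samples,
are flagged unidentifiable and excluded. The 1-s window keeps the
linear phase of the model local; longer windows let velocity
fluctuations of the preceding run leak into the fit and inflate the
recovered constant. The characteristic rise time of an ensemble is the
exponential-decay scale of the `t_r` histogram (Poisson log-linear
regression from the modal bin), with a bootstrap standard error.

**Multimodal fits.** Velocity histograms are fitted with a sum of four
Gaussians by Levenberg-Marquardt least squares, amplitudes bounded
below by zero and centers initialized at multiples of 250 nm/s. Three
stabilizing choices are defaults, all reversible through arguments:
centers are box-constrained to half a mode spacing (±125 nm/s) of
their initialization, so component m keeps denoting the m-th velocity
mode; widths are bounded below by one bin width, because a component
narrower than a bin is below the resolution of binned data and only
ever chases single-bin noise; and a component's relevance is judged by
its peak contribution within the histogram support, because a
component pushed against a boundary outside the data carries an
arbitrary raw amplitude while contributing nothing. The ratio `A2/A1` is, by default, the ratio of
fitted-curve heights at the first two mode centers — the reading of
"peak amplitude" that is insensitive to how overlapping components
split mass; the raw component-amplitude ratio is available as
`type = "component"`. A shared-width variant (`shared_sigma = TRUE`)
exists because the exact parameterization of the upstream
four-Gaussian fit is not reproduced in the available text.

## What the synthetic fixtures do and do not emulate

`make_fixture()` produces deterministic paths with known truth — pure
lines, triangle waves, linear-approach-to-exponential-reversion curves
and exact four-Gaussian histograms — used to validate the pipeline
independently of the simulator. They emulate the morphology of
trajectories (constant-velocity runs, wave-shaped reversions) but not
their microscopic structure: no stepping noise, no state changes, no
heavy-tailed restitution velocities. A pipeline that passes on
fixtures is validated as an estimator; its biological fidelity is
tested only through the simulator, and real tracking data additionally
carries localization noise and drift that neither source emulates (the
package deliberately performs no drift correction or noise
deconvolution).

## Problem sizes and reproducibility

The packaged test suite and the acceptance script reproduce the
study's quantities with ensembles of 120-500 trajectories per
condition (the original analyses pooled 1000-4000); all stochastic
quantities here are Monte-Carlo estimates whose scatter at these sizes
is a few percent for segment fractions and mu, and 10-20% for
rise-time scales and amplitude ratios. Every run is reproducible from
a single integer seed.

At these sizes, our realizations agree with the published values for
the region-I pulling ratio, the mode spacing, the loose-linker rise
time, and the dispersion-set observables, while the faster-window
pulling ratios and the stiff-linker rise time come out systematically
above the published point values: the velocity-filtered segment
population in this implementation correlates more strongly with
forward-only pulling states, and stiff-linker reversals are approached
through multi-state slow-downs rather than single sharp corners. Both
analyses depend on selection details of the original pipeline that the
available text does not fully specify; the corresponding thresholds
are exposed as arguments rather than hard-coded.

## Known limitations

* One spatial dimension; no cargo rotation, no microtubule lattice
  obstacles, no motor back-stepping (dropped deliberately in the model
  this package implements).
* The detachment law is a single exponential in the load magnitude;
  catch-bond or non-monotonic laws are out of scope.
* Parameter sets are inputs; the package fits no parameters to
  experimental data.
* `advance_state()` is a reference implementation for small-system
  diagnostics; production runs go through the compiled engine.
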