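---
title: "Modelling intermittent collective exploration from tracked fish trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intermittent collective exploration from tracked fish trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishsde)
```

## The problem

Small groups of zebrafish alternate between swimming in close proximity and
brief far-range excursions ("exploration episodes"), and the balance between
the two shifts with the availability of visual cues: in the dark, fish drift
farther apart and explore longer. fishsde implements the quantitative chain
that turns raw tracked trajectories into a mechanistic, simulatable model of
this behaviour:

1. visual-cue metrics (opacity, optic flow) quantifying what each fish sees;
2. exploration-episode statistics on the interindividual distance
   \(x(t)\);
3. data-driven identification of a one-dimensional stochastic differential
   equation \(dx = F(x)\,dt + G(x)\,dW\) for \(x(t)\);
4. a tilted double-well potential interpretation of the fitted drift;
5. Euler--Maruyama in-silico experiments reproducing the experimental design
   so the fitted model can be validated against the episode statistics.

Because the package ships no animal recordings, a synthetic-data module
generates every input the pipeline needs under the recording conditions of
the original setup: 30 Hz sampling, 18 000 frames per trial, a 60 cm circular
arena, 3 cm fish, groups of one to three.

## Visual-cue metrics

Conspecific bodies are discs of one body length (3 cm) diameter centred on
the tracked centroid. In the focal fish's frame (0 = heading), a disc at
distance \(d\) subtends an angular "shade" of half-width \(\arcsin(r/d)\)
centred on its bearing. Opacity is the measure of the *union* of shades
inside the visible field divided by \(2\pi - \gamma\), where
\(\gamma = 21^\circ\) is the blind angle, so overlapping conspecifics are
never double-counted and \(O \in [0, 1]\). Optic flow multiplies, for each
conspecific, the absolute angular velocity of its shade centre between
consecutive frames by the visible width of its shade, and sums over
conspecifics.

Two conventions exist for where the blind wedge sits. Anatomically the blind
area is behind the fish, and that is the default
(`blind_zone_centre = "rear"`); the indicator-set formulation that excludes
\((-\gamma/2, \gamma/2)\) around \(\psi = 0\) instead puts it in front of
the fish if \(\psi\) is measured from the heading, and is available as
`blind_zone_centre = "front"`. The package takes no position on which was
intended; the default follows anatomy.

The analytic interval-union computation is cross-checked, in the test suite
and the acceptance script, against an independent ray-cast oracle
(`opacity_raycast_oracle()`) that discretises the visual field into 36 000
rays; the two agree to the discretisation limit \(2\pi/n_\text{rays}\).

The per-shade angular velocity uses the displacement of the shade *centre*
between consecutive frames. Edge-based schemes are conceivable; the scheme
is isolated in `optic_flow()` so it can be swapped.

## Episodes

An exploration episode is a maximal run of frames with \(x(t)\) strictly
above 3 body lengths (9 cm) lasting strictly longer than 3 s, preceded by at
least one frame at or below the threshold -- the group must actually have
been together before an excursion counts. At 30 Hz "strictly longer than
3 s" means at least 91 frames; a 90-frame run is rejected. Episode amplitude
is the mean distance over the episode by default; a median mode exists
because both conventions are in circulation, and per-trial summaries average
episode durations and amplitudes.

## SDE identification

The drift and squared diffusion are estimated pointwise from conditional
increment moments,
\(\hat F(t) = (x(t+\delta t) - x(t))/\delta t\) and
\(\widehat{G^2}(t) = (x(t+\delta t) - x(t))^2/\delta t\),
each paired with the state \(y = x(t)\) it conditions on, pooled across
trials, and bin-averaged on a 0.1 cm grid for visualisation and potential
reconstruction. A fourth-order zero-phase Butterworth low-pass filter
(cutoff 0.1 rad s\(^{-1}\)) is available for noisy measured tracks; it is
*off* by default in `identify_sde()` because filtering removes exactly the
high-frequency increment variance from which \(G^2\) is estimated and
therefore biases the diffusion downward. At this cutoff the normalised
corner frequency at 30 Hz is about \(10^{-3}\) of Nyquist; the filter is
applied as two passes with odd-reflection padding and steady-state initial
conditions, which at such corner frequencies is required for a usable
response (a zero-initialised pass does not even preserve a constant input).

Functional forms are selected by stepwise sparse regression on a polynomial
library of degrees 0--5. A LASSO fit — cyclic coordinate descent with
soft-thresholding, penalty chosen by K-fold cross-validation over 30
log-spaced candidates — initialises the coefficients; terms are then removed
down the degree axis, re-fitting after each removal, and the iteration stops
when the cross-validated error genuinely increases. Three numerical choices
deserve explanation:

* **Exact polishing of the coordinate descent.** Raw power bases on a state
  range of tens of centimetres are severely collinear (condition numbers
  beyond \(10^9\)), where plain cyclic descent creeps for millions of
  sweeps. The solver therefore verifies the KKT conditions on the current
  active set and finishes with an exact orthant solve; if the sign pattern
  cannot stabilise — which happens when the penalty is below what the
  conditioning can resolve — an exact orthant enumeration (feasible because
  the library is small) supplies the global minimiser. Termination is
  otherwise by objective stall. `lasso_cd()` at \(\lambda = 0\) reproduces
  least squares to \(10^{-8}\), and matches glmnet along the path.
* **Degree-ordered pruning.** In a collinear basis the smallest standardised
  coefficient is a poor guide to which term matters least, and the L1
  penalty's choice among near-collinear powers is close to arbitrary (on the
  same data it may keep \(\{1, x, x^3\}\) or \(\{1, x, x^2\}\) depending on
  the seed). The library is nested by construction, so removal candidates
  walk down the degree axis: the top active term is dropped unconditionally
  when its standardised coefficient is below the pruning threshold
  (\(10^{-3}\)), and otherwise only if cross-validation tolerates the
  removal. This makes the selected degree reproducible across realisations.
* **Paired cross-validation termination.** "The error ceased to decrease" is
  judged at the resolution cross-validation actually has: both models are
  scored on the same folds, so the paired fold-difference standard error is
  the natural yardstick, and a pruning step is rejected only when the error
  rises by more than `cv_sigma` (default 2) paired standard errors plus a
  small relative floor. Fold assignment respects the data's structure:
  contiguous blocks for serially dependent pointwise estimates, seeded
  shuffles (at least 10 folds) for bin-level fits, where contiguous blocks
  of sorted bins would mean scoring polynomial extrapolation into a held-out
  state range.

The reported diffusion is \(G\), not \(G^2\): the parabola
\(b_2 x^2 + b_1 x + b_0\) is fitted to the square root of the bin-level
estimate. Two corrections matter here. The second conditional moment
estimates \(G^2 + F^2\delta t\), and near the wells' shoulders the drift
contribution is not negligible; the unbiased *within-bin variance* of the
increments removes the local mean — and with it the drift contribution, for
any drift — exactly, which is why the diffusion fit uses it (bins with a
single sample carry no variance information and are dropped). Second,
\(\sqrt{\chi^2_n/n}\) is biased low by a factor that depends on the bin
count, so sparsely visited bins would otherwise look systematically flatter
than \(G\); the standard chi-distribution correction removes this. The fit
weights bins by their counts, which makes the bin-level regression
equivalent to the pooled per-sample regression and concentrates the
curvature information where it genuinely lives — the sparsely visited
transition region between the wells.

## The potential model

The fitted cubic drift is interpreted through
\(V(x) = -\alpha x - \beta (x - x_l)^2 (x - x_h)^2\) with
\(F = -\partial V/\partial x\); `drift_from_potential()` and
`potential_from_drift()` convert exactly between the two
parameterisations. The form is implemented literally: stable wells at
\(x_l\) and \(x_h\) require \(\beta < 0\), and a positive \(\alpha\) tilts
the potential toward large \(x\). Because the sign conventions in circulation
are not mutually consistent, `bistability_report()` reports the realised
geometry — well locations, barrier position and height, tilt direction —
rather than trusting a parameter's sign. The empirical potential integrates
bin-averaged drift by the trapezoidal rule, anchored at the first retained
bin; on an exactly sampled cubic it converges to the analytic quartic at
second order in the bin width.

## Simulation and the in-silico experiment

`euler_maruyama()` integrates the fitted model with the first-order scheme
\(x_{k+1} = x_k + F(x_k)\delta t + G(x_k)\sqrt{\delta t}\, z_k\) at the
recording rate. The working domain defaults to \([0, 57]\) cm — distance is
non-negative and bounded by the tank diameter minus one body length — with
reflecting boundaries; the fitted diffusion parabola is floored at
\(10^{-3}\) cm s\(^{-1/2}\) so it cannot go negative at the domain edges.
The initial state defaults to a uniform draw between the wells. One master
seed spawns per-trial streams, so trial \(i\) is bit-identical whether
simulated alone or as part of the vectorised ensemble.

`run_insilico()` reproduces the experimental layout — Dyads-Bright,
Dyads-Dark, Triads-Bright, Triads-Dark, ten trials each — detects episodes
on every simulated path, removes outlier trials by the interquartile-range
rule (Tukey fences with linear-interpolation quartiles, applied per response
variable), and runs a two-way ANOVA (Illumination x Number of Individuals)
with \(\eta^2\) effect sizes on mean episode duration and amplitude. Type II
sums of squares accommodate the mild unbalance left by zero-episode or
outlier trials; for balanced designs they coincide with the classical
decomposition and are exactly additive.

## The synthetic regimes

`default_regimes()` provides clearly non-authorial bright/dark parameter
sets that mirror the qualitative experimental contrast: both regimes share a
negative-curvature diffusion parabola (noise largest at intermediate
distances), the bright regime has a stronger tilt toward the near well and a
higher barrier, and the dark regime a weaker tilt, a lower barrier and a
farther exploration well. The magnitudes were chosen once so that a 10-minute
trial shows a handful of multi-second episodes — the intermittency regime the
pipeline is about — and so that dark trials show longer and larger episodes
than bright ones. They are a test bed for the machinery, not a description
of any animal data.

The trajectory embedding places the group centroid on a smooth
mean-reverting walk inside the arena and rotates the group axis smoothly;
dyads sit at centroid \(\pm x/2\) along the axis, triads on an equilateral
triangle whose mean pairwise distance equals \(x(t)\) (matching all three
pairwise distances would be under-determined). Bounded uniform positional
jitter of 0.05 cm emulates tracking noise, bounded like the pixel
quantisation it stands in for. What the generator does *not* emulate:
burst-and-coast swimming kinematics, wall-following, hydrodynamic
interactions, occlusion artefacts, or any coupling from the visual cues back
to motion. Passing tests therefore demonstrate that the estimators and the
inference machinery are correct on data whose generating process is known —
not that the biological conclusions transfer to any particular recording.

## Problem sizes and determinism

The test suite and the acceptance script run the recovery studies at the
recording scale of the original design: ten trials of 18 000 samples per
condition for parameter recovery, \(10^6\) steps for the stationary-variance
check, 1 000 random scenes for the visual-field oracle. All stochastic
stages are pure functions of (configuration, seed); re-running any stage
with the same seed reproduces its outputs byte for byte.

## Known limitations

* The interindividual distance of a triad is the mean pairwise distance; a
  1-D state cannot represent which individual left the group.
* Kramers--Moyal estimates at 30 Hz carry \(O(\delta t)\) discretisation
  bias; the package corrects the leading drift contribution in the
  diffusion but does not implement higher-order or kernel-based estimators.
* Degree selection near the identifiability limit (few well-to-well
  transitions) is resolved by parsimony at the cross-validation resolution;
  with very few transitions the diffusion curvature sign, not its exact
  magnitude, is the robust quantity.
* For a quartic double-well the barrier height is tied to the well
  stiffness (barrier \(\approx \theta\,\Delta^2/32\) for well separation
  \(\Delta\)), so regimes showing *frequent* episodes necessarily have
  drift nonlinearity near or below the Kramers--Moyal noise floor at ten
  trials: on the default regimes the procedure parsimoniously — and
  correctly, at this resolution — reports a linear mean-reverting drift.
  Recovering the full cubic requires a strongly bistable regime (e.g.
  \(\beta = -0.01\)), where transitions are rare and the wells are sampled
  through relaxation instead.
* The in-silico ANOVA inherits the usual caveats of n = 10 trials per cell.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- synth_spec(seed = 1)
trials <- generate_trials(spec, "dark", n_trials = 3)
cues <- visual_cue_series(trials[[1]])
dist <- lapply(trials, interindividual_distance)
trial_episode_stats(dist)
fit <- identify_sde(dist, cfg = ssr_config(seed = 1))
bistability_report(fit$model)
```
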