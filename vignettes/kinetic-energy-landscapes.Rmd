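---
title: "Kinetic-energy landscapes and safe-range prediction for planar reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-energy landscapes and safe-range prediction for planar reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelscape)
```

## The scientific question

When a primate reaches repeatedly between the same two targets in a plane,
the path it settles on is rarely the straight line, and it differs
systematically between movements. `kelscape` implements one mechanistic
account of this selection: trajectories are constrained by the kinetic
energy (KE) they require, but the motor system does not chase the KE
minimum — it settles anywhere inside a *plateau* of the KE-versus-curvature
landscape, where changing the path a little changes the energy hardly at
all. The package provides the forward model (arm, trajectories, KE), the
behavioural metrics, the plateau predictor, and a synthetic study generator
that makes every stage testable without animal data.

## The biomechanical model and its assumptions

The arm is a two-link planar linkage, as held by a planar exoskeleton:
upper-arm length $L_1 = 0.13$ m and mass $m_1 = 0.220$ kg, forearm
$L_2 = 0.23$ m and $m_2 = 0.090$ kg by default. Each segment is treated as a
rigid rod with its mass concentrated at the distal end, so the moments of
inertia are $I_s = m_1 L_1^2$ and $I_e = m_2 L_2^2$. Gravity, friction,
interaction torques and muscle dynamics are all outside the model: KE is the
only cost considered, computed as the sampled sum
$$KE = \sum_t \left( \tfrac12 I_s \omega_s^2 + \tfrac12 I_e \omega_e^2 \right)$$
over shoulder and elbow angular velocities. Note this is a sum over samples,
not a time integral; its absolute scale therefore depends on the sampling
density. All landscape comparisons fix a common 501-point profile for
exactly this reason, and `estimate_ke_for_observed_shape()` scales as
$1/T^2$ when the total duration $T$ changes (halving $T$ doubles the
velocities and quadruples KE).

The angle convention is the exoskeleton's, not an anatomical one:
$X_h - X_s = L_2\cos(\theta_e-\theta_s) + L_1\cos(\theta_s)$ and
$Y_h - Y_s = L_2\sin(\theta_e-\theta_s) + L_1\sin(\theta_s)$, i.e.
$\theta_s$ is the absolute direction of the upper arm and
$\theta_e - \theta_s$ that of the forearm. Inverting these equations has two
solutions; `kelscape` selects the branch with
$\theta_e - 2\theta_s \in (0, \pi)$ (the elbow-open configuration of a right
arm in the device) and exposes the mirrored branch via
`arm_geometry(ik_branch = "closed")`. Recovered shoulder angles are wrapped
canonically to $(-\pi, \pi]$ so that inverse∘forward is the identity on the
chosen branch (tested to $10^{-9}$ rad). Reachability is enforced with a
$10^{-9}$ m slack at both rims of the annulus and the cosine argument is
clamped to $[-1, 1]$ before `acos`.

## Simulated trajectories

Candidate paths between two points are parabolas in the chord frame:
$y(x) = 4\,d\,l\,(x/l)(1 - x/l)$ on a chord of length $l$, sampled at equal
steps in $x$. The apex offset is $d\,l$, so the *signed normalised
deviation* — the maximum perpendicular distance to the chord divided by
$l$ — equals $d$ exactly, giving a clean round-trip with the measurement
operator. The sign convention puts negative deviations on the left of the
movement direction. $d = 0$ is the straight segment; the same construction
is used unchanged in joint space (shoulder-angle/elbow-angle plane).

Timing comes from an inverted-Gaussian schedule: with path samples indexed
$0..n-1$ ($n = 501$), interval $k$ receives duration proportional to
$C - g(k)$ where $g(k) = \exp(-\tfrac12((k-\mu)/\sigma)^2)$, $\mu = 250$,
$\sigma = 75$, and $C = \max g + 0.1$; the schedule is normalised to a total
duration of 1 s. Short central intervals mean fast mid-movement traversal —
the bell-shaped speed profile of natural reaching. One numerical choice is
ours: $g$ is evaluated at the *midpoint* of each interval ($k - 0.5$ in
sample-index units) rather than at either bounding sample. With $\mu$ at the
sample midpoint this makes the schedule exactly mirror-symmetric, consistent
with the interval-centred finite differences used for velocities (length
$n-1$, each velocity attributed to its interval midpoint, KE summed over
intervals).

## KE landscapes

`build_ke_landscape()` evaluates KE on a symmetric 33-level deviation grid,
$[-0.5, 0.5]$ a.u. by default. The grid span is a package choice (it covers
the effective ranges a subject plausibly produces); the count of 32 levels
around the straight path is the analysis's standard resolution. In hand
space each parabola is converted point-by-point to joint angles before KE is
computed; in joint space the endpoints are converted first and the parabola
drawn directly in the angle plane — which is why, with jitter off, every
joint-space landscape attains its minimum exactly at deviation 0 (straight
joint paths at fixed timing minimise the quadratic sum), while hand-space
minima scatter across non-zero deviations.

Endpoint variability is emulated by jittering start and end points uniformly
within the 1 cm target-acceptance ("logical") radius, 100 replicates per
level, with deviation defined relative to the jittered chord. Two design
choices matter here:

* **Common random numbers.** One set of 100 endpoint pairs per submovement
  is shared across all 33 levels. The marginal distribution at each level is
  unchanged, but the level-to-level *differences* — everything the slope
  threshold looks at — are freed from replicate noise, which would otherwise
  exceed the derivative signal by an order of magnitude.
* **Degenerate landscapes.** A landscape that is steep and monotone through
  the whole effective range has no level whose absolute slope is below the
  threshold. `kels_predict()` raises an error by default for this case;
  `fallback = "flattest"` instead collapses the safe range onto the single
  flattest in-range level and flags the prediction `degenerate`, which is
  what the whole-task pipeline uses so that all 19 submovements report.

## The safe-range predictor

For one subject, the *effective deviation range* is the central 98% quantile
range of all hand deviations pooled across submovements. Per submovement,
the slope threshold is the standard deviation (population form — the
divisor-by-$n$ convention is a documented choice, configurable by the user
at the call site) of the landscape's mean KE over the in-range grid levels.
The first derivative of KE with respect to deviation is estimated by central
differences on the grid, one-sided at the edges — note the derivative units
(J per a.u.) differ dimensionally from the threshold (J); the comparison is
deliberate and follows the predictor's definition (KE change per unit
deviation against typical KE variability), not a dimensional argument. The
safe range is the longest contiguous in-range run of levels below threshold;
ties go to the run with lower mean KE, then to the run nearer zero. The
KE-LS prediction is the run's median grid level, taking the lower-middle
level for even-length runs so predictions stay on-grid. Two competitors are
evaluated throughout: the deviation of minimum modelled KE (ties resolved
toward the smallest absolute, then negative, level) and the constant zero
(straightest hand path).

The threshold is computed per submovement. A per-subject pooled threshold is
a defensible alternative reading of the procedure; we chose the
per-submovement form because the threshold's rationale is the *typical KE
fluctuation of that submovement*, and a pooled value would be dominated by
between-submovement KE differences. Callers wanting the pooled variant can
pass any scalar to `kels_predict()` directly.

Prediction accuracy is compared by repeated k-fold RMSE: submovements are
shuffled into 5 near-equal folds, RMSE of each method computed per fold, and
the split repeated 20 times (identical partitions across methods within a
repeat), yielding 100 RMSE values per method. The predicted *change* for a
submovement is defined as `kels_pred - early_median` (prediction minus the
early-session median deviation) and is correlated with the observed change
(late minus early session means); the orientation of this difference is a
documented convention.

## Behavioural metrics

Movement onset uses a three-step detector: supra-threshold speed segments
shorter than 50 ms are discarded as blips; from the first surviving
threshold crossing the algorithm walks backwards to the most recent
acceleration zero-crossing into positive — the foot of the speed bell — and
falls back to the stream start (with a warning) if acceleration never dips.
Thresholds are per-dataset by nature; for the synthetic generator the
default is 0.02 m/s, chosen *below* the generator's bell-foot speeds
(~0.03 m/s on the shortest 3.6 cm reaches, because the inverted-Gaussian
schedule starts at a non-zero speed) and *above* hold-period noise speeds —
a threshold above the foot speed silently truncates curved movements and
biases deviations toward zero.

Trials are sectioned at target-reach events into three submovements keyed by
their (start, end) target pair, so the 24 sequence slots of the default task
collapse to 19 unique submovements. Spatial variability of a trajectory
bundle is the RMS Euclidean distance to the mean path on a 10 ms grid,
truncated at the shortest trajectory (the scalar distance-to-mean form, not
per-axis SDs). Deviation scatter in the (joint, hand) plane is summarised by
1-SD covariance ellipses (major-axis angle in $[-90°, 90°)$; collinear input
degenerates with a warning). Submovement classes are found by k-means under
the cosine distance — only the direction of the mean (joint, hand) deviation
vector matters — with random restarts and labels canonicalised so class 1
has the centroid with the smallest absolute joint component.

## The synthetic study generator

`generate_study()` emulates the task's stated world: 6 hexagon targets plus
centre (centre-to-top 3.6 cm / centre-to-side 4.5 cm for the E-like profile,
4 / 5 cm for J-like), 8 three-target sequences reducing to 19 submovements,
sessions of 3 blocks × 40 trials (5 per sequence per block, order shuffled
within block), ~840 ms movement durations (SD 0.08 s, clamped inside the
1.5 s timeout), 250 ms centre holds and 150–200 ms target holds, endpoint
scatter inside the 1 cm logical radius, and 1 kHz streams. The exact
sequence orders are not published; the default set is a reconstruction
chosen to produce the documented 19 unique pairs and is user-replaceable.
The hexagon centre sits 25 cm in front of the shoulder, a comfortable
mid-workspace position for these segment lengths; all targets and all
grid-deviation parabolas between them stay well inside the reachable
annulus.

Per-submovement mean deviations drift across sessions from an initial value
toward a target value by exponential approach (`1 - drift_rate` per
session); real learning dynamics are not monotone and are not claimed —
drift is a knob for testing recovery, not a model of learning. Trial
deviations are Gaussian around the session mean, truncated to the grid span.
Speed noise is a smooth multiplicative envelope on the profile intervals
(11 Gaussian log-factor knots per movement, renormalised to the drawn
duration): real kinematics are smooth at the millisecond scale, and
per-interval white noise would produce physically implausible speed traces
whose acceleration sign flips every sample, defeating any onset detector.
Hold jitter is likewise smooth (50 ms knots, 0.15 mm SD). Ground truth —
drawn deviations and durations per trial, true mean deviation and noiseless
re-timed KE per session × submovement — is recorded for every study.

What a green end-to-end test establishes is therefore limited: the pipeline
recovers what this generator plants (deviation means, drift differences,
safe-range convergence) under realistic sampling noise. It does not
establish that real monkeys behave this way, that the drift law matches
learning, or that onset detection is robust to artifacts (tremor, corrective
submovements, sensor dropouts) the generator does not produce.

## Numerical conventions collected

* Reachability slack $10^{-9}$ m; cosine clamp before `acos`; IK branch
  `open`, shoulder angle wrapped to $(-\pi, \pi]$.
* Finite differences: interval-centred, length $n-1$, honouring non-uniform
  steps; generator streams use central differences (one-sided at ends) on
  the uniform 1 ms grid.
* Time profile: $g$ at interval midpoints; schedule renormalised so the
  total duration is exact to $10^{-12}$.
* Deviation sign from the single maximising sample, ties toward the earlier
  sample; degenerate chords (coincident endpoints) are errors.
* Arclength resampling of observed shapes by linear interpolation;
  duplicate points dropped before interpolation.
* Safe-range tie-breaks: lower mean KE, then nearer zero; even-run median =
  lower-middle level. Min-KE ties: smallest $|d|$, then negative.
* All randomness flows from caller seeds (`generator_config(seed = )` plus
  fixed offsets for landscape jitter, fold resampling and k-means restarts);
  reruns are bit-identical.

## Known limitations

KE here is a sampled proxy, not work or metabolic cost; torque, jerk and
feedback costs are out of scope. The parabola family cannot represent
S-shaped or via-point paths. The generator produces only successful trials —
no aborts, corrections or reward effects. Landscape KE scale depends on the
501-point convention; only within-convention comparisons are meaningful.
The flattest-level fallback for plateau-free landscapes is a pipeline
convenience with no behavioural claim attached.
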