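# kelscape

Kinetic-energy landscapes for planar reaching trajectories.

## The problem

In planar sequential reaching — a hand moving between targets while the arm
is held by a two-link exoskeleton — many different curved paths connect the
same two targets. Which ones does the motor system actually pick, and why?
`kelscape` implements a biomechanical account: for every point-to-point reach
("submovement") it models the kinetic energy (KE) a trajectory of any
curvature would require, and asks whether observed behaviour settles not at
the KE *minimum* or at the straightest path, but inside a **safe KE range** —
the stretch of trajectory curvatures over which KE barely changes.

It is written for motor-control researchers who want to run this analysis on
their own planar kinematic recordings, or to study its statistical behaviour
on fully synthetic sessions with known ground truth.

## The model

The arm is two rigid rods with distal point masses (moments of inertia
`I = m L²`). The exoskeleton maps joint angles `(θs, θe)` to the hand
position by

    Xh − Xs = L2·cos(θe − θs) + L1·cos(θs)
    Yh − Ys = L2·sin(θe − θs) + L1·sin(θs)

and the package solves these inversely to move between hand space and joint
space. The KE of a movement is the sampled sum

    KE = Σt ( ½·Is·ωs² + ½·Ie·ωe² )

over the joint angular velocities `ωs, ωe`. Candidate trajectories are
parabolas through the two targets whose **signed normalised deviation** — the
maximum perpendicular distance from the straight chord divided by chord
length, negative to the left of the movement direction — is controlled
exactly. Each is traversed under an inverted-Gaussian schedule of inter-sample
intervals (501 points, 1 s), which yields the bell-shaped speed profile of
natural reaches. Evaluating KE on a 33-level deviation grid (endpoints
jittered within the 1 cm target-acceptance radius, 100 replicates) gives the
**KE landscape** of a submovement. The **KE-LS prediction** is the median of
the longest stretch of deviations, inside the subject's central-98% effective
deviation range, where the landscape's absolute slope stays below the
standard deviation of in-range KE.

## Worked example

```r
library(kelscape)
geom   <- arm_geometry()        # L1 = 0.13 m, L2 = 0.23 m, 220 g / 90 g
layout <- default_layout("E")   # hexagon: 3.6 cm to top, 4.5 cm to side

set.seed(1)
ls <- build_ke_landscape(target_position(layout, "C"),
                         target_position(layout, "T1"),
                         space = "hand", geom = geom, n_replicates = 100,
                         submovement_id = "C>T1")
ls
#> <KE landscape: submovement C>T1, hand space, 33 levels [-0.5, 0.5], 100 replicates/level>
#>   mean KE range: 0.5502 .. 0.7288 J; argmin at deviation -0.125

rng <- effective_range(-0.4, 0.4)
kels_predict(ls, kels_threshold(ls, rng), rng)
#> <KE-LS prediction (C>T1): safe range [-0.15625, -0.125], median -0.15625 a.u. (threshold 0.03412 J/a.u.)>
minke_predict(ls)
#> [1] -0.125
```

Reading: for the centre-to-top reach the modelled KE is lowest not for the
straight hand path but for one bowed slightly to the left (deviation
−0.125 a.u.), and the flattest stretch of the landscape within the effective
range — the energetically "safe" zone — spans deviations −0.156 to −0.125;
its median, −0.156 a.u., is the KE-LS prediction for where behaviour should
settle. The threshold (0.034 J per unit deviation) is the typical KE
fluctuation over the effective range.

For the full pipeline — synthetic multi-session study, behavioural metrics,
landscapes for all 19 submovements, the three competing predictors
(KE-LS, minimum KE, zero deviation) and their repeated 5-fold RMSE
comparison — see `run_full_analysis()` and the methods vignette in
`vignettes/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from a fresh run of the installed package, the self-contained
model quantities: the deviation level at which the joint-space KE landscape
of every submovement attains its minimum (computed with endpoint jitter
disabled for all 19 submovements of the default task), and the total duration
of the generated 501-point inverted-Gaussian time profile. Results are
written as JSON to the path given by `--out`.
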