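---
title: "Automated wish-list planning on synthetic thorax phantoms: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated wish-list planning: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wishplan)
```

`wishplan` is a desk-scale laboratory for studying automated multi-criteria
IMRT planning of locally advanced lung cancer. It re-creates, on seeded
synthetic phantoms, the full automated planning chain used by
wish-list-driven treatment planning systems: prioritized lexicographic
fluence-map optimization with integrated beam-angle optimization (BAO),
followed by an automated handover of the optimized plan's dose-volume
histograms (DVHs) to a second, template-driven optimizer that produces the
final plan. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical decisions -- including what the synthetic
setting can and cannot say about clinical data.

## The phantom

Patient geometry is emulated by a voxelized 2D axial thorax cross-section:
an elliptical body, two lateral lungs, a heart left of midline, a posterior
midline esophagus, a spinal canal, and a circular planning target volume
(PTV) placed at the ipsilateral lung/mediastinum border with configurable
laterality and size. Organ positions and sizes are jittered per seed
(defaults: 3 mm position SD, 5% size SD) to emulate inter-patient
variation; a fixed `(config, seed)` pair is bit-reproducible. Thin-3D grids
(trailing dimension 1) are accepted unchanged.

Deliberate simplifications:

* **2D, not 3D.** A single axial slice stands in for volumetric planning.
  Trade-offs between target coverage and organ sparing survive this
  reduction; absolute dose-volume numbers do not transfer to 3D anatomy.
* **Lungs exclude the target.** The lungs mask is delineated minus the PTV,
  the standard convention for lung dose reporting; with the tumor inside a
  lung, including target voxels would make every lung dose limit
  unattainable for any plan.
* **No CT intensities, margins chain, or breathing motion.** The PTV is
  emitted directly; the gross/clinical target expansion chain and motion
  management are out of scope.
* The default geometry was chosen once so that the clinical constraint set
  is attainable -- as it is for the clinical cohorts such planning systems
  are tuned on -- with lung, heart and esophagus doses landing near
  clinically typical values (lungs mean ~15 Gy, heart mean single digits).

Auxiliary conformity structures derive from the PTV: *shells* at 3 mm, 1,
3 and 7 cm (all voxels whose center-to-center Euclidean distance to the PTV
lies in `[d, d + voxel diagonal)`; the one-voxel band realizes a
fixed-distance contour on a discrete grid), and an *external ring*
(body voxels within 2 cm of the surface, minus the PTV dilated by 4 cm).
Distance transforms come from `EBImage::distmap`; tests verify them against
a brute-force pairwise-distance oracle. Shell distances below the voxel
resolution cannot be represented: `derive_shells()` errors, while the
`derive_structures()` convenience wrapper skips them with a message, so
coarse study grids simply lack the innermost band.

## The dose engine

Beams are coplanar and parallel (non-divergent); each beam is divided into
beamlets of width 5 mm (default) spanning the PTV projection plus an 8 mm
margin. A beamlet deposits

    dose(v) = exp(-mu * depth(v)) * [ Phi((l + w/2)/sigma) - Phi((l - w/2)/sigma) ]

per unit fluence: exponential attenuation along the ray (radiological depth
`depth(v)` integrates relative electron density -- body 1, lungs 0.25,
solid tumor 1 -- by midpoint-rule ray marching at half-voxel steps) and a
lateral profile equal to a top-hat of the beamlet width convolved with a
Gaussian penumbra (`sigma` = 3 mm). Defaults: `mu` = 0.004/mm, a
high-energy-beam attenuation at which the upstream dose build-over across
the uncapped annulus between conformity shells stays inside the 7% body
hot-spot limit; there is no scatter, divergence, or heterogeneity
correction beyond the lung density. Gantry angles follow the IEC
convention (0 = anterior, increasing toward patient left), which places
the template "anterior-posterior" fields near 0/180.

The candidate arc for BAO runs 140 to 40 degrees (right-sided) or 320 to
220 degrees (left-sided) at 5-degree spacing, inclusive, traversed through
the tumor's side -- 53 candidates per laterality and mirror images of each
other. The traversal direction is not uniquely determined by the endpoints
alone; the ipsilateral reading was adopted because contralateral entrance
is exactly what thoracic beam templates avoid, and the complementary arc
remains selectable (`arc = "contralateral"`).

## The wish-list and LTCP

Planning priorities are encoded in a wish-list: seven hard constraints
(PTV maximum 1.02 D_p and mean 0.997 D_p; spinal canal 47 Gy; brachial
plexus 60 Gy; shell and ring caps) and thirteen prioritized objectives
(target LTCP first, then lung/heart/esophagus mean doses interleaved with
shell maxima). Goal values encode "good enough, move on"; a Sufficient
value marks objectives that are not revisited in round 2.

The logarithmic tumor control probability over the PTV voxel doses,

    LTCP = (1/m) * sum_j exp(-alpha * (d_j - ref)),

with reference `0.95 * D_p` and `alpha` = 0.85/Gy at 60 Gy, 0.8/Gy at 66
and 70 Gy, equals 1 at a uniform reference dose, decreases strictly in
every voxel dose, is convex, and punishes cold spots exponentially -- a
coverage surrogate that the optimizer can push against hard caps.

All seven hard constraints are upper bounds, so zero fluence is feasible
and every stage problem has an interior. Coverage is driven entirely by
the priority-1 LTCP minimization, which raises dose until the PTV mean cap
(0.997 D_p) becomes active; on a solved plan that cap acts as the dose
scale anchor and `verify_hard_constraints()` reports its tightness.
Plans are subsequently normalized so the PTV median equals D_p exactly
(even voxel counts use the midpoint of the central order statistics); the
normalization factor is ~1.00 by construction.

The relaxation factor applied when a goal is missed defaults to 1.03; it
is a configurable quantity with no uniquely correct value, and every stage
logs the bound it inserted.

## Two-round lexicographic optimization

Round 1 minimizes each objective in priority order under the hard
constraints and all previously inserted bounds; afterwards a bound is
inserted -- the Goal if it was met (leaving headroom for lower priorities,
regardless of further improvement possible), otherwise the achieved value
times the relaxation factor. Round 2 re-minimizes, in priority order,
every objective *without* a Sufficient value to the fullest extent; its
bound is replaced by the new optimum while all other bounds stay fixed.
Objectives with a Sufficient value keep their round-1 bound.

Each stage is a convex program: Mean objectives are linear, Max objectives
are linearized with an epigraph variable, and LTCP is minimized in log
space (log-sum-exp of an affine map -- same minimizer, far better
conditioning). Stages are solved by the package's own log-barrier
interior-point method (`src/barrier.cpp`): damped Newton centering with an
analytic fraction-to-boundary step for the linear constraints, barrier
parameter growth by a factor 30 until the certified gap `m/t` falls below
`gap_tol` (1e-8 by default), a dimensionless Newton-decrement criterion
(1e-6; decrements below that are float-cancellation noise at large
barrier weight), and a ridged-direction retry when the Newton system is
too ill-conditioned. Max-type stage values are reported as `max(D x)` of
the returned fluence, not the epigraph variable (which sits above the true
maximum by its barrier slack).

Numerical choices that required care:

* **Inserted-bound slack.** Bounds are inserted with a relative slack of
  1e-6 (`BOUND_EPS`). Round-2 re-inserts an objective's *optimum* as its
  bound; with a much smaller slack the feasible region left for later
  stages is a sliver whose central path cannot be followed in double
  precision (stage errors up to 1e-5 were observed at 1e-9 slack). At
  1e-6 the solver agrees with an independently scripted generic-solver
  implementation of the same procedure to better than 1e-6 relative on
  random instances. Logged bounds are the exact nominal values (goal,
  achieved x relaxation, or round-2 optimum); the slack is internal.
* **Warm starts.** Each stage starts from the previous stage's solution,
  which sits on that stage's active set up to round-off; the solver
  absorbs round-off-level constraint violations into the bounds (at
  machine scale, far below solver tolerance) rather than rejecting the
  start.
* **Infeasibility** is detected by a shifted phase-1 solve and reported
  with the most binding rows and the stage's provenance.

## Integrated beam-angle optimization

Angles are selected greedily: starting from the empty set, each iteration
runs the *full* two-round optimization for every unused candidate appended
to the current set and keeps the candidate whose final objective vector is
best in the wish-list-induced plan order: lexicographic comparison of
goal-clamped values -- everything at or below a Goal counts as equally
satisfied, which is precisely what Goal values exist to encode -- with raw
values breaking full ties (absolute per-component tolerance, default 1e-3
during scoring; remaining ties go to the earliest candidate in arc order).
Comparing raw values instead would rank plans by differences the method
itself deliberately ignores, and makes beam-count monotonicity fail: when
an extra beam lets a mid-priority objective cross its Goal, the inserted
bound tightens from relaxed-achieved to the Goal, and a later priority can
end slightly worse despite the larger feasible set. This is a
design decision: the defining property kept from integrated BAO is that
angles are judged by the same wish-list optimization that shapes the
profiles, not by a surrogate score; the exact search scheme of clinical
implementations is not reproduced. Scoring uses a looser solver tolerance
(gap 1e-5), the final plan a tight one; on test fixtures the loose and
tight objective vectors agree to ~1e-8 relative.

Greedy selection is nested: the (k+1)-beam feasible set contains the
k-beam one (the new beam may carry zero fluence), so plans along one
trajectory are non-worsening in beam count under the goal-clamped order --
which also yields 4/6/8-beam plans from a single optimization run for
beam-count studies.

## Template handover and surrogate re-optimization

The optimized plan's OAR DVHs are sampled every 0.7 Gy from 0 up to and
including the first multiple at or above the structure maximum into *line
objectives*; these join fixed PTV Min/Max points (D_p -/+ 0.5 Gy, priority
130), OAR maximum points (spinal canal 48 Gy, brachial plexus 62 Gy,
priority 100), line priorities (lungs/heart 80, esophagus 60, canal and
plexus 40), and a normal tissue objective (NTO). The NTO's allowed dose at
distance d from the target border is

    D_p * (end + (start - end) * exp(-falloff * max(0, d - 5 mm))),

anchored at 105% of D_p at 5 mm and 60% far away, with the 0.15 fall-off
applied per millimeter -- the exponential form and mm scale are this
package's choice; the parameter values are the template's fixed settings.
Templates serialize to a documented XML schema and DVHs to two-column CSV.

The re-optimization stage stands in for a second, closed-source
template-driven optimizer. It minimizes a priority-weighted quadratic
penalty over nonnegative fluence on the *same* influence matrix (no leaf
sequencing), with dose-type deviations expressed as fractions of D_p so
dose- and volume-space terms share a scale:

* one-sided PTV under/over-dose versus the Min/Max points (with an extra
  weight factor 4, calibrated so coverage survives the handover);
* per line sample, squared excess of a smooth (sigmoid, width 0.2 Gy)
  achieved volume over the line volume, with a light symmetric weight
  (0.3) below the line;
* a distribution-tracking term: squared distance between the structure's
  sorted doses and the line's implied dose quantiles (weight 30). The
  quantiles invert the line as a step function with mid-gap target
  placement, so that voxel counts at every 0.7 Gy sample reproduce the
  line exactly and targets stay away from the sample edges;
* one-sided OAR maximum-point and NTO violations.

A purely one-sided penalty only *bounds* the DVHs from above; the fluence
optimum then drifts below the template curves wherever that helps the
other terms, which defeats the purpose of the handover -- reproducing the
first optimizer's DVHs in the second system. The two tracking terms anchor
the curves from below; they use only information present in the template.
The optimizer is L-BFGS-B with analytic gradients and restarts (the
sorting makes the objective piecewise smooth), and the result is
normalized to the PTV median. The penalty is homogeneous in the
priorities, so scaling all priorities leaves the optimum unchanged.

DVH-reproduction fidelity is measured in volume percentage points at every
line sample, which quantizes at 100/m for an m-voxel structure; fidelity
fixtures therefore use a 80x80 grid at 3 mm with enlarged posterior
structures (esophagus and canal radius 17 mm, about 100 voxels each) so
that the quantization step stays well below the 2-point reproduction
target. On those fixtures the surrogate reproduces the optimizer's OAR
DVHs to within 2 volume percentage points at every sample while keeping
PTV coverage (V_95% >= 98%).

## Plan comparison machinery

* **Wilcoxon signed-rank test**, two-tailed, paired. Zero differences are
  dropped (the classical treatment; the choice is stated because it is not
  the only one), ties get midranks. Up to 12 effective pairs the exact
  null distribution of the positive-rank sum is computed by dynamic
  programming over the observed ranks (equivalent to enumerating all 2^n
  sign assignments; doubled ranks make midranks integral); beyond that a
  normal approximation with tie correction and no continuity correction is
  used. The two-tailed p is `min(1, 2 * min(P(V <= v), P(V >= v)))`.
* **Population DVHs** are pointwise means on a common axis;
  **paired DVH difference bands** are percentile bootstrap over subjects
  (2000 resamples, seeded; the confidence-band construction is a package
  choice).
* **Beam-angle distributions** count beams per 5-degree bin with
  wrap-aware rounding (357.5 rounds to 0).
* **Metric tables** evaluate the standard comparison panel (PTV V_95%;
  lungs mean, V_5Gy, V_20Gy; heart mean, V_5Gy, V_30Gy; esophagus mean,
  V_20Gy, V_60Gy) with median, IQR and Wilcoxon p per metric.

## Study problem sizes

The package's tests and the reproduction script run everything at compact
sizes chosen as the package's own study conditions: random optimizer
instances with 12 beamlets and ~30 voxels; a 40x40 grid at 6 mm (anatomy
scaled 0.9) for the default 6-beam BAO pipeline; 32x32 at 7 mm (anatomy
0.85, 20-degree candidate spacing) for the 10-phantom beam-count study;
and the 80x80 / 3 mm fidelity fixture described above. At these sizes the
full suite and the reproduction script each complete in minutes on one
CPU core.

## What passing tests do and do not show

The synthetic phantoms exercise the *mechanics* of the method -- priority
protection, Goal/Sufficient semantics, integrated angle selection,
handover fidelity, and the direction of beam-count effects (more optimized
beams spare the heart and esophagus on average, fewer worsen them). They
do not emulate real CT heterogeneity, 3D scatter, delivery constraints, or
inter-patient anatomical diversity beyond parameter jitter; absolute
dose-volume values and the magnitudes of population effects are properties
of the phantom family, not predictions for patients.

## Known limitations

* Primal log-barrier stage solves certify optimality through the barrier
  gap; in double precision the practical accuracy floor is ~1e-7 relative
  per stage, and bound cascading can amplify stage differences by an order
  of magnitude across a 20-stage chain.
* The greedy BAO is not guaranteed to find the exhaustive-best beam *set*
  (only the best single-beam addition per iteration); nested monotonicity
  and the no-worse-than-template property are the guaranteed invariants.
* The surrogate optimizer's penalty is this package's design; it emulates
  the *behavior* of template-driven commercial optimizers (DVH
  reproduction), not their proprietary objective semantics.
* 4-beam plans can fail clinical hot-spot audits after handover even when
  the wish-list stage satisfied all hard caps, since the surrogate stage
  has no hard constraints -- mirroring the known behavior of
  template-driven re-optimization.
```
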