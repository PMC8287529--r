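---
title: "Methods: force-dependent kinematics simulation of an ATSA shoulder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-dependent kinematics simulation of an ATSA shoulder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atsasim)
```

## The problem

After anatomic total shoulder arthroplasty (ATSA) the glenohumeral (GH)
joint is a non-conforming metal-on-polyethylene ball-and-socket whose
stability depends on the rotator cuff. Secondary cuff tears are a common
late complication, and the mechanical question is how the loss of
individual cuff muscles redistributes muscle forces and changes the GH
contact force during arm elevation. `atsasim` is a desk-scale,
quasi-static multibody answer to that question: a reduced shoulder model
with deformable implant contact, redundant muscle recruitment, and
force-dependent resolution of the three released GH translations, swept
over a 0–90° abduction motion under an intact cuff and five deficiency
scenarios (Q1 infraspinatus; Q2 supraspinatus; Q3 both; Q4
subscapularis; Q5 supraspinatus + infraspinatus + subscapularis + teres
minor).

The package deliberately does **not** reproduce any full-body
musculoskeletal model: the skeleton is reduced to a fixed scapula and a
lumped 4 kg arm segment, and muscle paths are straight lines through
synthetic anchor points. Absolute force magnitudes are therefore
model-specific; the object of study is the *redistribution* across
scenarios.

## Model structure

All internal quantities are SI (m, kg, N, N·m, s); angles cross the user
boundary in degrees and are converted once. The GH frame sits at the
joint center of the right shoulder: +AP anterior, +SI superior, +ML
lateral, a right-handed triad. Abduction rotates the humerus in the
frontal (SI–ML) plane; the driven angle is interpreted as glenohumeral
elevation with an optional scapulohumeral-rhythm fraction (default 1.0,
i.e. the full driver angle is glenohumeral).

The simulation is quasi-static: the 90 s sweep makes inertial terms
negligible, so each step is an independent equilibrium problem and the
arm contributes a pure gravity load. The arm segment defaults to 4.0 kg
with its center of mass 0.30 m down the humeral axis — explicit,
configurable values chosen as a realistic lumped upper limb, not claimed
faithful to any subject.

### Implant contact

The articulation is a 48 mm spherical humeral head against a concave
polyethylene insert with an 8 mm *diametral* mismatch of curvature
(insert radius 28 mm — the standard convention for this implant family;
the convention lives in one constant in `implant_spec()`). Both surfaces
are triangulated by subdivided-icosahedron sampling, which gives
near-uniform vertex areas and therefore a well-behaved vertex quadrature;
boundary vertices are clamped to the cap rim so the mesh area tracks the
analytic cap area to well under 1% at the tested resolutions. The insert
cup covers a 60° half-angle and the head a 120° half-angle, keeping the
contact patch inside both meshes over the whole sweep.

Contact follows elastic-foundation (bed-of-springs) theory: each insert
vertex *i* carries a penetration depth $d_i$, a volume $V_i = d_i A_i$
($A_i$ = one third of incident triangle areas), and a force
$F_i = P_V V_i$ along the vertex inward normal, with $P_V$ the contact
pressure module. The insert is the slave body because the foundation
lives in the deformable polyethylene; penetration against the generated
spherical head is measured by exact signed distance (nearest-point
projection is the fallback for imported meshes). There is no friction
and no tangential component.

The default $P_V = 2.74\times10^{11}$ N/m³ is the precomputed value for
a conventional polyethylene insert. The elastic-foundation expression

$$P_V = \frac{1-v}{(1+v)(1-2v)}\;\frac{1}{h}\;\frac{2p_o}{\varepsilon_o}
\left[1 + n\left(\frac{p_i}{p_o}\right)^{n-1}\right]$$

with the nonlinear polyethylene constants $\varepsilon_o = 0.0597$,
$p_o = 18.4$ MPa, $n = 3$, is exposed as `pressure_module()` for
sensitivity work. The printed form of this expression is ambiguous about
how the constants assemble; the algebraic form above is the package's
single documented reading, and because the shipped default is the
constant — not an evaluation of the expression — sweep results never
depend on that reading. The Poisson ratio and thickness used to obtain
the published constant are not public, so recomputing it exactly is not
a goal.

### Muscle recruitment

Eight muscles act: the six principal units (two deltoid parts and the
four cuff muscles) plus two antagonists (pectoralis major, latissimus
dorsi) that keep the three-component moment balance solvable when the
whole cuff is deficient. Strength is PCSA × 27 N/cm² for every muscle;
muscles are ideal bounded force actuators (no Hill-type force–length
properties, which this analysis does not exercise).

Only the three moment equations about the GH center enter recruitment;
force balance is delegated to the translations (this mirrors the
force-dependent-kinematics decomposition). The quadratic polynomial
criterion minimizes $\sum_i (f_i/N_i)^2$ subject to $Rf = -M_{ext}$ and
$0 \le f_i \le N_i$, solved as a strictly convex quadratic program
(Goldfarb–Idnani active set via `quadprog`). The criterion order is a
configuration knob for the sensitivity sweep; orders above 2 use an
augmented-Lagrangian bound-constrained refinement warm-started from the
quadratic solution. Infeasibility is a reported state, not an exception,
so sweeps can record failed steps instead of fabricating equilibria.

### Force-dependent kinematics

At each driven angle the three GH translations are found by driving the
net humeral force residual — muscle pulls + gravity + contact + capsule
spring — below tolerance. The capsule and ligaments are lumped into one
linear spring of stiffness $1.74\times10^4$ N/m anchored at the joint
center. The solver is a damped Newton iteration on the 3-vector residual
with a forward finite-difference Jacobian (step $10^{-5}$ m):

* steps are clamped to 1 mm, because outside contact the Jacobian sees
  only the soft spring and would otherwise overshoot into deep
  penetration (the contact force grows quadratically with approach for
  mismatched spheres);
* a backtracking line search accepts only residual decreases; after two
  stagnant iterations a derivative-free Nelder–Mead fallback on the
  residual norm runs, since the mesh quadrature makes the residual only
  piecewise smooth;
* the iteration refines to 1% of the tolerance whenever progress is
  cheap, so the reported equilibrium does not depend on where inside the
  tolerance band the search happened to stop — convergence is still
  judged against the 20 N tolerance itself;
* sweep steps warm-start from the previous converged translation; the
  fixed points are path-independent (verified by a warm/cold comparison
  test).

The 20 N residual tolerance is the stated convergence criterion of the
reference simulations and is the package default. A step that exhausts
its iteration budget is reported `converged = FALSE` with its best
state, and a sweep aborts only when more than half its steps fail.

### Abduction driver

The driven angle is a truncated Fourier series
$Pos(t) = \sum_j A_j\cos(\omega_j t + B_j)$ in degrees. The coefficient
values of the original driver are not public, so the shipped default is
the smallest expansion with smooth start/stop and exact endpoints:
$Pos(t) = 45 - 45\cos(\pi t/90)$ over 90 s, i.e. $A = (45, -45)$,
$\omega = (0, \pi/90)$, $B = (0,0)$. Endpoints (0° and 90° within
$10^{-9}$) and monotonicity are validated for any user-supplied
coefficients at construction. The default grid is 91 uniformly spaced
times — one record per degree *on average*; because the profile is a
cosine ramp the per-step increments range from 0 to ~1.6°.

## What the synthetic model emulates — and what it does not

The synthetic-data layer generates everything a sweep needs: implant
meshes from the implant specification, the muscle attachment fixture,
and closed-form toy models (pure spring, single-muscle, symmetric
two-muscle, zero-gravity centered contact) that anchor the solver tests.

The attachment fixture was *designed*, not measured: coordinates were
chosen so that the signed moment arms are anatomically plausible — the
scapular deltoid is the prime abductor (largest PCSA, elevation moment
arm ≈ 40 mm at 30°), supraspinatus a weak abductor with strong medial
compression, infraspinatus/teres minor external rotators and
subscapularis an internal rotator with opposite axial moment signs, and
the subscapularis line of action carries a meaningful elevation
contribution with only moderate compression (its superior fibers do
abduct). Those constructed properties are exactly what the qualitative
scenario trends rest on: with them, deltoid load grows monotonically
with cuff loss (INTACT < Q4 ≤ Q5), losing supraspinatus + infraspinatus
unloads the joint (Q3 < INTACT), and losing subscapularis overloads it
(Q4 > INTACT) because the elevation share it carried moves to the
deltoid, whose line of action presses the head into the glenoid.

Passing these tests therefore shows that the *mechanism* — recruitment
redistribution feeding back into contact through force-dependent
kinematics — behaves correctly, not that any specific patient or the
original full-body model is reproduced. Real shoulders have curved
muscle paths with wrapping, scapulohumeral rhythm, and subject-specific
geometry; absolute newton values from this package should never be
quoted against in-vivo data, which is why the published force
magnitudes are not assertion targets anywhere in the test suite.

## Numerical choices

* Problem sizes: default insert/head meshes target 2000 triangles each
  (≈ 1100 vertices in the cup); the contact-oracle verification uses
  ≥ 10 000 triangles where the quadrature error falls under 2%; the
  trend suite runs the full 6 × 91-step sweep.
* Recruitment tolerances: moment-balance residual ≤ $10^{-6}$ relative
  for an optimal solution; the brute-force oracle (grid search with
  iterative window refinement after eliminating the equality
  constraints) agrees to $10^{-4}$ relative on random small instances.
* Degenerate inputs: zero-PCSA muscles, missing required muscles,
  non-rigid poses, left-handed frames, non-monotone drivers and
  sub-minimum mesh resolutions are rejected at construction with named
  errors; deficient-only recruitment systems are optimal only for a zero
  moment.
* Tie-breaks: the strictly convex quadratic criterion has a unique
  optimum, so no tie-breaking is needed at order 2.

## Reproducing the sweep

```{r, eval = FALSE}
model <- shoulder_model()
ids <- c("INTACT", "Q1", "Q2", "Q3", "Q4", "Q5")
traces <- setNames(lapply(ids, function(id)
  run_abduction_sweep(model, id)), ids)
summarize_sweeps(traces, query_angles = 78)
```

`scripts/acceptance.R` in the source repository runs exactly this sweep
plus the oracle checks and writes the headline numbers to JSON.

## Known limitations

Straight-line muscle paths (no wrapping), a fixed scapula, a single
lumped arm segment, one implant geometry, no partial-thickness tears,
no friction, and no dislocation/center-of-pressure analysis. The
sensitivity utility (`sensitivity_sweep()`) varies the pressure module,
criterion order and step count on reduced sweeps; scaling-law variations
have no meaning in a model without anthropometric scaling.
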