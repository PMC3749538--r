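---
title: "Modelling scoliosis correction surgery with spinesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scoliosis correction surgery with spinesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spinesim` simulates the posterior surgical correction of a scoliotic
spine — segmental translation onto a contoured rod followed by rod
derotation — as a sequence of quasi-static equilibria of a multibody
model. This vignette describes the model, its assumptions, the
parameters that matter, the numerical choices, and what the package's
synthetic validation does and does not demonstrate.

## The mechanical model

**Frames and units.** The global frame is patient-fixed: +X patient-left,
+Y anterior, +Z cranial; the coronal plane is XZ and the sagittal plane
YZ. All lengths are millimetres, forces Newtons, moduli MPa (N/mm²),
angles degrees at the interface and radians internally.

**Vertebrae.** Seventeen rigid bodies (T1–L5) with body dimensions graded
linearly down the column (heights 16–29 mm, widths 26–50 mm, depths
18–35 mm, overridable via `build_config()`). The surgical read-outs are
angle- and force-valued and only weakly sensitive to the exact
morphometry; a volumetric scale factor is exposed for sensitivity
studies. Boundary conditions follow the clinical set-up of a recumbent
instrumented patient: T1 constrained translationally in the transverse
plane, L5 fixed except coronal rotation. Locked coordinates are
eliminated from the unknowns, never penalized.

**Profile construction.** A patient profile is four angular targets (main
and proximal thoracic Cobb, T1–T12 kyphosis, L1–L5 lordosis) plus the
lateral-bending flexibility of the main curve. Each curve distributes
per-segment wedge rotations over a fixed level range with raised-cosine
weighting (proximal: T1–T6 measured T1–T5; main: T5–L1 measured T6–T12;
kyphosis: T1–T12; lordosis: L1–L5), and one scale per curve is solved by
bisection so that the curve *in its own plane* measures exactly its
target. Two consequences matter:

* Because finite rotations do not commute, the composed 3-D chain
  measures a few degrees short of the in-plane targets in projection —
  exactly the behaviour of radiographic measurements of a combined
  coronal/sagittal deformity. The reference patient (73/42/35/37) builds
  to measured 68.9/41.9/30.5/37.5. A tolerance-gated refinement iterates
  the curve scales only while some measured angle deviates more than the
  5° build tolerance, mirroring a build-to-tolerance protocol rather
  than exact inverse kinematics.
* A compensatory lumbar coronal curve is added automatically so that L5
  is level below the tilted lower end vertebra of the main curve, as in
  clinically balanced scoliosis. Without it, profiles with severe main
  curves leave the lumbar spine hanging obliquely and their projected
  lordosis becomes ill-conditioned.

Cobb angles are measured between the projected endplate lines of the
configured end vertebrae (local x-axis for coronal measures, y-axis for
sagittal), in the patient-fixed reference frame carried by every state,
which makes all measures exactly invariant under rigid motions of the
whole model.

**Discs.** Each motion segment carries a six-degree-of-freedom elastic
coupler with diagonal stiffness from beam formulas on the elliptical
cross-section: axial `E A/h`, shear `G A/h` with `G = E/(2(1+ν))`,
ν = 0.45, bending `E I/h` about both axes, torsion `G J/h`. The
composite modulus is the area-weighted mean of annulus and nucleus
moduli (defaults 8 and 2 MPa, nucleus area fraction 0.4; the assignment
of the two printed moduli to the two phases is selectable via
`swap_moduli`). Both attachment frames are co-located at the disc
mid-height as built, so a pure relative rotation about the disc centre
carries no translational penalty — the coupling of an Euler beam. With
endplate-attached frames (the obvious alternative) a bowed spine stores
the imposed curvature as inter-vertebral shear instead of bending and a
contoured rod cannot impose a sagittal profile; the mid-frame convention
is therefore essential, not cosmetic. Stress recovery per disc is the
lumped convention `σ = |Fz|/A + |Mx| b/Ix + |My| a/Iy`,
`τ = |Fs|/A + |Mt| r/J`, `σ_vM = √(σ² + 3τ²)`, which reduces to `F/A`
under pure axial load.

**Ligaments.** Five anatomical sets per segment — anterior and posterior
longitudinal, interspinous, ligamentum flavum and bilateral capsular —
give 96 tension-only linear springs (23.75, 26.15, 9.8, 22.6,
23.7 N/mm) attached at fixed anatomical offsets in the local vertebral
frames, with rest lengths equal to the as-built distances (zero
prestrain, no toe region, no damage). Slack ligaments transmit exactly
zero force.

**Instrumentation.** Pedicle screws are rigid with their vertebrae, the
head sitting lateral and posterior at the pedicle entry, axis pointing
into the body. The rod is a rigid planar curve contoured by raised-cosine
curvature bumps: its thoracic span sweeps the postoperative kyphosis
target and its short lumbar end the pro-rata arclength share of the
lordosis target (bending the full lumbar lordosis into ~45 mm of rod
would mean a 70 mm bend radius). It is registered onto the screw-head
line by rigid least squares and then rolled about its own chord so the
bow lies in the coronal plane on the side of the deformity — the
classic insertion from which derotation turns the bow into the sagittal
plane. The polyaxial capture cone (60° full angle, boundary inclusive)
is checked at every capture.

**Screw–rod linkages.** The joint chain between each screw head and the
rod is realized as stiff penalty bushings (10⁴ N/mm on locked
translational directions, 10⁵ N·mm/rad on locked rotations) with these
modes: uncaptured; captured at a point; captured with free global-axial
translation (set screw loose); and, after final tightening, both the
point constraint and a rotational clamp of the screw–rod relative
orientation. Capture targets always use the rod point nearest the head
at the moment of capture, and every mode switch re-bases the constraint
to the current relative position — a set screw clamps the rod where it
stands and never snaps back to an earlier station. Accepted states keep
penalty constraint violations below ~0.05 mm.

## The surgical plan

The default plan runs: (1) capture of the cranial (T3, sliding and
rotating axially) and caudal (L1, rotation only) screws, ramped over 5
equilibrium increments; (2) a recorded no-op; (3a–3g) reduction of T4,
T5, T6, T9, T10, T11, T12 in cranial-to-caudal order, each over 10 gap
increments; (9) derotation: the rod is fixed, captured set screws are
loosened axially, and the rod is rotated in 1° increments about its
chord through the end anchor points until the measured (projected,
unsigned) T1–T12 kyphosis is within 1° of the postoperative target; (10)
final tightening of all set screws, translationally and rotationally,
with the rod still held. The step labels 3a–3g map the seven individual
reductions onto the staged protocol whose printed numbering is
internally ambiguous. During phases where the partially captured rod
retains free rigid modes, a soft 6-DOF holder ("surgeon's grip"),
re-centred at every solve, regularizes them; an outer loop re-solves
until the holder carries no force, so recorded equilibria are unbiased.

Two behaviours deserve note. First, most coronal correction arrives
with the first caudal-group reduction and with the derotation — the
curve entering derotation measures ~42° from ~69° as built, and the
derotation is the single largest corrective step. Second, the apical
region rotates axially with the rod during derotation, so part of the
apparent coronal correction is the deformity turning into the sagittal
projection — a documented property of the real maneuver, visible here
because all measures are radiographic projections.

## Solver

The total potential (disc strain energy, ligament tension energy,
penalty and holder terms, minus external work) is minimized over the
free coordinates: per body an incremental translation and rotation
vector composed on the left, rotational coordinates scaled by 30 mm so
one gradient tolerance (10⁻³, infinity norm) applies to all. Gradients
are analytic (left-Jacobian transport of accumulated torques; compiled
kernel, with a pure-R reference retained and cross-checked to machine
precision in the tests). The search is a damped Newton method on a
finite-difference Hessian of the analytic gradient, cached across the
quasi-static ramp and refreshed when the line search or contraction
degrades; indefiniteness is handled by Levenberg damping. Convergence of
the full ten-step simulation takes a few seconds of CPU.

Degenerate and edge inputs: a zero profile builds an exactly straight
chain; an empty plan returns only the initial state; infeasible profile
targets and unreachable bending targets raise errors carrying the
residuals. The unloaded as-built state has exactly zero energy and is
returned unchanged by the solver.

## Flexibility calibration

The lateral-bending test applies a pure coronal moment at T1 in the
curve-reducing direction — 6 N·m by default, within the 4–7.5 N·m range
of published spinal flexibility protocols — ramped adaptively, on the
uninstrumented model. `calibrate_flexibility()` bisects the annulus
modulus within [0.5, 20] MPa until the bent main Cobb matches the
patient's bending radiograph within 1°, with the interval additionally
tightened to 2% for parameter identifiability; synthetic-recovery tests
confirm a known modulus is recovered within 2%. For the reference
patient (bending to 40°) the calibrated annulus modulus is ≈7.3 MPa,
between the two printed disc moduli; the default simulation uses the
calibrated discs. Moments much below ~5 N·m at soft moduli push the
passive column beyond the quasi-static regime and the load case reports
non-convergence; the bisection treats such failures as "bends past any
target", which keeps its bracket valid because they only occur below
the solution.

## What the synthetic validation shows — and what it does not

The test suite validates the machinery against closed forms (spring
formulas, rotation-composition Cobb oracles, series-spring compression,
a dense linear solve about a pre-loaded state), against property suites
(rigid-motion invariance, mirror symmetry, tension-only behaviour,
energy-gradient consistency, bit-determinism), and against the published
read-outs of one real instrumented patient (angle trajectory, disc
stress envelopes, pullout ceilings). The synthetic patient generator
draws double and single thoracic profiles from physiologic ranges (main
curve 45–85°, kyphosis 20–50°, lordosis 30–60°, flexibility 30–60%) and
every generated profile builds within the 5° tolerance; this
demonstrates robustness of the construction, not anatomical fidelity of
any individual synthetic spine. Real spines differ in ways the model
does not represent: vertebral rotation is not prescribed from imaging,
discs are neither poroelastic nor nonlinear, facet contact beyond the
capsular springs is absent, the rod is rigid (its elasticity is the
main reason the simulated final coronal angle, ~33°, overshoots the
reported patient-study value of 25°: a 5.5 mm rod flexes several
millimetres under construct-level loads, permitting more coronal
correction at the same sagittal endpoint), there is no muscle tone or
gravity, and the stabilizing second rod on the convex side is not
modelled. Conclusions about specific implants or patients require
patient-specific geometry and validated tissue properties.

## Reproducibility

Everything downstream of a case configuration and seed is deterministic:
identical runs reproduce trajectories bit-for-bit on one platform. The
acceptance script (`scripts/acceptance.R`) re-runs the full pipeline —
build, calibration, ten-step surgery — in well under a minute and writes
the headline quantities as JSON. Problem sizes used throughout the
package's own validation: the full 17-vertebra chain, nine screws, ten
surgical steps with 5–10 equilibrium increments each, 1° derotation
increments, and 100-profile sweeps of the synthetic generator.
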