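---
title: "A quasistatic multibody model of scoliosis instrumentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasistatic multibody model of scoliosis instrumentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scolisim asks a biomechanical question that clinical series cannot answer
directly: for a given adolescent idiopathic scoliosis (AIS) patient, does
removing roughly a quarter of the pedicle screws from a posterior fusion
construct compromise the correction achieved by a simultaneous two-rod
segmental-translation maneuver, and what does it do to the forces at the
bone-screw interfaces? The package builds a patient-specific quasistatic
multibody model of the spine from a row of clinical indices, calibrates
it to the patient's measured flexibility, simulates the instrumentation
under five screw-density patterns, and reports corrected radiographic
indices and per-screw forces. This vignette records the model, its
assumptions, and the numerical and design choices a maintainer needs to
know.

## Synthetic spine geometry

Real study geometry comes from calibrated biplanar radiographs; no such
reconstructions ship with the package. The `generate_spine()` generator
is therefore a first-class, tested module that stands in for the
reconstruction step: it produces per-vertebra rigid frames (T1..L5 plus
a pelvis frame) and the landmark set a reconstruction would deliver
(endplate centers and corners, pedicle entry points, transverse and
spinous process tips), placed so that *measuring* the geometry returns
the requested clinical indices.

The centerline is a composite of parametric bumps: one coronal
quarter-sine arc per curve region (proximal thoracic, main thoracic,
thoracolumbar/lumbar — each peaking at its apex and steepest at the end
vertebrae, which is what makes the end-vertebra endplate tilts carry the
Cobb angle), a sagittal kyphosis arc over the thoracic spine and a
lordosis arc over the lumbar spine, and an axial-rotation bump peaking
at each curve apex. Bump amplitudes are solved by a damped Newton
fixed-point loop against the package's own `index_report()` measurement,
so the round trip (generate, then measure) closes within 1 degree for
coronal and sagittal angles and 2 degrees for apical rotation
regardless of landmark jitter. Jitter (default SD 0.8 mm, a stand-in
for reconstruction error) is drawn mirror-symmetrically within each
vertebra so the local left/right landmark symmetry invariant holds
exactly, which also makes generation equivariant under coronal
mirroring: flipping every curve's convexity produces the mirror-image
geometry to machine precision.

Convexity is configuration, defaulted to a right-convex main thoracic
curve with left-convex proximal thoracic and thoracolumbar/lumbar
curves, the pattern implied by the cohort's Lenke types. Two quantities
a case table does not print are defaulted and recorded: the PT superior
end vertebra (T2) and the TL/L inferior end vertebra (L4, with the TL/L
apex at the span midpoint). Vertebral body dimensions come from a
monotone anthropometric table scaled linearly by stature.

What the generator does *not* emulate: vertebral wedging, pedicle
morphology variation, endplate irregularity, and any correlation
structure between indices beyond what the case table specifies. Tests
passing on synthetic cohorts therefore validate the pipeline's
mechanics and bookkeeping on realistic deformity magnitudes, not
reconstruction fidelity on any individual patient.

## The multibody model

Vertebrae and pelvis are rigid bodies. Each functional spinal unit (FSU)
carries nine flexible elements, assembled force-free in the preoperative
configuration (the model deforms *from* the reconstructed state; no
prestress data exist):

* six tension-only cables for the ligaments: anterior and posterior
  longitudinal ligaments, ligamentum flavum, left and right
  intertransverse ligaments, and the interspinous+supraspinous complex.
  Tension stiffness at the T6-T7 reference is 23.6, 24.9, 32.6, 12.9
  (each side) and 32.1 N/mm respectively; compression stiffness is
  exactly zero. Other levels scale by the vertebral-body depth ratio, a
  cross-section proxy; a per-level table can override this.
  The ISL+SSL cable attaches at 35% of the spinous offset; this
  moment-arm choice is what makes the release partition (below)
  feasible in flexion, and is a documented assumption.
* two facet-capsule springs and one primary intervertebral 6-D spring,
  all diagonal 6x6 stiffnesses expressed in the FSU mid-frame at the
  disc center. Placing the attachment frames at the disc center
  decouples the probe modes, which turns both calibration stages into
  nearly-diagonal fixed-point problems.

The primary spring's diagonal is a calibration output: `calibrate_fsu()`
adjusts it until constrained small-displacement probes of the assembled
reference FSU (T6-T7 thoracic, L2-L3 lumbar) reproduce a target table of
mode stiffnesses. The shipped targets (e.g. thoracic: 2.0 N.m/deg in
flexion, lateral bending and axial rotation, 1200 N/mm axial, 250 N/mm
shear; lumbar values 20-80% higher) are a documented assumption
representative of cadaveric FSU data — the package treats them as
configuration, not as ground truth. The rib cage is not modeled as
bodies; instead the thoracic primary-spring rotational diagonal is
augmented so whole-FSU stiffness rises by exactly 40% / 35% / 31% in
flexion-extension / lateral bending / axial rotation. The weighting is
applied to rotational terms only.

Pedicle-screw placement resects the facet capsules and the interspinous
complex; `apply_surgical_release()` removes exactly those three
elements per released FSU. `calibrate_release_partition()` distributes
stiffness between removed and remaining elements so the released FSU is
softer by 17% in axial rotation, 15% in flexion, 3.8% in coronal
bending and 14% in axial compression, each within 0.05 percentage
points, while the intact totals are preserved (the primary spring is
re-calibrated after every facet update).

## Patient-level calibration

Side-bending radiographs measure flexibility. The calibration stage
scales regional stiffness so simulated maximal voluntary bending
reproduces all six bending Cobb angles (three regions, both
directions). The load protocol is a fixed convention shared across
cases — a 5 N.m coronal moment at T1 plus 0.3 N.m on every other
vertebra, pelvis fixed — so that stiffness, not load, absorbs
inter-case variability.

Clinical bending tables are strongly left/right asymmetric (a structural
curve moves much further when bent toward correction than toward
aggravation), and a model whose elements are scaled symmetrically
cannot reproduce that: best-fit errors exceeded 10 degrees on the
bundled cohort. The calibration therefore fits six parameters — one
overall scale factor and one coronal-bending direction-asymmetry ratio
per region — realized as a bilinear (smoothly switched over ~0.1
degree) coronal stiffness on the primary springs. The fit itself
exploits problem structure instead of a generic optimizer: each target
is dominated by one region-direction stiffness, and in the quasi-linear
regime the simulated Cobb change is inversely proportional to it, so a
damped Gauss-Seidel sweep (multiply each direction stiffness by the
achieved/target change ratio, re-simulate) converges in five to eight
sweeps, deterministically, with all six targets typically within 0.5
degree. When a target demands a response the parametrization cannot
produce (for example a bending film in which the curve *decreases* in
both directions), the sweep drives that direction to its stiff bound
and returns the best achievable errors, flagged in the result.

## Instrumentation and the segmental-translation maneuver

The five screw patterns share bilateral screws at the upper and lower
instrumented vertebrae. Alternate patterns drop every other interior
level starting one level caudal to UIV, on the convex (pattern 2) or
concave (pattern 3) side; for even-length constructs of eight or more
levels strict alternation strands two adjacent bilateral levels above
LIV, and the level adjacent to LIV is then also dropped — this keeps
every construct's reduction inside the 21-25% envelope of the study's
constructs (mean 23%). Periapical patterns (4 convex, 5 concave) drop
the same number of screws at consecutive levels centered on the apex.
All dropout levels are configurable per case.

Rods are chains of rigid nodes (one per instrumented level) linked by
6-D beam springs with slender-beam constants for a 5.5 mm cobalt-chrome
section (E = 230 GPa); a stiffness multiplier emulates rigid rods. The
sagittal shape sweeps the thoracic contour angle (25 degrees convex,
35 concave) plus a lumbar lordotic sweep; in the coronal plane the rod
is the straight line between its end seating points, which is the
geometric driver of coronal correction. Rod bodies are stabilized by
very weak grounds (0.02 N/mm, 200 N.mm/rad per node) that remove
rigid-body singularities before the screws engage; their forces are
negligible against bone-screw forces.

The maneuver couples each screw to its rod through two elements:

* a tension-only *pull-in* penalizing the perpendicular distance from
  the pedicle entry point to the rod axis, ramped linearly from the
  initial distance down to the 8 mm head standoff over the schedule
  (default 20 increments, penalty 4 kN/mm). Distance-to-line rather
  than distance-to-point leaves the along-rod position free — the rod
  slides through unlocked saddles — and the residual standoff
  represents the polyaxial angulation slack;
* a *seating* rotational spring between vertebra and rod-node frames
  whose rest orientation ramps from the initial relative pose to
  alignment. Its three stiffnesses encode how the progressively seated
  head transmits orientation: strongly in coronal tilt (5e4 N.mm/rad,
  the rod lies in the saddle groove), moderately in sagittal pitch
  (3e4 — this carries much of the rod-contour kyphosis restoration),
  weakly in axial twist (4e3, friction only until locking). These
  constants were fixed once against the reference pattern of the first
  bundled case so that its percent correction lands in the clinically
  expected range for segmental translation (~65-75%), and are shared
  unchanged by all cases and patterns.

At the end of the schedule the construct locks: pull-in and seating
elements are replaced by stiff 6-D junctions assembled force-free at
the reached pose (a polyaxial head locks wherever it is), and one final
equilibrium — the springback onto the locked construct — is solved. The
bone-screw force is the translational reaction transmitted at each
anchor in that final locked state; cohort statistics pool all screws of
all cases per pattern.

## The solver

Everything above reduces to quasistatic equilibrium of rigid bodies
under nonlinear springs. The solver is damped Newton on 6 generalized
coordinates per body (translations plus incremental rotation vectors,
re-linearized every iteration, so no gimbal issues below 90 degrees).
Element residuals are exact; element tangents are analytic leading-order
approximations, kept positive semidefinite on purpose — with
Levenberg-Marquardt diagonal damping this guarantees a descent
direction whenever the true Jacobian is locally definite. Tension-only
laws are C1-smoothed over 0.02 mm to stop slack/taut chatter.
Increments that still fail are bisected, and persistent failures
(physical snap-throughs of the screw-seating geometry) are traversed by
viscous relaxation: temporary grounds to the increment-start state,
ramped off in five stages. Convergence means max force residual 0.5 N
and torque residual 50 N.mm on all free DOFs, verified by direct
re-evaluation. The residual and tangent kernels are compiled (Rcpp);
the R reference implementations remain in the package and the test
suite cross-checks both paths on randomized states.

Boundary conditions: pelvis fully fixed everywhere; during
instrumentation T1 additionally loses its transverse-plane
translations. Gravity and intraoperative positioning loads are
excluded (prone positioning assumed).

## Measurement conventions

Coronal Cobb is measured between the coronal-plane projections of
endplate lines through the corner landmarks, matching radiographic
practice; kyphosis T2-T12 and lordosis L1-S1 (the pelvis frame serves
as the S1 proxy), both common conventions, both overridable; apical
rotation is the transverse-plane angle of the vertebra's anterior axis
against the sagittal plane. All indices are invariant under global
rigid motion of the spine.

## Problem sizes and determinism

The bundled ten-case cohort with all five patterns — the package's
standard experiment — solves 10 calibrations and 50 instrumentation
simulations in roughly ten minutes on one core; single cases run in
under a minute. Scaled-down versions of the statistical experiments
(three randomized parameter-recovery repeats rather than twenty, a
single-geometry recovery suite) are used in the test suite; the
experiment functions themselves take the full sizes as arguments. All
randomness flows from one root seed expanded per case from the case
*content*, so duplicated rows generate identical geometry and re-runs
are bitwise reproducible.

## Known limitations

The model inherits every simplification it states: rigid vertebrae, a
lumped 9-element FSU, no muscles, no gravity, no facet contact, no rib
cage bodies, quasistatic solving only. Absolute bone-screw forces
depend on the synthetic geometry and on the FSU target table, so only
their orderings and spreads are meaningful; corrected-index
*differences* between patterns are far more robust than their absolute
values. The seating stiffness constants are effective parameters of the
head-rod interface, not measured implant properties. Cases whose
bending films move outside the model's reachable set calibrate to a
flagged best fit rather than an exact one.
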