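---
title: "Methods: inverse musculoskeletal simulation of a sprawling hindlimb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse musculoskeletal simulation of a sprawling hindlimb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprawlsim)
```

# The problem

Crocodylians walk with limb postures ranging from sprawling (femur abducted,
held near horizontal) to semi-erect "high walks". How muscle recruitment and
femoral loading change with body size and posture — and what they imply for
the largest extinct relatives — can be estimated without invasive recordings
by inverse simulation: measured stance-phase kinematics and ground reaction
forces (GRFs) are pushed through a musculoskeletal model to recover joint
moments, muscle forces, and bone stresses.

`sprawlsim` implements that pipeline end to end:

1. **Trial preprocessing** — zero-phase low-pass filtering of joint angles
   (4th-order Butterworth, 5 Hz default, forward–backward with odd-reflection
   padding and mean removal), and a centre-of-pressure (CoP) model: the CoP
   sits below the metatarsophalangeal (MTP-III) marker for the first half of
   stance and shifts linearly to the toe tip by the end of stance. A
   sensitivity variant (`ankleward`) starts it below the ankle–MTP midpoint.
2. **Inverse dynamics** — recursive Newton–Euler over the chain
   foot → shank → thigh → body, with gravitational and inertial terms
   (central-difference derivatives on the filtered coordinates; a
   `quasistatic` flag zeroes accelerations). Generalized joint moments are
   projections of the transmitted joint moment onto each coordinate's
   instantaneous axis, and are normalized by mass^(4/3) (N·m·kg^-4/3) for
   cross-size comparison.
3. **Static optimization** — at each timestep, minimize the sum of squared
   muscle activations plus squared normalized reserve/residual values subject
   to exact joint-moment balance, with activations bounded in
   [`activation_min`, 1].
4. **Joint reaction analysis and beam stresses** — Newton–Euler balance with
   muscle point forces applied along path lines of action; internal loads at
   the femoral midshaft; bending, axial and torsional stresses from
   cross-sectional geometry; safety factors against yield (78.6 MPa) and
   ultimate (108 MPa) bone stress.
5. **Allometric scaling** — models and trials scaled across body sizes
   (lengths with per-segment factors, F_max as a power `b` of the mass ratio,
   GRF proportional to mass, stance time as mass^(1/6)), up to a
   3704.5 kg giant-alligatoroid preset.

# Model structure and conventions

The skeletal model is a chain ground → body → thigh → shank → foot. The
ground frame is right-handed with x cranial, y left, z up; the neutral pose
(all coordinates zero) has the right hindlimb splayed laterally, with every
segment frame aligned to the ground frame and bones running along local −y.
Joint rotations are intrinsic z–y–x in each joint's axis triad (right-hand
rule); angles are stored in degrees in files and converted to radians
internally. The hip has three rotational degrees of freedom — extension–
flexion about the vertical triad z axis (a horizontal femoral sweep in the
splayed pose), abduction–adduction about the cranial y axis (positive =
adduction, i.e. towards erect), and long-axis rotation about the femoral x
axis — the knee and ankle one extension–flexion rotation each. The
ground–body joint carries three translations plus pitch and yaw; roll is
structurally locked (no coordinate), because single-sided marker sets cannot
constrain it.

Muscles are Hill-type musculotendon actuators under the rigid-tendon
convention. Maximal isometric force comes from belly mass:
F_max = m_musc·σ/(ρ·l0) with σ = 300 kPa and ρ = 1060 kg·m⁻³; pennation is
stored as metadata but deliberately excluded from the force computation. The
default dimensionless curves are a Gaussian active force–length curve (width
0.45, maximum exactly 1 at normalized length 1), a Hill hyperbola on the
concentric side (zero at the maximum shortening velocity, curvature 0.25)
with a saturating eccentric branch (plateau 1.4), and a passive curve that is
zero at or below the optimal length and quadratic above (gain 2). The passive
term is toggleable (`hill_config(passive = FALSE)`) because whether passive
force entered the original optimization is not stated; it is on by default.
Fibre velocities are normalized by a maximum shortening velocity of 10 fibre
lengths per second.

Moment arms use the tendon-excursion relation r = −∂L/∂θ (central finite
difference, step 1e-4 rad), which makes muscle moments exactly consistent
with the generalized moments of the inverse dynamics by virtual work. Tendon
slack lengths are tuned by bisection so each fibre operates at a target
normalized length (default 1.0) at a reference pose; the reference defaults
to the mid-stance mean pose, a documented choice since the original tuning
protocol is not published in detail. A single cylindrical wrap primitive per
actuator is supported for path lengths (planar obstacle-set construction with
axial stretching); joint reaction analysis requires via-point paths, since
wrap contact forces are not modelled.

# Static optimization

With reserve torques eliminated analytically, each timestep is a strictly
convex box-constrained quadratic program in the activations,

min Σᵢ aᵢ² + Σⱼ ((Mⱼ − pⱼ − Σᵢ rᵢⱼ Fᵢ aᵢ)/τ_opt,ⱼ)²,  aᵢ ∈ [a_min, 1],

where Fᵢ is the activation gain F_max·f_L·f_V, pⱼ the passive-moment
contribution and τ_opt,ⱼ the reserve's optimal torque. It is solved exactly
by a primal active-set iteration on the bounds, with the free-variable solve
in stacked least-squares form (numerically robust for the large reserve
weights), warm-started from the previous timestep (the first step from the
default activation 0.05). Because the reserves close the balance by
construction, the moment residual is zero to machine precision at every
accepted step; a step is flagged "saturated" when any muscle hits its upper
bound. Reserve optimal torques follow m^(4/3)·g/2000 for hip
extension–flexion and abduction–adduction and for knee and ankle
extension–flexion, and m^(4/3)·g/4000 for femoral long-axis rotation, so
reserves are expensive and engage only when muscle capacity is insufficient.
Residual actuators (body forces, ground–body pitch/yaw torques) take their
coordinates' requirements entirely — no muscle can act on those coordinates,
so they do not interact with the muscle solution. The minimum activation
bound (default 0.01) implies a small positive objective floor.

The reserve-to-external-moment ratio is evaluated at the instant of the
per-coordinate peak external moment; it is the capacity diagnostic used for
the size and F_max-exponent analyses.

# Midshaft loads and bone stress

The femoral centroid line is discretized at 101 stations between the hip and
knee centres (a straight line for the idealized models generated here); the
midshaft frame sits at its midpoint with x towards the adjacent distal
station, y = x × (knee dorsoventral axis), and z completing the right-handed
triad. Midshaft loads are computed from the free body distal to the section
plane: GRF at the CoP, gravity and inertia of the foot, shank and distal
half-thigh, plus the tension of every muscle path segment that pierces the
plane, applied at its crossing point and pulling the distal free body towards
the proximal side. Attachment forces of muscles entirely inside the free body
are internal and cancel; this formulation is algebraically equivalent to
propagating the knee reaction and adding the loads on the distal femoral
segment, and cannot double-count. Loads are reported as the action of the
distal part on the proximal face, so axial tension is positive.

Stresses follow straight-beam theory on the section properties about the
centroid (Green's-theorem polygon integrals, or per-pixel sums for mask
input; polar moment J = I_y + I_z; extreme-fibre distances are the means of
the two opposite maxima per axis):
σ_bend = √((M_y·y/I_y)² + (M_z·z/I_z)²), σ_ax = F_x/A,
σ_tens = σ_bend + σ_ax, σ_comp = −σ_bend + σ_ax,
σ_tor = M_x·(y+z)/(2J), and the neutral-axis angle φ_na = atan(M_z/M_y)
(zero along the mediolateral axis, positive counterclockwise in distal view).
These formulas assume material distributed symmetrically about the section
axes; `asymmetric_bending_stress()` provides the product-of-inertia
generalization σ = [(M_y·I_z + M_z·I_yz)·z − (M_z·I_y + M_y·I_yz)·y]/(I_y·I_z
− I_yz²), which follows the true moment-vector convention (it is invariant
under in-plane frame rotations, verified in the tests) and reduces to the
per-axis form when I_yz = 0. Section moduli of unscanned individuals can be
predicted by log–log regression on femur length.

# The synthetic-data generator

No motion-capture or scan data ship with the package; a seeded generator
produces models, trials and cross-sections with the statistical structure the
analysis expects, so every stage runs from scratch.

**Reference individual.** A 5.64 kg juvenile (total length ≈ 1.28 m): thigh
75 mm, shank 65 mm, foot 75 mm, body segment 300 mm carrying 92.5% of the
mass. Twelve musculotendon actuators cover the functional groups: caudal hip
extensor/retractor, two ventral adductors, a dorsal abductor, a cranial
protractor, internal and external long-axis rotators (mirror-image paths with
circumferential insertions), knee extensor and flexor, two ankle
plantarflexors routed over a calcaneal-tuber (heel) point — the crocodylian
Achilles lever — and an ankle dorsiflexor. The knee extensor rides over a
supracondylar via point directly above the joint so its moment arm survives
deep flexion (a straight dorsal line would cut the corner and change sides at
the strongly flexed stance angles). Belly masses were set so the reference
individual solves its own trials like a healthy juvenile: reserve ratios stay
at or below ~5% on every coordinate, with most muscles at moderate
activations and the principal hip stabilizers working near capacity around
midstance. All other
sizes are isometric scalings of this description with F_max ∝ mass^b
(b = 0.67 by default, the isometric expectation for cross-sectional area).

**Trials.** Stance-only, sinusoid-plus-offset angle trajectories. Mean hip
adduction is 30° minus the `abduction_offset` knob; mean knee flexion is 80°
plus the `knee_offset` knob. By default the knobs covary — 1.5° of extra knee
flexion per degree of abduction — emulating the observed pattern that more
sprawled postures are also more crouched; passing `knee_offset` explicitly
decouples them. The vertical GRF is a single-peak half-sine whose impulse
equals body weight × stance duration (single-limb support idealization;
peak ≈ 1.57 body weights), with fore–aft (braking→propulsive, ±0.15 BW) and
medial (0.08 BW) components. Stance duration is 0.45 s at the reference size
and scales as mass^(1/6); forward speed scales to keep dynamic similarity.
The foot long axis sweeps 60° cranially from the limb axis so the CoP path
has a cranial offset from the limb plane and loads the femur in torsion.
Markers are generated by forward kinematics; optional Gaussian noise (marker,
GRF) is reproducible under the trial seed. Cross-sections are elliptical
annuli (outer dorsoventral semi-axis 6% of femur length, mediolateral
eccentricity 1.15, cortical thickness fraction 0.35) with an optional seeded
radial perturbation.

**What the generator does not emulate.** Real kinematic waveforms, speed
effects, double support and limb-share of body weight, wrap-path muscle
geometry, non-annular cortical geometry, and within-individual stride
variability. Passing tests on these data demonstrate the mechanics and the
direction of size/posture effects, not the experimental stress magnitudes —
synthetic peak stresses at a given mass exceed the measured ones mainly
because the generator assigns the whole body weight impulse to one limb.

# Design choices and numerical notes

* Derivatives by central differences on filtered signals, one-sided at the
  ends; the two-link-pendulum oracle bounds the resulting inverse-dynamics
  error below 1% at 1 kHz sampling.
* Terminal missing centra in a vertebral series take the nearest observed
  value; interior gaps take the flanking mean (only the interior rule is
  prescribed by the source procedure); two consecutive interior gaps are an
  error.
* The giant preset (`"deinosuchus-TMM43632-1"`) carries the published outputs
  total length 8.68 m and mass 3704.5 kg; the underlying interspecific
  regressions are not published in a reusable form, so user-supplied
  power-law coefficients are required outside the preset.
* Tie-break and convention choices documented in code: half-open midstance
  window [0.25, 0.75) of stance; activation onset/offset by linear
  interpolation of the 0.05 threshold crossing with stance remapped to
  [0, duty factor] of the stride (0.7 for comparison against
  electromyographic timing data); posture regressions are ordinary least
  squares — no mixed-effects structure, which overfits three-individual
  designs — with activation responses below mean midstance 0.02 excluded,
  and significance tiers at P < 0.05 (significant) and 0.05 ≤ P < 0.1
  (marginal).
* For the F_max-exponent sweep of the giant, the reserve-ratio decrease is
  assessed on the demand-bearing coordinates (hip adduction, knee, ankle).
  Hip extension–flexion carries a near-zero external moment in the synthetic
  trials, so its ratio divides by a small number and is dominated by
  saturation side-effects — the same reason the femoral-rotation reserve is
  conventionally excluded from such comparisons.
* Problem sizes in the tests and the acceptance script: 46-sample stance
  trials, 12 muscles, cohorts of 2–3 individuals. These are the package's
  default study conditions; all pipeline quantities are deterministic given
  the seeds.

# Worked example

```{r example, eval = FALSE}
model <- generate_model(mass = 5.64, seed = 1)
trial <- generate_trial(model, seed = 1)
run <- run_individual(model, trial)
run$peak / 1e6                      # peak stresses, MPa
run$reserve_ratios                  # reserve / external moment at the peaks
safety_factor(run$peak[["sigma_tens"]],
              material_properties()$yield_stress)
```

Scaling to the giant and sweeping the F_max exponent:

```{r giant, eval = FALSE}
fmax_exponent_sweep(exponents = c(0.67, 0.7, 0.75, 0.8), seed = 1)
```

# Limitations

Stance is the only simulated phase; swing enters only through the
duty-factor remap of activation timing. Tendon compliance, activation
dynamics and antagonist co-contraction are outside the static-optimization
formulation. The midshaft model assumes straight-beam theory on a single
section; whole-bone curvature and shear deformation are ignored. The
synthetic generator's magnitudes are indicative, not experimental.
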