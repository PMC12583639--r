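---
title: "Models, numerics and limitations of the symphysim pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and limitations of the symphysim pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(symphysim)
```

`symphysim` reproduces, at desk scale, a musculoskeletal finite-element
analysis of the pelvic ring: density-dependent elastoplastic bone, a
Mooney–Rivlin interpubic disc, Hill-type muscle forces distributed by
static optimization, and a small tetrahedral FE solver with tie
constraints, distributed couplings and mixed fixed/spring supports. This
vignette records the models, every numerical choice that affects results,
and what the synthetic world does and does not establish.

## 1. Bone constitutive model

Bone is treated as inhomogeneous, isotropic and elastoplastic with strain
softening. The chain per element is

1. calibration: apparent density ρ = 1.54·ρ_CT + 0.0784 (g/cm³), with ρ_CT
   the calibration-scale CT density;
2. classification: ρ ≥ 0.945 g/cm³ is compact (cortical), below is
   cancellous — the same threshold the yield law branches on, so one
   consistent cut drives both;
3. elasticity: E = 2065·ρ^3.09 MPa (compact) or 1904·ρ^1.64 MPa
   (cancellous), ν = 0.3 for both tissues;
4. yield: σ_y = 57.75·ρ^1.73 MPa (ρ ≥ 0.945) or 76.5·ρ^6.7 MPa (ρ < 0.945).
   The two branches intersect within 0.001 MPa of each other near the
   threshold (≈ 52.37 MPa), so the switch is effectively continuous;
5. softening: σ_min = 8.5·ρ^3.68 MPa, E_p = −244·ρ^2.2 MPa,
   ε_ab = 0.258·ρ − 0.07.

The uniaxial curve built by `bone_curve()` rises linearly to
(σ_y/E, σ_y), holds a perfectly plastic plateau to ε_ab, softens linearly
with slope E_p to σ_min, and stays at σ_min beyond. Three decisions shape
it:

- **ε_bc.** The printed end-of-softening expression
  |(σ_y − σ_min)/E_p + ε_ab| has a negative interior term, so it evaluates
  *below* ε_ab for ordinary densities (0.0138 vs 0.188 at ρ = 1) — almost
  certainly a sign erratum in the source formula. `softening_params()`
  reports it verbatim; the curve terminus instead uses
  ε_ab + (σ_y − σ_min)/|E_p|, which produces the intended shape.
- **Plateau.** No hardening law between yield and an "ultimate strength" is
  computable from the available information, so the plateau is perfectly
  plastic (σ_m = σ_y).
- **Degenerate densities.** ε_ab ≤ 0 for ρ ≤ 0.2713: softening is
  undefined there. `softening_params()` raises an error;
  `bone_material_table()` flags such elements and the solver treats them as
  elastic–perfectly-plastic. Densities are floored at 0.05 g/cm³ so no
  element becomes singular. At very low density (ρ < 0.483) the printed
  laws give σ_min > σ_y; the curve degenerates gracefully (the softening
  segment has zero length and the "residual" plateau at σ_min acts as a
  mild jump); such elements carry almost no load in practice.

## 2. Interpubic disc

The disc uses the three-term incompressible Mooney–Rivlin energy
W = C₁₀(I₁−3) + C₀₁(I₂−3) + C₁₁(I₁−3)(I₂−3), with fibrocartilage constants
C₁₀ = 0.1, C₀₁ = 0.45, C₁₁ = 0.6 MPa. `mr_uniaxial_stress()` provides the
closed-form Cauchy stress on the incompressible uniaxial path
(I₁ = λ² + 2/λ, I₂ = 2λ + 1/λ²),
σ = 2(λ² − 1/λ)(∂W/∂I₁ + λ⁻¹·∂W/∂I₂), and is verified against a
central-difference derivative of the energy to 1e-6 relative.

The FE core uses linear kinematics, so the solve itself uses a linearized
disc: initial shear modulus μ₀ = 2(C₁₀+C₀₁) = 1.1 MPa and a
near-incompressible ν = 0.475, hence E = 2μ₀(1+ν) ≈ 3.25 MPa
(`disc_linearized()`). ν = 0.475 rather than 0.5 keeps the displacement
formulation well-conditioned; linear tetrahedra lock as ν → 0.5, and at
0.475 the added stiffness error is small against the bone/disc contrast of
three orders of magnitude. The full hyperelastic law remains available and
tested in the materials module.

## 3. Muscle forces and static optimization

`hill_force()` uses F = a·F₀·f_L·f_v·cos α with a rigid tendon. The factor
shapes are not dictated by the source analysis, so standard forms are the
defaults and both are injectable:

- f_L = exp(−((L/L_opt − 1)/0.45)²) — Gaussian active force–length with
  width 0.45;
- f_v — Hill hyperbola for shortening with shape constant 0.25, saturating
  eccentric branch at 1.4, f_v(0) = 1, v_max defaulting to 10 optimal
  lengths per second.

For the static single-leg-stance snapshot v = 0, so f_v is exactly 1 and
these choices do not affect the packaged analyses.

`solve_static_opt()` minimizes Σ aᵢ² subject to Σ aᵢFᵢr_ij = Q_j and
0.01 ≤ aᵢ ≤ 1. Because activations and gains are non-negative, the absolute
value that formally wraps each term of the moment sum is inert and dropped
after asserting positivity. The problem is a strictly convex QP solved by a
dual active-set method (`quadprog`), hence deterministic, with the
objective rescaled to O(1) curvature so solver tolerances are unit-free.
Infeasible targets return the minimal-residual bounded least-squares
solution, flagged `feasible = FALSE`. An arbitrary number of moment axes is
supported since the axis count of the source analysis is unstated.

The packaged 27-muscle force table ships exactly as printed, including
zeros and two typeset artifacts ("13.I", "27.IV") stored with the printed
string, a best-reading numeric value (13.1, 27.4) and an `ambiguous` flag.

## 4. FE core

Linear displacement tetrahedra with exact constant strain–displacement
operators; Voigt order (11, 22, 33, 12, 23, 13) with engineering shears.
Key choices:

- **Constraints by transformation.** Tie constraints express every slave
  degree of freedom as the barycentric interpolation of its master facet
  (projection tolerance 1e-6 mm by default, orphans are an error), and the
  reduced system K̃ = TᵀKT is solved by sparse Cholesky. Ties transmit
  tension and compression — the bone–disc interface is glued, no unilateral
  contact. Chained ties (a master that is itself a slave) are rejected.
- **Distributed coupling.** A reference-point force maps to uniform nodal
  shares plus the minimum-norm correction field enforcing zero resultant
  moment about the reference point (a 6×6 saddle system). Resultants are
  exact to machine precision; this is the RBE3-style behaviour expected of
  load-introduction couplings.
- **Supports.** Fixed sets pin all three translations (optionally to
  prescribed values, which enables patch tests); spring sets add grounded
  stiffness k/n per node per translational axis so the patch total per axis
  equals the published k = 4285 N/mm. Whether the physiological SIJ spring
  acts on one or three axes is unstated; all three is the default and the
  choice is confined to `spring_diagonal()`.
- **Incremental secant solve.** The stated increments "0.05 / 0.1" are
  interpreted as load-factor fractions (they are dimensionally inconsistent
  as lengths for a static step). At each load level the solver iterates:
  assemble with current secant moduli, solve, form the von Mises equivalent
  strain ε_eq = σ_vm/E_sec per bone element, evaluate the bone curve at
  ε_eq, update E_sec ← σ(ε_eq)/ε_eq (relaxation 0.8, floor 1e-6·E, cap E)
  until the global residual — internal minus external reduced forces,
  normalized by the larger of the external and full internal force scales —
  drops below 1e-6. Purely elastic states converge in one iteration, which
  makes the incremental solver coincide with a one-shot linear solve (a
  tested invariant). The final state is re-solved once with the converged
  moduli so stored displacements satisfy equilibrium to solver precision.
  This secant (deformation-theory) treatment was chosen over return-mapping
  plasticity for robustness at desk scale; it cannot represent elastic
  unloading from a softened state, which the monotonic single-snapshot
  load cases never exercise.
- **Reactions.** Support reactions are the residual of the bulk stiffness,
  R = Ku − f, evaluated at constrained and sprung nodes (springs therefore
  report −k·u). Summed over all support sets they balance the applied loads
  identically up to solver precision.
- **Coordinates.** Right-handed x (lateral, toward the right side),
  y (superior), z (anterior); the hip reaction components (852, 2052,
  −1042) N map to (x, y, z) in that order. The source figure's axis
  convention is not fully recoverable, so the mapping is an argument of
  `reference_load_case()`.

## 5. The synthetic toy pelvis

`generate_toy_pelvis()` stands in for the unavailable subject CT: each hip
bone is a square-section bar (24 mm) swept 1.92 rad along a circular arc
(110 mm) in the transverse plane from the pubic end to the SIJ end; a
5×18×18 mm disc block bridges the pubic end faces; everything is meshed by
a conforming 6-tet split of structured hexes (5 mm edges in the bone,
refined to 2.5 mm within 10 mm of the symphysis, 2 mm in the disc —
mirroring the bone/symphysis refinement idea at toy scale), ~8200 elements
in total against a 50 000 budget. Muscle attachment sites are placed along
the arc in anatomical order — pubic adductor origins, ischial hamstrings,
anterior-iliac sartorius/tensor/rectus, mid-wing gluteus minimus/medius,
posterior gluteus maximus and piriformis — with the acetabular patch at
0.62–0.80 of the arc, under the SIJ, as in a real innominate. Muscle force
*directions* are not recoverable from magnitudes alone, so each muscle
pulls from its attachment centroid toward a schematic femoral or tibial
landmark (greater/lesser trochanter, shafts, distal femur, posterior
tibia); the landmark table is an argument and the magnitudes remain
authoritative.

The density generator gives cortical ρ_CT = 1.0 (apparent 1.62 g/cm³,
E ≈ 9.2 GPa) to elements whose centroid lies within 3 mm of the bar
surface and cancellous ρ_CT = 0.3 (apparent 0.54 g/cm³, E ≈ 700 MPa) to the
core, plus zero-truncated Gaussian noise (sd 0.03 g/cm³) under the given
seed — values a musculoskeletal modeller would call typical for pelvic
cortical shell and trabecular core, and chosen so both the compact and the
cancellous constitutive branches are exercised (a tested invariant). Two
load cases are packaged, evaluated **separately** as in the source
analysis: the hip reaction (852, 2052, −1042) N at the right acetabular
reference point, and the 27 muscle forces; both fix the left SIJ and
spring-support the right SIJ. (`include_hip_reaction = TRUE` superimposes
the reaction on the muscle case for sensitivity studies.)

What the toy does *not* emulate: real innominate geometry (wide iliac
plates, acetabular cup), ligaments, contact, voxel-level density texture,
or any subject specificity. A green test on the toy therefore establishes
that the *mechanics pipeline* behaves correctly and that the qualitative
load-sharing structure is right — never that absolute published field
values are reproduced; those depend on the subject CT, which is out of
reach by design.

## 6. Known limitations

- **Hip-bone load-case ordering.** The published narrative has the hip
  bones loaded ~15% more under the bare joint reaction than under the
  muscle forces, and the symphysis ~30% more under the muscles. The toy
  robustly reproduces the symphysis half (+35% across all noise seeds) but
  *not* the hip-bone half: on the noise-free world the bone peak is 33.7
  (reaction) vs 37.6 MPa (muscles), and with default noise the margin is
  smaller than seed-to-seed variability. Both peaks sit at the sprung
  right-SIJ region — consistent with where the source reports yield being
  slightly exceeded — but in a one-dimensional bar ring the gluteal pulls
  act on long lever arms to that support and bend it more than the adjacent
  acetabular load does, whereas a real iliac wing is a wide plate that
  shears those loads into the SIJ over a broad front. The corresponding
  acceptance check asserts the ordering on the deterministic noise-free
  world and is expected to fail; it documents this limitation rather than
  passing on a lucky noise realization.
- **Large disc strains under linear kinematics.** The toy's soft disc
  reaches logarithmic strains of order 0.5–0.8; the small-strain solver
  reports these consistently (log strains are computed from the full
  displacement gradient) but the equilibrium configuration ignores
  geometric nonlinearity. Published symphysis strains (~0.3–0.5) are of
  the same order, so the idealization is comparable, not better.
- **Element technology.** Linear tetrahedra everywhere, including the
  near-incompressible disc (the source used quadratic hybrid hexes there);
  expect the disc to be somewhat too stiff and bending-dominated bone
  regions to need the mesh densities used in the verification tests (the
  cantilever oracle passes within 5% at 20 elements through the depth).
- **Resume semantics.** `run_pipeline(resume = TRUE)` skips re-writing
  existing generation/material artifacts; solves are recomputed in memory.
  Since every stage is deterministic under the config seed, resumed runs
  are bit-identical to fresh ones (a tested invariant).

## 7. Reproducibility

All randomness (density noise only) flows from one integer seed; meshes,
load cases, solver and reports are fully deterministic, and the pipeline
serializes its merged config (`config.json`) into the output directory so
any run can be replayed exactly.
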