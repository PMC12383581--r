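---
title: "Methods: coupled vibro-thermal simulation of ultrasonic tumour aspiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled vibro-thermal simulation of ultrasonic tumour aspiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusafem)
```

## The problem

A Cavitron Ultrasonic Surgical Aspirator (CUSA) fragments soft tumour
tissue with a tip vibrating at 23 or 36 kHz and peak-to-peak strokes of
35--355 µm.  When the device is used inside the spinal cord -- resection
of an intramedullary tumour -- two collateral effects matter for safety:
the mechanical strain the vibration induces in the surrounding cord, and
the temperature rise produced when the radiated vibratory energy
dissipates as heat.  `cusafem` models both on a simplified cervical-spine
segment: five vertebrae (C3--C7) with intervertebral discs, and a
coaxial stack of epidural fat, dura mater, cerebrospinal fluid (CSF) and
spinal cord inside the vertebral cavity, with a cylindrical tumour
(7 mm diameter, 25 mm height) embedded in the cord at the C4--C5 level.
The device tip acts on a 2 mm circular face on the tumour surface.

The pipeline has three coupled stages, executed on one mesh:

1. **Harmonic response** -- linear elastodynamics
   $((1+i\eta)K - \omega^2 M)u = 0$ with the tip face driven at the
   sinusoid amplitude $u_0 = \mathrm{pp}/2$ along the face normal (the
   model $y$ axis) and the outer vertebrae fixed.
2. **Equivalent radiated power (ERP) coupling** -- the vibrating tumour
   surface radiates $Q = \tfrac12 \rho_f c_f \oint |v_n|^2\,dS$; assuming
   all of it dissipates as heat, the flux density $q = Q/A$ (with $A$
   the whole-tumour surface area) is applied to the 2 mm tip face.
3. **Thermal response** -- transient (1 s horizon) and steady-state heat
   conduction with convection $h\,(T - T_\mathrm{amb})$ on the exposed
   outer boundary, summarized as per-tissue maximum temperatures and
   compared with the 44 °C (tolerable) and 46 °C (damage) thresholds
   reported for spinal cord in animal hyperthermia studies.

All tissue properties are isotropic and homogeneous, at a 37 °C
reference state; the CSF is treated as a very soft solid.  Geometry is
kept in mm and converted to SI once, at assembly.

## The model factory as the study-condition generator

Every input is parametric and generated in code: `default_geometry()`
returns the reference dimensions, `default_materials()` the seven-tissue
property registry (density in g/cm³, Young's modulus in MPa, Poisson
ratio, conductivity in W/(m·°C), heat capacity in J/(kg·°C)), and
`load_case_preset()` the two reference operating points -- 70 µm pp
(20% power) and 213 µm pp (60% power), both at 36 kHz.  A reduced
single-vertebra `toy_config()` exercises every stage in seconds and is
the fixture for most tests.

Two bookkeeping choices deserve emphasis:

* **Peak-to-peak convention.** Solvers impose the sinusoid amplitude
  `displacement_pp / 2`.  Changing this convention would scale every
  strain and (quadratically) every flux, so it is centralized in
  `load_case()`.
* **The published heat budgets are inputs.** The acoustic medium behind
  the reference ERP values is not derivable from the anatomy -- no
  reasonable impedance reproduces them from first principles (with air
  the piston formula gives an order of magnitude less power).  The
  presets therefore carry the published $Q$ (0.3907 / 3.6579 W) and
  tumour area $A$ = 6.5742×10⁻⁴ m² and derive $q = Q/A$ exactly
  (594.3 / 5563.9 W/m²), keeping the thermal stage decoupled from the
  unknown medium constant.  A `first_principles` mode computes ERP from
  the harmonic solution and a configurable `fluid_impedance()` instead.
  Note the published triplets are mutually inconsistent by about 1% --
  the package always reports the exact quotient.
* **Flux placement.** $q$ is normalized by the *whole-tumour* area but
  applied only to the 2 mm tip face; the injected power is therefore
  $q \cdot A_\mathrm{tip} \ne Q$.  This mirrors the reference procedure
  rather than "fixing" it; both numbers are reported in the case
  diagnostics.

The 4 mm slack between the 90 mm segment height and the summed part
heights (5×14 + 4×4 = 86 mm) is absorbed as 2 mm end caps merged into
the two outer vertebrae, preserving every printed part dimension.  The
vertebra cross-section is a posterior arch ring (8 mm outer radius)
around the 12 mm cavity merged with an elliptical body footprint
(24.5 × 14 mm) offset 5 mm anteriorly; the arch shape is not dimensioned
anatomically, and thermally almost irrelevant (the epidural fat
insulates the bone).

## Meshing

No external mesher is assumed: the package meshes the layered model with
a structured polar $(r, \theta, z)$ tensor-product grid whose surfaces
coincide *exactly* with every tissue interface, so no element straddles
two materials.  Hexahedral cells are split into tetrahedra with a
parity-alternating 5-tet decomposition (conforming by construction;
collapsed 3-tet wedges on the axis), and the polygonal rings are
rescaled so each layer keeps its exact cross-sectional area (volume
errors are then dominated by the outer bone boundary, < 1%).

Sizing follows a sphere of influence of radius 20 mm at the tumour
centre and a finer window around the tip face.  The defaults
(`mesh_sizing()`: global 4.5 mm, 1.6 mm inside the sphere, 0.4 mm at the
tip) are calibrated so the tensor-product mesher lands in the
25 000--100 000 element band of the reference discretization
(~50 000 adaptive tetrahedra); a tensor grid refines whole coordinate
planes at once, so its size targets are not numerically identical to an
adaptive mesher's local sizes.  The default full mesh has ≈ 70 000
elements and ≈ 15 000 nodes.

The 2 mm tip face is extracted as the set of tumour-surface facets
clipped *exactly* against the tip disc in the developed (arc-length, z)
plane of the tumour cylinder -- the cylinder is developable, so the
clipped area equals the true contact area (π mm² to machine precision)
at any mesh resolution, and flux loads use the clipped facet areas.

## Harmonic stage: damping and the tip boundary layer

Two numerical facts shape this stage.

First, the compressional wavelength in the tumour at 36 kHz is
$\lambda = 2\pi c_p/\omega \approx 42$ µm ($E$ = 1.8 kPa, $\nu$ = 0.3,
$\rho$ = 1075 kg/m³) -- three orders of magnitude below the model size.
No affordable global mesh resolves it; on the full mesh the discrete
response is mass-dominated and decays within one element of the tip.
The package therefore computes the headline peak strain on a dedicated
**axisymmetric tip submodel** (`tip_strain_submodel()`): the tip is a
rigid frictionless piston on the tumour half-space, which is
axisymmetric about the face normal, and a graded 2-D $(r, y)$ mesh of
axisymmetric triangles resolves the wave with ~12 elements per
wavelength near the face.  Its peak $|\varepsilon_{yy}|$ agrees with the
damped plane-wave closed form
$|\varepsilon| = \omega u_0 \sqrt{\rho/M}\,(1+\eta^2)^{-1/4}$ to within
~10% (the difference is piston-rim diffraction), and is exactly linear
in the drive amplitude.  Strain-energy confinement and the global
response still come from the full 3-D solve.

Second, the undamped interior problem at 36 kHz is resonance-dense and
ill-posed: the discrete spectrum of the soft tissues crowds every
neighbourhood of $\omega$, so an undamped solve is dominated by whichever
numerical resonance happens to fall closest.  The package therefore
defaults to a hysteretic loss factor $\eta = 0.1$ on all stiffnesses --
representative of soft-tissue loss tangents at ultrasonic frequency --
which regularizes the solve and makes the submodel wave decay within
~0.5 mm.  Peak strain depends on $\eta$ only through
$(1+\eta^2)^{-1/4}$ (≈ 0.25% at $\eta = 0.1$); an undamped path remains
available (`loss_factor = 0`) for static and fixture work.

Large harmonic systems are solved by preconditioned Krylov iteration --
COCG for the damped complex-symmetric operator, MINRES for the undamped
real one -- with a CHOLMOD factorization of the SPD shift
$K + \omega^2 M$ as preconditioner (relative residual ≤ 10⁻¹⁰, and the
prescribed face displacement is a hard constraint, echoed exactly).
Small systems and the 2-D submodel use a sparse LU of the equivalent
real block system.  Sparse direct LU of the full 3-D operator was
rejected on measurement: the available non-supernodal factorization
needs minutes at 30 000 dof, while the preconditioned iteration solves
the 45 000-dof full model in ~15 s (~300 iterations).

## Thermal stage

Conduction uses the same linear tetrahedra (lumped capacity, lumped
Robin boundary), CHOLMOD Cholesky solves, and backward-Euler stepping
(dt = 10 ms, 1 s horizon) for the transient -- unconditionally stable,
monotone toward the steady state from the neutral start.  The convection
parameters are not anatomically fixed quantities: `h` = 10 W/(m²·°C) is
a representative still-air film coefficient, and `T_amb` = 37 °C makes
the environment thermally neutral, consistent with far-field tissues
resting at ≈ 37 °C.  Both are configuration keys; because the injected
power (~2--18 mW) is minute against the model's outer surface, the
far-field rise is < 0.1 °C and the application-site rise is insensitive
to `h`.  The steady response is exactly linear in `q`, so case runs scale
one cached unit-flux rise field; at the reference fluxes the tumour
maximum reaches ≈ 37.6 °C (70 µm) and ≈ 42.5 °C (213 µm), with the
rise ratio equal to the flux ratio by construction.

The heated face is an interior interface (the tumour sits inside the
cord), so heat spreads into both sides; this halves the classical
uniform-flux disc rise $qa/k$ of a one-sided half-space, which is why
`disc_source_peak_estimate()` is used only as a 0.2×--2× bracket.

No perfusion, metabolic heat, irrigation cooling or aspiration is
modelled (a Pennes-type sink could be added to the capacity/conduction
operators, but is deliberately out of scope); the result is a worst-case
stationary-contact estimate, which is the conservative quantity the
safety thresholds should be compared against.

## Verification strategy

Every operator has an independent reference: dense per-element assembly
via explicit shape-function inversion (`dense_reference_solve()`,
agreement ≤ 10⁻¹⁰ on fixtures), closed-form slab conduction and
lumped-capacitance decay (≤ 1%), the uniform-stretch patch test and
static ramp (exact for linear fields), the regular-tetrahedron dihedral
angle, rigid-motion null spaces, the damped plane-wave strain formula,
and exact linearity/quadratic-scaling laws.  The discrete energy balance
(injected tip power vs. total convective loss at steady state) closes to
solver precision because both sides are evaluated with the same lumped
operators.

What the toy fixture does *not* exercise: anatomical realism (spinal
curvature, white/grey matter, infiltrative tumour margins), the true
acoustic radiation problem, and any validation against measured tissue
temperatures -- the package verifies its numerics, not the biology.

## Problem sizes and runtime

Default full-model runs used throughout the documentation: ≈ 70 000
tetrahedra / 15 000 nodes (45 000 elastic dof), one COCG harmonic solve
(~15 s), one unit-flux steady Cholesky (~2 s), 100 implicit transient
steps, and a ~7 000-dof axisymmetric submodel (~1 s).  A complete
two-case pipeline finishes in about a minute on one CPU.
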