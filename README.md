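# cusafem

Coupled vibro-thermal finite-element simulation of a Cavitron Ultrasonic
Surgical Aspirator (CUSA) acting on an intramedullary spinal-cord tumour.

Neurosurgeons use ultrasonic aspirators to fragment and aspirate soft
tumours inside the spinal cord. The vibrating tip (23/36 kHz, 35–355 µm
peak-to-peak) deposits mechanical strain and — through dissipation of the
radiated vibratory power — heat into tissue millimetres away from
irreplaceable neural structures. `cusafem` is an open, testable
reimplementation of the standard simulation chain used to assess that
risk, for biomechanics researchers and surgical-device engineers:

1. **Parametric anatomy** — a C3–C7 cervical segment: vertebrae + discs
   around a coaxial stack of epidural fat, dura mater, CSF and spinal
   cord, with a 7 × 25 mm tumour embedded at the C4–C5 level and a 2 mm
   tip-application face on its surface.
2. **Harmonic elastodynamics** — `((1+iη)K − ω²M) u = 0` with the tip
   face driven at the sinusoid amplitude `pp/2` and the outer vertebrae
   fixed; the peak drive-axis strain is resolved on an axisymmetric tip
   submodel (the compressional wavelength in the 1.8 kPa tumour is only
   ~42 µm).
3. **Equivalent radiated power (ERP)** — `Q = ½ ρc ∮ |v_n|² dS`; assuming
   100 % dissipates as heat, the flux `q = Q/A` (with `A` the
   whole-tumour surface area) is applied to the tip face.
4. **Bioheat conduction** — transient (1 s dwell) and steady-state
   conduction with convection on the outer boundary, summarized as
   per-tissue maximum temperatures and checked against the 44 °C
   (tolerable) / 46 °C (irreversible damage) spinal-cord thresholds.

Everything — geometry, materials, graded tetrahedral meshing with exact
layer interfaces, assembly, solvers — is generated in code; there are no
external data or mesher dependencies.

## Worked example

```r
library(cusafem)

ctx <- simulation_context(simulation_config())
r70  <- run_case(ctx, "paper-70um")    # 70 um pp @ 36 kHz (20% power)
r213 <- run_case(ctx, "paper-213um")   # 213 um pp @ 36 kHz (60% power)
r213
#> <cusa_case_result> 213 um pp @ 36 kHz
#>   peak strain 17.533, extent 2.1 mm, confinement 1.0000
#>   Q = 3.6579 W, A = 0.00065742 m^2, q = 5564.0 W/m^2
#>   tumour steady max 42.54 C; PASS

r213$region_table
#>   tissue   steady transient_end
#> 1 tumour 42.53697      38.78421
#> 2   bone 37.16085      37.00060
#> 3   disc 37.15476      37.00005
#> 4    fat 37.18249      37.00857
#> 5   dura 37.19260      37.02191
#> 6    csf 37.26495      37.19882
#> 7   cord 42.53697      38.78421

r213$safety$margin
#> [1] 3.462983
```

What these numbers mean: at 60 % power the radiated 3.66 W, spread as a
5 564 W/m² flux over the 2 mm contact face, warms the application site to
a steady 42.5 °C — measurable, but 3.5 °C below the 46 °C damage
threshold (and after a 1 s dwell the site has only reached 38.8 °C). The
vibration itself produces a peak directional strain of 17.5 ε confined to
a ~2 mm zone at the contact: essentially all strain energy stays inside
tumour and cord. At 20 % power the heating is a negligible 0.6 °C. An
amplitude sweep (`sweep_amplitudes(ctx, c(70, 140, 213, 280))`) reports
the extrapolated amplitude at which the steady maximum would cross 46 °C.

A command-line front end with `build-model`, `mesh`, `harmonic`,
`thermal`, `run`, `sweep` and `report` subcommands lives at
`inst/cli/cusafem.R` (see `--toy` for a seconds-scale reduced model);
meshes and fields can be exported as Gmsh MSH and VTU for inspection.

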