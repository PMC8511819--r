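---
title: "Methods: the fracenv phantom-to-report pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fracenv phantom-to-report pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracenv)
```

# Overview

`fracenv` models the mechanical environment of a healing long-bone fracture
stabilized with an intramedullary nail. A single run walks through six
stages:

1. **Phantom** — generate a synthetic, calibrated CT-like volume of an
   idealized fractured tibia with ground truth.
2. **Calibration** — fit the HU → equivalent-mineral-density regression from
   six rods of known density.
3. **Segmentation** — derive disjoint implant / bone / gap labels from the
   image alone.
4. **Meshing and materials** — convert labels into a conforming tetrahedral
   mesh and map calibrated density to heterogeneous bone stiffness.
5. **Elasticity** — solve small-strain linear elasticity under a configured
   load case.
6. **Mechanobiology** — classify fracture-gap elements into
   tissue-differentiation ("healing") zones, compute interfragmentary
   movement (IFM) and per-part peak von Mises stress.

Units are fixed: mm, N, MPa, g/cm³. Because mm·MPa = N·mm⁻¹·mm, forces in N
and moduli in MPa are mutually consistent without conversion factors.

# The synthetic phantom

Real subject CTs and subject-specific joint loads are not shippable in a
text-only package, so the pipeline's committed inputs are generated. The
phantom is an axis-aligned idealization with every feature the downstream
chain must exercise:

| Feature | Default | Why |
|---|---|---|
| Volume | 56 × 56 × 40 voxels at 1 × 1 × 2 mm | desk-scale CT-like anisotropy |
| Cortical shell | radii 7.5–9 mm, ρ_eqm = 0.8 g/cm³ | dense outer bone |
| Trabecular ring | radii 6–7.5 mm, ρ_eqm = 0.2 g/cm³ | density contrast for the two elasticity laws |
| Medullary canal | radius 6 mm, marrow HU | free nail fit |
| Nail | Ø 9 mm (8 mm in the failed scenario), z 12–68 mm | treatment parameter under study |
| Locking screws | 4 × Ø 4 mm, transverse | load path across the fracture |
| Fracture gap | 3 mm slab, configurable obliquity | the region being classified |
| Calibration rods | 6 rods, 0–0.8 g/cm³ | HU→density regression |
| HU law | HU = 1000·ρ_eqm + 0 plus N(0, 5²) noise | known recoverable ground truth |

Rasterization is by voxel centre with priority implant > gap > bone > rod >
background; noise only perturbs bone and rod HU (implant, gap, marrow and
background carry constant HU), and the generator is deterministic given
`seed`.

Two deliberate realism limits: geometry is cylindrical rather than
anatomical, and the nail is separated from the endosteal wall by a marrow
ring so that load transfer across the fracture happens through the locking
screws and the soft gap — the clinically relevant path in a locked
construct. Partial-volume effects exist only via voxel-centre rasterization;
there is no beam hardening or metal artifact model.

# Calibration

`fit_hu_to_density()` regresses known rod density on the **median** rod HU
(robust to rim voxels) by ordinary least squares, and warns when R² < 0.99.
`apply_calibration()` maps the whole volume and clamps negative densities to
zero, which keeps the downstream ash-density mapping in its valid domain.

# Segmentation

The chain is deliberately simple and fully logged:

1. implant: HU ≥ 2000 (far above any tissue);
2. bone: calibrated density ≥ 0.15 g/cm³ — the threshold is expressed in
   density units and converted per scan through the fitted calibration, so
   it adapts to scanner gain;
3. optional morphological closing and Gaussian mask smoothing (off by
   default: the committed phantom needs neither, and closing at 2 mm slices
   would bridge the thin fracture slab);
4. island removal (strips the calibration rods), cavity filling;
5. a **directional gap fill**: a voxel becomes gap when bone exists above
   and below it along the bone axis within `max_gap_span_mm` and it lies in
   a fracture slice (slice bone count below half the per-slice median). This
   deterministic rule stands in for the manually curated gap mask of a
   clinical workflow;
6. priority resolution into disjoint labels (implant > gap > bone).

On the committed phantom the chain recovers the ground truth with Dice 1.0
(noiseless) and ≥ 0.95 under default noise.

# Meshing and material mapping

Each foreground voxel is split into six tetrahedra around the cube's main
diagonal (Kuhn subdivision). Because every voxel uses the same diagonal,
neighbouring voxels triangulate shared faces identically and the global mesh
is conforming with no hanging nodes; the subdivision is volume-exact.
`order = 2` promotes each unique edge to a midside node (straight-edge
quadratic tetrahedra).

Bone elements sample the calibrated density at the voxel containing their
centroid, then:

* ash density: ρ_ash = 1.22·ρ_eqm + 0.0523 g/cm³;
* cortical (ρ_ash ≥ 0.6): E = 10200·ρ_ash^2.01 MPa;
* trabecular (ρ_ash < 0.6): E = 5307·ρ_ash + 469 MPa;

with ν = 0.30 for bone. The titanium implant uses E = 108000 MPa, ν = 0.37;
the soft gap tissue E = 3 MPa, ν = 0.4. The two bone laws intentionally
disagree at the threshold — they come from different tissue regressions —
and the report records the ASTM F1472-14 minimum yield (860 MPa) and tensile
(930 MPa) strengths for advisory comparison only; they never alter the
solve.

# Finite-element solve

Small-strain isotropic linear elasticity with Voigt order
(xx, yy, zz, xy, yz, xz) and engineering shear. TET4 uses single-point
integration (exact for constant-strain elements); TET10 uses 4-point Gauss
quadrature, exact for straight-edge quadratic tetrahedra. Dirichlet
conditions are imposed by elimination, with optional prescribed-displacement
functions (used by the patch test). Loads are distributed either uniformly
over the region's nodes or as consistent nodal loads for a uniform traction
over the region's boundary faces. Systems up to 2·10⁵ free DOF go through a
direct sparse Cholesky factorization, larger ones through Jacobi-
preconditioned conjugate gradients (tolerance 1e-8); every solve reports its
relative residual and a global equilibrium check.

**Element order default.** The committed pipeline runs TET4: at ~40 k
elements per scenario the full phantom solves in seconds, and the verified
correctness suite (uniaxial bar u = FL/EA to 1e-10 with TET10; exact TET4
affine patch test; rigid-body nullspace; independent R-side assembly oracle)
pins both formulations. TET10 is available end-to-end via `order = 2` when
strain-field smoothness matters more than runtime.

# Mechanobiological classification

Per element the package computes volumetric strain (tr ε), octahedral shear
strain γ_oct = (2/3)√((ε₁−ε₂)²+(ε₂−ε₃)²+(ε₃−ε₁)²) from the principal
strains, and hydrostatic pressure p = −tr σ/3 (**compression positive**,
echoed in every report). Gap elements are then classified by an ordered,
first-match rule in the (γ_oct, p) plane:

| Zone | γ_oct | p (MPa) |
|---|---|---|
| resorption band (optional) | ≤ 0.002 | \|p\| ≤ 0.02 |
| intramembranous ossification | ≤ 0.05 | \|p\| ≤ 0.15 |
| endochondral ossification | ≤ 0.15 | ≥ 0.15 (compressive) |
| connective tissue (excess) | otherwise | — |

These boundaries are configurable literature-style defaults, not measured
constants; rule validation rejects any configuration that fails to cover the
plane, and the rule actually used is echoed in every report. IFM is the
difference of the mean displacement of the two gap/bone interface node sets,
decomposed along and perpendicular to the fracture-plane normal.

# The committed scenario pair and the default load

`scenario_pair()` builds two configurations that differ **only** in nail
diameter: `failed_8mm` and `revision_9mm`. The default load case applies
2.5 × body weight axially (73 kg → ≈ 1790 N, a standard gait-peak surrogate)
plus a transverse component of 0.45 × body weight (≈ 322 N) at the proximal
face, distal face fixed.

The transverse multiple is a **phantom-calibrated** choice, fixed once
before the test suite was written: across a sweep of 0.15–0.75 × BW it is
the setting at which the 9 mm revision places ~98 % of gap elements in
ossification zones while the 8 mm construct shows a clearly larger
excess-strain fraction (11 % vs 2 %) and higher implant peak von Mises
stress (316 vs 276 MPa) — i.e. the committed pair reproduces the expected
directional contrast between an undersized and an exchange nail without
putting either scenario in an implausible regime. The fractions are stable
across phantom noise seeds. Both multiples remain user-configurable.

```{r, eval = FALSE}
pair <- scenario_pair(seed = 1)
failed   <- run_pipeline(pair$failed)
revision <- run_pipeline(pair$revision)
compare_scenarios(failed, revision)
```

# Problem sizes and runtime

Typical desk-scale numbers (one CPU): the committed phantom meshes to ~40 k
TET4 elements / ~28 k DOF and solves directly in a few seconds; the full
two-scenario comparison runs end-to-end in well under a minute. TET10 on the
same phantom is ~6× more DOF and still solves directly.

# Limitations

* Linear elasticity only — no contact, no tissue evolution over healing
  time; the healing-zone map is a single-time-point stimulus snapshot.
* The phantom is an idealization; absolute stresses depend on its geometry
  and the surrogate load, so results should be read as controlled
  comparisons between scenarios, not patient predictions.
* Voxel meshes have stair-stepped surfaces; stress concentrations at
  single-voxel features should not be over-interpreted.
* Screws are rasterized as transverse cylinders unioned with the nail; no
  threads, no interface mechanics.
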