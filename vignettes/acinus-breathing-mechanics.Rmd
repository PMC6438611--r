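---
title: "Breathing mechanics of a fibrotic pulmonary acinus: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing mechanics of a fibrotic pulmonary acinus: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(acinusim)
```

`acinusim` simulates normal breathing in an idealised pulmonary acinus and
compares healthy tissue with two patterns of septal fibrosis (diffuse, as in
nonspecific interstitial pneumonia, and peripheral-dominant, as in
idiopathic pulmonary fibrosis). This vignette is the package's account of
the model itself: the geometry generator, the tissue and airflow physics,
the coupling, the numerical choices, and — importantly — what the
desk-scale discretisation can and cannot be expected to reproduce.

## The synthetic acinus geometry

The alveolus is idealised as a truncated octahedron (14-hedron): the only
isotropic space-filling polyhedron, and the classical idealisation of
alveolar packing. `truncated_octahedron()` builds the 24-vertex, 6-square /
8-hexagon cell; its volume is exactly `8 sqrt(2) a^3` for edge length `a`,
which the tests use as a closed-form oracle.

`assemble_acinus()` packs cells on a BCC lattice into

* a two-cell **parent duct** (generation 1) whose distal square face is the
  single open (inlet/outlet) boundary,
* a symmetric bifurcation into two **alveolar sacs** (generation 2), each a
  three-cell duct column surrounded by 12 alveoli in three columns of four.

Faces between two duct-path cells and between duct cells and alveoli are
removed, forming the continuous duct lumen and the alveolar mouths. The
remaining walls are classified by what they separate: **primary septa**
face the surrounding interstitium, **secondary septa** separate two air
spaces inside the acinus. The open-face rim is the clamped ring of the
solid problem. Exact integer lattice coordinates make shared faces and
vertices match exactly, so the lumen surface is watertight by construction
(the tests verify the divergence-theorem volume against both the summed
cell volumes and a voxel-count oracle).

Which faces are opened is not uniquely determined by the anatomical
literature; the choice here — every duct-alveolus contact becomes a mouth,
duct-path faces are fully open — is recorded by `build-geometry` in its
geometry report.

### Disease scenarios and calibration

`scenario_presets()` carries the three parameter bundles (thicknesses in
mm, modulus in Pa, resting volume in mm³):

| scenario | primary septa | secondary septa | E | resting volume |
|----------|--------------|-----------------|------|----------------|
| healthy  | 0.025        | 0.025           | 35714 | 0.512 |
| NSIP     | 0.050        | 0.050           | 35714 | 0.493 |
| IPF      | 0.050        | 0.025           | 35714 | 0.465 |

Septal fibrosis is modelled as *interstitial* thickening: collagen is laid
down within the wall, so the wall thickness map changes while the lumen
surface shape is preserved, and a global isotropic scale factor calibrates
the resting lumen volume to the tabulated target (`apply_scenario()`; the
calibration is exact by construction and the tests assert it to 1%). The
alternative — growing the wall into the lumen — was rejected because an
orifice narrowed by half a wall thickness changes its Sampson resistance as
`1/r^3..4`, which would raise the fibrotic airway resistance by far more
than the few-percent changes this class of model exhibits; early interstitial
disease is characterised by near-normal airway calibre. Disease still
affects the airflow twice: every opening narrows with the global scale, and
the alveolar-mouth channel lengthens with the secondary-septum thickness.

`perturb_scenario()` applies seeded log-normal multiplicative noise to the
thicknesses and modulus for sweeps and recovery tests.

## Tissue mechanics

Septa are thin (25–50 µm) compared with the alveolar chamber size
(~300 µm), so the tissue is discretised as a shell on the septal
mid-surfaces rather than with solid elements:

* **Membrane**: each wall triangle is a Neo-Hookean membrane in plane
  stress. The stored energy is the modified Neo-Hookean form
  `W = K U(J) + G/2 (J^{-2/3} I_C - 3)` with
  `U(J) = (J^2 - 1 - 2 ln J)/4`, `K = E/(3(1-2nu))`,
  `G = E/(2(1+nu))`, `E = 35714` Pa and `nu = 0.42`. The through-thickness
  stretch is condensed out element-wise from `sigma_33 = 0` by a scalar
  Newton iteration. The same energy is exposed for full 3×3 deformation
  gradients (`strain_energy()`, `cauchy_stress()`), where the tests verify
  the stress against finite differences of the energy (1e-6 relative),
  objectivity under rotations, and the linear-elastic small-strain limit.
* **Bending**: a discrete-shell hinge term
  `k_h (theta - theta_0)^2`, `k_h = D |e|^2 / (2 (A_1 + A_2))`,
  `D = E t^3 / (12 (1 - nu^2))`, over every edge shared by exactly two
  wall triangles. This supplies the transverse stiffness of the flat
  septal facets and the fold stiffness of the polyhedral edges. Hinge
  bending models are not convergent discretisations of Kirchhoff shell
  theory on general meshes; on structured plate meshes this constant is
  conservative (stiff) by a factor approaching two, which the test suite
  documents through an explicit plate comparison only at the order-of-
  magnitude level. This is the dominant fidelity limit of the solid model
  (see *Known limitations*).
* **Loads**: follower pressure on each triangle, `q = p_inside -
  p_outside`; for primary septa the outside pressure is the intrapleural
  waveform, for secondary septa both sides carry alveolar air pressures.
  Inertia is dropped (quasi-static stepping): breathing at 0.25 Hz with
  tissue densities of order 10³ kg/m³ produces inertial stresses many
  orders below the elastic ones, and no tissue density is part of the
  scenario parameterization.

Equilibrium is found by Newton iteration on the energy gradient with a
cached sparse Cholesky factorisation of an approximate tangent (linear
membrane + geometric stress + bending Gauss–Newton), refreshed
periodically and whenever convergence degrades; a Levenberg-style diagonal
shift keeps the preconditioner positive definite when compressive membrane
stress appears near end-expiration. Convergence is declared at a relative
residual of 1e-8; because the driving waveform crosses zero load, the
residual scale is floored at 0.1% of the load-amplitude force norm (a pure
relative criterion is ill-posed at the zero crossing). Armijo line search
is used far from the solution; near it the energy decrease is below
summation round-off and undamped Newton steps are taken under a residual
safeguard. Load sub-stepping handles the rare non-converging step.

The thin-shell solver is verified against the Lamé pressurised-sphere
closed form `dR = p R^2 (1 - nu) / (2 E t)` (within 5% at sub-percent
strain, with the expected `1/t` scaling).

## Airflow

At the acinar scale the flow is creeping (`Re` well below 1), so the
incompressible Navier–Stokes system is solved in its Stokes limit; the
convective and transient inertial terms are negligible at the breathing
frequency. Two representations are provided:

* **Duct network** (default; used for the breathing cycles): one node per
  polyhedral cell plus the atmosphere, one edge per opening. Alveolar
  mouths carry a Sampson orifice plus channel resistance
  `3 mu / r^3 + 8 mu t / (pi r^4)` (the channel length is the septal
  thickness the opening pierces); duct-path faces and the open boundary
  are continuations of the duct channel at its equivalent calibre
  `R = 2a / sqrt(pi)` with Poiseuille half-cell segments. The Kirchhoff
  balance on the conductance Laplacian conserves mass exactly: the open
  flux equals the summed compartment volume rates to round-off.
* **Stabilised finite elements** (`mesh3d`): P1–P1 tetrahedra with
  Brezzi–Pitkäranta pressure stabilisation, no-slip walls at the prescribed
  wall velocity, zero-pseudo-traction open boundaries. The solver is
  verified against Hagen–Poiseuille flow (3%), the wall-shear closed form
  `4 mu Q / (pi R^3)` (5%), swept-volume mass balance on a radially
  expanding tube (0.5%) and a tapered-tube cross-validation of the network
  mode (10%).

Air is humid air at body temperature, `rho = 1.145` kg/m³ and
`mu = 1.86e-5` Pa s by default (configurable); these values are a modelling
choice, not part of the scenario tables. The Reynolds number is
`rho u_max L / mu` with `L = 1` mm (the sac length scale) and `u_max` the
largest velocity magnitude of the flow representation — cross-section mean
velocities in network mode, nodal velocities in `mesh3d`.

## The coupled breathing cycle

The intrapleural pressure `p_IP(t) = -p0 (1 - cos(omega t))/2` (`p0 = 244`
Pa ≈ 2.5 cmH₂O, `omega = pi/2` 1/s) loads the outer surface; the shell
solve returns wall displacement and per-cell lumen volumes; compartment
volume rates (BDF2 in time, trapezoidal first step so the start is
second-order with the known zero initial flow) drive the fluid solve; the
alveolar pressures are fed back onto the inner wall surfaces. The exchange
is sub-iterated (Gauss–Seidel with Aitken under-relaxation, tolerance 1e-6
on the relative interface displacement, or equivalently a pending
alveolar-pressure update below the same tolerance relative to the driving
load), with a `loose` switch for single-exchange explicit staggering. In
`mesh3d` mode wall displacements are interpolated to the fluid boundary by
Wendland-C2 radial basis functions with linear polynomial augmentation
(exact on linear fields; the transposed operator transfers forces
conservatively), and the lumen mesh follows by a graph-Laplacian smoothing
solve that errors on element inversion.

Defaults: `dt = 0.01` s, two cycles of 4 s, metrics on the last cycle.
The time discretisation is verified to second order on
`dt ∈ {0.02, 0.01, 0.005}` using a high-viscosity variant in which the
pressure-relaxation time is comparable to `dt` (with the standard air
viscosity the coupling relaxes so fast that the time-discretisation error
is below solver tolerance — itself a statement of how weak the
fluid–solid coupling of normal acinar breathing is). With quasi-static
physics the cycle is immediately periodic (the cycle-to-cycle tidal-volume
change of the default runs is at round-off), and the flow–volume loop is
symmetric: peak inspiratory and expiratory flow agree to well within 2%.

## Lung-function metrics

From the scalar history of the last cycle: tidal volume (maximum volume
minus resting volume); compliance as the least-squares slope of volume
against the *driving* (intrapleural) pressure magnitude over the
inspiratory limb — with a zero-pressure open boundary the alveolar gauge
pressure is of order 0.1 Pa and a volume–alveolar-pressure slope is
degenerate, so the driving pressure is the physically meaningful loop
axis (the alveolar axis is available as an option); acinus resistance as
pressure drop over flow at peak inspiratory flow; peak flows; maximum
pressure-drop magnitude (signed negative in inspiration, positive in
expiration); Reynolds number; maximum wall shear stress; peak principal
Cauchy stress by septal class. `compare_scenarios()` tabulates percent
differences with healthy as the reference and the NSIP-vs-IPF contrast
with IPF as the denominator.

## Problem sizes

The desk defaults keep every run on one CPU in seconds to minutes: shell
level 1 has ≈1.6k wall triangles and 2.4k unknowns, the fluid mesh ≈2.3k
tetrahedra (refinement quadruples both per level, capped well under 5·10⁴
fluid cells and 3·10⁴ solid triangles), and a two-cycle run is 800 coupled
time steps. Full-resolution meshes of the kind used in large parallel
FSI studies of this system (millions of cells) are out of scope.

## Known limitations

* **Absolute compliance bias.** The shell discretisation of the faceted
  acinus is more compliant than full 3D-solid-element tissue models of the
  same geometry class: flat facets and free polyhedral folds let the
  structure inflate partly by bending, whose discrete stiffness is the
  least certain ingredient (hinge models are non-convergent on general
  meshes, and a solid model additionally stiffens the wall junctions).
  Mesh refinement moves the headline volumes only modestly, so this is a
  modelling bias, not a resolution artifact. Absolute volumes, flows and the Reynolds number inherit the
  bias (they come out high by tens of percent); *ratios* between scenarios
  — compliance and pressure-drop decreases, resistance contrasts — are
  much more robust, and the scenario orderings healthy vs fibrotic are
  unaffected.
* **NSIP vs IPF fine structure.** Because doubling the secondary-septum
  thickness also multiplies its fold stiffness by eight, the diffuse
  (NSIP) model comes out stiffer than the peripheral (IPF) model here,
  where reference full-fidelity models make their tidal volumes
  essentially equal; the few-percent NSIP-vs-IPF contrasts in pressure
  drop and resistance are at the edge of what this reduced model resolves.
* **No surface tension.** The air–liquid interface and surfactant dynamics
  are not modelled; the quasi-static cycle therefore shows no hysteresis
  and the P–V loop has zero enclosed area.
* The generator emulates an idealised lattice acinus: real acinar
  geometry is irregular, sacs share septa with their neighbours, and
  advanced IPF shows honeycombing beyond uniform septal thickening.
  Passing tests demonstrate correctness of the stated model and its
  numerics, not anatomical fidelity of any individual lung.
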