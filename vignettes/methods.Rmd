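---
title: "Methods: steady laminar airflow in age-specific G6-G9 airway trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady laminar airflow in age-specific G6-G9 airway trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bronchoflow)
```

This vignette documents the scientific and numerical choices behind the
package: the airway model and its assumptions, the governing equations and
their discretization, the parameters that matter, what the synthetic
fixtures do and do not emulate, and the known limitations — including a
quantitative account of where the pipeline reproduces the published
age-comparison study and where it deviates.

## The airway model

The conducting airways between generations G6 and G9 are represented by a
planar, symmetric, dichotomously branching tree. Each age group — infant
(6 months), child (5 years), adult (25 years) — is defined entirely by a
per-generation table: segment length $L$, inner diameter $D$, outer-wall
transition radius $R$ and carinal ridge rounding radius $r$ (all in mm),
with a bifurcation angle of 70° at every junction. The root (G6) segment
lies along $+x$; each daughter deviates by ±35° from its parent within the
$z = 0$ plane; the *right* daughter is the one deviating towards negative
$y$, which fixes the meaning of the "right G7" probe line used for mesh
independence. Units are converted from mm to SI metres once, when the
centerline tree is built.

The lumen is described implicitly by a signed distance field: the union of
flat-ended circular cylinders around the centerline segments. Flat ends
make the junction a *lofted* union — the two daughter tubes overlap each
other immediately past the junction node, so the flow divider (carina)
emerges where their walls separate, at an axial distance of roughly
$r_\mathrm{daughter}/\sin 35°$ from the node, without any spurious bulge.
Two creases remain and are rounded by a smooth-union correction whose
blend width is calibrated so that the maximum added material equals the
depth of a true circular fillet of the tabulated radius: the carinal ridge
between the daughters uses $r$, the outer wall transition parent→daughter
uses $R$. The correction is faded out away from the junction so that
distant loci equidistant from two tubes (for instance the symmetry plane)
are untouched. The exact surface equations of the morphologically
realistic bifurcation that the dimension tables descend from are not
published; this fillet construction is a stated, reproducible stand-in,
and its consequences are assessed below.

Terminal ends (the G6 inlet, the eight G9 tips) are cut flat,
perpendicular to the local centerline, exactly at the segment end — these
are the caps on which boundary conditions act. The triangulated surface is
extracted by marching *tetrahedra* (six tetrahedra per lattice cube),
which, unlike classic marching cubes, has no ambiguous sign cases: the
result is provably a closed orientable manifold, which the constructor
verifies (edge-pairing and orientation checks) before returning. The
default surface resolution is a target edge length of $D_{\min}/10$ —
fine enough to resolve the smallest tubes well while keeping desk-scale
cost; the carinal radii (60–230 µm) are below any affordable resolution
and are represented by the fillet geometry, not by surface refinement.

## Respiratory parameters

All breathing inputs are tabulated per age group: tidal volume (mL),
respiratory rate (breaths/min) and the inspiration:expiration time ratio
(stored normalized to $t_i = 1$). Derived quantities:

* minute ventilation $MV = V_T \cdot RR$ (mL/min);
* square-wave phase flow rates
  $Q_\mathrm{insp} = MV\,(t_i{+}t_e)/t_i$,
  $Q_\mathrm{exp} = MV\,(t_i{+}t_e)/t_e$ — each phase moves the full
  minute ventilation during its fraction of the breath, consistent with
  treating the phases as steady;
* symmetric Weibel split $Q_\mathrm{branch}(g) = Q_\mathrm{total}/2^g$.
  The G6 model inlet therefore receives $Q/2^6$; this choice makes the
  computed G6 velocities agree with the published maxima to a few percent,
  which corroborates it;
* Reynolds number $\rho U D / \mu$ (≈ 80–153 at the G6 inlets): laminar;
* Womersley number $\alpha = (D/2)\sqrt{\omega \rho/\mu}$ with
  $\omega = 2\pi f$. The *radius*-based definition reproduces all three
  published inlet values (0.25, 0.34, 0.44) to two decimals from the
  tables alone; a diameter-based definition does not, which pins the
  convention.

Air is standard-atmosphere sea level: $\rho = 1.225$ kg/m³,
$\mu = 1.7894\times10^{-5}$ kg/(m·s).

## Governing equations and discretization

The airflow solves steady incompressible laminar Navier–Stokes,
$\nabla\!\cdot\!\mathbf v = 0$ and
$\rho\,\mathbf v\!\cdot\!\nabla\mathbf v = -\nabla p + \mu\nabla^2\mathbf v$,
with a velocity inlet (uniform plug at the prescribed branch flow),
0 Pa gauge pressure outlets, and no-slip walls. During inspiration the G6
cap is the inlet and the eight G9 caps are outlets; during expiration each
G9 cap is an inlet carrying $Q_\mathrm{exp}/2^9$ and the G6 cap is the
outlet.

The discretization is a finite-volume staggered (MAC) scheme on a uniform
Cartesian lattice with immersed stairstep walls:

* cells are classified against the signed distance field as fluid, solid,
  or boundary-ghost (a three-cell-deep extension beyond each cap where
  inlet velocities or the outlet pressure datum are imposed);
* momentum advection is implicit first-order upwind plus an explicit
  second-order-upwind deferred correction; diffusion and pressure are
  central (second order);
* no-slip walls use *sub-cell wall distances*: the conductance of a wall
  seen by a near-wall face is $\mu A/d$ with
  $d = |\phi|/|n_\mathrm{axis}|$ the axis-aligned gap recovered from the
  signed distance field, clamped to $[0.05h, 1.5h]$. This restores most of
  the accuracy a stairstep boundary loses: a straight tube at 8–14 cells
  per diameter reproduces the Hagen–Poiseuille pressure gradient within
  2 % and the analytic wall shear stress within 5 %, and oblique tubes
  (20°, 35° to the lattice) behave comparably;
* pressure–velocity coupling is SIMPLE with under-relaxation 0.3
  (pressure) and 0.5 (momentum); the pressure-correction Poisson equation
  is solved by Jacobi-preconditioned conjugate gradients (relative
  tolerance $10^{-2}$, ≤ 40 iterations per outer step), momentum by three
  fixed-order Gauss–Seidel sweeps;
* convergence requires all four scaled residuals (three momentum,
  continuity) below $10^{-5}$. Residuals are normalized by their largest
  value over the first five outer iterations — equations that start from
  an exactly balanced zero state (the transverse momentum components at a
  quiescent start) would otherwise normalize by zero. A zero-flow problem
  short-circuits to the exact zero solution;
* initialization is quiescent (zero velocity, zero gauge pressure), all
  iteration orderings are fixed, and no randomness enters the solver:
  solutions are bit-reproducible. Non-convergence returns a flagged
  result with the residual history, never an exception.

Prescribed inlet velocities are scaled so that the *discrete* influx
through the stairstep cap equals the requested flow rate exactly; global
mass imbalance at convergence is below $10^{-5}$ relative in practice.

The lattice is laid out symmetrically about the $y = 0$ and $z = 0$
planes, so the geometric mirror symmetry is exact in the discrete system;
mirrored mid-section statistics agree to ~0.1 %, far inside the
discretization error.

## Meshing and mesh independence

The volume mesh is the classified lattice; a conforming tetrahedral
decomposition (six Kuhn tetrahedra per fluid cell) is available for export
(legacy VTK, Gmsh MSH 2.2) and reporting. Near-wall "layers" are
wall-distance bands one cell wide, tagged for post-processing — there are
no extruded prisms on a Cartesian core, and wall-normal resolution comes
from the sub-cell distances instead. Cap patch open areas are computed as
discrete face vector-area sums and agree with the projected cap areas of
the surface within a few percent; stairstep *wall* patch areas exceed the
smooth wall area by a geometry-dependent factor and are therefore not
compared against the surface.

Mesh independence follows the grid-convergence-index practice: a ladder of
lattices (default three levels, linear refinement ratio ~1.3), the probe
metric being the mean velocity magnitude at five points on the right-G7
axis, the selected level the coarsest whose relative change to the next
finer level is below 0.3 %, and the GCI computed with safety factor 1.25
and order 2. At desk scale the infant inspiratory probe metric still
changes by ~0.5 % between 6 and 10 cells per G9 diameter, so the 0.3 %
criterion selects the finest level *with a warning* at the ladder sizes
the test suite can afford (6–10 cells per smallest diameter); the
published study used meshes of 0.6–1.6 million commercial-solver cells,
roughly an order of magnitude beyond the lattice sizes used here.

## Fixtures and what they do (not) emulate

The fixture generator supplies the verification problems: a straight tube
with analytic Poiseuille references (pressure gradient, wall shear stress,
centerline velocity), a single bifurcation with the resistance-network
oracle, and the age trees themselves. An age-continuous interpolator
produces synthetic profiles between the three anchor ages by per-field
linear interpolation — a plumbing device for parameter sweeps, not a
physiological growth model. None of the fixtures emulate real airway
asymmetry, off-plane rotation of successive bifurcation planes, cartilage
ring corrugation, wall compliance, or unsteady breathing waveforms;
passing tests demonstrate correctness of the numerics on the idealized
geometry, not predictive accuracy for a particular patient.

## Comparison with the published study, and known limitations

With six cells across the smallest diameter (the coarse acceptance
resolution) through ten (the refinement study), the pipeline reproduces:

* all six maximum velocity magnitudes within ~4 % (published values
  2.22/1.82/1.41 m/s inspiration, 1.49/1.12/0.89 m/s expiration), the
  maximum always in G6;
* every ordering property: velocity, pressure drop and wall shear stress
  strictly decreasing infant → child → adult in both phases, inspiratory
  exceeding expiratory drop for each age, section-average velocity
  decaying G6 → G9 during inspiration;
* per-bifurcation mass conservation from section fluxes within 1 %.

Two quantities deviate systematically, and the deviation is itself
informative:

* **Pressure drops.** Computed inlet-to-outlet drops are a near-constant
  0.60× the published values across all six age/phase cases (e.g. infant
  inspiration ≈ 6.8 Pa vs 11.15 Pa), stable under refinement, and ~2 %
  *below* the fully developed Poiseuille network total for the infant
  inspiratory case. The solver itself reproduces analytic tube resistance
  within a few percent at these resolutions, including oblique tubes, so
  this is a geometry-model difference, not a numerical one: in the lofted
  junction the daughters share a merged lens over the first
  $r_d/\sin 35°$ of their length (25–30 % of each segment here), which
  cancels most of the extra junction losses, whereas the CAD bifurcations
  behind the published study (curved-duct transitions following the outer
  radius $R$, with Dean-type secondary flows and narrower junction
  cross-sections) evidently add ~65 % to the ideal network resistance.
  The constancy of the ratio across ages and phases supports this
  reading. The package reports both the inlet-average drop (the
  comparison quantity) and the maximum wall pressure.
* **Peak wall shear stress.** The published maxima (1.74/1.23/0.66 Pa
  inspiration) sit at the carinal ridges, where the local boundary layer
  is of order $\sqrt{\mu x/\rho U}\approx 20\text{–}30\,\mu$m — an order
  of magnitude below any affordable lattice spacing (60–100 µm here), and
  below the carinal radii themselves. The computed peaks (≈ 0.3–0.4 Pa
  for the infant) are resolution-limited and rise slowly under
  refinement; the *ordering* across ages and phases is nevertheless
  reproduced robustly. Wall shear stress near a velocity-inlet cap is
  excluded from the reported maximum: a plug profile meeting a no-slip
  wall has a mesh-divergent shear singularity there that is an artifact
  of the idealized boundary condition.

Other numerical choices worth recording: the pressure drop is defined as
the face-area-weighted mean gauge pressure of the fluid cells adjacent to
the velocity inlet (outlets pinned at 0 Pa); maxima are taken over lattice
cell values with the 0.999 quantile logged as a spurious-peak guard (the
two agree to ~1 % in all cases); section integrals use Gauss–Legendre ×
uniform-angle quadrature extended 0.45 cells past the nominal radius so
the full stairstep lumen is captured, with the interpolant tapering to the
zero field stored in solid cells; streamline seeding uses a deterministic
sunflower layout at 85 % of the cap radius (wall-hugging seeds advance
arbitrarily slowly), and streamline split fractions are reported but not
acceptance-tested.

## Problem sizes

The test suite solves: the Poiseuille tube at 8–14 cells per diameter
(≈ 2–11 k fluid cells), the six-case study at 6 cells per smallest
diameter (≈ 16 k fluid cells per case), a three-level infant ladder at
6–10 cells per diameter, and a creeping-flow single bifurcation. The
acceptance script re-solves the infant (both phases) and adult
(inspiration) cases at 6 cells per smallest diameter. These sizes were
chosen as the smallest at which the verification fixtures meet their
analytic tolerances and the study properties are stable.
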