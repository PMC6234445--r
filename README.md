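# bronchoflow

Steady laminar airflow simulation in age-specific tracheobronchial airway
trees (generations G6–G9), in pure R (with a compiled solver core).

Respiratory disorders are treated across a patient population whose airway
geometry and breathing mechanics change dramatically between infancy and
adulthood. `bronchoflow` builds idealized symmetric in-plane bifurcating
airway models of the sixth to ninth conducting-airway generations for an
infant (6 months), a child (5 years) and an adult (25 years) from tabulated
morphometric dimensions, derives the age-specific respiratory flow
parameters, solves the steady incompressible laminar Navier–Stokes
equations for both breathing phases, and post-processes velocity, pressure
drop and wall shear stress — the quantities used to compare airflow burden
across ages.

The package is aimed at respiratory biofluid-mechanics researchers who want
a self-contained, scriptable, deterministic pipeline (no external CAD or
CFD software) for idealized airway studies and for teaching.

## The model

* **Geometry.** Each age group is a planar symmetric dichotomous tree:
  four generations G6–G9 with tabulated length `L`, diameter `D`, outer
  transition radius `R` and carinal rounding radius `r`, bifurcation angle
  70°. The lumen is described implicitly (signed distance field) as a
  lofted union of flat-ended circular cylinders whose junction creases are
  rounded with fillets of radius `r` (carinal ridge) and `R` (outer wall);
  a watertight labeled triangulated surface is extracted by marching
  tetrahedra.
* **Respiration.** Minute ventilation `MV = VT × RR`; square-wave phase
  flow rates `Q_insp = MV (t_i+t_e)/t_i`, `Q_exp = MV (t_i+t_e)/t_e`;
  symmetric Weibel split `Q_branch(g) = Q / 2^g`. Womersley numbers
  `α = (D/2)√(ωρ/μ)` ≈ 0.25–0.44 at the G6 inlet justify treating each
  phase as quasi-steady, and Reynolds numbers ≤ ~150 justify laminar flow.
* **Solver.** Finite-volume SIMPLE (segregated, under-relaxed 0.3/0.5)
  on a staggered Cartesian lattice with immersed walls; second-order-upwind
  momentum (deferred correction), central pressure, sub-cell wall distances
  from the signed-distance field; scaled residuals < 1e-5. Inspiration:
  uniform velocity inlet on the G6 cap, 0 Pa outlets at the eight G9 caps;
  expiration: the reverse. Deterministic (fixed ordering, quiescent
  initialization).
* **Post-processing.** Mid-segment section statistics, maximum velocity,
  inlet-to-outlet pressure drop, wall shear stress recovered along wall
  normals, streamlines, and a cross-age report with the published
  comparison values; a Hagen–Poiseuille resistance-network oracle provides
  an analytic lower bound for tree pressure drops.

## A worked example

```r
library(bronchoflow)

prof <- build_profile("infant")
prof
#> Airway profile 'infant' (G6-G9, bifurcation angle 70 deg)
#>  generation   L   D   R    r
#>           6 3.5 1.0 1.8 0.09
#>           7 2.9 0.9 1.4 0.07
#>           8 2.5 0.7 1.2 0.06
#>           9 2.1 0.6  NA   NA
#> Breathing: VT 39 mL, RR 36 /min, I:E = 1:1.5

phase_flow_rates(prof$pattern)          # L/min
#> inspiration  expiration
#>        3.51        2.34
womersley_number(1.0e-3, 36)            # G6 inlet, quasi-steady regime
#> [1] 0.2540095

tree <- build_centerline_tree(prof)
poiseuille_network_drop(tree, branch_flow_rate(3.51, 6))
#> Poiseuille network drop (Pa):
#>  segment generation            Q     drop
#>        1          6 9.140625e-07 2.332445
#>        2          7 4.570312e-07 1.472792
#>        ...
#> root-to-tip total: 6.89 Pa
```

The fully developed network total (6.89 Pa) is the analytic lower bound
the flow solve is compared against. A full study —

```r
report <- run_study(study_config(cells_per_dmin = 8))
```

— solves all six age/phase cases (about 215 000 tetrahedra each; a few
minutes per case on one CPU) and returns the headline table. With
that configuration the maximum velocity magnitudes are 2.19 / 1.75 / 1.36
m/s during inspiration and 1.52 / 1.14 / 0.90 m/s during expiration for
infant / child / adult, all within 4 % of the published reference values
(2.22 / 1.82 / 1.41 and 1.49 / 1.12 / 0.89 m/s), with the maximum located
in G6 in every case, and every age-ordering property (velocity, pressure
drop and wall shear stress decreasing from infant to adult in both phases)
holds. Computed inlet-to-outlet pressure drops are a near-constant 0.60 of
the published values across all six cases — a systematic geometry-model
difference discussed in the methods vignette (`vignettes/methods.Rmd`).

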