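---
title: "Modelling endovenous radiofrequency ablation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling endovenous radiofrequency ablation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Endovenous radiofrequency ablation (RFA) closes an incompetent superficial
vein (typically the great or small saphenous vein) by heating it from
inside: a catheter-mounted electrode is held at a controlled surface
temperature of 358 K (85 °C) and withdrawn slowly along the vessel while
the surrounding blood and the vein wall absorb heat.  Whether the wall
reaches damaging temperatures — above about 313 K (40 °C) tissue damage
begins, above 323 K (50 °C) it is irreversible — depends on the competition
between conduction from the electrode and convective cooling by whatever
blood still flows through the lumen.  `rfavein` simulates this
configuration and reports the quantities a treatment planner cares about:
the peak temperature on the blood–wall interface, where along the vessel
it occurs, how much of the domain is thermally influenced, and how much
energy the wall has absorbed.

## Model

**Geometry.** A straight cylindrical lumen of radius $R = 1.5$ mm and
length 60 mm, wrapped by a homogeneous 0.4 mm wall; a coaxial electrode of
radius 0.2 mm and length $L = 10$ mm whose inlet-side end starts 20 mm
from the inlet.  Because the electrode is centred ("in the middle of the
lumen") the configuration is rotationally symmetric, and the package uses
a 2-D axisymmetric $(r, z)$ reduction of the 3-D problem.  Venous valve
leaflets and wall compliance are outside scope; the wall is rigid.

**Flow.** Incompressible laminar flow (Reynolds numbers for all studied
inlet velocities are far below 2300),

$$\nabla\cdot\vec u = 0, \qquad
\rho_b\left(\partial_t \vec u + \vec u\cdot\nabla\vec u\right)
  = -\nabla p + \nabla\cdot(\mu\nabla\vec u),$$

with blood as a generalized Newtonian fluid under the Carreau–Yasuda
shear-thinning law

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
  \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a},$$

with $\mu_\infty = 0.0035$, $\mu_0 = 0.16$ kg/(m·s), $n = 0.2128$,
$a = 0.64$, $\lambda = 8.2$ s, and
$\dot\gamma = \sqrt{2\,D\!:\!D}$ from the axisymmetric strain-rate tensor.
Boundary conditions: uniform axial velocity $U$ at the inlet, no slip on
the vessel wall, traction-free outflow, axis symmetry, and the electrode
surface moving at the pullback velocity $-V\hat z$ — so even in stagnant
blood the withdrawal itself stirs the lumen.  When $U = 0$ the inlet is a
closed free-slip plane so that the moving electrode can displace fluid
through the outlet.

**Heat.** A single conjugate temperature field over lumen and wall obeys
an advection–diffusion (bioheat) balance,

$$\partial_t T + \vec u\cdot\nabla T =
  \frac{K}{\rho C_p}\nabla^2 T + \frac{Q_{RF}}{\rho C_p},$$

with region-wise properties: blood values ($\rho_b = 1050$ kg/m³,
$C_{pb} = 3820$ J/(kg·K), $K_b = 0.492$ W/(m·K)) in the lumen and wall
values ($\rho_w = 1120$, $C_{pw} = 3780$, $K_w = 0.56$) in the wall — this
is what conjugate heat transfer means here, with temperature and normal
flux continuous at the interface.  The electrode surface is an isothermal
heat source: its occupied cells are Dirichlet at 358 K, and consequently
$Q_{RF} \equiv 0$ in the tissue (the field retains a configurable
volumetric term, defaulted to zero).  Inflowing blood carries body
temperature 309.15 K (36 °C); the outer wall surface, the outlet and (for
$U = 0$) the inlet are adiabatic.  Perfusion and metabolic sources are
neglected, properties are temperature-independent, and the flow does not
feel the temperature (one-way coupling).  Since the electrode is capped at
358 K < 373 K no boiling model is needed.

## Discretization and solvers

* **Mesh.** Structured axisymmetric finite volumes, cell-centred scalars,
  staggered (face) velocities.  Radial faces are pinned exactly to the
  electrode radius and to the lumen–wall interface; spacing is uniform
  within each band.  The reference resolution is `nr = 38`, `nz = 240`
  (0.05 mm radial, 0.25 mm axial — the electrode length and start position
  are exact multiples), chosen so that halving both the spacing and the
  time step moves the peak interfacial temperature by less than 0.5 K
  (the mesh-independence test in the suite).
* **Moving electrode.** Blocked cells on the fixed grid (an immersed
  boundary): cells whose centre lies inside the electrode are solid for
  the flow and Dirichlet for the heat equation, with half-cell links from
  the neighbouring fluid to the true interface radius so no-slip and the
  surface temperature act at the physical surface.  The mask is half-open
  in $z$, so its cell count is constant during pullback up to one axial
  row.  The electrode tip is a flat-ended cylinder.
* **Flow solve.** The flow is quasi-steady: with Re ≲ 36 and pullback at
  millimetres per second, the viscous relaxation time
  ($\rho R^2/\mu \sim 0.7$ s) is short against the traverse time of the
  electrode across its own length, so the momentum transient is dropped
  and the steady problem is re-solved as the electrode moves.  Momentum
  and continuity are assembled as one sparse saddle-point system
  (second-order central diffusion, first-order upwind convection with
  lagged mass fluxes, pressure anchored through a traction-free outlet
  ghost) and solved directly; discrete continuity therefore holds to
  rounding, and every cross-section carries exactly the inlet flux.  The
  shear-thinning closure iterates Picard/Oseen style with Aitken dynamic
  relaxation seeded at a factor 0.7, to a velocity residual below
  $10^{-8}$ of the inlet/pullback scale.  Consecutive solves warm-start
  from the previous field.
* **Flow refresh cadence.** The steady flow is re-solved after the mask
  has shifted by `flow_update_rows = 2` axial rows (0.5 mm of travel at
  the reference grid).  The flow pattern essentially translates with the
  electrode, and halving the cadence to every row changes the peak
  interfacial temperature by about 0.01 K while doubling the run time;
  the cadence remains a solver setting.
* **Heat step.** Operator splitting: explicit conservative first-order
  upwind advection under an advective CFL limit (default target 0.5,
  `dt_max` 5 ms), then implicit (unconditionally stable, second-order in
  space) diffusion via a cached sparse Cholesky factor that is rebuilt
  whenever the electrode mask or the step size changes.  Face
  conductivities use harmonic means, which enforces interface flux
  continuity by construction.  Both sub-steps are monotone, so the
  discrete maximum principle — temperatures confined to the hull of the
  initial and boundary values — is asserted after every step, and an
  energy audit checks each step's storage change against the boundary and
  electrode fluxes to $10^{-6}$ relative.
* **Kinematics.** Time integration proceeds in epochs bounded by mask
  changes and snapshot times, so snapshots land exactly on the requested
  times.  If pullback would carry the electrode past the inlet the run is
  truncated with a warning.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `inlet_velocity` | 0 | m/s | uniform inlet blood velocity $U$ (study values 0–40 mm/s) |
| `pullback_velocity` | 0 | m/s | electrode withdrawal speed $V$ toward the inlet (study values 1, 2 mm/s) |
| `electrode_temperature` | 358 | K | isothermal electrode surface |
| `body_temperature` | 309.15 | K | inlet, initial and reference temperature |
| `duration` | 7 | s | treatment time |
| `nr`, `nz` | 38, 240 | – | radial/axial cells (faces pinned to material interfaces) |
| `dt_max`, `cfl_limit` | 5 ms, 0.5 | – | time-step bound and advective CFL target |
| `flow_update_rows` | 2 | rows | electrode travel between quasi-steady flow re-solves |
| `influence threshold` | body + 1 K | K | defines the "thermally influenced" region |

The influenced-region threshold deserves a note: there is no standard
criterion for when a region counts as "thermally influenced", and
reported percentages are meaningless without one.  The package therefore
exposes the threshold (default a 1 K rise over body temperature) and
`influenced_sweep()` reports a whole threshold sweep, in both
volume-weighted and symmetry-plane-area-weighted forms, rather than
asserting a single number.  Damage fractions use the fixed literature
thresholds 313.15 K and 323.15 K as instantaneous exceedance volumes; no
Arrhenius or CEM43 dose model is included.

## Verification suite and what it does (not) show

`run_verification()` compares the solvers against closed forms built by
`poiseuille_fixture()`, `annular_poiseuille_fixture()`,
`conduction_fixture()` (semi-infinite erf solution),
`two_layer_fixture()` (composite-cylinder conduction, including the
interface gradient ratio $K_w/K_b$) and
`manufactured_solution_fixture()` (operator orders of accuracy: two in
space for diffusion, one for upwind advection).  Fixture tolerances (2–3 %
for profile comparisons at the test resolutions) come from the measured
convergence curves of this discretization.

These verify the numerics, not the physiology: the scenarios share the
idealizations listed above (rigid straight vessel, no valves, constant
properties, uniform inflow, isothermal electrode).  Passing tests say the
stated model is solved correctly at the stated resolutions; they do not
certify predictions for a tortuous varicose vein with pulsatile flow or
temperature-dependent tissue.

## Problem sizes used by the shipped checks

The scenario checks run at the reference resolution (9120 cells, ≤ 5 ms
steps, about two minutes per 7 s scenario on one core).  The
velocity-sweep monotonicity checks use a half-resolution grid
(`nr = 19`, `nz = 120`), where the qualitative ordering is already
grid-converged; the mesh-independence check compares that grid against
the reference on a 2 s window.  These sizes are the package's trade-off
between fidelity and a test suite that runs in minutes; nothing prevents
running finer grids through `solver_settings()`.

## Known limitations

* First-order upwind advection is diffusive; sharp thermal fronts in fast
  flow (U ≳ 20 mm/s) are smeared over a few cells.  The peak interface
  temperatures, which are conduction-dominated, are much less sensitive.
* The quasi-steady flow assumption drops the brief flow transient after
  each mask shift; at the studied velocities its thermal footprint is
  below the mesh-independence tolerance.
* The blocked-cell electrode staircases the (flat) tip by half a cell;
  fields within one cell of the surface are first-order accurate.
* Mass exchange at the moving flat ends of the electrode is represented
  by the Dirichlet cells appearing/vanishing row by row; the energy audit
  accounts for it, but the sub-cell motion is not reconstructed.
* The axisymmetric reduction cannot represent buoyant plumes or a
  non-centred catheter.
* Cells vacated by the withdrawing electrode keep their last (electrode)
  temperature as they rejoin the fluid.  A variant that reseeds them from
  the adjacent fluid ring changes the wall energy budget by about 0.01 J
  over a full scenario, so the simpler treatment is kept.
* On matched-time *total* wall energy the two pullback speeds are nearly
  tied, and the model resolves the tie in favour of the faster electrode
  (it continuously faces colder surroundings, hence a higher surface
  flux) — by a few percent, as the shipped comparison test records.  The
  slower pullback still clearly wins on every per-location measure: it
  drives the wall to higher peak temperatures and deposits roughly twice
  the energy per unit of swept vessel length.
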