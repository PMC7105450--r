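---
title: "A particle model of endothelial cell migration under flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A particle model of endothelial cell migration under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmigrate)
```

## The model

Endothelial cells (ECs) line the inner surface of blood vessels. After an
injury such as stent deployment, recovery of the monolayer depends on ECs
migrating back over the denuded wall, and the disturbed flow around stent
struts — in particular the recirculation zones downstream of them — is known
to trap migrating cells. `ecmigrate` implements a phenomenological,
particle-based model of this process.

Each cell is a particle of radius $r_\mathrm{cell} = 15\ \mu m$ on the wall
of a perfused channel. Three ingredients drive its motion:

**Contact forces.** Particles interact through a signed central force
(positive repulsive):

* a truncated Lennard-Jones 12/6 force,
  $48\,\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right]$, for
  $2 r_\mathrm{cell} \le r < r_\mathrm{cutoff}$ — attractive throughout that
  range, zero at the equilibrium distance $\sigma = 2 r_\mathrm{cell}$ and
  below $10^{-6}$ a.u. at the cutoff $4 r_\mathrm{cell}$;
* a soft-core neo-Hookean repulsion for overlapping particles
  ($r < 2 r_\mathrm{cell}$), built on the contact radius
  $a(r) = \sqrt{\tfrac{r_\mathrm{cell}}{2}(2 r_\mathrm{cell} - r)}$, which
  stays finite at full overlap (no diverging LJ core).

Forces are in arbitrary units (a.u.): the contact model is phenomenological,
its job is to keep cells in a coherent mat, attached to the substrate, and
apart from each other. An alternative contact-radius convention
$a(r) = \sqrt{r_\mathrm{cell}(2 r_\mathrm{cell} - r)}$ is selectable via
`model_params(contact_variant = "caption")`: the two conventions differ by
a factor $\sqrt 2$ in $a$ and give full-overlap repulsions of
$3.45\times10^{-4}$ vs $1.66\times10^{-3}$ a.u. Published descriptions of
this force family are not consistent between the printed formula and the
printed full-overlap value, which is why both are implemented and tested;
the printed formula is the default and nothing is silently "fixed".

**Persistent random walk.** Each cell carries a random force
$\vec F_\mathrm{rand}$ with three independent $N(0, c)$ components
($c = 9\times10^{-4}$ a.u.²), so its magnitude is Maxwell-distributed with
mean $\sqrt{8c/\pi} \approx 0.048$ a.u. The force persists: each instant it
is replaced with a fresh draw at rate $p_\mathrm{change} = 0.075$ per hour
(exponential holding times, mean $1/p_\mathrm{change} \approx 13.3$ h).
Discretely, a step of length $dt$ refreshes with probability
$1 - e^{-p_\mathrm{change} dt}$, which makes the process step-size
independent.

**Flow cue.** The local flow velocity biases the direction of migration but
not its speed. With $w(v)$ rising linearly from $w_\mathrm{min} = 0.3$ at
$v = 0$ to $w_\mathrm{max} = 0.7$ at $v_\mathrm{max} = 0.036$ m/s (constant
above), the migration direction is the blend
$\vec d = (1-w)\,\hat e_\mathrm{rand} + w\,\hat e_\mathrm{vel}$ and the
migration force is $|\vec F_\mathrm{rand}|\,\vec d/|\vec d|$ — the cue
redirects the random force without rescaling it. At zero local velocity the
walk is purely random. ROCK inhibition (a pharmacological intervention that
dampens the migration cascade's response to weak cues) is modelled solely
by lowering $w_\mathrm{min}$ from 0.3 to 0.05.

The total force on a cell adds the migration force and all pairwise contact
forces within the cutoff; motion is overdamped, $\vec v = \mu \vec F$.

## Units and the mobility constant

Lengths are in mm, time in hours, forces in a.u., and flow speeds in m/s
(flow enters only through $v/v_\mathrm{max}$ and the unit vector
$\hat e_\mathrm{vel}$, so the two systems never mix). The drag constant of
the overdamped law is not fixed by the published parameter set; we take
$\mu = 1$ mm/h per a.u. This is the unique choice under which the mean
Maxwell force magnitude (0.048 a.u.) reproduces the calibrated average
migration speed of roughly 50 µm/h, which is what makes the parameter table
self-consistent.

## Geometry, obstacles and confinement

Channels are boxes with $x$ streamwise, $y$ wall-normal, $z$ spanwise.
Three configurations are built in (`flat_channel()`, `ridged_channel()`,
`step_channel()`). Chamber dimensions are not published ("not to scale"),
so the defaults are this package's own choices, recorded in every output:
a 0.5 mm-high chamber for the flat and ridged channels (ridges 0.1 × 0.1 mm,
strut-scale), and for the backward step the same 0.5 mm inlet section whose
floor drops by 0.25 mm at the step (2 mm from the inlet). All three default
geometries therefore share a 0.5 mm inlet opening.

Wetted surfaces are covered by *obstacle elements*: fixed spheres of radius
$r_\mathrm{cell}$ on a hexagonal lattice with spacing $1\,r_\mathrm{cell}$,
interacting with cells through the same contact law (cells adhere to the
substrate and struts). Two position constraints complete the monolayer
picture:

* **Band confinement.** Cell centres stay within $3 r_\mathrm{cell}$ of the
  nearest obstacle element (ECs stay in a monolayer). This is enforced as a
  hard projection after each accepted step, not as a penalty force — the
  model restricts positions, so we restrict positions.
* **Impenetrability.** At the published scale the contact repulsion
  (soft-core maximum $\sim 3.5\times10^{-4}$ a.u.) is two orders of
  magnitude weaker than the migration force ($\sim 0.05$ a.u.), so the
  obstacle force alone cannot stop a cell from being pushed through a
  surface — with any mobility, since only the force ratio matters. Surfaces
  are therefore also geometric: after each step, centres are kept at least
  $r_\mathrm{cell}$ clear of solid regions (pushed out through the face of
  least penetration). The clearance equals the seeding height and, with the
  default parameters, is the height at which the sampled near-wall cue
  reaches $v_\mathrm{max}$.

Side walls are frictionless force walls: a purely spanwise restoring force
(`k_wall` = 10 a.u./mm, giving sub-micron equilibrium penetration) with no
tangential component, plus a hard clamp as a backstop.

Monolayers are seeded hexagonally with 60 µm ($4 r_\mathrm{cell}$) centre
spacing at $r_\mathrm{cell}$ above the floor; in the flat and ridged
scenarios the four leftmost rows are immobile anchors that keep the sheet
from drifting out of the domain.

## The flow solver

Steady flow is solved on the channel's $x$–$y$ plane and extruded across
$z$ (the chamber is narrow and spanwise variation is secondary for the
migration cue; a user-supplied field can be loaded instead via
`read_flow_field()`). The solver is a D2Q9 BGK lattice-Boltzmann scheme on
a grid with spacing $\Delta = 0.015$ mm, nodes at integer multiples of
$\Delta$, and on-node solid walls with full-way bounce-back — under this
layout the first fluid node sits $\Delta$ from the wall surface, which is
the convention behind the wall-shear-stress estimate below. The inlet
prescribes a parabolic velocity profile (imposed as an equilibrium
distribution whose density adapts to the adjacent column, so the inlet
pressure is free); the outlet copies the neighbouring column's populations
rescaled to $\rho = 1$ (zero velocity gradient at fixed pressure). Flat
channels return the analytic Poiseuille profile directly; `method = "lb"`
forces the solver for verification.

Numerical choices worth knowing:

* **Time step / relaxation.** The lattice velocity is capped at 0.05
  (Mach $\approx$ 0.09) and the relaxation time follows from the physical
  viscosity, $\tau \approx 0.52$–$0.57$. Capping the Mach number was
  preferred over fixing $\tau$ at a larger value: with $\Delta$ and the
  viscosity fixed, one cannot have both, and matching the Reynolds number
  with small compressibility error is what the migration cue cares about.
* **Convergence.** Iteration stops when the maximum relative velocity
  change per 100 steps falls below $10^{-7}$; non-convergence within the
  budget is an error that reports the residual. The default step-channel
  solve converges in roughly $2\times10^{5}$ iterations (about 2–4 minutes
  on one core).
* **Conservation.** The weakly compressible scheme conserves *mass* flux
  ($\sum \rho u_x$, constant along the channel to $\sim10^{-5}$); the bare
  velocity flux drifts by $\sim$1% with the axial density gradient. The
  solver therefore returns the lattice density for diagnostics
  (`cross_section_flux()`).
* **Effective walls.** Full-way bounce-back places the no-slip plane about
  $\Delta/2$ inside the fluid. The Poiseuille verification accounts for
  this by comparing against the flux-matched parabola between the effective
  wall planes; the profile agrees to $\ll 1\%$ in L2.

**Wall shear stress** is estimated the way the model defines it:
$\mathrm{WSS} = \nu\,|u_\mathrm{first\ node}|/\Delta$ with
$\nu = 10^{-3}$ Pa·s. With the near-wall speed at
$v_\mathrm{max} = 0.036$ m/s this gives the physiological ceiling
$10^{-3}\cdot 0.036 / (1.5\times10^{-5}) = 2.4$ Pa.

**Inflow default.** The peak inlet speed is the one for which the inlet
parabola at the first fluid node equals $v_\mathrm{max}$ — i.e. the inlet
wall operates at the 2.4 Pa ceiling. All default geometries share the
0.5 mm inlet opening, so this is a single number, 0.309 m/s; the resulting
step Reynolds number (mean inlet speed, step height) is ≈ 52, giving a
recirculation zone that reattaches ≈ 0.9 mm downstream of the step.

**Recirculation zones** are the maximal intervals where the streamwise
velocity at the first fluid node above the local floor is negative; the
downstream end of a zone is the reattachment point. Halving $\Delta$ moves
the reattachment point by less than 10% (tested), so the default grid is
adequate for zone geometry.

## Time integration

The position ODE is integrated with classical RK4 under step-doubling
control: a full step is compared with two half steps and accepted when the
largest per-cell discrepancy is below `tol_abs` = $10^{-5}$ mm; the
accepted result is the two-half-step one and the step adapts by the
standard 4th-order factor within $[10^{-5}, 0.05]$ h. The persistent random
force is frozen within a step (it is persistent by construction), while
contact forces and the flow cue are re-evaluated at substep positions.
After acceptance: solid projection, band projection, side-wall clamp, then
the random-force refresh for the elapsed step. Because the motion is
overdamped and the force field smooth on the cell scale, runs spend almost
all their time at the 0.05 h cap (≈ 480 accepted steps per 24 h).

Degenerate cases are handled explicitly: a blended direction that collapses
below $10^{-12}$ (random force exactly opposing the cue at $w = 1/2$)
triggers a resample of that cell's random force; coincident centres
(a measure-zero event) are separated by a $10^{-6} r_\mathrm{cell}$ random
perturbation before integrating.

All randomness flows through R's global RNG, seeded once per run from the
configuration; identical `(config, seed)` pairs give bit-identical
trajectories, and runs can be checkpointed and resumed through the returned
state.

## Scenarios and readouts

`run_scenario()` wires the stages together for the four built-in
experiments; durations default to 24 h (flat, ridged, ROCK) and 48 h
(step), with frames every 0.1 h. Readouts (all pure functions of the
trajectory):

* `mean_migration_speed()` — sampled path length over duration, averaged
  over mobile cells. Path-based rather than net-displacement-based: that is
  the standard readout in migration assays and the quantity the calibration
  reproduces.
* `angular_distribution()` — net-displacement angles in the substrate
  plane, 24 bins of 15° (matching the visual granularity of published rose
  plots; the exact binning is not published), with 180° = downstream. For
  ridged channels only cells starting downstream of the ridge are included
  and the origin sits 50 µm past its trailing face. Wall-normal motion is
  ignored in angles; both counts and percentages are reported.
* `axial_distribution()` — normalized streamwise density, default bin
  0.06 mm (one seeded cell spacing).
* `density_minimum_location()` — minimum of the 3-bin moving-average
  smoothed profile in a search window; ties resolve to the smallest x. In a
  completely evacuated stretch (exact zeros over many bins) this tie rule
  pins the estimate to the stretch's upstream edge — averaging the density
  profile over replicate seeds before locating the minimum reduces that
  degeneracy and is what the bundled acceptance analysis does.
* `entrapment_count()` — cells that enter a recirculation interval during
  the window and are still inside, continuously since their last entry, at
  its end.

`calibrate_p_change()` sweeps the refresh rate over a grid with replicate
seeds and tabulates speed and angular spread; it deliberately selects no
"best" value, since the in vitro reference tracks are not distributed with
the model.

## What the simulations do and do not show

The study conditions are the defaults above: Maxwell-forced persistent
walks at the published parameter set, strut-scale obstacles, near-wall flow
at the 2.4 Pa shear ceiling. Under them the model reproduces the calibrated
behaviours: a flat-channel mean speed within the 50 ± 5 µm/h calibration
band (the hard floor/band projections absorb a few µm/h of the 47.9 µm/h
free-space mean — the grand mean sits near the band's lower edge), a
strongly downstream-biased angular distribution, entrapment of cells that
cross a ridge into its recirculation zone, and — in the step chamber —
upstream migration of near-step cells with a depleted zone whose location
tracks the reattachment length. The absolute position of that density
minimum depends on the chamber dimensions and flow rate, which are not
published; with this package's defaults the reattachment point is ≈ 0.9 mm
from the step and the pooled-profile minimum lands at ≈ 0.75–0.85 mm.

Real data differ in ways the model does not attempt to capture: ECs are
flat, not spherical (published axial distributions of real cells show less
pronounced peaks); cells change phenotype and stop migrating once confluent
(after roughly 40 h in vitro), which is outside this model; proliferation
is absent; the flow is cell-free and steady. Passing tests therefore speak
to the migration rules, not to a full account of endothelial healing.

## Problem sizes

The bundled analyses are sized for a desk machine: the flat calibration
runs ≈ 360 mobile cells for 24 h (seconds to ≈ 20 s per run), the step
scenario ≈ 640 cells for 48 h plus one lattice-Boltzmann solve shared
across seeds (a few minutes in total). The statistics involved (mean speed,
density-minimum location) are insensitive to the population size at these
scales; the monolayer in the published ridged setting is a few times
larger and runs proportionally longer.
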