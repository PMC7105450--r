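# ecmigrate

Particle-based simulation of endothelial cell (EC) migration under flow.

After vascular injury — stent deployment in particular — recovery depends on
ECs migrating back over the denuded wall, and the disturbed flow around
stent struts (recirculation zones with reversed near-wall velocity) traps
migrating cells. `ecmigrate` is for computational mechanobiology work on
this process: it simulates a monolayer of ECs as adhesive particles on the
wall of a perfused channel, with a built-in channel-flow solver, end-to-end
scenario runners, and trajectory statistics matching the readouts used in
flow-chamber migration assays.

## The model

Each cell is a particle of radius $r_\mathrm{cell} = 15\,\mu m$. Cells (and
the fixed *obstacle elements* tiling the substrate, ridges and step faces)
interact through a signed central force, positive repulsive:

$$
F_\mathrm{int}(r) =
\begin{cases}
48\,\epsilon\left[\left(\frac{\sigma}{r}\right)^{12} -
  \left(\frac{\sigma}{r}\right)^{6}\right],
  & 2r_\mathrm{cell} \le r < r_\mathrm{cutoff}\\[4pt]
\dfrac{8a^3 C\,(16a^2 - 36\pi a r_\mathrm{cell} + 27\pi^2 r_\mathrm{cell}^2)}
      {3 r_\mathrm{cell}\,(4a - 3\pi r_\mathrm{cell})^2},
  & r < 2r_\mathrm{cell}\\[4pt]
0, & r \ge r_\mathrm{cutoff}
\end{cases}
$$

with $\sigma = 2r_\mathrm{cell}$, $r_\mathrm{cutoff} = 4r_\mathrm{cell}$,
and contact radius $a = \sqrt{\tfrac{r_\mathrm{cell}}{2}(2r_\mathrm{cell}-r)}$
(an alternative convention $a = \sqrt{r_\mathrm{cell}(2r_\mathrm{cell}-r)}$
is selectable; see the vignette for why both exist). Migration is a
persistent random walk biased by the local flow: each cell carries a
Maxwell-distributed random force $\vec F_\mathrm{rand}$ (components
$N(0, c)$, refreshed at rate $p_\mathrm{change} = 0.075\,h^{-1}$), the flow
weight is

$$
w(v) = \min(v/v_\mathrm{max},\,1)\,(w_\mathrm{max}-w_\mathrm{min}) + w_\mathrm{min},
$$

and the migration force preserves the random-force magnitude along the
blended direction
$\vec d = (1-w)\hat e_\mathrm{rand} + w\hat e_\mathrm{vel}$:

$$
\vec F_\mathrm{migr} = |\vec F_\mathrm{rand}|\,\frac{\vec d}{|\vec d|},
\qquad
\vec F^i_\mathrm{total} = \vec F^i_\mathrm{migr} +
  \sum_{j \in \mathrm{Nb}^i} \vec F^{ij}_\mathrm{int}.
$$

Motion is overdamped ($\vec v = \mu\vec F_\mathrm{total}$, $\mu = 1$ mm/h
per a.u.), integrated by adaptive step-doubling RK4, with cells confined to
a monolayer band within $3r_\mathrm{cell}$ of the obstacle lattice. Steady
flow comes from a D2Q9 BGK lattice-Boltzmann solver (parabolic inlet,
zero-gradient outlet, bounce-back walls) on a $\Delta = 0.015$ mm grid; the
wall-shear-stress estimate is $\nu\,v/\Delta$ at the first fluid node
(2.4 Pa at $v_\mathrm{max} = 0.036$ m/s). ROCK inhibition is modelled by
lowering $w_\mathrm{min}$ from 0.3 to 0.05.

## Worked example

```r
library(ecmigrate)

cfg <- scenario_config("flat_calibration", hours = 6, seed = 42)
res <- run_scenario(cfg)

sp <- res$stats$speed
sprintf("mean speed: %.1f +/- %.1f um/h over %d mobile cells",
        sp$mean_umh, sp$se_umh, sp$n)
#> "mean speed: 46.8 +/- 1.0 um/h over 333 mobile cells"

res$stats$angular
#> angular_histogram: 333 cells over 0.0-6.0 h (0 excluded, zero displacement)
#>   peak bin 180-195 deg: 35.1% (180 deg = downstream)

max(wall_shear_stress(res$flow, cfg$params)$wss)
#> [1] 2.4
```

The mean path speed sits in the calibrated ~50 µm/h range (the Maxwell mean
$\sqrt{8c/\pi}$ is 47.9 µm/h; monolayer confinement absorbs a little of
it), the displacement angles peak at 180° — the downstream direction — and
the near-wall flow runs at the 2.4 Pa physiological shear ceiling. The
other scenarios run the same way: `"ridged"` (three stent-strut ridges,
with entrapment statistics for the recirculation zone behind the first
ridge), `"ridged_rock"` (ROCK inhibition), and `"backward_step"` (48 h,
reporting the axial cell-density minimum downstream of the step).

A command-line interface wrapping the same functions is installed at
`exec/ecmigrate`:

```sh
ecmigrate run --scenario backward_step --seed 1 --out results/step
ecmigrate calibrate --grid 0.025,0.05,0.075,0.1 --reps 5
ecmigrate analyze --traj results/step/trajectory.csv --what axial
```

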