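---
title: "Simulating root system architecture growth around rigid obstacles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating root system architecture growth around rigid obstacles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizogrow)
```

## The model

`rhizogrow` simulates the growth of a plant root system in a thin,
vertically oriented substrate chamber (a rhizobox or petri dish observed
in 2D), coupling three components at every growth step:

1. **Unsaturated soil water flow.** The pressure head `h` (cm) obeys the
   Richards equation
   `d(theta)/dt = div(K grad(h + z)) - S` with the Van Genuchten
   retention curve
   `theta(h) = theta_r + (theta_s - theta_r) (1 + (alpha |h|)^n)^(-m)`,
   `m = 1 - 1/n`, and the Mualem-Van Genuchten conductivity
   `K = K_s Se^l (1 - (1 - Se^(1/m))^m)^2`. The default substrate
   parameters are `theta_r = 0.06`, `theta_s = 0.41`,
   `alpha = 0.03 1/cm`, `n = 2.51`, `K_s = 10.24 cm/day` with bulk
   density `rho_b = 1.2 g/cm^3`. The pore-connectivity exponent `l` is
   not constrained by the calibration data; we use the standard Mualem
   value 0.5 (configurable).

2. **Xylem water flow.** Each root segment exchanges water radially with
   the soil (`q_r = L_r (h_s - h_x)`, `J_r = 2 pi r l_seg q_r`) and
   conducts it axially toward the collar
   (`J_x = -K_x (dh_x/dl + dz/dl)`). With storage neglected the network
   is a linear resistive system; a prescribed transpiration flux at the
   collar (0.2 cm^3/day by default, a typical wheat rate) closes it.
   Defaults `K_x = 4.32e-2 cm^3/day` and `L_r = 1.73e-4 cm/day` are per
   unit segment length; the root radius (0.03 cm) is a configurable
   assumption, as no measured value is available.

3. **Architecture update.** Tips elongate by `E * dT` along a direction
   combining growth-history inertia, gravitropism, and avoidance of
   mechanically resistant substrate. The elongation rate is
   `E = E_max(age) * (1 - R_ave / (4000 + 2.33 |psi|))`, where the
   penetration resistance follows the empirical pedotransfer law
   `ln R = 0.35 log10(|psi| Se) + 0.93 rho_b + 1.26` (R in kPa, psi in
   kPa). The direction update is
   `d_new = normalize(rotate(d_old, delta') + W_g g + W_r u)`, with
   `delta'` uniform on `[-delta, +delta]` and `u` the unit vector
   opposite the resistance gradient. Calibrated weights: `W_g = 0.1`,
   `W_r = 0.45`, `delta = 35` degrees.

Laterals initiate at every multiple of the branch spacing (0.3 cm)
along a parent, insert at the branching angle (32.55 degrees) on
alternating sides, and activate after the branching delay (2.1 day).

## The obstacle contact/recovery function

Rigid obstacles are rotated rectangles treated as regions of stiff,
quasi-impermeable substrate (`rho_b = 1.4 g/cm^3`, `K_s = 5 cm/day`):
the penetration-resistance gradient then repels tips from the obstacle
without any change to the flow solver. A per-tip phase machine adds the
observed behaviour of roots that do touch an obstacle:

* **Contact (Phase 1).** When the tip comes within the contact
  threshold of the obstacle periphery at time `t0`, the geotropism
  weight is forced to 1 and the random deviation suppressed; steps that
  would enter the rectangle are projected onto the nearest edge tangent
  (forward sense preserved), so the tip slides along the obstacle and
  its growth angle `beta` equals the obstacle inclination `eta`. The
  unit step directions are averaged into `d_bar`.

* **Recovery (Phase 2).** When contact is lost at `t1`, the tip keeps a
  memory of the along-obstacle direction: the history term of the
  direction rule is replaced by `W_o(t) * H`, where `H` is `d_bar` on
  the first recovery step and the previous step direction afterwards,
  and `W_o` falls linearly from `W_oi` (default 5, calibrated) at `t1`
  to 0 at `t2 = t1 + kappa (t1 - t0)` (default `kappa = 2`,
  calibrated). The recovery duration is therefore proportional to the
  contact duration by construction. Any new contact during recovery
  restarts Phase 1.

After `t2` the normal rule resumes and gravitropism returns the tip to
vertical growth; with `W_g = 0.1` the angle to the vertical contracts
by roughly a factor `1/(1 + W_g)` per step, so `beta` is back within a
few degrees of 90 after about one extra recovery period.

### Contact threshold

The detection threshold is resolved at run time to
`max(root radius, 1.5 * smallest element edge)` (0.15 cm on the default
obstacle mesh). A threshold below ~1.5 element widths cannot work with
an element-based resistance field: the discrete gradient extends one to
two elements from the material interface and deflects approaching tips
into a sliding trajectory at a standoff distance of about one element,
so a tighter threshold never registers contact and the phase machine
stays inert. The threshold is configurable for meshes where the root
radius dominates.

## Numerical scheme and robustness

The soil solver is a node-centred finite-volume discretisation of the
structured grid (equivalent to mass-lumped bilinear finite elements)
advanced with the mass-conservative mixed-form Picard iteration. A step
is accepted only when the head increment falls below `tol_h` (1e-6 cm)
*and* the global nonlinear mass residual is below tolerance (1e-9
relative to the sink volume, with a 1e-7 cm^3 absolute floor);
otherwise the step is halved, down to `dt/64`, after which a diagnostic
error is raised. Under-relaxation with an adaptive factor and physical
head bounds guard the iteration in strongly nonlinear (near-dry)
conditions. Hydrostatic equilibrium is an exact fixed point of the
scheme, and a converged step with no-flux boundaries conserves mass to
solver tolerance.

Two regularisations matter only near depletion: conductivity and
capacity floors (1e-12 relative) keep the linear systems non-singular,
and extraction is reduced in cells drier than -15000 cm (linearly to
zero at -25000 cm), the classic stress-reduction treatment for root
uptake sinks.

Soil and xylem are coupled by sequential operator splitting once per
growth step: soil step, interpolate heads at segment midpoints, solve
the xylem network, re-assemble the uptake for the next soil step. The
uptake is handed to the soil solver in linearised form,
`S = c (h - h_x)` with `c` the radial conductance distributed over the
elements a segment crosses: evaluated implicitly, uptake self-limits as
a cell dries toward the xylem head, which keeps the coupled system
feasible even when the chamber nears exhaustion. A collar stress switch
additionally caps the collar head at -15000 cm and reduces the
transpiration flux when the demand cannot be met; in a well-watered run
the prescribed collar flux is recovered by the summed radial flows to
machine precision.

The chamber used for obstacle experiments (4.8 x 6.8 cm, 0.08 cm
element thickness) holds only ~0.9 cm^3 of plant-available water
against a demand of 0.2 cm^3/day, so multi-day coupled runs there end
in deep depletion. For obstacle *trajectory* analyses the package
therefore defaults its worked examples to a static hydrostatic soil
field: the quantities of interest (contact/recovery durations, the
`W_o` schedule, the growth-angle plateau and return) are properties of
the direction rule, and in the depleted chamber the tip's own drying
wake produces resistance-gradient noise of the same order as the
obstacle signal. Fully coupled runs remain the default everywhere else.

## Branching-delay semantics

The branching delay trait admits two readings: a lateral activates a
fixed time after the parent tip passes its branch point, or the first
lateral germinates a fixed time after the parent root itself. The trait
is *measured* the second way (germination to first branch, 2.1 day),
so the package anchors the first branch point of each root at the
parent's birth (`activation = birth + tip_delay`) and uses the
passage-based rule (`activation = passage + tip_delay`) for all later
branch points, where the two readings differ only by the time to grow
one spacing (~0.1 day). Set `first_lateral_from_birth = FALSE` for the
pure passage rule.

## The synthetic fixture generator

No tabulated tracing data accompany the growth experiments the model
emulates, so `generate_fixture()` produces the data set a tracing study
would yield: an axis elongation-versus-age table that decreases over
the first 3.5 days, a constant lateral elongation table, growth-angle
trajectories around obstacles with a plateau at the inclination and a
recovery of configured `kappa` and `W_oi` (generated by iterating the
direction rule itself), contact episode tables, and network-index time
series from a smooth parametric family. Gaussian noise of configurable
standard deviation can be superposed; with zero noise every output lies
exactly on the generating curves, which is what the calibration
recovery tests exploit. The fixtures emulate the *statistical
structure* of traced root systems, not any measured values; passing
recovery tests on them demonstrates that the estimators are consistent,
not that the biological parameter values are correct.

## Default study conditions

The default configuration grows five axes (emerging at 0, 0.5, 1, 1.5,
2 day with orientations 90, 60, 120, 45, 135 degrees from horizontal)
for 6 days in a 10 x 10 x 0.2 cm chamber meshed 40 x 40, with a growth
step of 0.05 day and the calibrated trait set. Axis elongation falls
from 2.0 to 0.4 cm/day over the table ages 0-6 day and laterals grow at
0.4 cm/day; these magnitudes are fixture choices of typical wheat
seedling rates, as the calibration data report only their shape
(decreasing axes, constant laterals). Branching is limited to second
order by default. The obstacle chamber is 4.8 x 6.8 cm with 0.08 cm
thickness, the obstacle 2 cm long, and the axis emerges 2 cm above the
obstacle centre.

Problem sizes throughout the examples and tests (40 x 40 soil meshes,
6-7 day horizons, single-obstacle runs) are chosen so a complete
analysis runs in minutes on one CPU; halving the mesh spacing changes
the one-day pressure field by progressively smaller amounts, which the
test suite asserts as a convergence trend.

## Known limitations

* The growth plane is strictly 2D (pseudo-3D only through the element
  thickness); no root overlap or out-of-plane deflection.
* Xylem capacitance, rhizosphere resistance and osmotic potentials are
  neglected; solute transport is out of scope.
* The Euclidean Steiner reference length is the minimum-spanning-tree
  2-approximation, documented as such; exact Steiner topologies are not
  searched.
* Betweenness centrality is normalized per node by the number of vertex
  pairs excluding it (`(n-1)(n-2)/2`); other normalizations exist and
  would change the absolute (not relative) values.
* The foraging area is the convex hull of the axis group's node
  coordinates; concave outlines of real systems are not represented.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config()
cfg$time$t_end <- 3
sim <- simulate_rsa(cfg)
network_indices(sim)
beta_trajectory(sim, axis = 1)[1:5, ]
```
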