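---
title: "A two-layer Cellular Potts model of tissue growth and homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer Cellular Potts model of tissue growth and homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsgrowth)
```

## The model

`pottsgrowth` simulates a planar epithelial tissue growing from a single
founder cell inside a rigid square confinement. It couples two layers that
tick on the same clock, the Monte Carlo step (MCS):

**Physical layer (Cellular Potts Model).** Each lattice site carries an
integer identity: 0 for medium, a positive id for a cell. The mechanical
energy is

$$E = \sum_{\langle i j \rangle,\; n_i \ne n_j} J(\tau_i, \tau_j)
      \;+\; \lambda \sum_\alpha \left(A_\alpha - A^T_\alpha\right)^2,$$

with contact energies $J_{cc}$ (cell–cell) and $J_{cm}$ (cell–medium,
including the confinement wall), and an area-elastic term penalising
deviations of each cell's area $A_\alpha$ from its target $A^T_\alpha$.
Interfacial pairs are counted on the 2nd-order (8-neighbour Moore)
neighbourhood, the common choice that reduces lattice anisotropy; the copy
source is drawn from the same neighbourhood. One MCS performs $L^2$
Metropolis copy attempts at temperature $k_BT$: a random site takes the
identity of a random Moore neighbour with probability 1 if the energy
falls, else $e^{-\Delta E / k_BT}$.

**Decision layer (cell-autonomous rules), once per MCS, in a fixed
order** (changing the order is a breaking change):

1. cells whose area has drained to zero are removed;
2. *extrusion*: a cell whose area is strictly below a quarter of the mean
   live-cell area is removed;
3. *apoptosis*: each live cell enters apoptosis with probability
   $P_{apo}(\rho) = p_{apo,max} / (1 + e^{-\alpha(\rho - \rho_{1/2})})$,
   where the local density $\rho$ is the sum of inverse areas of the cell
   and its touching neighbours; its target area is set to zero and the
   Potts dynamics drain it;
4. *growth*: the target area of every non-apoptotic cell grows as
   $dA^T\!/dt = G\, e^{-k\,(A - A^T)^2}$ — contact inhibition as an
   exponential shutdown of growth with the squared area deficit;
5. *G1 sizer*: a G1 cell whose area strictly exceeds its individually
   drawn threshold $A_{S,i}$ enters the S/G2/M timer phase;
6. *timer and mitosis*: after a fixed individual duration $\tau_{0,i}$ the
   cell divides along the straight line through its centroid perpendicular
   to its long axis; each daughter gets a new id, starts in G1 with target
   area equal to its own post-split area, and draws fresh thresholds.

The per-cell thresholds are Gaussian ($A_S$: mean 1377 sites, $\tau_0$:
mean 225 MCS, both 2.5% CV at the default calibration), truncated at
$\pm 3$ SD and floored (1 MCS; 25 sites) so draws can never be
nonphysical. Daughters draw fresh values rather than inheriting them.

All parameters are managed by `sim_params()`, which expresses the default
calibration through the sizer scale: $k_BT = 1.95\times10^{-4} \lambda
A_S^2$, $J_{cc} = 1.17\times10^{-4} \lambda A_S^{3/2}$, $J_{cm} =
1.96\times10^{-4} \lambda A_S^{3/2}$, $k = 1.897\times10^{5} A_S^{-2}$,
$G = 1.16\, A_S/\tau_0$, $\rho_{1/2} = 1.5015/A_S$, $\alpha = 0.968 A_S$,
$p_{apo,max} = 0.0015$ per MCS, confinement $1600 A_S$.
`rescale_params()` maps a parameter set to any other $(A_S, \tau_0)$ scale
while preserving every dimensionless group to machine precision, which is
how the desk-scale test conditions below are produced.

## Numerical choices that required judgement

### Reading the area deviation above the thermal noise floor

In equilibrium the Potts layer's area fluctuates with equipartition
variance $\sigma^2 = k_BT / 2\lambda$, i.e. $\sigma \approx 0.0099\,A_S$
at the default calibration, while the growth rule shuts down beyond
deviations of $1/\sqrt{k} \approx 0.0023\,A_S$. Fed the raw instantaneous
area, the growth rule therefore reads pure lattice noise as crowding and
an *isolated* cell grows at only $\approx 0.35\,G$ (we measured this
directly), which contradicts the model's own single-cell behaviour: early
timer-like divisions at intervals of $\tau_0$ and a G1 duration of
$(A_S - A_{birth})/G$ for uncrowded cells.

The simulation loop therefore evaluates the growth rule on the cell area
averaged over the preceding MCS, and reads only the part of the deviation
exceeding a resolution floor as crowding:
$\exp\!\left(-k\,\max(0, |A - A^T| - c)^2\right)$ with
$c = \sqrt{k_BT/2\lambda}$ (`sim_params()$crowding_floor`). The floor is
the equipartition fluctuation amplitude — a quantity derived from $k_BT$
and $\lambda$, not a free dial — and with it an isolated cell grows at
$0.99$–$1.00\,G$ (measured over 200 MCS) while crowded cells, whose
deviations are persistent and much larger than $c$, are suppressed
exactly as the bare rule dictates. `grow_target_area()` itself keeps the
bare exponential contract (`floor = 0`) so the rule can be studied in
isolation.

### Rejecting fragmenting copies exactly

A copy that removes a site from a cell may fragment it. The cheap local
test (the cell's sites within the Moore neighbourhood of the removed site
must stay mutually connected) is *sufficient* but far from necessary: at
the default temperature ($k_BT/J_{cm} \approx 10$) boundaries are rough,
cells contain internal loops, and the local test fails at essentially
every boundary site — shrinking dynamics freeze entirely and apoptotic
cells never drain (we observed zero removals over 2000 MCS). The engine
therefore uses the local test as a fast path and, when it fails, decides
with an exact flood fill over the cell; only genuinely fragmenting copies
are rejected. `connectivity_ok()` exposes the local test, and the
no-fragmentation invariant (every cell one Moore-connected component) is
asserted after every MCS in the test suite.

### Division geometry

The split line passes through the centroid perpendicular to the principal
axis of the site-coordinate second moment; degenerate moments are broken
by a uniform random orientation, exact zero projections by a fair coin.
Because a straight cut of a rough cell can strand fragments, stray
components are re-attached to an adjacent daughter (the smaller one when
both touch), so daughters are connected by construction. Division is
deferred one step while a cell has fewer than 2 sites.

### Event accounting

Each division retires the mother (`division` event) and books one `birth`
per daughter, keeping the two elimination channels (`apoptosis_removal`,
`extrusion`) separate, so the live count reconstructs exactly:
$N(t) = N(0) + \#births - \#divisions - \#removals$. An apoptotic cell
crossing the extrusion threshold is booked as `apoptosis_removal`, and the
extrusion threshold compares against the mean area of non-apoptotic cells
only. $k_{birth}$ is the division rate and $k_{elim}$ the removal rate,
both per live cell per $\tau_0$.

### Continuum companion model

The whole colony is reduced to an area $A$ relaxing at rate $\lambda$
towards a preferred area $A_0$ that grows logistically under a confinement
$A_{max}$, with the same crowding factor:
$\dot A = -\lambda (A - A_0)$,
$\dot A_0 = (G/a_0)\, e^{-k (A - A_0)^2} A_0 (1 - A_0/A_{max})$.
In scaled units ($a_0 = 1$, time in $1/\lambda$, $A_{max} = 800$) the
homeostatic fixed point is $A = A_0 = A_{max}$. Integration is fixed-step
RK4 (default $dt = 10^{-3}$, verified by step-halving to $10^{-6}$
relative); blow-ups are detected and reported rather than returned. The
continuum "tissue pressure" is $\lambda (A_0 - A)$ — single-$\lambda$
prefactor matching the relaxation term, compression-positive like the
cell-scale pressure $p_\alpha = -2\lambda (A_\alpha - A^T_\alpha)$. Only
the *trends* of the peak pressure in $(G, \lambda, k)$ are treated as
meaningful, since its absolute normalisation is a convention.

## Study conditions at desk scale

The test suite exercises the collective phenomenology at a reduced scale
chosen once: $A_S = 100$ sites, $\tau_0 = 40$ MCS, confinement
$100\,A_S$ (a $100 \times 100$ lattice), all other parameters given by the
dimensionless calibration above, three fixed seeds, runs of 1600 MCS
(apoptosis off) and 2400 MCS (apoptosis on). At this scale a colony
grows from one cell to confluence (~140 cells) in roughly $9\tau_0$ and a
full run takes seconds, which keeps the default test run within minutes
while preserving every dimensionless group.

Two desk-scale observations deserve flagging:

* **Founder extinction.** With apoptosis on, the apoptosis probability is
  small but nonzero even at low density
  ($P_{apo}(\rho \to 0) \approx 2.8\times10^{-4}$ per MCS), so the founder
  lineage occasionally dies out before the colony is established — a
  plain branching-process effect. Homeostasis phenomenology is defined
  for surviving tissues; tests condition on non-extinction by advancing
  the seed deterministically (in steps of 1000) until the tissue survives
  the run. Extinct runs remain perfectly valid simulations.
* **Elasticity range.** The growth-speeding effect of $\lambda$ is probed
  at and below the default $\lambda$. Above $\lambda \approx k_BT$ per
  site the single-site Metropolis mobility becomes the bottleneck for
  boundary motion and the trend saturates at this lattice resolution;
  within $[\lambda/4, \lambda]$ the trend is clean and monotone.
* **Plateau tolerance.** Homeostasis onset is detected as the first time
  from which windowed cell count and density stay within a relative band
  for $5\tau_0$. The band is 2% by default (appropriate for
  thousand-cell tissues); at desk scale ($N \approx 140$) turnover noise
  is a few percent, so the comparative tests use a 10% band.

What the desk-scale tests do **not** show: quantitative agreement with
full-scale trajectories (cell counts, absolute times and pressures differ
by the scale factors), pattern maps at the published lattice size, or any
fit to experimental data — the apoptosis parameters are taken as given
constants.

## Observables

`run_simulation()` samples a time series (cell count, colony area, mean
area and local density, G1 fraction, boundary vs bulk mean areas, boundary
pressure gradient) and returns the full event log, completed cycles and
G1/S transition records. On top of these, the package provides
`measure_tgrowth()` (time to fill 99% of the confinement, interpolated),
`detect_homeostasis()`, `proliferation_rates()`, `radial_profile()`,
`growth_rate_map()`, `g1_fraction()`, `cycle_statistics()` and
`boundary_pressure_gradient()` (mean pressure of the boundary-cell ring
minus its interior neighbour ring; boundary = touching medium). The colony
centre for radial profiles is the area-weighted centroid of occupied
sites, recomputed per snapshot.

## A worked run

```{r example, eval = FALSE}
p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 100 * 100,
                seed = 11, apoptosis_enabled = FALSE, t_max = 1600)
sim <- run_simulation(p)
sim
measure_tgrowth(sim$time_series, p$box_area)   # ~367 MCS = 9.2 tau0
aggregate(cycle_time ~ generation, sim$cycles, mean)
```

The run prints ~141 cells at confluence, generations 1–3 dividing every
40–43 MCS (timer-like, $\tau_0 = 40$), then G1 arrest of the whole
tissue with birth and elimination rates exactly zero — the arrested
homeostatic state. With `apoptosis_enabled = TRUE` the same conditions
give a dynamic homeostasis with $k_{birth} \approx k_{elim} \approx 0.06$
per cell per $\tau_0$.

## Known limitations

* Cell motility is deliberately absent; the physical layer has no
  surface-area constraint or chemotaxis.
* The decision layer ticks once per MCS; the absolute homeostatic
  turnover timescale (but not its $A_S$-dependence) is tied to that
  convention.
* The interfacial neighbourhood order is a convention (Moore); the
  published energy scalings may implicitly assume a different one, so
  quantitative boundary-tension calibration should revisit it.
* At $k_BT \gg J$ cell boundaries are rough; pixel-level cell shapes
  should not be over-interpreted at desk scale.
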