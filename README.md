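# pottsgrowth

Cell proliferation in a dense tissue is not a property of single cells
alone: crowding suppresses growth, compression triggers apoptosis and
extrusion, and the balance of these feedbacks sets how fast a colony
fills its niche and what it looks like once it has. `pottsgrowth` is an R
implementation of a two-layer cell-based model of a growing planar
epithelium for studying exactly these couplings — aimed at quantitative
biologists and biophysicists who want a scriptable, fully deterministic
simulator with the analysis observables built in.

## The model in one paragraph

A **Cellular Potts Model** supplies the physics: lattice sites carry cell
identities, the energy

E = Σ_(neighbour pairs, n_i ≠ n_j) J(τ_i, τ_j) + λ Σ_α (A_α − A_α^T)²

combines interfacial tension/adhesion (J_cc ≤ J_cm) with an area-elastic
penalty, and Metropolis–Hastings copy dynamics at temperature k_BT evolve
cell shapes (one Monte Carlo step = L² copy attempts). A **decision
layer** runs once per MCS: target areas grow at rate G·exp(−k(A−A^T)²)
(contact inhibition of proliferation), a **G1 sizer** (area must exceed an
individually drawn threshold A_S) gates entry to a fixed-duration
**S/G2/M timer** τ₀ after which the cell divides perpendicular to its
long axis, apoptosis strikes with the density-dependent probability
p_apo,max / (1 + exp(−α(ρ − ρ_1/2))) and drains the cell, and live cells
below a quarter of the mean area are extruded. Cell pressure is
p_α = −2λ(A_α − A_α^T). A zero-dimensional **continuum companion model**
(area A relaxing to a logistically growing preferred area A₀ under the
same crowding factor) reproduces the colony-scale growth trends. The
default calibration: k_BT = 1.95e−4·λA_S², J_cc = 1.17e−4·λA_S^1.5,
J_cm = 1.96e−4·λA_S^1.5, k = 1.897e5·A_S⁻², G·τ₀ = 1.16·A_S,
τ₀ = 225 ± 5.625 MCS, A_S = 1377 ± 34.4 sites, p_apo,max = 0.0015,
ρ_1/2 = 1.5015/A_S, α = 0.968·A_S, confinement 1600·A_S.

## A worked example

Grow a colony from a single founder cell at desk scale — sizer 100 sites,
timer 40 MCS, a 100 × 100 box, every dimensionless group at its default
value — without apoptosis:

```r
library(pottsgrowth)
p <- sim_params(As_mean = 100, tau0_mean = 40, box_area = 100 * 100,
                seed = 11, apoptosis_enabled = FALSE, t_max = 1600)
sim <- run_simulation(p)
sim
#> Potts tissue simulation: 1600 MCS on a 100 x 100 lattice (seed 11)
#>   final: N = 151 cells, colony area = 9995 sites (100.0% of box), G1 fraction = 1.00
#>   events: 151 divisions, 0 apoptoses started, 1 extrusions

measure_tgrowth(sim$time_series, p$box_area)
#> [1] 327.4
head(aggregate(cycle_time ~ generation, sim$cycles, mean), 5)
#>   generation cycle_time
#> 1          0    58.0000
#> 2          1    40.0000
#> 3          2    42.2500
#> 4          3    40.6250
#> 5          4    40.5625
```

Reading the output: the colony fills its confinement after ~327 MCS
(about 8 τ₀). The founder's cycle lasts 58 MCS — the G1 growth from 50
sites to the ~100-site sizer threshold at rate G = 2.9 sites/MCS plus the
40-MCS timer — while the next generations are born above threshold and
divide at timer-like τ₀ intervals (40–42 MCS). After confluence every
cell is arrested in G1 (`G1 fraction = 1.00`) and the birth and
elimination rates are exactly zero: the arrested homeostatic state.
Setting `apoptosis_enabled = TRUE` instead yields a dynamic homeostasis
with matching, non-zero birth and elimination rates (~0.06 per cell per
τ₀) and continuous turnover.

Other entry points: `run_sweep()` (one- or multi-factor parameter sweeps
with stable derived seeds), `integrate_continuum()` /
`continuum_tgrowth()` / `continuum_max_pressure()` for the continuum
model, `radial_profile()`, `boundary_pressure_gradient()`,
`cycle_statistics()`, `detect_homeostasis()` for analysis, and
`make_fixture()` for small deterministic test tissues. A thin CLI wrapper
lives at `inst/scripts/potts_sim.R`
(`simulate --config FILE --out DIR [--seed N] [--no-apoptosis]`,
`sweep`, `continuum`); packaged configurations are in `inst/extdata/`.

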