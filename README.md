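# bioprintCA

A 3D cellular-automaton model of how tumour cells behave *after* they have
been bioprinted inside a porous gelatin/alginate scaffold. The package is
aimed at tissue-engineering and mathematical-oncology groups who want to
explore post-printing proliferation, quiescence, death and aggregate
formation in silico — e.g. to choose a seeding density or bioink
formulation — instead of repeating 11-day culture experiments.

## Model in brief

Cells live on a `190 × 190 × 30` lattice with four `50 × 50 × 30` pore
channels that stay cell-free. Each cell carries a stochastic doubling time
`T ~ N(μ = 96 h, σ = 6 h)` and evolves in 1 h steps for 11 days:

* **Division** — when the cycle clock reaches `T`, a daughter is placed
  uniformly on the nearest vacant Moore shell (orders 1–3). At carrying
  capacity `C` the attempt aborts with probability `P₀` and the parent
  enters G0; with no vacancy it enters G0 directly.
* **Quiescence / death** — a quiescent cell may re-enter the cycle with
  probability `1 − P₀` per hour while its G0 spell is below its personal
  threshold `C_d ~ U[cd_min, cd_max]`; past the threshold quiescence is
  terminal and the cell dies with probability `P_d` per hour. Dead cells
  keep their lattice site.
* **Movement** — every `m_c` hours (+ jitter) a cell steps to one of six
  axis neighbours with probabilities ∝ `1 + α·N_i + β·Φ_i`, where `N_i`
  counts live cells within Chebyshev range `L_c` in direction *i* and
  `Φ_i = max(0, 1 − d/L_p)` points toward the nearest pore at distance
  `d ≤ L_p`. With `α = β = 0` this is exactly the 1/6 random walk.

Simulated assay analogues: MTT fold = `live(t)/live(0)`; viability =
`live/(live+dead)`; Ki-67 fraction = `proliferative/live`; plus 26-connected
voxel cluster statistics. Free parameters are calibrated to the packaged
in-vitro time courses by inverse-variance weighted least squares over a
seeded Latin-hypercube search with local refinement. Two held-out
validation scenarios change exactly one knob each: `case1` sets
`C_initial = 2000` (lower seeding density), `case2` sets `m_c = 20 h`
(stiffer 4%/5% bioink).

## Worked example

```r
library(bioprintCA)

p <- sim_params(seed = 42)   # calibrated base case
p
#> <ca_params>
#>   C_initial 3338 | C 9836 | P0 0.9896 | Cd [71, 109] h | Pd 0.0164
#>   doubling N(96, 6) h | m_c 15 h (+U{0..4}) | biased movement
#>   L_c 3 | L_p 10 | alpha 0.07 | beta 0.52 | horizon 264 h | seed 42

sim <- run_simulation(p)     # ~1.5 s; default 190x190x30 four-pore lattice
sim
#> <ca_sim> 264 h | live 9836 (P 4682 / Q 5154) | dead 193 | seed 42

ts <- sim$timeseries
fold_proliferation(ts, c(96, 168, 240, 264))
#> 2.03 / 2.95 / 2.96 / 2.95        # fold at days 4/7/10/11
viable_fraction(ts, 264)           # 0.981
proliferating_fraction(ts, 264)    # 0.476

cs <- cluster_stats(sim$snapshots$h264, sim$scaffold)
cs$n_clusters                      # 7592 clusters, largest 15 sites
```

Reading: from 3,338 seeded cells the population reaches the carrying
capacity (fold ≈ 2.9, plateau from day 7), 98% of cells are still alive on
day 11 while only ~48% are still cycling — the same qualitative picture as
the wet-lab assays (rapid growth to day 7, near-constant live counts with
falling Ki-67 afterwards). Ensembles, calibration and scenarios:

```r
ens <- run_ensemble(p, 100)                       # mean ± SD time courses
cal <- calibrate_model(in_vitro_base(), budget = 200, seed = 1)
sc1 <- run_scenario(cal$params, "case1", n_runs = 10)  # C_initial = 2000
```

A CLI covering the same operations ships in `inst/exec/bioprintca`
(`simulate`, `ensemble`, `calibrate`, `scenario`, `consistency`,
`clusters`), reading JSON configs and writing CSV/JSON/multi-page-TIFF
outputs with a checksum manifest.

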