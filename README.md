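# rhizograd

Nutrient gradients around single plant roots: a radially symmetric 1D
transport model of the rhizosphere, and the image-analysis statistic used to
measure such gradients in micro-X-ray fluorescence (µ-XRF) element maps.

Roots change the soil around them. When root uptake is slower than resupply
by mass flow, nutrients accumulate at the root surface (Ca, S in fertilized
substrates); when uptake outruns soil supply, they are depleted (P). This
package is for soil and rhizosphere scientists who want to simulate those
gradients mechanistically, compare them with element maps of root-soil thin
sections, and reproduce both analyses end to end. It implements:

* **Transport model** — for pore-water concentration `c(r, t)` around a
  cylindrical root of radius `a`:

  ```
  (θ + b) ∂c/∂t = (1/r) ∂/∂r ( r De ∂c/∂r + a Jw(t) c ) − Q_hair − k M²
  ```

  with linear instantaneous sorption (buffer power `b`), effective diffusion
  `De = D·θ·f`, a diurnally varying water flux `Jw(t)`, Michaelis–Menten
  uptake `Fm·c/(Km + c)` at the root surface, a homogenized root-hair sink
  `Q_hair = (L/l)(2π a_h/l²)·Fmh·c/(Kmh + c)` active in the hair zone for
  the 2-day hair lifetime, and irreversible CaSO₄ precipitation at rate
  `k·M²` where `M = max(min(c_Ca − √Ksp, c_S − √Ksp), 0)` couples the Ca
  and S balances 1:1. Parameters for maize in two substrates (loam, sand)
  ship as plain-text tables in `inst/extdata/`.

* **Scenario matrix and model extent** — the 12-scenario factorial
  (2 substrates × 7-day root tips / 21-day primaries × hairy-full,
  hairy-half, hairless), with the rhizosphere extent defined as the
  outermost radius where the mapped profile (sorbed + precipitated for
  Ca/S, sorbed for P) deviates from bulk by more than 0.8 µmol cm⁻³.

* **µ-XRF radial profiling** — Euclidean distance transform of a root mask,
  distance-binned weighted count profiles with pore exclusion, weighted
  bulk statistics from 1 mm outward, and the bulk ± 2 SD extent rule with a
  deterministic persistence criterion and an ambiguity flag for undulating
  profiles.

* **Synthetic map generator** — seeded µ-XRF-like count maps (grainy "sand"
  with shell-ordered packing around the root, fine-textured "loam"), known
  enrichment envelopes, patchy deposition at pore contacts, Poisson noise,
  and ground-truth records, so the imaging stage is fully testable without
  experimental data.

## Worked example

Simulate a hair-bearing maize root tip in loam for 7 days and measure its
rhizosphere:

```r
library(rhizograd)

sim <- run_simulation(scenario("loam", "tip", "WT-full"))
print(sim)
#> rhizosphere simulation 'loam_tip_WT-full_7d': 300 cells, 7 d, a = 0.0095 cm
#>   cumulative uptake (mol/cm): Ca 1.39e-05, S 1.41e-06, P 2.81e-08
#>   max mass-balance residual: 4.20e-10

sim_extent(sim, "Ca")
#> rhizosphere extent: 10332 um (depletion) [outer-boundary artifact excluded]
sim_extent(sim, "P")
#> rhizosphere extent: 515 um (depletion)
```

The hair sink around this thin tip is strong enough that Ca is *depleted*
at the root surface despite mass-flow delivery — the hair-driven halo
reaches about 1 cm at the 0.8 µmol cm⁻³ threshold. P is depleted in every
scenario; here its depletion zone spans ~0.5 mm. The mass-balance residual
audits inventory + cumulative uptake − boundary influx against the initial
inventory.

On the imaging side, generate a synthetic sand map with a 300 µm
exponential enrichment envelope and profile it:

```r
sm   <- generate_map(map_recipe("sand", extent_um = 300, seed = 42))
prof <- radial_profile(sm$map, sm$distance, sm$pore)
bs   <- bulk_stats(prof)          # weighted bulk from 1 mm outward
#> bulk: 50.1 +/- 0.37 counts
extent_estimate(prof, bs, "accumulation")
#> radial-profile extent: 1145 um (accumulation, cutoff 50.84) [ambiguous: 14 crossings]
```

Two things this shows deliberately: for an exponential envelope the 2 SD
rule detects where the enrichment sinks into the bulk band — analytically
`E·log(amplitude/2SD) ≈ 1110` µm here, not `E` itself — and the grain
shells of the sand style imprint an undulating profile that crosses the
band many times, which the estimator reports via the ambiguity flag instead
of resolving silently (step envelopes recover `E` itself within one bin;
see the test suite).

The full factorial matrix with per-nutrient extent ranges:

```r
run <- run_scenarios()            # ~30 s
summarize_extents(run)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/rhizograd` (subcommands `simulate`, `scenarios`, `profile`,
`synth`, `report`).

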