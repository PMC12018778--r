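---
title: "Modelling nutrient gradients around single roots and measuring them in element maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutrient gradients around single roots and measuring them in element maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizograd)
```

# The problem

Roots change the soil chemistry around them. Nutrients whose root uptake is
slower than their resupply by mass flow accumulate at the root surface
(calcium, sulphur in fertilized substrates); nutrients whose uptake outruns
soil supply are depleted (phosphorus in almost any soil). The volume over
which these gradients extend — the rhizosphere — depends on root radius,
root age, root hairs and the soil's buffering, and can be probed
experimentally by micro-X-ray fluorescence (µ-XRF) element mapping of
resin-embedded soil-root sections. `rhizograd` implements both halves of
that comparison:

* a radially symmetric 1D transport model of Ca, S and P dynamics around a
  single maize root (sorption, Michaelis–Menten uptake, a homogenized
  root-hair sink, irreversible gypsum precipitation, diurnally varying water
  flux), with a factorial scenario matrix and a threshold-based rhizosphere
  extent; and
* the experimental statistic: Euclidean-distance-transform radial profiles
  of 2D element-count maps with pore exclusion and a weighted bulk + 2 SD
  extent rule, together with a seeded synthetic map generator that provides
  ground truth for testing it.

# The transport model

For each nutrient the pore-water concentration $c(r,t)$ (mol cm⁻³ solution)
around a root of radius $a$ obeys

$$(\theta + b)\,\partial_t c \;=\; \frac{1}{r}\,\partial_r\!\left(r\,D_e\,
\partial_r c + a\,J_w(t)\,c\right) \;-\; Q_{rh} \;-\; k M^2,$$

with effective diffusion $D_e = D\,\theta f$ ($f = 0.3$), buffer power $b$
(the dimensionless solid:solution partition coefficient; sorption is linear
and instantaneous), and the water flux $a J_w(t)/r$ imposed by continuity
from the flux $J_w$ at the root surface. The boundary conditions are
Michaelis–Menten uptake at the root surface,

$$D_e\,\partial_r c + J_w c \;=\; \frac{F_m\,c}{K_m + c}
\quad\text{at } r = a,$$

and a Dirichlet condition $c = c_{pw,ini}$ at the outer radius
$R_{out} = 6$ cm, far enough that root-driven gradients never reach it
within 21 days. Initial pore-water concentrations derive from measured
totals by $c_{pw,ini} = c_{tot,ini}/(\theta + b)$
(`pore_water_init()`), and the diurnal water flux is
$J_w(t) = J_{w,daily}(\sin(2\pi t/24 - \pi/2) + 1)$ — zero at midnight,
twice the mean at noon (`water_flux_at()`).

**Gypsum precipitation.** Ca and S are advanced as a coupled pair. Where
both pore-water concentrations exceed $\sqrt{K_{sp}}$ (4.9 mM, i.e.
4.9 µmol cm⁻³ of solution), CaSO₄ precipitates at rate $kM^2$ with
$M = \max(\min(c_{Ca} - \sqrt{K_{sp}},\, c_S - \sqrt{K_{sp}}),\, 0)$; the
deposit is an immobile, irreversibly growing per-cell pool that removes Ca
and S 1:1. With the packaged initial concentrations *both* substrates start
mildly supersaturated, so a small uniform precipitation transient runs
through the whole domain during the first day or two. Two consequences
matter for extent evaluation and are discussed below.

**Root hairs.** Hair uptake is homogenized into a volumetric sink active in
the hair zone ($r - a < l_{rh}$), while the hairs are functional
($t < 2$ d), on hair-bearing genotypes only:

$$Q_{rh} = \frac{L}{l}\,\frac{2\pi a_h}{l^2}\,\frac{F_{mh}\,c}{K_{mh}+c},$$

where $a_h$ is the hair radius, $l$ the mean spacing between hairs, and
$L = 1$ cm the characteristic root length of the homogenization. The
hairless mutant (rth3) is modelled by switching this sink off; wild type
runs use $F_{mh} = F_m$ or $F_{mh} = F_m/2$.

## The hair-spacing choice

The spacing $l$ admits two readings that differ by two orders of magnitude
in sink strength, and the choice decides qualitative outcomes:

* `"root-surface"`: $l = \sqrt{2\pi a_{root}/N}$ — the square root of the
  root surface area associated with one hair ($N$ hairs per cm root). This
  gives a weak, radius-dependent sink (volumetric coefficient
  $\propto a_{root}^{-3/2}$; about 365 cm⁻¹ at a 95 µm tip, 30 cm⁻¹ at a
  0.5 mm primary). Under this reading hair uptake never outruns resupply:
  hair-bearing tips in loam still show Ca/S *accumulation*.
* `"hair-radius"` (default): $l = \sqrt{2\pi a_h/N} \approx 39$ µm — the
  literal form of the published spacing formula. The sink coefficient
  ($\approx 4.2\times 10^4$ cm⁻¹, radius-independent) is strong enough to
  locally exhaust Ca and S in the hair zone within hours, so hair-bearing
  tips in loam show net *depletion* at the surface and a wide (≈ 1 cm)
  perturbation halo — the behaviour reported for this system, with tip
  extents of the expected magnitude.

Only the second reading reproduces the documented sign pattern
(accumulation everywhere except hair-bearing loam tips), so it is the
packaged default; `rg_parameters(hair_spacing_mode = "root-surface")`
selects the other. Note the default also perturbs 0.5 mm primaries
noticeably at the deviation-threshold level, which widens the simulated Ca
extent range upward relative to a sink that weakens with root radius.

# Numerics

The solver (`run_simulation()`) uses a conservative finite-volume
discretization on a geometrically graded grid (default 300 cells from the
root surface to 6 cm; innermost cell 2.5 µm), central face averaging for
the advective term (cell Péclet numbers are far below 1 at these water
fluxes), and stiff implicit integration with `deSolve`'s `lsodes`
(relative tolerance 1e-8, absolute 1e-14 mol cm⁻³). Three choices are worth
recording:

* **State ordering.** The coupled Ca/S/pool states are interleaved by cell,
  which keeps the Jacobian tightly banded; block ordering by species makes
  the sparse solver orders of magnitude slower on the strong-hair-sink
  runs.
* **Clipping.** Transport fluxes act on the raw states; only the reaction
  terms (uptake, hair sink, supersaturation) see concentrations clipped at
  zero. Clipping the transported states introduces kinks at zero exactly
  where the hair sink pins phosphorus, collapsing the integrator step size
  (two orders of magnitude slower) and breaking strict conservation.
* **Event handling.** Integration is split at the hair-lifetime switch
  (2 d) so the sink turns off at a segment boundary rather than as a
  discontinuity inside the integrator.

Mass balance is auditable exactly: cumulative root uptake, hair uptake and
outer-boundary influx are carried as appended integral states, and
`mass_balance()` checks inventory + uptake − influx against the initial
inventory (residuals are ~1e-10 or better; the packaged test bound is
1e-3). An independent explicit forward-Euler scheme on a uniform fine grid
(in the test suite) agrees with the implicit solver to well under 1% in
L∞ over the interior.

# Model-side rhizosphere extent

`sim_extent()` maps the final profile to what an element map would see —
sorbed + precipitated per soil volume for Ca and S ($b\,c + p$), sorbed for
P ($b\,c$) — and measures the outermost radius where the mapped profile
deviates from bulk by more than 0.8 µmol cm⁻³, linearly interpolated at
the crossing (`model_extent()`).

Two definitional details follow from the domain-wide precipitation
transient:

* **Bulk reference.** The initial mapped value is *not* a valid bulk
  reference: the uniform precipitation transient shifts the sorbed +
  precipitated bulk by ≈ +0.3 µmol cm⁻³ in loam and ≈ +1.1 µmol cm⁻³ in
  sand — in sand more than the threshold, which would label the entire
  domain rhizosphere. The default reference is therefore the profile's own
  far-field plateau at the evaluation time (its value at $0.75\,R_{out}$);
  `reference = "initial"` is available for comparison.
* **Outer boundary artifact.** The outer Dirichlet condition pins the
  supersaturated initial concentration at the boundary, which feeds a
  millimetre-scale reaction layer whose precipitated pool grows for the
  whole simulation. A contiguous threshold-exceedance region attached to
  the outer boundary is therefore excluded from the extent and flagged
  (`boundary_artifact`), so only the root-attached deviation zone counts.

The factorial matrix (`scenario_matrix()`: loam/sand × 7-day tips /
21-day primaries × hairy full, hairy half, hairless = 12 core scenarios,
plus four optional age-swapped extras) runs in about half a minute
(`run_scenarios()`), and `summarize_extents()` reports per-nutrient ranges.
With the packaged defaults the simulated ranges are roughly Ca 360–14000,
S 360–3900 and P 310–1600 µm; P is depleted in every scenario and Ca/S
accumulate everywhere except around hair-bearing loam tips. Extents at the
low end are threshold crossings of near-cancelling profiles (hair removal
versus advective accumulation at sand tips), which makes them very
sensitive to the hair-sink strength; this is the main source of
disagreement between alternative hair-spacing readings.

# The imaging statistic

For a 2D element map with a binary root mask and (optionally) a pore mask:

1. `distance_map()` — Euclidean distance transform of the root mask,
   scaled to µm (20 µm pixels by default).
2. `radial_profile()` — per-bin (half-open bins `[k·w, (k+1)·w)`, default
   width = pixel size) mean and population SD of counts over evaluable
   pixels (neither root nor pore), with the evaluable pixel count as the
   bin weight.
3. `bulk_stats()` — frequency-weighted mean and SD of the bin means over
   all bins from 1 mm outward: the operative definition of bulk soil.
4. `extent_estimate()` — the cutoff is bulk mean ± 2 SD. Scanning outward,
   a crossing is a transition from outside the band back inside,
   interpolated between bin centers; the estimate is the *first* crossing
   after which the profile stays inside the band for at least 5 consecutive
   evaluable bins. Undulating profiles (granular substrates) produce
   several candidate crossings; they set the `ambiguous` flag rather than
   being resolved by hand.

A caveat worth stating explicitly: with counting noise, bins just outside
the enrichment zone sit at smaller radii (fewer pixels, larger standard
error) than the bulk bins that set the cutoff, so isolated spurious
excursions beyond ±2 SD are expected at the percent level per bin no matter
how strong the signal — this is a geometric property of the rule, not of
the implementation, and it is why the persistence rule prefers the first
rather than the outermost qualifying crossing.

# Synthetic maps and what they do (not) show

`generate_map()` produces seeded, reproducible µ-XRF-like count maps with
known ground truth: a central root disc; either a fine-textured matrix with
sparse pores and a smooth multiplicative texture field ("loam") or
well-sorted grains packed in angle- and radius-jittered concentric shells
around the root ("sand" — shell ordering against a wall is what imprints
the undulating radial porosity pattern of granular substrates, which is why
shells are used instead of random sequential packing); an enrichment
deposited on matrix pixels with a known radial envelope (exponential or
step, extent `E`), optionally concentrated at pore-contact pixels while
preserving each distance bin's mass exactly; and finally Poisson counting
noise.

The generator emulates the *statistical geometry* the profiling stage
consumes — distance distributions, pore exclusion, patchiness, undulation,
count noise — not the physics of X-ray fluorescence (no matrix effects, no
screening, no detector response). Ground-truth recovery is therefore
validated in the generator's noiseless (high signal-to-noise) limit, where
seeds still vary the pore geometry and patch placement: there the injected
step extent is recovered within one bin across all seeds and extents
tested. With Poisson noise enabled the 2 SD rule keeps its percent-level
per-bin false-excursion rate (see above), as it does on real maps; passing
the noiseless recovery test shows the pipeline is correct, not that the
rule is noise-proof.

The per-substrate root radii, hair lengths and densities, water contents,
buffer powers and initial concentrations packaged in `inst/extdata/` are
the measured/literature values for the maize-in-loam/sand system the model
targets; the synthetic map defaults (20 µm pixels, 4 mm half-width field of
view, 100 µm grains, background ≈ 50 counts) match the imaging setup's
scale. Problem sizes used in the packaged tests — 300-cell grids for the
factorial matrix, 80–250 cells for property checks, 301-pixel maps for
recovery — were chosen so the full suite documents the science at
interactive run times.

# Known limitations

* The model is a 1D continuum: pore-scale localization (precipitation at
  grain contacts), root growth, co-precipitation with carbonates, gypsum
  re-dissolution and water-flow dynamics are out of scope; the water flux
  is prescribed, not solved.
* The supersaturated initial condition makes the outer Dirichlet boundary
  slightly inconsistent (it keeps feeding the precipitation reaction); the
  extent logic works around it as described, but inventories near the
  boundary should not be interpreted physically.
* The two readings of the hair-spacing formula bracket, but do not pin
  down, the true hair sink; conclusions that hinge on absolute hair-zone
  uptake should be checked under both (`hair_spacing_mode`).
* The experimental extents of the system this model targets were obtained
  with manual cutoff choices on undulating profiles; the deterministic
  persistence rule here is reproducible but not identical to expert
  judgement, and flags rather than resolves genuinely ambiguous profiles.
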