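---
title: "Methods: habitat-driven active dispersal of juvenile sea turtles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-driven active dispersal of juvenile sea turtles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stamm)
```

## The model

`stamm` simulates each juvenile as a discrete agent advancing one day at a
time. Its ground velocity is the sum of the local surface current and its
own swimming velocity. Swimming speed is `Vm(a) * (1 - h)`: individuals
sprint through poor habitat and idle in good habitat, where `Vm` is the
maximum sustainable speed — the speed minimising energy per unit distance —
whose size dependence `Vm = v0 * L^0.126` follows from metabolic-rate
scaling (`RMR ~ M^0.831`) combined with the length–mass allometry
(`M = 112.31 L^2.86`). Headings are drawn from a von Mises distribution
whose mean is the direction of the habitat gradient and whose concentration
is `kappa = alpha * ||grad h||`: flat habitat yields an isotropic random
walk, steep gradients near-deterministic taxis.

Habitat suitability is the product of a thermal and a feeding index. The
thermal index equals 1 between the pivotal temperatures `T2` and `T3` and
decays as a Gaussian outside, with the cold tail scaled by `T2 - T1`; both
lower pivots fall with the square root of body mass, encoding
gigantothermy — as animals grow they tolerate ever colder water. The upper
pivots (`T3`, `T4`) are retained in the code but default to 45/50 °C, far
above any open-ocean surface temperature, so the overheating branch is
inert for leatherbacks (those temperatures were never estimable from data
for this species). The feeding index is demand-relative prey availability,
`min(1, P / (P0 * F0(a)))`, with net primary production as the prey proxy
and `F0(a)` the normalized food demand, which tends to 1 in adults.

Mortality has a single cause: death after `mortality_window` (default 10)
days with water colder than the individual's current `T1`. We read the
published "at least 10 days" as *consecutive* days — a cold-stunning
mechanism in which any warm day allows recovery — and expose
`cold_rule = "cumulative"` as the alternative reading. The threshold uses
each day's own mass, so it relaxes as the animal grows.

## Parameters

All constants live in `stamm_params()`; the defaults are the published
North Atlantic leatherback calibration:

| parameter | default | units | role |
|---|---|---|---|
| `v0` | 1.2 | m s⁻¹ | swim-speed scale; gives adults ~0.6 m s⁻¹ at `h = 0.5` |
| `alpha` | 3e6 | m | heading concentration per unit gradient norm |
| `P0` | 80 | mmol C m⁻² day⁻¹ | NPP scale saturating the feeding index (90th-percentile rule) |
| `t1_*`, `t2_*` | 24, 1.05 / 0.21 | °C, °C kg⁻⁰·⁵ | mass-dependent cold pivots |
| `L_inf`, `k_growth`, `a0` | 1.43, 0.226, 0.17 | m, yr⁻¹, yr | growth curve |
| `mass_coeff`, `mass_exp` | 112.31, 2.86 | — | length–mass allometry |
| `rmr_exp` | 0.831 | — | metabolic scaling exponent |
| `f0`, `food_rate`, `food_a0` | 0.094, 0.299, 0.17 | —, yr⁻¹, yr | food-demand curve |
| `vm_exp` | 0.126 | — | speed-law exponent |
| `mortality_window` | 10 | days | consecutive-cold death rule |

`vm_exp` deserves a note: the exact reduction `(rmr_exp * mass_exp - 2)/3`
equals 0.12555…, which rounds to the printed 0.126. We default to the
printed value (the difference in `Vm` is below 0.1 % across the whole size
range) and validate the two against each other to 5e-4 at construction, so
incoherent recalibrations fail fast. `params_leatherback_pacific()` carries
the only published alternative calibration (`P0 = 55`).

`alpha` is dimensioned so that `kappa = alpha * ||grad h||` is a pure
number when the gradient is per metre; with basin-scale habitat contrasts
(order 1 change in `h` over a few hundred km) this puts `kappa` in the
range 1–10, i.e. between weakly and strongly directed walks — the regime
the calibration targeted.

## Numerics

* **Integration.** Forward Euler with the model's daily step, sampling
  current and habitat at the step's start; displacements convert to
  degrees with the spherical metric (east spacing scaled by
  `cos(latitude)`, Earth radius 6371 km). The original trajectory engine
  used an analytic streamline scheme for the advective part; at daily/1°
  resolution Euler is an accepted approximation and we document it as a
  known deviation.
* **Interpolation.** All forcing fields are sampled bilinearly in space
  and linearly in time, matching the published treatment of the NPP
  fields. Land neighbours are excluded with weight renormalization; a
  point whose four neighbours are land is invalid and the caller must
  handle the coastline.
* **Habitat gradient.** Centred finite differences at ± one forcing-grid
  cell (configurable, `sense_deg`), converted to per-metre; one-sided
  where a stencil point is land-blocked, zero where both sides are. The
  source work never states its sensing scale; one grid cell is the scale
  at which the published `alpha` was tuned to gridded fields. Gradients
  use instantaneous daily fields (whether the original smoothed them is
  unstated).
* **Coastline.** If a proposed step lands on shore, the zonal or
  meridional component that stays on water is retained (the larger one if
  both work alone); otherwise the animal stays put. No position on land is
  ever returned.
* **von Mises sampling.** Best–Fisher (1979) rejection from a wrapped
  Cauchy envelope. Below `kappa = 1e-5` we sample uniformly: the
  distribution is then within total-variation distance ~`kappa/2` of
  uniform, and near `kappa = 1e-8` the envelope constants degenerate in
  double precision.
* **Randomness.** Every draw belongs to a per-individual substream keyed
  by `(seed, box label, within-box index)` and, for daily headings,
  the simulation day. Results are therefore reproducible bit-for-bit,
  independent of cohort ordering, and a passive run is bit-identical to an
  active run with `v0 = 0` (no swim speed, and heading draws touch no
  shared state). The engine modifies the global RNG state.
* **Calendar.** A fixed 365-day year; cyclic forcing is reused modularly
  (`loop_time()`), with interpolation across the seam between the last and
  first stored slices.

## The synthetic ocean

`synthetic_ocean()` generates an idealized basin (default 60°W–0°, 0–60°N,
1°, one 365-day year at 5-day cadence, looped) with the large-scale
structure the dispersal analysis needs, so the full pipeline runs with no
downloads:

* **Currents** derive from a Stommel-like gyre streamfunction, so the flow
  is non-divergent to rounding on the grid's own difference operators and
  has no coastline-normal component — passive particles cannot beach,
  which isolates the coast-handling code for targeted tests. The boundary
  layer narrows poleward (`wbc_south_width_deg = 30` at the southern edge
  to `wbc_width_deg = 4` at the northern flank): the tropical limb is
  broad and slow while the mid-latitude jet is narrow and fast, as in real
  basins where boundary transport concentrates poleward. This matters
  biologically: hatchlings (whose cold tolerance `T1` starts near 24 °C)
  spend their first year in warm water and meet the cold mid-latitudes at
  an age where survival is possible, producing a second-winter mortality
  peak rather than total first-autumn loss. The gyre is confined south of
  `gyre_north_lat = 42`; the strength (`psi_amp = 1.05e5` m² s⁻¹, centre
  at 20°N) stretches the basin crossing over several years so that
  multi-year seasonal migration is observable within a 6-year window.
* **SST** is a poleward-cooling mean profile (`28 - 22 * latfrac^3`; the
  cubic keeps the subtropical interior warm with a steep subpolar drop)
  plus a seasonal cosine whose amplitude grows linearly poleward (7 °C at
  the northern edge, peak day 245). Winter at 40°N sits well below the
  `T1` of a 2-year-old, so the cold-mortality pathway is genuinely
  exercised.
* **NPP** combines an oligotrophic interior (15 mmol C m⁻² day⁻¹), a
  tropically-confined western band (Gaussian latitude scale 8°; the
  tropical-shelf analog — confining it matters because any productive band
  with a coastal maximum at mid-latitudes would trap active swimmers
  against the coast once their growing demand unsaturates it), an eastern
  band spanning the upwelling latitudes, and a high-latitude seasonal
  bloom whose southern foot (30°N) reaches far enough south that its
  summer gradient connects with the thermal winter gradient to establish
  the summer-north/winter-south migration ratchet. Amplitudes place the
  90th percentile of NPP over water near 80, so the published
  percentile rule for `P0` is exercised at its nominal value.

What the generator does **not** emulate: mesoscale eddies and storm
variability (flows are smooth and seasonal-deterministic), real coastline
geometry (two meridional margins only — no Caribbean detour, no
Mediterranean), cross-streamline Lagrangian dispersion beyond numerical
truncation, and interannual variability. Tests passing on this basin show
the model components behave correctly and that the published qualitative
mechanisms (habitat-gradient taxis, gigantothermic range expansion,
seasonal migration, P0-controlled eastern attraction) emerge from them;
they do not validate quantitative dispersal timing against the real
Atlantic, which requires reanalysis forcing.

## Diagnostics conventions

Individuals that die of cold are discarded *entirely* from density maps,
arrival ages and cohort-environment series (mortality curves use everyone),
following the published analysis convention. Ages are decimal 365-day
years. Polygon membership uses an even-odd rule with boundary points
counted inside; longitudes are normalized to (−180, 180].

`seasonal_latitude_autocorr()` quantifies the seasonal migration as the
lag-12-month autocorrelation of the monthly mean latitude of 2+-year-old
survivors. Two estimator choices matter at the series lengths a 6-year run
produces (~50 months): we remove a *quadratic* trend — the minimal
polynomial for the known low-frequency arc of a dispersing cohort
(tropical exit, poleward drift, settlement), which a linear fit cannot
capture and whose residual curvature otherwise masks the seasonal signal —
and we use the pairwise Pearson correlation of the lag-12 pairs rather
than the windowed ACF estimator, which is biased toward zero by a factor
of about `(n - 12)/n` on short series.

## Problem sizes

The test suite exercises: unit and oracle fixtures on grids of 3×3 to
11×11 cells; distributional checks of the heading kernel and release dates
at 10⁴–10⁵ draws; and emergent-behaviour runs on the default synthetic
ocean with cohorts of 500 individuals followed for 6 years in active,
passive and low-`P0` configurations — sizes chosen so the whole suite runs
in a few minutes on one core while leaving the emergent statistics well
clear of their decision thresholds. The published study scale (5000
individuals, 18 years, reanalysis forcing) runs through exactly the same
code path via `release_spec_fgs()` and user-supplied netCDF forcing.

## Known limitations

* Euler advection at daily/1° resolution under-resolves tight boundary
  currents; trajectories in strong shear are first-order accurate.
* The 10-day cold rule is a step function: no sublethal effects, no
  acclimation.
* Swimming is the only behaviour; there is no frenzy period (handled, as
  in the source work, by releasing offshore), no diel movement, no
  magnetic map.
* `T3`/`T4` defaults make overheating impossible; simulating heat stress
  requires setting them to species-appropriate values.
* The synthetic basin's idealizations listed above.
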