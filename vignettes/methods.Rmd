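---
title: "Methods: process choices and their limits in tirewash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: process choices and their limits in tirewash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tirewash` simulates daily deposition, wash-off, routing, sorption, decay
and stream delivery of 6PPD-quinone (6PPD-Q) on a gridded urban watershed
with explicit storm-sewer infrastructure. This vignette records the model
as implemented: the assumptions, every tunable that matters, the numerical
choices, and — importantly — what a green test on the synthetic fixture
does and does not establish.

## 1. The process chain and its fixed order

Each simulated day applies, in this order:

1. **deposit** — the constant traffic-scaled deposition grid is added to
   road-surface storage;
2. **rainfall partition** — impervious covers (roads, roofs, parking) and
   the channel shed the full depth; pervious cells infiltrate up to the
   daily capacity and soil-layer-1 headroom;
3. **evapotranspiration** — a fixed seasonal draw from layer 1 of pervious
   cells;
4. **wash-off** — `min(surface mass, S × runoff volume)` dissolves and
   leaves the surface;
5. **surface + pipe routing** — same-day transit along D8 chains; inlets
   intercept 100% of arriving water and dissolved mass; MS4 pipes deliver
   to their outfall cell (channel → pour point; pervious → soil layer 1),
   CSS pipes to the WWTP sink;
6. **percolation and lateral flow** — above-field-capacity water moves
   down at a daily fraction, bottom-layer water drains laterally to the
   D8 successor (baseflow where the successor is the channel), aqueous
   mass advecting in proportion to the moved water fraction;
7. **equilibrium partitioning** — every soil layer re-partitions between
   aqueous and sorbed phases;
8. **decay** — soil pools only;
9. **ledger update** — daily mass and water balances are checked at
   relative 1e-9 and the run aborts on violation.

The daily time step makes sub-daily pipe hydraulics and hydrograph shape
unobservable; same-day complete transit is therefore assumed for all
surface and pipe water. Output cadence never alters this trajectory
(asserted in the test suite).

## 2. Parameters

### Deposition (constant in time)

| parameter | default | units | meaning |
|---|---|---|---|
| `trwp` | 100 | mg km⁻¹ day⁻¹ | TRWP emission per km of travel |
| `cell_resolution` | 5 | m | grid cell edge |
| `tc_fraction` | 0.02 | – | 6PPD share of tire mass (reported 0.4–2%) |
| `cc_fraction` | 0.38 | – | 6PPD→6PPD-Q conversion; midpoint of the 1–75% theoretical range (experimental values since suggest ≤20%, so deposition is likely conservative) |
| `alpha` | 1.0 | – | calibration multiplier, unused |

The unit chain is `trwp × 10⁻⁶ / cell_resolution` g m⁻² day⁻¹, then the
two chemical fractions and `alpha`; with defaults the watershed maximum is
1.52e-7 g m⁻² day⁻¹. The printed form of the mg→g, km→m conversion in the
source material is typographically garbled; the factor 10⁻⁶ is fixed
unambiguously by the units on each side. The traffic product symbol is
likewise read as "for each cell", i.e. independent per-cell min–max
scaling — a literal product over cells is dimensionally meaningless.
Min and max are taken over street cells of the *modeled* watershed: the
pour-point delineation plus inlet-chained streets whose inlets divert to
the WWTP (which are outside the topographic delineation but still
deposit). If all counts are equal the scalars are all 1 with a warning —
preserving deposition rather than silently zeroing it. Deposition is
constant per day: no weekday or seasonal traffic modulation, no parking
lots, no airborne TRWP dispersion.

### Contaminant

| parameter | default | units |
|---|---|---|
| `koc` | 11000 | L/kg |
| `molar_solubility` | 1.58e-4 | mol/L |
| `molar_mass` | 268.404 | g/mol |
| `k_max` | 0.2207475 | day⁻¹ |
| `log_kow` | 2.745 | – (metadata only) |
| `q10`, `t_opt_c` | 2, 25 | –, °C |

"Fraction per day" for the maximum decay rate is interpreted as a
continuous first-order rate applied as `exp(−k)`: ln 2 / 3.14 days =
0.2207475 day⁻¹ reproduces both published numbers exactly, which a
discrete daily fraction would not. The temperature and moisture
modulation scalars are *not* inherited from any published formulation —
the source only requires that decay slow under sub-optimal conditions.
We use the simplest bounded monotone forms, `f_T = min(1, Q10^((T−25)/10))`
with air temperature as a proxy for soil temperature, and
`f_W = min(1, θ/θ_fc)`; both are config-exposed. Surface (on-road) mass
does not decay: the decay process is tied to soil conditions, and
photodegradation on pavement is a 6PPD-Q *source* in the recent
literature, not a sink — we model neither. Estimating Koc from logKow
(`direct_koc = FALSE`) is deliberately not implemented and errors
clearly; the study configuration specifies Koc directly.

Sorption is an instantaneous linear equilibrium isotherm, Kd = Koc × foc,
re-solved each day per layer; the aqueous concentration is capped at the
mass solubility S = 0.0424 g/L both at wash-off and in soil (the cap's
placement is a choice; at realistic road loadings it never binds —
capacity exceeds stored mass by ~5 orders of magnitude, which is why the
first storm after a dry spell removes essentially the whole accumulated
store: the first-flush mechanism). Sorption kinetics, multiphase/NAPL
behavior, and 6PPD→6PPD-Q transformation kinetics are out of scope; the
instantaneous-equilibrium reduction is this module's largest
simplification.

### Hydrology (the deliberately minimal part)

The hydrologic engine of the source system is published separately and
not reprinted; this package implements the smallest daily bucket-and-route
scheme able to drive contaminant transport through the right regimes
(flashy wet-season runoff, near-zero summer flow, baseflow, riparian
re-infiltration):

* impervious = 100% runoff; pervious infiltration capped at
  `infiltration_capacity_mm` (50 mm/day) and layer-1 headroom;
* 4 soil layers, thickness 0.1/0.2/0.3/0.4 m, porosity 0.45, field
  capacity 0.30, bulk density 1300 kg/m³, foc 0.05/0.03/0.01/0.005 —
  generic loamy urban-soil values, uniform in space;
* percolation = 0.5/day of above-field-capacity water, limited by the
  receiving layer's headroom; lateral drainage 0.1/day from layer 4 only,
  to the D8 successor's layer 4 (baseflow where that successor is the
  channel);
* evapotranspiration: fixed 2 mm/day June–September, 0.5 mm/day
  otherwise, from layer 1 of pervious cells (water only — solutes stay
  and concentrate, as evaporation should).

All five constants are config keys. No claim of equivalence with any
calibrated model is made: peak timing, recession shapes and absolute
discharge are schematic. One known artifact: a fully saturated column
drains only through the bottom-layer lateral bottleneck, so deep-storage
recessions can plateau before decaying; the recession is monotone
non-increasing and reaches zero, but slowly. Inlets intercept 100% of
arriving surface water; roofs shed water (never contaminant) into
surface routing, since no roof-drain data model exists in the source.
Whether roof runoff should carry 6PPD-Q is an open question there; here
roofs carry water only. At an MS4 outfall on a pervious (riparian) cell,
delivered *water* infiltrates up to layer-1 headroom with the excess
continuing downslope, while the delivered *dissolved mass* merges
entirely into soil layer 1 and partitions there — matching the described
re-emergence of contaminant onto riparian soils followed by sorption.
Saturation overflow pushed back to the surface carries water only; the
associated aqueous mass stays in its layer (a small, documented
inconsistency that errs toward retention).

## 3. Terrain and network numerics

* **Pit filling**: priority-flood from the boundary (and nodata holes)
  with a strictly increasing epsilon of 1e-6 m across flats, so D8 always
  terminates; external DEM conditioning tools are out of scope.
* **D8**: steepest descent of drop/distance with diagonal distance
  `cell × √2`; ties broken deterministically in the fixed neighbor order
  E, SE, S, SW, W, NW, N, NE (first maximal gradient wins) for
  platform-independent reproducibility.
* **Delineation**: a cell belongs to the watershed iff its successor
  chain *visits* the pour point; MS4 links extend chains from inlet to
  outfall, CSS links divert them out of every delineation.
* **Deposition mask**: street cells whose successor chain reaches an
  inlet while traversing street cells only. A single non-street cell
  breaks the chain.
* Cells are addressed 1-based (row, col) from the northwest corner, the
  R convention; the ESRI header's llcorner refers to the southwest corner
  per that format. Grids store nodata as `NA` internally.

## 4. The synthetic world — and what green tests mean

No real GIS stack or weather record ships with the package. The seeded
generator builds a V-shaped valley (cross-slope 0.05, down-valley slope
0.01 — chosen so hillslope D8 runs perpendicular to the channel and
street rows align with flow chains), street rows every 10 cells with the
northernmost row deliberately inlet-free (exercising the mask rule),
inlets every 10 street cells, a max-traffic arterial row, 20% CSS share,
50% riparian outfalls, and scattered roofs (15%) and parking (3%).

Weather: wet-season (Oct–May) storms with daily probability 0.45 and
exponential mean depth 8 mm match Pacific-Northwest climatology
(~950 mm/yr here). Dry-season (Jun–Sep) storms are *near-zero*
(probability 0.01, mean 2 mm). That is drier than a typical Seattle
summer, and deliberately so: it is the stated regime of the world this
package models, in which the road-surface store builds through the whole
dry season and the year's first-flush events belong to the first fall
storms. Under the package's solubility-capped wash-off, *any* measurable
summer storm would strip the accumulated store into a tiny discharge and
put the year's highest concentrations inside June–September, destroying
the end-of-summer buildup pattern the simulator exists to reproduce. The
temperature sinusoid (mean 11 °C, amplitude 7.5 °C, peak August 1, noise
sd 1.5 °C) is Seattle-like.

A green test on this fixture establishes *internal* correctness:
conservation, linearity, masking, routing topology, seasonal phasing,
first-flush ordering. It does **not** establish concentration realism:
the demo valley's traffic, soils and weather are invented, and its peak
concentrations (hundreds of ng/L) exceed the 2–27 ng/L observed at the
real field site, whose reproduction requires the original GIS and
weather inputs that are not shipped. The bundled five observed grab
samples are a comparison *fixture* for `compare_observed()`, not a
validation target for the synthetic year. Comparisons are daily simulated
averages against instantaneous grab samples, as in the source study.

## 5. Numerical and convention choices

* Mass and water ledgers are accumulated with the same floating-point
  operations that update state, so daily closure holds to ~1e-15
  relative; the enforced tolerance is 1e-9.
* Zero-discharge days report 0 ng/L with a `zero_flow` flag rather than
  NaN — matching "undetectable" dry-season conditions.
* Exceedance against the LC50 (95 ng/L) is inclusive (≥), the protective
  convention.
* The degenerate all-equal-traffic case scales to 1 everywhere with a
  warning.
* All generator randomness flows through `set.seed` offsets of one spec
  seed; identical inputs and seed give bit-identical outputs (tested).
* The engine refuses negative masses, cycles in pipe routing (guarded
  fixed-point iteration), and modulation scalars outside [0, 1].

## 6. Known limitations

Hydrology is schematic (no calibration, no snow, no sub-daily dynamics);
sorption is equilibrium-linear; soil properties are spatially uniform;
deposition ignores seasonal traffic, truck shares, parking lots and
airborne transport; roof drains are collapsed into surface routing; decay
modulation forms are plausible but unvalidated; and absolute
concentrations on synthetic watersheds are indicative only.
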