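---
title: "Quantifying stranded farm assets under dietary transitions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stranded farm assets under dietary transitions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Shifts away from animal-sourced food (ASF) put farm capital at risk of
stranding: buildings, machinery and equipment, and breeding livestock are
long-lived, illiquid assets whose value presumes continued demand for the
products they help produce. `agstrand` quantifies that exposure by coupling
three ingredients:

1. a **physical multi-regional input-output (MRIO) system** in tonnes per
   year — an inter-industry flow matrix $Z$, final demand $Y$ and total
   output $x$ over region-commodity sectors, in the style of physical
   biomass IO databases;
2. a **farm-asset satellite account** — per-farm-type asset values by
   region and asset class, allocated to commodity sectors through a
   concordance matrix; and
3. **isocaloric diet scenarios** that reduce ASF consumption in a
   consuming bloc (the EU-like set of regions) and rescale plant foods.

## The contribution analysis

Assets are traced along supply chains with the standard Leontief machinery.
Technical coefficients are $A = Z\hat{x}^{-1}$ (inputs per unit output; the
column of any zero-output sector is set to zero rather than divided), and
the Leontief inverse is $L = (I - A)^{-1}$, defined whenever the spectral
radius of $A$ is below one. Asset intensities per sector and asset class
are $b' = e'\hat{x}^{-1}$ (EUR per tonne), where $e$ is the allocated
extension. The embodied-asset contribution analysis is

$$R^c = \hat{b}\, L\, Y,$$

which retains producing-sector detail for every final-demand column. On a
balanced system in which all output is absorbed ($x = Z\mathbf{1} +
Y\mathbf{1}$), the identity $e'\hat{x}^{-1} L\, Y \mathbf{1} =
e'\hat{x}^{-1} x$ makes the analysis conservative: total embodied assets
over all final demand equal the total allocated extension. This identity
is asserted in the test suite at $10^{-8}$ relative tolerance.

**Value-chain attribution.** For each food item the final demand for that
commodity is routed through $L$; contributions from livestock sectors are
tagged `livestock`, crop contributions upstream of an animal item are
tagged `feed`, and crop contributions to plant items `plant_food`. A
sector-level first-order tag (share of a crop's output sold directly into
livestock sectors) is also reported via `classify_value_chain()`; with no
crop-to-crop flows the two coincide, which is tested.

## Asset allocation

Farm-type values are split over eligible commodities with weight
proportional to *concordance weight x own-region commodity output*.
Output here is physical (tonnes): in a physical IO system "total output
per commodity" is a mass, and using it keeps the allocation unit-free
within a region. Assets never cross regions. When a farm type's eligible
set carries zero total weight — an all-zero concordance row, or zero
regional output — its value is reported as an unallocated residual rather
than being spread evenly; coverage below 100% is therefore visible in the
allocation report instead of being silently redistributed.

## Diet scenarios

Scenario rules are fixed pairs over the reference intake ranges:

| level | ASF rule | legumes/nuts/oils rule |
|---|---|---|
| `moderate_asf` | upper limit | lower limit |
| `low_asf` | midpoint | midpoint |
| `zero_asf` | zero | upper limit |

Items outside the reference-diet scope (`alcohol`, `other`) are removed
from scenarios. The remaining plant items (`other_plant`) scale by one
common factor so each scenario diet is isocaloric at the 2,500 kcal
person^-1^ day^-1^ target; the factor is reported and may be above or
below one. An infeasible configuration (no `other_plant` energy left to
close the gap, or fixed groups already above target) raises a classed
error rather than producing a non-isocaloric diet.

**Waste.** Each item's waste fraction $w \in [0,1)$ is read as the share
of supplied food lost before intake, so primary demand is
$\text{intake}/(1-w)$ — FAO-style loss accounting. Applied identically to
baseline and scenario, $w$ cancels from the demand ratio that shocks $Y$;
the cancellation identity is tested item-wise.

**Shock scope.** By default only the consuming bloc's final-demand columns
are scaled (commodity-wise, by the scenario/baseline demand ratio);
exports to other regions keep their baseline demand, so the default
quantifies consumption-driven stranding only. The `global_adoption` flag
shocks every region's demand and brackets the alternative reading. Items
with zero baseline but positive scenario demand are allocated across the
bloc proportionally to population and sourced pro-rata to the commodity's
current producers — the static-technology assumption carried throughout
(constant coefficients and trade structure).

ASF reductions are reported on both a kcal and a mass basis; the kcal
basis is primary, since the scenario rules and the isocaloric constraint
are both energy-denominated.

## Stranding, depreciation, sensitivity

Per cell (commodity x asset class x chain tag): stranded value is
$\max(0, \text{baseline} - \text{scenario})$ and the new-asset requirement
$\max(0, \text{scenario} - \text{baseline})$; a cell never has both, and
losses are never netted against plant-side gains. Land is summarised
separately from the three fixed-asset classes, and every share is printed
next to its denominator, because "share of total" is ambiguous across
mixed denominators.

The mean depreciation rate is depreciation flow over depreciable stock
(the three fixed-asset classes; land does not depreciate). The default
schedule is **straight line**, $V(t) = V_0\,(1 - rt)^+$, reaching zero at
$t = 1/r$ — with $r = 0.09$, about 11.1 years. This is the only
book-value convention consistent with finite phase-out timelines;
declining balance, $V(t) = V_0(1-r)^t$, never reaches zero and is
available by configuration. An accelerated phase-out at a deadline
strands the undepreciated book value remaining at that date, assuming a
complete investment stop from year zero and book value independent of
utilisation — the simplest auditable convention.

Sensitivity intervals deflate nominal historical values to base-year
prices (real = nominal / index, index normalised to 1 at the base year),
take each group's minimum and maximum fractional deviation from the base
value, and report the implied interval; constant history collapses the
interval onto the base case, which is tested.

## The synthetic generator

The generator provides the study conditions: seeded, balanced,
productive MRIO systems with crop-to-livestock feed flows, FADN-like
accounts, diet tables with reference ranges, and a deflator. Defaults are
desk-scale — 3 regions x 6 commodities (4 crops, 2 livestock) x 2
final-demand categories, 4 farm types, feed share 0.4, crop seed-use
share 0.05 — chosen so the whole pipeline and its property suite run in
seconds while keeping every structural feature (multi-region trade, feed
chains, a consuming bloc that is a strict subset of regions). Database-
scale dimensions (187 x 123 x 6, 14 farm types) are available through the
same arguments and are exercised at index level in the tests.

Construction details that matter:

* **Balance is bit-exact** because $x$ is defined as $Z\mathbf{1} +
  Y\mathbf{1}$ after the flows are drawn, not solved for.
* **Productivity is structural**: livestock sectors sell nothing into
  $Z$, so $A$ is block-triangular and its spectral radius equals that of
  the crop-to-crop block, bounded by the seed-use share. The radius is
  still asserted (at $1 - 10^{-9}$) and a named error is raised if it
  ever failed.
* **Livestock output is exogenous** (roughage and pasture are outside the
  table), so a zero feed share yields a valid system with producing
  livestock sectors rather than a degenerate one.
* **Ground truth is computed twice**: `synthetic_ground_truth()` re-derives
  the extension, intensities and embodied values with plain loops and a
  truncated Neumann series $\sum_k A^k$ (summed until the analytic tail
  bound $\max|A^{K+1}|/(1-\rho)$ falls below tolerance), so parameter
  recovery is a genuine two-route check, and the test suite carries a
  third, independent series oracle.

What the generator does **not** emulate: realistic trade calibration,
supply-use (rectangular) tables, non-food biomass uses, food versus
non-food splits of agricultural output, processing sectors, or price
responses. Passing tests therefore demonstrate the correctness of the
accounting and the scenario mechanics under the stated assumptions — not
the magnitude of stranding in any real economy, which depends entirely on
the real IO tables and asset accounts supplied.

## Numerical choices

* Zero-output sectors: coefficient and intensity entries are zero;
  balance is preserved and no division by zero occurs.
* The Leontief solve uses a dense direct solve and is contract-checked
  against $(I-A)L = I$ at $10^{-8}$ max-abs; any method meeting that
  contract would be acceptable.
* Monetary unit is million EUR internally; reports can present billions.
* All tables are plain delimited text (UTF-8, comma, `.` decimal, header
  row), matrices stored long; doubles are written in shortest round-trip
  form so read-back is exact.
* Manifests record MD5 checksums of every written file plus the hash of
  the canonical config JSON (output directory excluded), making
  reproducibility a byte-level property: identical config and seed give
  identical manifests.

## Known limitations

The analysis is static and gross: no price or substitution responses, no
asset vintaging, no repurposing value, no farm-level debt or liquidity,
no downstream-sector cascades. Final demand in $R^c = \hat{b}LY$ includes
all final-demand categories by default (a configuration filter can
restrict it). The residual breeding-livestock value that multifunctional
farm animals would retain under a full ASF phase-out has no mechanistic
model here; in synthetic systems it can be represented through the
concordance and feed parameters rather than guessed.
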