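---
title: "Methods: bioeconomic assessment of a pine wood nematode invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioeconomic assessment of a pine wood nematode invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwnimpact)
```

## The problem

The pine wood nematode (*Bursaphelenchus xylophilus*, PWN) kills conifer
trees through pine wilt disease (PWD), but only where summers are warm:
infested trees express the lethal syndrome when mean summer temperature
exceeds a threshold, conventionally 20 °C. An uncontrolled European
invasion therefore produces damage wherever three spatial layers
intersect: the pest's expanding range, the warm climate zone, and the
standing conifer stock. `pwnimpact` implements this assessment chain as
a reproducible pipeline: data layers → spatial integration → partial
budgeting of direct losses → partial-equilibrium (PE) welfare analysis of
the round-wood market → uncertainty analyses.

## Data layers and spatial integration

Three layers live on two nested regular grids (row 1 is north):

* **Spread** — presence/absence of PWN per *coarse* cell (the
  spread-model resolution), per year, per stochastic replicate.
* **Climate** — mean summer (July–August-type) temperature per *fine*
  cell (nominally 1 km²).
* **Host** — standing stock (m³) per administrative region, split into
  six vulnerability classes: age ≤ 20 yr / > 20 yr crossed with
  susceptible / intermediate / resistant species.

Integration happens at two resolutions, and the difference between them
is itself a result:

* **Coarse (region level).** Each region gets a proportion infested
  $r_i$ (share of its coarse cells occupied) and a 0/1 disease indicator
  $d_i$ from its *mean* temperature. A warm-averaged region counts in
  full; a region whose mean sits below the threshold counts not at all,
  even if parts of it are warm.
* **Fine (cell level).** A fine cell *qualifies* iff its parent coarse
  cell is occupied **and** its own temperature exceeds the threshold
  (strictly, in both pipelines: "higher than" is read as a strict
  inequality, so a cell at exactly 20 °C does not express PWD). The
  region's exposure is then its qualifying-cell fraction, which replaces
  $r_i d_i$.

Aggregation averages temperatures within regions; disaggregation assumes
production value homogeneously distributed, splitting a regional impact
equally over its qualifying cells with one cell absorbing the
floating-point remainder so cell values sum to the regional value
exactly. In the limit of block size 1 and thermally uniform regions the
two pipelines coincide; the test suite asserts this equivalence.

Coarse cells that straddle a region boundary are assigned to the region
holding the majority of their fine cells (ties to the lowest region id).
A region too small to own any coarse cell gets $r_i = 0$; the default
worlds use regions much larger than coarse cells, as real administrative
regions are.

## Direct losses: partial budgeting

For polygon $i$ (a region, or a fine cell), the cumulative direct loss
after the period of interest is

$$ L_i \;=\; p \, r_i \, d_i \sum_{j,k} m_{jk}\, s_{ijk}, $$

where $p$ is the round-wood price (€/m³), $m_{jk}$ the mortality
fraction for age class $j$ and susceptibility class $k$, and $s_{ijk}$
the standing stock. Trees expressing PWD are treated as completely
worthless; survivors keep full value; there is no salvage, no
discounting, and no regrowth or replanting within the horizon. The
mortality presets are literature-based: default 100/80/50 % (young
susceptible/intermediate/resistant) and 90/70/40 % (old); a minimum set
60/60/40 and 50/50/40; a maximum set 100/100/50 and 90/90/50.

Because occupancy only grows and stock is fixed, the yearly totals form
the cumulative series directly; the marginal (annual) series is its
first difference, with the introduction year's marginal equal to its
cumulative value. Fine-resolution exposure is recomputed every year
rather than only at the final year, so the marginal series is consistent
at both resolutions.

## The round-wood market: partial equilibrium

Direct losses are stock values; the welfare analysis concerns the
*flow* of wood to the industrial round-wood market. All curves are
constant-elasticity (log-linear), calibrated so each reproduces the
baseline exactly:

$$ D(P) = \chi P^{\eta}, \qquad S(P) = \beta P^{\theta}, \qquad
   P = WP + \mu, \qquad M(WP) = \upsilon\, WP^{\omega}, $$

with demand elasticity $\eta = -0.11$, supply elasticity
$\theta = 0.8$, excess-supply (import) elasticity $\omega = 6.07$,
baseline consumption $D_0 = 249{,}101$ and production
$S_0 = 242{,}528$ thousand m³, producer price $P_0 = 50.49$ and world
price $WP_0 = 54.5$ €/m³. Calibration gives $\chi = D_0/P_0^{\eta}$,
$\beta = S_0/P_0^{\theta}$, $\mu = P_0 - WP_0 = -4.01$ €/m³ and
$\upsilon = (D_0 - S_0)/WP_0^{\omega}$. The EU–world price link is
implemented as an additive wedge — the simplest linear relation
consistent with both baseline prices — and since baseline consumption
exceeds production, the EU is a net importer whose net imports rise with
the world price.

A pest shock shifts domestic supply down by the factor $(1 - x)$, where
$x = z h$ aggregates the proportion of producers affected and their
proportional wood loss. Since the two never enter separately when the
cost mark-up $\nu$ is zero (mitigation costs are out of scope), the
package parameterises $x$ directly and accepts the $(z, h, \nu)$
decomposition as optional input, folding $\nu$ into the affected
producers' price as $((1-\nu)P)^{\theta}$ when given. The accumulated
stock loss converts to a yearly flow shock by the harvest-flow rule:
yearly removals are 1.8 % of standing stock, so the supply reduction in
a year is 1.8 % of the stock volume accumulated as lost up to that year,
and $x$ is that volume over $S_0$.

The equilibrium price solves
$\beta P^{\theta}(1-x) + \upsilon (P-\mu)^{\omega} = \chi P^{\eta}$.
The left side is strictly increasing and the right strictly decreasing,
so the root is unique; it is found with `uniroot()` on
$[P_0/2,\, 4P_0]$ at tolerance $10^{-12}$, and a zero shock returns the
baseline state exactly by construction. Welfare changes use the
closed-form surplus integrals: consumer surplus changes by
$-\chi\,(P_1^{1+\eta} - P_0^{1+\eta})/(1+\eta)$ (logarithmic
antiderivative at $\eta = -1$; absolute consumer surplus diverges for
inelastic demand, so only changes between two prices are reported), and
producer surplus for a constant-elasticity curve through $(P, S)$ is
$S P/(1+\theta)$. Quantities are thousand m³ and prices €/m³, so
surplus integrals are thousand € and are divided by 1 000 to report M€.
Total welfare is the sum of the two surplus changes, an exact identity.

The analysis cannot pin down the exact shock behind the published 2030
equilibrium: converting the fine-resolution loss (22 375 M€) to volume
at 50.49 €/m³ and applying the 1.8 % rule gives $x \approx 3.29\,\%$,
while the published price and quantity changes imply an effective
$x \approx 3.0\,\%$ — the value-to-volume conversion behind the
published table is not stated. The package therefore exposes $x$
directly, reproduces the published surplus arithmetic from the printed
price/supply changes (`market_welfare_table()` overrides), and reports
the 1.8 %-rule equilibrium as a bracketing computation. Percent-change
columns in the outcome table use baseline quantities, the baseline net
trade magnitude, and the surplus proxies $D_0 P_0/(1+\eta)$ and
$S_0 P_0/(1+\theta)$ as denominators; the published table's denominators
are unreported, and these choices approximately reproduce its
percentages but are cosmetic.

## Synthetic worlds: what they emulate, and what they do not

No deposited spread, climate or host data exist, so the package
generates worlds with the statistical structure the analysis assumes:

* **Temperature**: a south–north gradient (default base 16 °C at the
  north edge, +0.1 °C per row southwards on a 100-row world) plus
  i.i.d. Gaussian noise (sd 0.5 °C), so regions straddle the 20 °C
  threshold the way southern and central Europe do. Degenerate all-warm
  or all-cold worlds are permitted but flagged.
* **Regions**: contiguous rectangular tiles — enough for zonal
  statistics; no polygon geometry or geodesic areas are modelled.
* **Stock**: total 24 594 million m³ (the European conifer total), with
  class shares chosen so susceptible species hold about 56 % of stock,
  matching the reported 13 665 of 24 594 million m³. Regional totals are
  proportional to area times a log-normal factor, weighted toward the
  north (`stock_north_bias = 2`) because European conifer stock is
  concentrated in the cool north while the invasion enters the warm
  south; the grand total is rescaled to hit the target exactly.
* **Spread**: a generic monotone stochastic process — yearly occupation
  of cells within a Chebyshev radius of the front with fixed probability
  (default 0.35 in the pipeline, so the front advances about a third of
  a cell per year on the 20 × 20 coarse grid), plus Poisson
  long-distance jumps (rate 0.3/yr) to uniform random cells. The default
  run grows 200 replicates over 2008–2030, selects the median replicate
  for the central analysis and the 5th/95th percentile replicates
  (nearest-rank on final invaded-cell count, ties to the lowest index —
  no interpolation, for exact reproducibility) for the spread
  sensitivity.

These worlds reproduce the *structure* that the pipeline's logic
depends on — monotone invasion, a binding climate constraint, stock
concentrated away from the entry point, replicate variation — but not
the geography of Europe: mechanistic vector flight and wood-trade
jumps, real climate surfaces, and the actual host distribution are all
out of scope. Passing tests therefore validate the assessment machinery
and its invariants, not the absolute European damage figures, which are
checked instead against the published tables shipped as built-in
reference parameter sets.

## Uncertainty analyses

Three designs, mirroring the study:

1. **Single parameter** (`run_single_parameter()`): vary one of spread
   percentile (5/50/95), temperature threshold (18/19/20 °C), mortality
   preset (minimum/default/maximum) or price, holding the rest at the
   base scenario. Price sweeps scale exactly proportionally (a property
   the tests assert). The default price pair is (50.49, 67.7) €/m³ —
   the pair consistent with the published sweep result of 37 363 M€ —
   and any pair may be supplied.
2. **Worst/best case** (`run_extreme_cases()`): 95th-percentile spread,
   18 °C, maximum mortality and highest price against 5th-percentile,
   20 °C, minimum mortality and lowest price, with per-region impacts
   also expressed relative to regional asset value (stock volume at the
   scenario price; the ratio is price-free).
3. **Data-layer removal** (`run_layer_removal()`): assume either no
   temperature limit (disease wherever the pest is) or an unknown entry
   point (disease wherever it is warm). Either relaxation can only
   enlarge the qualifying set, so removal impacts bound the constrained
   impact from above.

## Numerical choices and edge cases

* Strict threshold inequality at both resolutions; boundary equality
  means no disease.
* Nearest-rank percentile with `k = max(1, ceil(q n / 100))`, clamped
  to `n`; `q = 0` returns the smallest replicate.
* Downscaling distributes the remainder onto the last qualifying cell;
  a positive impact with zero qualifying cells is an invariant error
  (impact must be 0 when nothing qualifies).
* Internal arithmetic in € at full precision; tables report M€.
* The solver refuses brackets without a sign change and reports the
  end-point residuals; shocks at or above 100 % of baseline production
  are rejected.
* All randomness flows from explicit integer seeds; the same seed gives
  byte-identical worlds, replicate sets and output CSVs.

## Problem sizes

The shipped configuration runs 200 replicates on a 100 × 100 fine grid
(20 × 20 coarse, 16 regions) over 23 years, the full two-resolution
impact and welfare series, all sweeps and the extreme cases in a few
seconds on one core; unit tests use 12 × 12 worlds. Both sizes are the
package's own defaults for a fast, fully reproducible demonstration,
and scale up linearly in cells × years × replicates.

## Known limitations

* The spread stand-in has no mechanistic dispersal; percentile
  scenarios differ in extent but carry no geography of risk corridors.
* Single-market PE: no fuel-wood segment, no multi-market or general
  equilibrium spillovers, no tariff policy, no mitigation costs.
* Welfare percentages depend on surplus baselines that the published
  analysis leaves undefined (see above).
* Region/area bookkeeping uses cell counts times a constant cell area;
  no projections.

## A worked example

```{r example, eval = FALSE}
mkt <- roundwood_market()
# published fine-resolution 2030 changes: +1.44 EUR/m3, -1.89 M m3
market_welfare_table(mkt, price_change = 1.44, supply_change = -1890)
# the 1.8% flow rule applied to the 22,375 MEUR accumulated loss
shock <- shock_from_cumulative_loss(22375, 50.49)
equilibrium_welfare(mkt, solve_equilibrium(mkt, shock))
```
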