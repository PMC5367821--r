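---
title: "Precision farm planning: model, solver, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision farm planning: model, solver, and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroplan)
```

## The planning problem

A farm is an $M \times N$ raster of square *land units* (here half an acre
each), every unit carrying one soil class $j \in 1..J$. Before the season
the farmer fixes, for every unit, a *management option* $i(r, s)$: an
irrigation frequency $r$ (daily, weekly, every two/three/four weeks, or
never) joined with a seed hybrid $s$ (twelve corn hybrids in four
drought-resistance classes). Practical management happens on *decision
units* — rectangles of contiguous land units that must share one decision —
so the planning question is twofold: what to plant and how to irrigate, and
at which spatial granularity to manage.

With binary assignment variables $x_{iu}$ (option $i$ on unit $u$),
land-condition indicators $L_{ju}$, yields $Y_{ij}$ (t/ha), seasonal
applied water $W_{ij}$ (m$^3$ per unit), per-area costs $C^f_{ij}$
(irrigation labor/equipment) and $C^m_{ij}$ (other operating), unit area
$E$ and farm area $A$, the annual net profit objective is

$$
\max_x \sum_{i,j,u} x_{iu} L_{ju}
\Big( Y_{ij} E P + Y_{ij} E \tfrac{\alpha (1-\beta)}{1-\alpha} R^b
  - C^m_{ij} E - C^f_{ij} E - W_{ij} C^w / \gamma \Big) - C^o A ,
$$

where $P$ is the corn price, $R^b$ the residue price, $\alpha$ the
residues index (grain-to-biomass mass ratio), $\beta$ the sustainability
factor (residue fraction left on the field), $\gamma \in (0,1]$ the
water-use efficiency (purchased water is applied water divided by
$\gamma$), and $C^o$ the farm overhead. Optional side constraints bound
the irrigation budget, the operating budget, the minimum total yield, and
— most importantly in the case study — the seasonal purchased-water total

$$
\sum_{i,j,u} x_{iu} L_{ju} W_{ij} / \gamma + W^p A \;\le\; W^l A ,
$$

with $W^p$ the (unconditional) pre-season irrigation and $W^l$ the
per-area allotment. Frequency variables $y_{ru}$ and seed variables
$z_{su}$ are linked to $x$ by $x_{iu} \le y_{r(i)u}$, $x_{iu} \le
z_{s(i)u}$, with exactly one frequency and one seed per unit.

Three nested variants differ only in the uniformity constraints:

* **Model I** — every land unit decides independently (the profitability
  ceiling);
* **Model II** — $x$ is uniform within each decision unit of one shared
  partition;
* **Model III** — seed and irrigation use *independent* partitions (for
  example seed chosen per block while irrigation is switched per row).

Model I equals Model II on the all-singletons partition, and Model II on
partition $P$ equals Model III with both partitions $P$; the package
asserts both identities exactly in its tests.

One modelling choice deserves a note: the linking constraints alone allow
the all-zero assignment, which would make "option" semantics vacuous, so
the package adds $\sum_i x_{iu} = 1$ and represents idle land explicitly
through *fallow options* (every seed paired with the "never" frequency at
zero water, zero yield, zero operating cost). Idle land then appears in an
optimal plan exactly when a constraint (in practice the water limit) makes
planting some units unprofitable, while the one-option-per-unit invariant
holds everywhere. A corollary worth knowing: because the pre-irrigation
term $W^p A$ is unconditional, a water allotment below the pre-irrigation
commitment makes the model infeasible even if the whole farm lies fallow.

## Units and the case-study parameterization

All internal quantities are SI — hectares, cubic metres, metric tons, USD
— with acre-based field data converted once at entry (1 acre = 0.40469 ha,
1 acre-foot = 1233.48 m$^3$). The bundled case-study economics are: corn
$141/t, residue $35/t, water $0.073/m$^3$, $\alpha = 0.5$, $\beta = 0.3$,
$\gamma = 0.6$, pre-irrigation 8 acre-inches, seasonal allotment 2.5
acre-feet per acre, farm area 65.56 ha (324 half-acre units). The farm
area is validated against `n_units * unit_area` with a 2 % tolerance
(warning, not error), since published figures round the half-acre unit to
0.2 ha.

## The synthetic farm: what it emulates and what it does not

The study farm's soil survey and its yield/water tables were never
published, so the package generates *synthetic* farms that emulate the
described conditions; every generated quantity is a pure function of an
explicit seed (global RNG state is never read or written).

**Soil map.** `generate_soil_raster()` grows `blob_count` contiguous
patches by randomized region growing on a fine raster (default
3× the land-unit resolution) and integrates to land units by majority
vote, ties to the lowest class id. Five classes by default, sampled with
sand-heavy weights (0.30, 0.20, 0.20, 0.15, 0.15). The patches reproduce
the *contiguity* of real soil maps, not their geostatistics — no
variograms, no anisotropy — so spatial autocorrelation beyond patchiness
is absent from the tests' evidence.

**Water balance.** Each soil class has a per-event refill volume $q_j$
(m$^3$/ha; 245, 420, 600, 730, 965 from sand to clay — a 0.91 m root zone
at management-allowed depletion). Writing $d$ for the daily crop demand
(`water_need / season_days`, default 3600 m$^3$/ha over 105 days), an
event applies $\min(q_j, d \cdot \text{interval})$ — soils refill to
saturation but never beyond what was depleted — and irrigation adequacy is
$\min(1, q_j / (d \cdot \text{interval}))$. Heavier soils therefore reach
full adequacy at longer intervals: sand needs weekly irrigation, loam
three-weekly, clay four-weekly. Yield is $\text{max\_yield}_s \cdot
\text{adequacy}^{\text{sensitivity}_s}$, zero when seasonal applied water
falls below the survival requirement or the option is fallow (irrigation
stops when the crop is dead). Hybrid peak yields span 13.17–18.81 t/ha;
sensitivities (1.2, 0.45, 0.75, 1.7 for the stringy / drought / smart /
extravagant classes) encode the drought-resistance trade-off.

**Costs.** Operating cost is $1333/ha for every planted option, uniformly
applied; irrigation labor/equipment is $35/ha per event (surge sets must
be walked at every irrigation, which is what makes daily irrigation
uneconomical and sandy ground expensive); both are zero for fallow.

**Calibrated values.** Two defaults are deliberate calibrations rather
than field data, chosen once so the default farm reproduces the
case-study's qualitative structure, and documented as synthetic:

* *Survival-water basis.* The published survival requirement (1131
  m$^3$) does not state its area basis. The package defaults to the
  per-hectare reading (`survival_basis = "per_hectare"`), because under the
  per-acre reading every whole-farm-uniform option kills the sandy half of
  the farm and the uniform baseline collapses to a loss, which contradicts
  the reported modestly-profitable baseline. The per-acre reading remains
  one configuration key away.
* *Overhead.* $C^o$ was never published; the default $180/ha makes the
  uniform baseline modestly profitable (about $200/ha on the default
  farm) while unit-level management reaches about $695/ha — a gain ratio
  of 3.4, inside the reported 3–4× band. On other seeds the soil mix
  moves this ratio across roughly 2–4.5.

On the default farm (seed 1) the optimal unit-level plan shows the
expected structure: irrigation frequency tracks soil class (sand weekly
through clay four-weekly), a single high-end hybrid dominates wherever
water is adequate, the seasonal water limit binds, and about 9 % of the
units — all on the two sandiest classes — are left fallow. One caveat the
tests respect: sand and loamy-sand units can be *exactly* equivalent
economically (their capped per-event volumes coincide at the weekly
optimum), so which of them idles is solver-arbitrary.

```{r default-farm, eval = FALSE}
farm <- synthetic_farm(farm_recipe(seed = 1))
sol <- solve_farm_model(farm, model_spec("I"))
sol
table(
  soil = farm$grid$classes$name[as.integer(t(farm$grid$cells))],
  frequency = farm$catalog$frequencies$label[as.integer(t(sol$frequency))]
)
```

## The exact solver

No linear-programming backend is assumed: the package ships its own exact
solver (in compiled code, `src/mckp.cpp`), specialized to the structure
every model variant shares — *pick one option per decision cell under a
handful of farm-level resource constraints*.

For a shared partition the problem is a multiple-choice knapsack over the
decision cells. The solver:

* groups cells with identical option rows (land units on the same soil
  are indistinguishable) and forces their choices to follow a fixed
  preference ranking, removing the interchangeable-cell symmetry;
* reduces each group's options to the usage/profit skyline (dominated
  options can never be uniquely optimal) and its concave frontier;
* bounds every node by the *exact LP value* of the remaining subproblem —
  a greedy walk over frontier increments in slope order, $O$(frontier)
  per node;
* builds its incumbent by rounding the LP greedy down cell-wise,
  continuing through cheaper increments, and polishing with single and
  *pairwise* group-level exchange moves. The pair moves matter: distinct
  soil groups often carry exactly identical frontier increments, so the
  optimum frequently trades one group's upgrade for another's;
* prunes options whose Lagrangian reduced cost already caps them below
  the incumbent.

For independent partitions (Model III) the search branches over
per-irrigation-block frequencies; node bounds are the capacity-exact
cell-level LP with decided blocks frequency-fixed and consistency
relaxed, and every complete frequency assignment leaves an exact
multiple-choice knapsack over seed blocks. The search is warm-started
from the *common coarsening* of the two partitions — uniform decisions on
the join are always Model-III-feasible, and when the partitions coincide
this start already is the optimum, so the equality with Model II is
proved rather than assumed.

Constraint sets outside this shape (several simultaneous budgets, yield
floors) fall back to a Lagrangian-bounded search in R; those instances
are small in practice, and the brute-force oracle covers them in the
tests.

**Numerical choices.** Optimality is certified to a relative tie
tolerance of $10^{-9}$ (`solver_control(tol = )`); constraint feasibility
uses a relative slack of $10^{-7}$; the search aborts with an explicit
error beyond $5 \times 10^7$ nodes rather than silently degrade. Ties
among optima are broken by the solver's deterministic preference
rankings, so equal inputs give identical plans; distinct *equal-valued*
plans (the sand/loamy-sand case above) are possible across code paths,
which is why tests compare objectives, not assignments. The brute-force
oracle breaks ties lexicographically and refuses instances beyond an
explicit enumeration cap ($10^6$ assignments).

## The analysis layer

`run_scenario_table()` solves Model II across the sixteen-step
management-scale ladder (1 whole-farm unit up to 324 singletons, in row,
column, and square shapes) and reports the *gain ratio* against the
uniform baseline. `run_pattern_table()` fixes the irrigation partition to
per-row, per-column, or whole-farm (Patterns 1–3) while the seed
partition walks the same ladder, and reports the *relative gain for
customized irrigation* (RGI): the best of Pattern 1, Pattern 2, and
Model II, over Pattern 3.

`fit_scale_regression()` fits, by ordinary least squares
(`stats::lm()`),

$$ P^a = \beta_0 + \beta_1 \ln(n) + \beta_2 \ln(n)\, I(\text{square}) + \varepsilon, $$

with $\sigma$ on $n_{\text{obs}} - 3$ degrees of freedom. The $n-3$
divisor was validated against the published residual errors, which it
reproduces where the published column itself is internally consistent.
Scenario 1 is labelled square; since $\ln 1 = 0$ the indicator is
irrelevant there and the row stays in the square group. If all
observations fall in one shape group the collinear indicator is dropped
with a message.

`one_at_a_time_sensitivity()` re-solves the model along one-parameter
grids (corn and water price over their historical ranges, $71.65–271.26/t
and $0.073–0.89/m$^3$; operating cost, overhead, efficiency, and water
limit over ±25 %). Re-optimization at every grid point is the default —
the alternative of holding base-case decisions fixed and re-pricing them
is available via `reoptimize = FALSE` and can only do worse.
`breakeven_price()` bisects the optimal-value function (monotone in
either price) to a $0.01 tolerance for the trigger corn price and the
termination water price; `profit_region()` maps the profitable set over
a corn-price × water-price grid, which is up-closed in the corn price
and down-closed in the water price.

Absolute case-study dollars are *not* reproducible — they depend on the
unpublished soil map and tables — so the published per-scenario profits
are bundled as data (`case_study_tables()`), and the derived quantities
that are recomputable from them (gain ratios, RGI, the scale regression)
are recomputed and checked to the printed precision.

```{r case-study, eval = FALSE}
tabs <- case_study_tables()
round(gain_ratio(tabs$scenarios$net_profit), 2)
fit_scale_regression(tabs$scenarios)
```

## Problem sizes and runtime

The test-suite and acceptance runs use the full 324-unit farm for every
structural property (specialization identities on twenty seeded farms,
refinement monotonicity along the 1→4→36→324 square ladder, audits,
qualitative structure), 2×2 and 3×3 farms with reduced catalogues for the
fifty brute-force oracle comparisons, and nine-point grids for the
break-even and profit-region consistency checks. A Model I solve on the
324-unit farm takes well under a second; the whole suite runs in well
under a minute on one core.

## Known limitations

* Yields are table-driven; there is no crop-growth simulation, no
  weather, no multi-period deficit-irrigation scheduling (the water model
  is a single-season balance).
* Soil classes affect water holding only; nutrition is assumed uniform.
* The synthetic generator's patches are contiguous but not
  geostatistically realistic, and its agronomic tables are calibrated
  constructions, so passing tests demonstrate the *method* — exactness,
  nesting, monotonicity, qualitative economics — not predictions for any
  real field.
* Partitions are regular rectangles (rows, columns, square blocks);
  irregular or soil-adaptive tilings are out of scope.
* The compiled solver handles one non-negative resource constraint at
  full speed; multi-budget instances use the slower fallback path.
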