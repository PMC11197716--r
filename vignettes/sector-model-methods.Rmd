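---
title: "Methods: a price-endogenous sector model for peri-urban pesticide policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a price-endogenous sector model for peri-urban pesticide policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasm)
```

## The model and its assumptions

`pasm` implements a regional agricultural sector model in the
price-endogenous mathematical-programming tradition: a single optimization
whose optimum reproduces the competitive equilibrium of a multi-commodity
regional market. The objective is the sum of consumer surplus (the area
under each commodity's inverse demand curve up to the quantity sold) and
producer surplus (revenue minus input and activity costs). Decision
variables are the acreage of every (district, crop, technology) activity,
commodity sales, purchased inputs, and the weights of the crop-mix
constraint.

Key economic assumptions, each of which a user should be conscious of:

* **Linear inverse demand.** Each commodity has `P(y) = a − b y` (yuan/t),
  calibrated so the line passes through the observed (quantity, price)
  point with a stated own-price elasticity: `b = p0/(|e| q0)`,
  `a = p0 (1 + 1/|e|)`. Linearity makes the welfare integral quadratic and
  the whole problem a concave QP. A constant-elasticity demand system with
  piecewise-linear approximation would be the natural extension; it is out
  of scope in this version.
* **Own-price effects only.** No cross-price substitution on the demand
  side; substitution happens on the supply side through land competition.
* **Perfectly elastic input supply.** Pesticide, fertilizer and labor are
  available in any quantity at fixed prices, so the input-side surplus
  integral collapses to `Σ w_i X_i`. No input-supply elasticities are
  modeled.
* **Two market closures.** `P_fixed` treats the region as a price taker
  (demand perfectly elastic at observed prices; the objective degenerates
  to a linear program and all welfare is producer surplus — consumer
  surplus is reported as zero because it is undefined at a flat demand
  curve). `P_free` treats the region as a closed agricultural economy in
  which local consumption moves along the local demand curves. Reality is
  between the two; the pair brackets it.
* **Single-output activities.** Every budget produces exactly one
  commodity.
* **Free disposal.** Sales are bounded above by production
  (`Y ≤ Σ c Q`); at any positive price the balance binds, so sales equal
  production except in pathological cases.

## The crop-mix constraint

Land and agronomic detail (rotations, soil, seasonality) are not modeled
explicitly. As in the established sector-model practice, a district's
acreage vector is instead restricted to a flexible cone around historically
observed mix vectors:

`Σ_tech Q_{n,c,tech} ≤ (1+δ) Σ_h λ_{n,h} mix_{n,h,c}`, with `λ ≥ 0`.

The cone (rather than a convex hull) lets a district scale its historical
pattern up to the land limit; the flexibility multiplier `δ` (default
0.15, settings key `mix_delta`) allows moderate recomposition beyond any
convex combination. A crop never grown in a district cannot enter it. The
constraint is switchable off (`mix_constraint = FALSE`) for analytic test
instances. Without it, multi-district problems are typically degenerate:
the optimum pins down regional sales and land rents but not which district
grows what — the cone is precisely what disciplines that indeterminacy
(see *Numerical choices*).

## Pesticide caps and the baseline

The policy instrument is a quantity cap: scenario reduction `r` bounds
pesticide use at `(1−r)·B`, where the baseline `B` is computed from
base-year observed acreage times base-budget application rates (per
district, or the regional total). Baselining from observed data rather than
from the solved zero-reduction scenario mirrors how the actual mandate was
phrased ("relative to base-year usage"); a settings switch
(`baseline_from = "model_r0"`) exists for sensitivity analysis. Note that
the `r = 0` scenario still carries the cap at `B` — holding use at its
base level can itself be binding (and carry a positive shadow price) when
the unconstrained optimum would use more pesticide than the base year did.
Under `district` imposition every district must comply individually; under
`region` imposition only the total matters, so districts implicitly trade
reductions through the commodity market — the model's central policy
comparison.

## From survey to technology budgets

The mechanized-application technology is parameterized from a paired farm
survey (machinery users vs non-users). The pipeline is:

1. `annualize_equivalent_cost()` converts machinery purchase prices to an
   equivalent annual cost (annuity at a 5% discount rate over a 10-year
   life, both bundle settings).
2. `summarize_survey()` takes arithmetic means per variable per subsample;
   the machinery cost total is annualized purchase mean + rent mean.
3. `tech_effects()` forms signed percentage differences (mechanized vs
   non-mechanized) for the four propagated channels: yield, pesticide
   rate, labor requirement, machinery cost. Fertilizer and wage
   differences are summarized but deliberately not propagated — the
   technology description names exactly those four channels.
4. `build_tech_budgets()` scales base budgets multiplicatively by the four
   effects, for rice only (`TechR`) or all crops (`TechA`).

Two open choices resolved here: the machinery-cost effect is applied
*multiplicatively* to each budget's single machinery line (the alternative
— adding the rice absolute difference — is less robust across crops whose
machinery costs differ by an order of magnitude); and `TechA` applies the
rice-derived effect uniformly to all crops, which is the stated
construction of that scenario dimension, not an empirical claim about
horticultural machinery.

## The scenario grid and reporting metrics

`enumerate_scenarios()` crosses reduction level × technology × imposition
× closure and collapses the vacuous imposition dimension at `r = 0`,
giving 66 scenarios; ids are stable strings like `R3_TechB_region_P_free`.
`run_grid()` emits a long-format table (scenario, metric, entity, value)
with welfare components, per-crop production and prices, per-district
acreage, pesticide use and intensity, land rents and cap shadow prices.

Percentage changes are taken against the zero-reduction scenario of the
*same technology and closure*, which isolates the policy effect from the
technology effect. Price summaries use Laspeyres, Paasche and Fisher
indexes in both price and quantity variants; under `P_fixed` the price
variant is identically 100 (prices cannot move), so any reported price
effect under that closure must come from the quantity variant — both are
always computed and no guess about which one an external source used is
hard-coded. Validation tables report modeled/observed ratios per crop with
arithmetic and revenue-weighted means (weights: observed production ×
observed price); the ratio direction follows the numerical convention of
the published validation tables (modeled in the numerator), which their
accompanying prose inverts — the numbers win. Rounding is half-up, applied
only at the reporting boundary (3 decimals for ratios, 2 for percents).

## The synthetic-data generator

Everything is testable offline because `generate_instance()` produces
complete bundles emulating the structure of the real deposited data: 9
districts and 15 crops by default (any sizes are accepted), log-normal
yields around category means with district multipliers, gamma-distributed
input rates, a base-year observed table, demand specs calibrated to that
observed baseline, and historical mixes containing the base year plus
perturbed, land-rescaled copies.

Stated-world defaults and their grounds:

* **Pesticide rates**: gamma with category means; horticultural categories
  (leafy and other vegetables, fruit) at 5× the grain mean — the lower end
  of the 5–10× agrochemical-intensity contrast reported for horticulture
  versus field crops. Grain mean 5 kg/ha puts regional intensity near
  15 kg/ha, the right order for an intensively farmed peri-urban region.
* **Elasticities**: uniform in [−1.2, −0.2]. The source literature values
  are not published; this range spans inelastic staples to moderately
  elastic vegetables, and every elasticity is bundle data a user can
  replace.
* **Survey**: 532 farms, 251 non-mechanized / 281 mechanized, with
  injected technology effects defaulting to the published citywide rice
  budget differences (+1.788% yield, −4.693% pesticide, −9.845% labor,
  +16.182% machinery cost). Noise is independent multiplicative
  log-normal with cv = 0.08 per field: the real survey's dispersions are
  unpublished, and 0.08 is the level at which 1–5% subsample differences
  at n ≈ 250 per arm are genuine signal (≥2σ) — consistent with treating
  the published paired differences as meaningful — while keeping the
  large-n (10⁵ per arm) recovery of injected effects within ±0.1
  percentage point a ≥2.5σ property rather than a coin flip.

What the generator does **not** emulate: spatial autocorrelation between
neighboring districts, year-to-year yield shocks, the real survey's
snowball sampling, correlated noise across budget fields, or any
calibration making model-baseline validation ratios cluster near 1 the way
a hand-tuned regional dataset would. A green test on synthetic data
therefore establishes that the machinery is correct — not that any
particular regional projection is reproduced.

`generate_known_equilibrium_instance()` builds the parameter-recovery
oracle: it fixes an interior optimum first (all land planted, equalized
marginal net revenue per hectare equal to the land rent) and then reverse
engineers intercepts and costs so the Karush–Kuhn–Tucker conditions hold
exactly. It is restricted to a single district: with two or more districts
sharing one demand curve per commodity, the welfare optimum determines
sales and rents but *not* the within-district acreage split (cross-district
crop swaps that preserve totals leave the objective flat), so no unique
closed-form acreage target exists there.

## Numerical choices

* **Solver.** A dense Mehrotra predictor–corrector primal–dual
  interior-point method (`solve_qp()`), written for this package because
  the model is only positive-*semi*definite — a pure LP under `P_fixed` —
  which the strictly-convex Goldfarb–Idnani solver available in the
  environment cannot handle natively. Geometric column/row equilibration
  plus objective scaling keeps the condensed normal equations stable with
  coefficients spanning 1 to 10⁹. quadprog (with a tiny diagonal ridge)
  remains available as `backend = "quadprog"` and as an independent
  cross-check in the tests.
* **Crossover polish.** On convergence the active set is read off the
  final iterate (a row is active if its slack is dominated by its dual or
  essentially zero — the second clause catches constraints that bind with
  a zero multiplier, such as a cap holding exactly at the optimum),
  vacuous and linearly dependent rows are dropped by QR pivoting, and the
  equality-constrained KKT system is solved exactly. On nondegenerate
  instances this yields machine-precision primal and dual solutions; if
  the sign conditions fail the interior iterate is returned unchanged.
* **Input substitution.** Because input supply is perfectly elastic,
  purchases equal use at any optimum; the `X` variables are substituted
  out at assembly (cost folded into acreage coefficients) and reported
  back afterwards. This removes a family of always-binding rows whose
  duals are economically trivial (`= w_i`) but numerically degenerate.
* **Tolerances.** Solver relative KKT tolerance 1e-10 (settings key
  `solver_tol`); test comparisons at 1e-4 relative for primal quantities
  and duals, 1e-6 for welfare, as stated by the recovery contract.
* **Ties.** Degenerate alternate optima are permitted (LP closures can
  have flat optimal faces — on the calibrated two-crop instance under
  `P_fixed` *every* full-land allocation is optimal because equalized
  margins are exactly the equilibrium condition). Tests requiring
  uniqueness use strictly concave (`P_free`) instances or perturbed fixed
  prices.
* **Degenerate inputs.** Zero demand slopes (perfectly elastic), zero
  input prices, and crops absent from a district's history are all legal;
  the zero-production point is always feasible, so a valid bundle can
  never be infeasible at any scenario.

## Known limitations

Intensive-margin adjustment (changing application rates within a crop) is
represented only through the discrete mechanization technology; the
continuous channel is absent. No pesticide transport or fate modelling —
the model stops at use totals and intensities, so environmental
implications are proxies, not concentrations. No multi-year dynamics,
risk, or extreme-event scenarios. The `P_fixed`/`P_free` pair brackets
consumer stickiness to local produce instead of modelling it. Scenario
welfare is comparable *within* a closure but not across closures (the
objectives differ by the consumer-surplus term).
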