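---
title: "Modelling vitamin A intervention strategies for young children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vitamin A intervention strategies for young children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Vitamin A deficiency raises young children's risk of death, and many
low-income countries address it with two kinds of programs: twice-annual
high-dose supplementation (VAS) delivered through campaign platforms, and
food fortification (edible oil, bouillon cubes, biofortified maize).
Supplementation is effective but expensive; fortification is cheap once
running but takes years to build out and does not reach every child. A
planner must decide which portfolio of programs, deployed where and when
over a ten-year horizon, meets a national coverage objective at least cost —
and how to stage the withdrawal of supplementation safely as fortification
matures.

`vaplan` implements this analysis for a three-macroregion setting (North,
South, Cities) calibrated to national planning figures for Cameroon. Its
pieces are: a synthetic dietary-survey generator; a usual-intake estimator
for repeated 24-hour recalls; program overlays that convert fortification
levels into per-child additional vitamin A and re-estimate the prevalence of
inadequate intake; a mortality linkage; a program cost model; an exact
portfolio optimizer; a staged-withdrawal pathway engine; and a Monte Carlo
robustness layer.

## The dietary model

Usual (habitual) intake $U$ of a child is taken lognormal within a region:
$\log U \sim N(\mu, \sigma_b^2)$. An observed recall day is
$Y = U \cdot \varepsilon$ with $\varepsilon$ lognormal, mean one, CV
`within_cv` (default 0.8 — day-to-day variability of vitamin A intake is
large because intake is dominated by a few rich foods). A child is classed
inadequate when $U$ falls below the age-bracket EAR (defaults 190 µg
RAE/day for 6–11 months, 210 for 12–47, 275 for 48–59; the source tables do
not print their EAR values, so these IOM-style values live in the
configuration, not in code).

Vehicle consumption is drawn per child: bouillon, maize and supplement
receipt independently of intake; *oil-consumer status is correlated with the
intake z-score* through a probit link that preserves the marginal consumer
fraction (`oil_consumer_z_slope`, positive = oil consumers have poorer
baseline vitamin A intake). The correlation is not a free embellishment: the
printed per-program coverage cells for the South and Cities exceed the
algebraic cap `consumer_fraction × baseline_prevalence` that *any*
independent model obeys, so the survey behind those tables must concentrate
fortifiable-oil consumption among children with low baseline vitamin A.
That is nutritionally plausible — households relying on refined market oil
consume less provitamin-A-rich red palm oil — and with the slope calibrated,
the South and Cities oil cells are reproduced almost exactly with realistic
consumption amounts (oil ≈ 10–14 g/day, bouillon ≈ 1.3–1.7 g/day).

## Estimating usual intake from 1–2 recalls

The estimator is an amount-only analogue of the NCI method: a Box–Cox power
chosen by profile likelihood over \{0, 1/4, 1/3, 1/2\} (ties to the smaller
power; the Jacobian is included so likelihoods are comparable), then a
linear mixed model with a person random effect on the transformed scale,
the within-person variance identified from the repeat-day subsample. The
full two-part (probability × amount) NCI model is deliberately reduced to
its amount part: vitamin A intake is essentially daily in this population,
so the consumption-probability part is degenerate.

Person-level usual intakes are shrunken (BLUP) person means rescaled by the
model-based shrinkage factor, so their variance matches the estimated
between-person variance — raw BLUPs understate the spread and badly bias
tail prevalences. Back-transformation uses the exact lognormal mean
correction on the log scale and a second-order Taylor correction for other
powers.

Prevalence is computed in *predictive* form by default: each child
contributes the posterior probability that their usual intake lies below the
(possibly program-shifted) cut-point, given their recall days and the
fitted variance components. This is unbiased for the population prevalence
under the model and smoother than classifying point estimates.

Two estimation subtleties matter and are worth stating plainly:

* **Attenuation in program overlays.** A program's dose depends on the
  child's own vehicle consumption, which correlates with their true usual
  intake. Any per-child point estimate correlates imperfectly with the
  truth, so "shift the estimate by the child's dose" dilutes that targeting
  and overstates deep-tail prevalence after strong interventions. For
  ordinary scenario accounting (effective coverage by region-year) the
  effect is small and the fast shift route is the default in
  `run_scenario()`. For the withdrawal trigger, which reads a ≈2% tail,
  it is not small: `run_pathway()` therefore refits the intake model on the
  program-shifted recall days (the transform power kept at its baseline
  choice), which estimates the shifted *marginal* directly. A config switch
  (`scenario_method`) exposes both routes.
* **Simulation vs estimation noise.** The optimizer consumes
  effective-coverage streams. Its default input is the deterministic
  population-level state table (`population_coverage_table()`), computed
  from the calibrated distributions by fixed-seed quadrature; the
  survey-estimated table (`coverage_state_table()`) is its finite-sample
  counterpart, and the two agree to within sampling noise (this is tested).
  Using the population table makes the optimization and its Monte Carlo
  robustness analysis reproducible quantities of the calibrated model
  rather than of one simulated survey.

## Programs

| Program | Dose | Schedule |
|---|---|---|
| Oil, 44% target | oil g/day × 12 µg/g × 0.44 | all years |
| Oil, enhanced | factor ramps 0.44 / 0.72 / 1.00 | full target from year 3 |
| Bouillon | g/day × 80 µg/g | three start-up years, benefits from year 4 |
| Biofortified maize | kcal/day × 0.34 µg/kcal | three phase-in years, benefits from year 4 |
| Supplementation | 167 µg RAE/day equivalent to reached children | any years, per region |

Reach (fraction receiving any additional vitamin A) follows consumption;
supplementation reach stays at the survey-measured values (0.89 North,
0.64 South, 0.58 Cities). Effective coverage of a program set is the drop in
prevalence of inadequate intake relative to baseline, floored at zero, and
is computed by the dietary model for every dose combination — overlapping
programs are never assumed additive.

## Mortality and costs

Deaths averted use a regional envelope of vitamin-A-preventable child deaths
(South 780/year and Cities 355/year as printed; North 2,194/year derived so
the printed ten-year supplementation deaths-averted total for the North,
13,630, is reproduced by the calibrated coverage stream) scaled by effective
coverage as a fraction of the resolvable burden (the baseline prevalence),
capped at the envelope. This deliberately collapses the cause-of-death
machinery of a full projection tool into one monotone map; it preserves the
two facts the analysis uses — the envelope bound, and the vanishing marginal
benefit of supplementation once fortification nears the resolvable burden.

Costs are annual streams in '000s of 2013 USD (500 CFA = 1 USD recorded as
metadata). The startup/operating/M&E decomposition is solved from the
printed ten-year totals, the optimal-sequence annual cost row (≈$598k/yr in
years 1–3, ≈$855k/yr thereafter net of supplementation), the mature South
fortification cost ($336k/yr) and the ≈$2.2m oil-upgrade / ≈$2.9m bouillon
anchors; regional shares are the printed per-region totals.
Supplementation is costed per region as a fixed annual component (a
configured share of which is campaign overhead charged at 90%) plus a
per-child delivery cost; 16% of the ten-year total scales with the child
population, matching the drift of the printed year-by-year totals.
Validation studies cost $450k per study (South printed; North assumed
equal; Cities $350k, printed only as "lower"). Ten-year totals under the
default configuration reproduce the printed program totals within 2%. No
discounting, matching the printed undiscounted totals.

## Optimization

The decision space is discrete: each national fortification program has a
start year (or never) and runs uninterrupted to the horizon (start-up
capital is sunk); the two oil programs are mutually exclusive;
supplementation is free per region-year. For a fixed fortification plan,
every region-year's coverage is a lookup into the state table, so the exact
solver sweeps all fortification plans in ascending cost order (with
incumbent pruning, the sweep terminates provably optimal) and solves an
exact branch-and-bound covering knapsack over the 30 supplementation items
for any residual coverage gap. No external MILP library is involved; the
solver is exhaustive over the structural space, deterministic, and ties
break toward the canonical enumeration order and earliest years. A point
solve takes well under a second, which is what makes the 1000-replicate
robustness loop cheap.

With the default calibration and the published floor of 12,836k child-years
the optimum selects enhanced oil + bouillon nationally in all ten years and
supplementation only in the North, only in years 1–2, at ≈$9.5m — the
published sequence and total.

## Withdrawal pathways

Each region runs the fixed build-out (enhanced oil ramp, bouillon from year
4) with supplementation retained. The trigger watches the
fortification-only dietary prevalence — the question being whether the
*diet* has become adequate — and fires the first year it drops below 2.5%.
One study confirms in the trigger year; in two-study mode a second study
follows two years later (the "nonconsecutive year" read as trigger + 2,
matching the published year-4/year-6 staging), and supplementation ends the
year after the final confirmation. Regions that never trigger keep
supplementation all ten years and still charge one year-4 study. Studies
are assumed to confirm; a config hook (`validation_confirms`) injects a
failure, which re-arms the machine.

On the calibrated defaults the South and Cities trigger in year 4 (bouillon
arriving), validate in years 4 and 6 and withdraw from year 7; the North
plateaus near 17% and never triggers. The one-study mode saves the South
two supplementation years plus one study, ≈$3.0m.

## Monte Carlo robustness

Each of 1000 replicates multiplies every program-region coverage stream by
an independent normal draw (mean 1, CV 0.05, truncated at zero — the
coverage standard errors are not published; 5% is the package default and
config-exposed) and each program family's costs by an independent uniform
draw in ±20% (published). One cost multiplier covers both oil variants: the
enhanced program is an upgrade of the same industrial base and shares the
oil coverage stream, so its cost uncertainty co-moves. A state's perturbed
coverage allocates the stream multipliers proportionally to the member
programs' solo coverages. Replicates that become infeasible are counted and
reported, never dropped. Inclusion follows the published rule:
fortification programs count when selected at all, supplementation counts
in a region when active at least three years.

## Calibration: what was solved, and what could not be

The generator's parameters are not hand-picked: `calibrate_region_profiles()`
solves, per region, for the between-person spread, the three consumption
medians and the oil-consumption correlation slope by weighted least squares
against the printed anchors (baseline prevalences; per-program coverage
cells; the mature-fortification prevalence floors; the mature
enhanced-vs-44% oil differential implied by the published program choice),
with the baseline prevalence matched exactly by an inner bisection. The
packaged configuration stores the solved values; re-running the calibration
reproduces them.

The printed anchors are mutually inconsistent in places, and the
calibration takes documented sides:

* The Cities baseline prevalence is not printed; 0.42 is forced by the
  printed business-as-usual coverage for Cities (coverage cannot exceed
  baseline prevalence) and is consistent with the "roughly half" national
  figure.
* The published North plateau ("from 60% to 20%") and the published
  year-by-year coverage row of the optimal sequence imply different North
  floors (≈0.20 vs ≈0.14); the calibration lands between (≈0.17).
* Several per-program cells (oil-44 South, supplementation Cities) exceed
  hard caps of any single coherent intake model; they are matched as well
  as the caps allow. The North supplementation stream is placed at the
  upper end of its anchor's uncertainty (0.45 vs the printed ten-year
  0.41) — without this the national fortification total, held down by the
  capped cells, would leave a coverage gap too large for exactly two
  supplementation years, contradicting the published sequence.
* Maize consumption is capped at complementary-feeding levels (≤75
  kcal/day medians); letting it float to its printed solo-coverage cell
  would make biofortified maize cost-effective enough to enter the optimal
  portfolio, contradicting the published exclusion (and its published ~11%
  Monte Carlo inclusion, which the calibrated model reproduces at ~4–10%).
* Child populations grow at 1.4%/yr — the growth implied by the constant
  coverage fractions of the printed year-by-year rows — with year-1 levels
  set so the ten-year child-year totals (12.7m / 13.9m / 5.8m) are exact.

## Problem sizes and numerical choices

The analysis scripts and acceptance checks use surveys of 4,000 children
per region with a 30% repeat-day subsample; unit tests use 1,200. The
population quadrature uses 40,000 fixed-seed draws per region. The
generator calibrates the sample median by bisection to the target
prevalence within ±0.01 and errors (reporting the achieved value) if it
cannot. Survey weights default to 1 — the source gives no weighting scheme
— and the sampling design (clusters, strata) is not emulated beyond region
stratification. Degenerate inputs behave by definition: zero within-person
CV makes recalls equal usual intake; zero consumer fractions zero the
vehicle; an EAR of zero (infinity) gives prevalence 0 (1).

## What passing tests do and do not show

The synthetic population reproduces the *structure* the published analysis
assumes — lognormal usual intake, vehicle consumption patterns with the
printed consumer fractions, the printed coverage anchors where they are
attainable — and the pipeline recovers known generator truths (prevalence
bias < 0.02 at n ≥ 1000 across a within-person-CV grid). That validates the
machinery, not the original survey: real recall data have seasonal
structure, correlated vehicle amounts, survey weights and cluster designs
that the generator deliberately omits, and the 2009 survey itself is not
publicly available. Results that depend on the exact survey joint
distribution (the per-cell coverage table) are reproduced only up to the
documented calibration compromises; results that depend on printed
arithmetic (costs, ratios, the optimal sequence, the pathway staging) are
reproduced essentially exactly.
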