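---
title: "A stock-and-flow population model of coexisting tobacco products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-and-flow population model of coexisting tobacco products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrpsim)
```

## The model

`prrpsim` projects the population-health consequences of markets in which
combustible cigarettes coexist with up to two potentially reduced-risk
nicotine products (PRRPs) — e-cigarettes and tobacco heating products (THPs)
— using a deterministic system-dynamics (stock-and-flow) formulation.

A person's tobacco status is their joint never/current/former status on every
modelled product, so a market with $N$ products has $3^N$ population stocks:
3 for cigarettes alone, 9 with one PRRP, 27 with two. Each status has exactly
one admissible move — never $\to$ current (initiation), current $\to$ former
(cessation), former $\to$ current (relapse) — and a transition flow changes a
non-empty subset of products simultaneously, each changed product performing
its admissible move. That yields $2^N - 1$ outflows per stock and
$3^N (2^N - 1)$ flows in total: 3, 27 and 189 for one, two and three
products.

```{r states}
states <- enumerate_states(2)
states
nrow(enumerate_flows(enumerate_states(3)))
```

Simultaneous multi-product moves are retained in the structure because they
are part of the flow combinatorics above, but default rate tables assign them
zero probability: the estimation sources for the transition inputs are
single-product Markov models, and no joint-move estimates exist.

Stocks are further resolved by gender and single year of age 0–100, and
former smokers by years abstinent (bins 1–20 and an open 20+ pool). Counts
are continuous (fractional persons), matching the difference-equation
semantics of a system-dynamics model; there is no individual-level
stochasticity anywhere in the deterministic engine.

## One simulated year

The projection runs from 2001 to 2100 in one-year steps. Each step applies a
fixed, audited sub-step order:

1. **Mortality.** Every cell dies at its status-specific annual probability
   (below). Age 100 dies with certainty, which closes the age ladder.
2. **Transitions.** Annual transition probabilities (not instantaneous
   hazards, matching the one-year intervals of the estimation sources) are
   applied to the survivors. Where a stock's outflow means sum above 1 they
   are rescaled proportionally.
3. **Ageing.** Every cohort ages one year and the quit clock advances; a
   smoker who quit during year $t$ is one year abstinent at the start of
   $t+1$; bin 20 pools into 20+.
4. **Births** enter at age 0 as never-users of everything.
5. **Net migration** is spread over gender and age by the schedule's age
   distribution; migrants adopt the product-status mix of the cell they join
   (a neutral assumption — no migrant smoking data are modelled), and
   removals larger than a cell clamp at zero with a warning.

Only the ageing/mortality coupling is dictated by the model description; the
rest of the order is a design choice fixed for reproducibility, and every
year the engine reconciles
`pop' = pop - deaths + births + net migration` to within $10^{-9}$ relative
(the test suite asserts it).

## Mortality and risk

Current smokers carry an age/gender relative risk $RR$ versus never-smokers.
The never-smoker death rate is derived once per (gender, age) at
initialisation by prevalence-weighted decomposition of the all-cause life
table rate, $m_{never} = m \cdot N / \sum_s n_s RR_s$, and then held as the
baseline (rescaled with the life table in later years); deriving it once
avoids circularity as prevalence evolves. Former smokers' *excess* risk
$RR - 1$ decays as a negative exponential with configurable half-life
(default 10 years — the sources behind this class of model support
single-figure to low-double-figure half-lives, and the value is exposed as
configuration rather than asserted); the open 20+ bin is evaluated at a
representative 25 years.

A PRRP "with X% the risk of cigarettes" scales the excess: an exclusive
current user of a product with fraction $f$ has $RR = 1 + f(RR_{cig} - 1)$
(defaults: e-cigarette 5%, THP 10%). This keeps never-users at $RR = 1$ and
matches the "95% less harmful" framing behind the 5% figure. Dual users take
the maximum of the component excesses — smoking dominates — a deliberately
conservative rule, since compensatory reductions in cigarettes smoked by
dual users are not modelled. Former PRRP use decays with the same half-life
machinery using the shared cigarette quit-time ledger; in cells where no
cigarette clock exists (the cigarette status is not "former") the PRRP
excess is evaluated undecayed, again conservative and quantitatively minor
because PRRP excesses are already scaled by $f$.

Life-years lost weight each death by the life table's remaining life
expectancy at the age of death, accumulated over the horizon; scenarios are
compared by the *reduction* in cumulative life-years lost versus the
smoking-only baseline. An alternative person-year-differencing mode
(`lyl_mode = "person_years"` in `compare_scenarios()`) is provided because
the published tables do not pin down the accounting; expectancy weighting is
the default since the life table's expectancy column is listed among the
model inputs.

## Scenarios

A scenario is a rate table plus modifiers: per-product market-introduction
years (e-cigarettes 2010, THPs 2014 in the reference setting; all flows
touching a product are gated to zero before its introduction and its stocks
start empty) and an optional geometric decline of cigarette initiation,
$(1-r)^{y - y_0}$ with $r = 3\%$ from 2020 in the "declining" variants. The
decline is applied to cigarette initiation only; whether it should also thin
PRRP initiation is not specified anywhere, and restricting it to cigarettes
is the narrower reading.

Two *pseudo-PRRP* scenarios approximate a three-product market inside a
two-product model: every transition probability (means and CI bounds alike,
with the same weights) and the excess-risk fraction are blended across the
two sole-product parameterisations at 50:50 or 63:37, giving combined risk
fractions of 7.5% and 6.85% of the cigarette's. The pseudo-product enters
the market in 2010 (the earlier of the two component introductions; the
source scenarios do not state it).

```{r blend}
100 * combine_pseudo_risk(0.05, 0.10, 0.50)
100 * combine_pseudo_risk(0.05, 0.10, 0.63)
```

Prevalence is reported for ages 14+ and, by default, counts dual users under
*both* products' series (`prevalence(..., dual = "exclusive")` implements the
other convention); the published prevalence rows do not define exclusivity,
so both are available and the default is documented rather than asserted.

## Monte-Carlo sensitivity

Transition estimates carry 95% confidence intervals, some very wide (a
THP-user-to-dual-use transition of mean 3.0% with CI 0.0–20.5% is the
canonical example). The sensitivity procedure redraws every sampled flow
independently within its CI and re-runs the projection, classically 1,000
times. The distribution *within* the CI is not specified by the procedure's
description, so two options ship: uniform on $[lo, hi]$ (default — the
least-informative reading) and a truncated normal with
$\sigma = (hi - lo)/3.92$. Draws are clamped to $[\max(0, lo), \min(1, hi)]$,
no correlation across flows is imposed (no joint distribution is published),
and all draws come from one seeded stream consumed in a documented order
(rows within a run, runs in sequence), so results are reproducible from the
seed alone. Summaries report min/max/mean/median/SD, the 5–25% percentiles by
linear interpolation between order statistics (`quantile` type 7, pinned for
comparability), and the share of runs with a negative life-years-lost
reduction.

## The synthetic fixture generator

No real demographic or smoking inputs ship with the package; the generator
builds an Italy-*shaped* bundle so that every module is runnable and the
tests need no downloads. Choices, made once for realism:

* **Mortality**: Gompertz–Makeham, $m(a) = c + \alpha e^{\beta a}$
  ($\alpha = 2.0\times10^{-5}$ male / $1.2\times10^{-5}$ female,
  $\beta = 0.1$, $c = 2\times10^{-4}$, infant bump at age 0), giving life
  expectancies at birth in the low-to-mid 80s. Remaining life expectancy is
  computed from the same rates by standard life-table construction, so the
  table is internally consistent.
* **Pyramid**: cohort sizes proportional to a declining-birth history times
  survival, lightly perturbed by seeded noise — old-heavy, as in Italy.
* **Smoking**: ever-smoking rises logistically through an initiation window
  of ages 11–30 (zero at 11), the former share of ever-smokers grows with
  age; the curve is scaled so that age-14+ current smoking at initialisation
  hits 19.7% *exactly* (the published 2010 anchor level, used as a
  calibration target for realism, never as a test oracle). Initiation
  hazards are then obtained from the ever curve by the discrete-hazard
  inversion `calibrate_initiation_from_prevalence()`, so the fixture's
  initiation is self-consistent with its prevalence.
* **Cigarette transitions**: cessation 2.5–4.5% per year rising with age;
  relapse 8% per year in the first abstinent year, declining geometrically
  (ratio 0.75) over the quit-time bins; dual users quit cigarettes at 2.5
  times the base rate (this is the mechanism by which a PRRP reduces
  smoking).
* **PRRP transitions** (e-cigarette-like reference): never-user initiation
  0.008 at ages 14–34, smoker uptake 0.03, former-smoker uptake 0.005,
  product cessation 0.12, product relapse 0.05; CI half-width 40% of the
  mean. The THP-like style applies exactly the structure reported for the
  underlying estimation sources — one quarter the never-user initiation,
  double the smoker uptake — and shares every other flow.

What the generator does **not** emulate: cohort-specific smoking histories
(the ever curve is a period curve), education/region gradients, year-varying
life tables and cessation rates, correlated transition uncertainties, and
any behavioural feedback between products beyond the dual-use flows. Passing
tests therefore demonstrate the *mechanics* of the model on plausible
inputs, not the published projections: those depend on proprietary
transition tables and national data extracts that are consumed as inputs,
not reproduced. The package's acceptance checks accordingly pin the
*structural* published quantities (stock/flow counts, blend fractions) and
the engine's numerical contracts, plus one qualitative ordering that follows
from the transition structure: with the quarter/double THP structure and
risk fractions 10% vs 5%, the THP-like scenario's life-years-lost reduction
exceeds the e-cigarette-like one's at 2100 — the direction, not the
magnitude, of the published comparison.

## Numerical choices and conventions

* Ages are integer completed years 0–100; a calendar year labels the state
  on 1 January. Year-indexed schedules carry the latest available year
  forward (no interpolation between life-table years — the published model
  leaves this unstated and carry-forward is the simpler auditable choice).
* Age-banded rate and risk inputs are expanded by repetition, not
  interpolation, since the sources report band-level estimates.
* `normalize_outflows()` expands bands to single ages before rescaling
  groups whose outflow means sum above 1; the engine performs the same
  normalisation on its compiled per-age arrays.
* Gender-specific rows override `"*"` rows; year-specific rows override
  all-year rows.
* All serialisation is comma-separated UTF-8 text at full (round-trip)
  precision; the decade comparison tables round to one decimal only when
  printed.

## Problem sizes used by the test suite

The shipped tests exercise the full 2001–2100 horizon on the synthetic
bundle (a run takes well under a second per scenario), a 50-step
Markov-oracle equivalence on a three-cohort toy population, a 31-year
calibration round-trip, and a 1,000-run sensitivity analysis over the
reduced 2001–2050 horizon — the same run count as the reference procedure at
half the horizon, which keeps the whole suite comfortably inside a few
minutes while still measuring the full-scale sensitivity machinery.

## Limitations

All-cause mortality only (no disease-specific risks); relative risks are not
linked to smoking duration; average consumption is implicit in the status
definitions (dual users' likely lower cigarette consumption is not
modelled); the population is stratified by age and gender only; and the
engine makes no forecasting claims — outputs are projections conditional on
the inputs and on currently-observed behaviour continuing.
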