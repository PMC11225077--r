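---
title: "A Markov cohort cost-utility model of cardiovascular polypill therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of cardiovascular polypill therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypillcea)
```

## The decision problem

A fixed-dose combination pill — aspirin 81 mg, hydrochlorothiazide 12.5 mg,
atorvastatin 20 mg, and valsartan 40 mg or enalapril 20 mg — is a candidate
strategy for the primary prevention of cardiovascular disease in adults aged
35 and over. The question this package answers is whether the polypill is
good value compared with giving each of its components alone, measured in
discounted lifetime cost (USD, patient perspective, direct medical costs)
and quality-adjusted life-years (QALYs).

The core is a deterministic Markov cohort model. A cohort enters an
event-free state at age 35 and is propagated through annual cycles to age
100 over nine health states:

* `EventFree` — no cardiovascular event yet;
* `Stroke`, `HF`, `PVD` — chronic post-event states entered directly;
* `AcuteMI` / `PostMI` and `AcuteAngina` / `PostAngina` — myocardial
  infarction and angina split into a one-cycle acute *tunnel* state and a
  chronic post-event state, so the event year can carry its own (much
  higher) cost and its own utility;
* `Dead` — absorbing.

There are no transitions between disease states: the model prices and
weights the *first* cardiovascular event and its sequelae. This is a cohort
model — state-occupancy fractions, not individuals — so results are exact
expectations per person; the nominal cohort size of 10,000 is only a
reporting multiplier.

## Inputs and their uncertainty

All inputs live in a single YAML config
(`system.file("extdata", "basecase.yaml", package = "polypillcea")`):
annual baseline event risks, state utilities, annual state costs, per-pack
drug prices, relative treatment effects (risk and hazard ratios), case
fatality, standardized mortality ratios (SMRs), and run settings. Every
uncertain input is a `(mean, sd, family)` triple, converted to native
distribution parameters by the method of moments at sampling time:

* **Beta** for probabilities and utilities:
  $\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$.
* **Gamma** for costs: shape $m^2/s^2$, scale $s^2/m$.
* **Log-normal** for RR/HR effects: $\sigma^2 = \log(1 + s^2/m^2)$,
  $\mu = \log m - \sigma^2/2$. The printed ratio is read as the
  *arithmetic* mean of the effect; a `lognormal_mean_is: median` config
  flag switches to the median convention ($\mu = \log m$), since the
  source table says only "mean".

Three input-handling rules deserve comment:

* **Infeasible Beta spreads.** Several printed utility rows violate the
  Beta feasibility bound $s^2 < m(1-m)$ (e.g. the stroke utility,
  mean 0.63 with sd 0.56). The sd is capped at
  $0.95\sqrt{m(1-m)}$, the mean — which drives the base case — is
  preserved, and the cap is logged per parameter at load time and in every
  run's `validation.txt`. The capped distributions are extremely dispersed
  (close to U-shaped), which the probabilistic analysis inherits; this is a
  stated stance, not a claim about what the original spreads meant.
* **SMRs.** The source table labels the SMR rows (means 2.17–2.72) as Beta,
  which cannot hold for a mean above 1; the shipped config fits them with
  Gamma distributions instead.
* **Missing effects.** Where a strategy has no printed effect for an event
  (dashes in the source), the effect is a fixed 1.0 and a notice is logged.
  The event-free utility of exactly 1 is treated as fixed rather than
  sampled, since a Beta at the boundary is degenerate.

Ranged inputs — MI, angina and PVD risks (1.1–9.4%, 1.5–13.3%, 0.7–6.2%)
and the sex-specific MI case fatality — are age profiles: both endpoints
are stored, and the value at age $a$ is linear interpolation over the span
35–85 (configurable via `risk_age_span`), clamped outside it. The base
case blends the male and female MI fatality 50/50 (`sex_mix_male`).

## The transition engine

From `EventFree` at age $a$ under strategy $k$, the five first events
compete. Each baseline risk $p_e(a)$ is adjusted by the strategy's effect
$e_{k}$ on the constant-rate scale, $p = 1-(1-p_e)^{e_k}$ — exact for
hazard ratios and numerically indistinguishable from a multiplicative risk
ratio at these annual magnitudes, so one convention serves both. Stroke,
HF and MI events split into an immediately fatal share (case fatality,
routed straight to `Dead`) and a nonfatal share entering the event state.
To this are added background mortality $q_x$ from the life table (SMR 1)
and a disease-specific death probability of 0.015 applied from `EventFree`
only, reduced by the strategy's *composite* effect — the geometric mean of
its printed event effects — so that a broadly protective therapy also
reduces this residual hazard without double-counting the SMRs. The
event-free residual is whatever mass remains; rows are never rescaled, and
a draw whose competing risks exceed 1 is an error (resampled inside the
PSA). In chronic states, annual death is $1-(1-q_x)^{SMR}$; acute tunnels
feed their post state with the complement of that same mortality. At the
terminal age $q_x = 1$ closes the table and the row collapses to `Dead`.

Rewards per cycle are occupancy-weighted utilities and costs. Costs
comprise the annual state cost (acute-year costs for the MI and angina
tunnels; no printed ongoing cost for the post states, hence zero there)
plus the annual medication cost in every alive state. Half-cycle
correction — averaging start- and end-of-cycle occupancy — is on by
default and switchable (`half_cycle_correction`); discounting uses
$(1+r)^{-t}$ with $t$ the zero-based cycle index, at 5.8%/year for costs
and 3%/year for QALYs. The closed-form oracle in the test suite (the
two-state chain with death probability 0.1 and 3% discounting, giving
$1/(1-0.9/1.03) \approx 7.9231$ discounted life-years) runs with the
correction off, where the geometric series is exact.

## The synthetic life table

The national life table behind the original analysis is not publicly
reprinted, so the package generates a deterministic stand-in: Gompertz
mortality $h(x) = h_{35}\,2^{(x-35)/8}$ (hazard doubling every 8 years),
with $h_{35}$ calibrated by root-finding so that further life expectancy
at 35 is 42 years — a plausible national figure for the study period —
and $q_x$ forced to 1 at age 100. This emulates the *shape* of adult
all-cause mortality but none of its sex structure, cohort trends, or
old-age plateau; any replacement table (CSV with `age,qx`, optional `sex`
column) shifts all absolute results, which is the dominant structural
caveat on the QALY totals. Passing tests therefore certify the engine's
arithmetic and the stated input conventions, not agreement with any real
national mortality experience.

Similarly, the age-linear interpolation of the ranged risks stands in for
the risk-equation-derived profiles the original inputs came from; the true
age pattern between the printed endpoints is unknowable from what is
printed.

## Drug-cost models and the calibrated factor

Printed pharmacy prices are per pack of ten tablets. Three conversions to
an annual cost are available (`cost_model`):

* `per_tablet_daily` — one (fractional) tablet a day:
  price/10 × 365 × dose fraction. The 12.5 mg hydrochlorothiazide dose is
  half of the printed 25 mg tablet, so its daily cost is half a tablet.
* `per_pack_monthly` — one pack a month: price × 12.
* `calibrated` — `per_tablet_daily` scaled by `drug_cost_factor`.

Taken literally, `per_tablet_daily` implies an annual polypill spend above
1,500 USD — larger than the published *lifetime* discounted total of
871 USD, so the printed price units cannot be taken at face value. The
shipped config uses the calibrated model with factor 1/42 ≈ 0.0238,
derived from the exchange rate quoted alongside the prices (42,000 rials
per USD): the printed figures read naturally as thousand-rial amounts
(42.85 ≈ 42,850 rials ≈ 1.02 USD per pack, a realistic pharmacy price),
and dividing by 42 converts them to actual USD. The factor is a declared
unit-reconciliation constant, not a fitted quantity: no choice of it can
reproduce the published total, because the model's disease-state costs
alone (about 1,785 USD discounted for the polypill arm, dominated by the
11,461.6 USD acute-MI year times lifetime MI incidence) already exceed it.

## Uncertainty analysis

* **Tornado** (`tornado()`): every scalar uncertain parameter is varied to
  ±20% of its mean (one-sided +20% available), probabilities and utilities
  clamped to [0, 1], all else held at base; the outcome is the incremental
  net monetary benefit at the 21,768 USD/QALY threshold (or the pairwise
  ICER) for a chosen pair of arms, by default polypill versus the
  comparator with the highest base-case NMB — the decision-relevant
  next-best alternative. Bars are sorted by absolute spread.
* **PSA** (`run_psa()`): joint independent draws of all uncertain
  parameters (no correlation structure is given to impose), one draw
  shared across arms per iteration, full model run per arm; iterations
  with structurally invalid draws (inverted ranges, competing risks past
  1 at some age) are resampled with a logged count. Default n = 5000,
  seed mandatory.
* **CEAC** (`ceac()`): at each threshold, the probability a strategy has
  the maximal net monetary benefit, ties split equally — unbiased and
  deterministic; the valsartan arm, which borrows the enalapril inputs
  wholesale, ties it exactly and shares its probability mass.
* **Plane quadrants** (`quadrant_summary()`): fractions of draws per
  cost-effectiveness-plane quadrant against each comparator.

With n = 5000 the full PSA takes on the order of two minutes on one core;
the deterministic base case is well under a second.

## What the model finds, and a known inconsistency

Running the shipped base case (`cmd_run()`, or the acceptance script)
gives, per person discounted: polypill 2,284.8 USD and 17.39 QALYs, with
hydrochlorothiazide strictly dominant at 1,637.8 USD and 17.54 QALYs, and
a polypill CEAC value of about 26% at the threshold (n = 5000, seed 1).
The published analysis of the same input table reported the polypill as
dominant (lowest cost 871 USD, highest QALYs 14.55; 92% probability at
the threshold). The discrepancy is structural, not numerical: the input
table gives hydrochlorothiazide a stronger MI effect (HR 0.34) than the
polypill (0.66), and MI is both the deadliest and by far the costliest
event, so *any* engine that applies the printed effects uniformly across
arms will rank hydrochlorothiazide above the polypill; the cost totals
likewise cannot fall to the published level while the acute-MI cost row
and the annual event risks are taken as printed. The acceptance tests
encode the published values at their stated tolerances and are expected
to fail on this model; they document the gap rather than hide it.

## Numerical choices and limitations

* Ties in the frontier (equal cost and QALYs) keep the alphabetically
  earlier label, logged; extended dominance is implemented via the
  standard non-increasing-ICER elimination and verified against a
  brute-force convex-combination oracle on random instances.
* Degenerate inputs: zero-sd or boundary-mean specs become point masses;
  a utility outside [0, 1] or an inverted range is a load-time error
  naming the parameter.
* The model is first-event only (no stroke-after-MI and similar), has no
  adherence, discontinuation or adverse-event structure, and no
  value-of-information analysis.
* Problem sizes used throughout (66 annual cycles, 5000 PSA iterations,
  1000-instance frontier checks) keep every analysis comfortably fast
  while leaving Monte-Carlo error on CEAC probabilities near ±1
  percentage point.
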