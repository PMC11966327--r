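---
title: "Methods: the AKI-prevention implementation cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AKI-prevention implementation cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akicea)
```

## Model structure and assumptions

The package evaluates four strategies for implementing a contrast-associated
AKI prevention protocol in cardiac catheterization laboratories. Each
strategy is characterized by exactly two quantities: the probability that a
patient develops AKI within 7 days of catheterization, and a per-person
upfront implementation cost (training time, and for surveillance strategies,
dashboard construction and maintenance). Everything downstream of the AKI
event is shared across strategies.

The structure is a decision tree feeding a Markov cohort model:

1. **Decision tree (day 0–30).** A Bernoulli AKI branch at the strategy's
   AKI probability, then a categorical 30-day disposition over
   `normal`, `ckd`, `esrd`, `death`, conditional on AKI status. The tree
   accrues `upfront + p_aki * aki_episode_cost` at time zero, undiscounted.
2. **Markov phase (years 1–3).** Yearly cycles over the living states
   stratified by AKI history — post-AKI patients carry systematically worse
   annual transition probabilities (e.g. 12.3%/y vs 6.7%/y mortality from
   normal kidney function). Death is absorbing; backward transitions
   (CKD→normal, ESRD→CKD) are structurally absent; stay probabilities are
   residuals of the printed exits. The stratification is implemented as an
   8-state block-diagonal transition matrix, so occupancy always sums to 1
   and the history label never changes.

Key assumptions inherited from the data-generating trial setting:

* The annual transition tables are the mean of the three observed yearly
  tables; the model applies the same table each cycle.
* A single payer (the VA) bears both implementation costs and downstream
  care costs, so cost offsets accrue to the same budget.
* AKI's immediate impact is a single $14,000 episode cost; patients who
  recover by day 30 accrue no further episode-related cost.
* The first 30 days contribute no QALYs; the horizon counts the three
  Markov years only. Patients dead at day 30 enter the Markov phase dead
  and accrue nothing.

## Parameters

All parameters live in one validated table (`param_table()`), addressable
by id. Units and base-case defaults:

| group | ids | units | base case |
|---|---|---|---|
| AKI probabilities | `p_aki.<strategy>` | fraction | 0.079–0.133 (95% CIs from trial data) |
| 30-day dispositions | `p30.<aki/no_aki>.<state>` | fraction | trial data; rows sum to 1 ± 0.005 |
| annual transitions | `annual.<origin>.<history>.<dest>` | fraction/year | trial data (±25% ranges) |
| utilities | `utility.<state>` | QALY/year | 0.85 / 0.80 / 0.70, death 0 |
| upfront costs | `cost.upfront.<strategy>` | 2020 USD/person | $2.69–$12.74 (±25%) |
| disease costs | `cost.aki_episode`, `cost.annual.ckd`, `cost.annual.esrd` | 2020 USD | $14,000 / $25,322/y / $78,537/y (±25%) |

Settings (not sampled): discount rate 3%/year, horizon 3 years, WTP
$100,000/QALY primary and $50,000/QALY secondary. Model files are YAML
(fractions by default, `units: percent` accepted); the bundled file is
`inst/extdata/improve_aki.yaml`.

Two input irregularities are handled explicitly:

* The no-AKI 30-day row sums to 0.999 as printed — a rounding artifact. It
  is renormalized proportionally at load with a warning; deviations beyond
  0.005 are errors.
* The AKI episode cost's published interval is inconsistent with its own
  base case (the point estimate lies outside it), so the package uses ±25%
  of the base case for both one-way and probabilistic sensitivity analysis,
  matching the convention used for the other cost inputs.

## Cycle and discounting conventions

Published three-year totals depend on an accrual convention that
cohort-model reports rarely state. The engine therefore exposes toggles:

* `accrual = "pre"` (**default**): cycle *t*'s reward is earned by the
  occupancy at the start of the year and discounted at that time point,
  `(1+r)^-(t-1)`. The 30-day distribution earns the first year's reward.
* `accrual = "post"`: end-of-year occupancy, discounted `(1+r)^-t`.
* `half_cycle = TRUE`: the average of the two, each half at its own
  discount point (trapezoid / half-cycle correction).

The default was chosen by golden-test calibration: among the toggle
combinations, cycle-start accrual comes closest to the originally reported
totals for these inputs, and reproduces the reported *incremental* QALYs
between strategies to three decimals along with the full dominance pattern.
The dominance ordering, incremental signs, and every threshold and PSA
conclusion are stable across all toggle combinations.

A residual discrepancy remains and is worth stating plainly, because it is a
property of the published inputs rather than of any convention. The
reported absolute totals (≈$2,480 and 2.314 QALYs for the preferred
strategy) are not jointly reachable from the published transition tables:
with 1.4% 30-day and 6.7%/year baseline mortality, the discounted
three-year QALY total of even an AKI-free cohort is bounded above by ≈2.29
under any convention that accrues at most one utility-year per cycle, and
the implied downstream cost difference between the AKI and no-AKI branches
is several-fold larger than the reported between-strategy cost spreads
imply. The package keeps the inputs as published and reports what they
yield (≈$2,814 and 2.250 QALYs at the default toggles); the acceptance
suite records the comparison honestly rather than adjusting inputs to
retrofit the published outputs. All comparative conclusions — dominance,
signs, PSA preference, the ranking of sensitivity drivers — are unaffected.

## Sensitivity analyses

**One-way.** `run_owsa()` re-evaluates the model at each bound of one
parameter's range with everything else at base case, reporting the
incremental NMB of a strategy pair at each bound; `tornado()` orders bars
by swing width (stable sort, ties by name). Editing one exit of a 30-day
row makes the row sum ≠ 1; rows are renormalized proportionally at use, so
a bound edit perturbs the complementary exits pro rata. An edit that drives
an annual row's exits past 1 is an error naming the bound.

**Probabilistic.** `run_psa()` draws every uncertain parameter once per
iteration — beta for probabilities and utilities, gamma for costs, moment
matched with `sd = (high − low)/3.92`, treating printed intervals as
normal-approximation 95% ranges (a conservative variance choice given that
no SDs are published). Utilities vary over their published CIs. Parameters
are drawn independently (no correlation information exists in the inputs);
30-day rows are renormalized after drawing each exit independently, since
only marginal distributions are available. Structurally infeasible draws
(negative stay residual) are redrawn, capped at 100 per iteration; with the
bundled inputs redraws essentially never occur. Ties for the preferred
strategy break by lower cost, then name — a measure-zero event. Default
n = 1000 iterations.

**Threshold.** NMB is affine in a strategy's upfront cost with slope −1,
so the break-even cost against a comparator has the closed form
`c* = c_base + NMB_varied(c_base) − NMB_comparator`. A bracketed root
search (`uniroot` on `[c_base, c_base + 1e6]`) is always run alongside and
must agree within $10^{-6}$; the dual route validates the affinity
assumption and would generalize if cost ever entered nonlinearly. Varying a
strategy that is not preferred at base case is an error ("no positive
headroom") rather than a negative threshold.

## The synthetic trial generator

`simulate_trial()` emulates the patient-level data-generating process the
cohort model assumes: Bernoulli 7-day AKI per arm, categorical 30-day
disposition conditional on AKI, and yearly categorical transitions from the
history-stratified annual tables. Each arm draws from a substream keyed by
the master seed and the arm name, so arms are reproducible independently of
which other arms are simulated. `estimate_parameters()` inverts it:
empirical proportions with Wald 95% CIs (`p ± 1.96·√(p(1−p)/n)`, truncated
to [0,1]) for every probability cell, pooling transitions across years.
Wald intervals were chosen because the model's input intervals are
symmetric; the estimator is deliberately simple and swappable.

What the generator does *not* emulate: the cluster randomization of the 20
trial sites (no site-level random effects are estimable from the published
inputs), per-year transition tables (only the 3-year average is available),
and any patient-level covariates. Passing recovery tests therefore shows
that estimation inverts *this* generative model at trial-scale n — not that
the model captures site heterogeneity in real data. Real per-arm
denominators are not published, so arm sizes are user-chosen.

`accrue_records()` accrues per-patient discounted cost/QALYs under exactly
the cohort conventions, which supports the microsimulation cross-check:
cohort totals are expectations of the patient-level accrual, and the test
suite verifies agreement within three Monte Carlo standard errors at
n = 10⁵.

## Numerical choices and problem sizes

* Occupancy conservation is enforced to 1e-9 per cycle (achieved at ~1e-16);
  death occupancy must be non-decreasing.
* Threshold solver tolerance 1e-6 USD; thresholds reported to 2 d.p.
* PSA distribution fits reproduce base-case means to relative 1e-6.
* Validation tolerances: 30-day row sums within 0.005 (renormalized);
  annual exit sums ≤ 1 strictly.
* Test-suite problem sizes: 1000-iteration PSA over 10 seeds for the
  preference fraction; 10⁵ patients for the microsimulation check; 20
  seeds × 50,000 patients/arm for Wald-coverage of the generating
  probabilities (target ≥ 90%); RMSE monotonicity over n ∈ {10³, 10⁴, 10⁵}.

## Limitations

* Three-year horizon: no lifetime extrapolation, so chronic-disease cost
  and QALY differences are truncated; a longer horizon would favor the
  low-AKI strategy further (or less, if implementation effects fade).
* The published-input inconsistency described above means absolute totals
  should be read as model outputs of the printed inputs, not as replicas of
  the originally reported totals; comparative results are robust.
* Single-payer (VA) perspective; a predominantly male, older cohort; no
  transportability adjustments to other systems.
* Whether recovered post-AKI patients accrue first-year costs beyond the
  episode cost is not stated in the source inputs; the model assumes not.
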