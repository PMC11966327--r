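# akicea

Cost-effectiveness modeling of implementation strategies for preventing
contrast-associated acute kidney injury (AKI) after cardiac catheterization.

## The problem

Guideline-based protocols (intravenous volume expansion, contrast-volume
limits) reliably reduce contrast-associated AKI, but their uptake depends on
*how* they are implemented. In a multisite VA trial (IMPROVE AKI), cardiac
catheterization laboratories deployed an AKI-prevention protocol under four
implementation strategies: technical **assistance**, assistance with
automated **surveillance** reporting, a virtual learning **collaborative**,
and collaborative with surveillance. The strategies differ in their 7-day AKI
rates and their per-person upfront costs, and an AKI episode carries both an
immediate cost and a lasting excess risk of chronic kidney disease (CKD),
end-stage renal disease (ESRD) and death. `akicea` asks, from the payer's
perspective: which strategy buys the most health for the least money?

## The model

A decision tree feeds a Markov cohort model. For strategy $s$ with AKI
probability $p_s$, the cohort branches on 7-day AKI, then lands in one of
four 30-day states $j \in \{\text{normal}, \text{CKD}, \text{ESRD},
\text{death}\}$ via the AKI-conditional disposition row $P(j \mid
\text{AKI})$. The tree accrues $c_s + p_s \, c_{\text{AKI}}$ at time zero
(upfront cost plus expected episode cost, $c_{\text{AKI}} = \$14{,}000$).
The cohort then runs through $H = 3$ yearly Markov cycles over the living
states stratified by AKI history (post-AKI patients progress faster), with
death absorbing and no backward transitions. With discount rate $r = 3\%$
per year and cycle-$t$ occupancy $\pi_t$,

$$\text{Cost} = c_s + p_s c_{\text{AKI}} + \sum_{t=1}^{H} (1+r)^{-(t-1)}
\pi_{t-1}^\top c, \qquad \text{QALY} = \sum_{t=1}^{H} (1+r)^{-(t-1)}
\pi_{t-1}^\top u,$$

under the default cycle-start accrual convention ($c$, $u$ are per-state
annual costs and utilities; cycle-end and half-cycle conventions are
toggles). Strategies are ranked by dominance and net monetary benefit,
$\mathrm{NMB} = \mathrm{QALY} \times \mathrm{WTP} - \mathrm{Cost}$, at
willingness-to-pay thresholds of \$100,000 and \$50,000 per QALY.

On top of the base case the package provides one-way sensitivity analysis
with tornado ordering, probabilistic sensitivity analysis (beta/gamma
distributions moment-matched to the input intervals; CEAC output),
break-even threshold analysis on the upfront intervention cost, and a
synthetic patient-level trial generator with Wald re-estimation of every
probability — closing the loop from simulated trial data back to model
inputs.

## Worked example

```r
library(akicea)
m <- aki_model_improve()                  # bundled trial inputs
res <- evaluate_strategies(m)
build_cea_table(res, wtp = 1e5)
```

```
Cost-effectiveness league table (WTP $100,000/QALY; increments vs collaborative_surveillance)
 strategy                   dominance cost    inc_cost qaly  inc_qaly icer nmb
 collaborative_surveillance dominant  2813.81 NA       2.250 NA       NA   222224.78
 assistance_surveillance    dominated 3413.94 600.13   2.239 -0.011   NA   220530.17
 collaborative              dominated 3640.94 827.12   2.235 -0.015   NA   219896.65
 assistance                 dominated 3744.14 930.33   2.233 -0.017   NA   219605.82
```

Collaborative with surveillance — despite the highest upfront cost
(\$12.74/person) — is *dominant*: cheapest and most effective, because its
lower AKI rate (7.9% vs 11.4–13.3%) avoids \$14,000 episodes and downstream
kidney disease. Every other strategy costs \$600–930 more per patient and
loses 0.011–0.017 QALYs over three years. How expensive could the preferred
strategy become before losing that status?

```r
threshold_table(m)
```

```
                      varied              comparator    wtp threshold
1 collaborative_surveillance assistance_surveillance 100000  1707.349
2 collaborative_surveillance assistance_surveillance  50000  1160.107
3 collaborative_surveillance              assistance 100000  2631.702
4 collaborative_surveillance              assistance  50000  1787.386
```

Its upfront cost could grow roughly a hundredfold (to ~\$1,700 per person at
WTP \$100,000/QALY against the next-best strategy) before the ranking flips
— the decision is driven by disease costs, not implementation costs, as the
tornado analysis (`tornado(owsa_all(m))`) confirms.

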