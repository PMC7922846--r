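---
title: "A lifetime Markov cost-effectiveness model of NET imaging strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cost-effectiveness model of NET imaging strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcea)
```

## The decision problem

Neuroendocrine tumors (NETs) are rare, often indolent neoplasms whose
somatostatin-receptor expression makes them visible to nuclear imaging.
When a NET is suspected, the imaging choice — CT alone, ¹¹¹In-pentetreotide
SPECT/CT, or ⁶⁸Ga-DOTA-TATE PET/CT — trades diagnostic performance against
tariff: PET/CT is the most sensitive and the most expensive per scan. The
question the model answers is whether the extra imaging cost is repaid by
downstream savings and better outcomes, from a US-payer perspective, over a
patient's remaining lifetime.

`netcea` implements this as a two-stage decision-analytic model:

1. **Diagnostic decision tree.** With pre-test probability $p$ and test
   performance $(se, sp)$, an imaged patient is a true positive with
   probability $p \cdot se$, false negative $p(1-se)$, true negative
   $(1-p)sp$, false positive $(1-p)(1-sp)$. Each outcome carries an acute
   cost (imaging, confirmatory workup, timely or delayed surgery and
   treatment) and determines the starting state of the cohort model.
2. **Lifetime Markov cohort model.** Annual cycles from age 30 to age 100
   through the states *no relevant tumor burden*, *clinically relevant
   tumor burden without treatment*, *clinically relevant tumor burden with
   treatment*, and *death*, accumulating discounted costs and
   quality-adjusted life years (QALYs).

Strategies are compared by incremental cost-effectiveness ratio
$\mathrm{ICER} = (C_1 - C_0)/(E_1 - E_0)$, dominance and the efficiency
frontier, and by net monetary benefit $\mathrm{NMB} = \lambda E - C$ at a
willingness-to-pay of $\lambda$ = \$100,000/QALY.

## State space and structural choices

The published four-state diagram under-determines an executable model, so
the engine refines it into seven concrete columns
(`health_states()`), chosen so that every input parameter is wired in
exactly once:

* `no_burden` — baseline disease-free life (utility 1, no yearly cost);
* `no_burden_postwork` — the same clinical situation in the first year
  after an unnecessary workup (utility 0.779). The penalty is a one-cycle
  reward track: survivors who do not progress return to `no_burden`;
* `no_burden_posttreat` — remission after treated disease: utility 0.779,
  yearly after-treatment cost \$2,107, and 8.8 %/yr recurrence;
* `clinrel_untreated` — clinically relevant disease missed by imaging
  (utility 0.612, yearly cost \$61,375, 12.12 % annual disease death);
  conditional on survival the patient always presents and moves to
  treatment on the *delayed* track;
* `clinrel_treated_timely` / `clinrel_treated_delayed` — treated disease
  (utility 0.768, yearly cost \$61,375) with 4.0 % vs 4.5 % annual disease
  death; survivors enter remission after one cycle;
* `death` — absorbing, zero reward.

Disease-specific death, the 2.5 %/yr competing-cause risk and the
age-specific life-table risk combine as independent competing risks,
$p_{die} = 1 - (1-p_{dis})(1-p_{comp})(1-q_x \cdot rr)$, in **every** alive
state; no combination rule is published, and treating the three hazards as
independent is the standard assumption. Progression from any disease-free
track re-enters the *timely* treated state: recurrence is detected under
surveillance.

Two timing conventions are fixed by the model's own first-cycle
calibration: rewards are applied to start-of-cycle occupancy with **no
half-cycle correction**, and the discount factor is $1/(1+r)^{k-1}$ so
cycle 1 is undiscounted. With these, the first-cycle accumulators reproduce
arithmetic identities of the inputs exactly — a true-positive start accrues
$85{,}068 + 61{,}375 = \$146{,}443$ and 0.768 QALYs after one year, a
false-negative start $127{,}602 + 61{,}375 = \$188{,}977$ and 0.612 — which
is how the parameter wiring is validated end to end.

```{r calibration}
cfg <- default_net_config()
tr <- run_cohort(cfg, "clinrel_treated_timely", acute_cost = cfg$costs$timely_treatment)
c(cost = tr$cum_cost[1], qaly = tr$cum_qaly[1])
```

The confirmatory biopsy (\$1,375) is charged to every test-positive, true
or false: a positive scan triggers the same workup either way. The toggle
`charge_biopsy_tp` exposes the alternative reading (biopsy only on false
positives). The utility table also records a 0.690 "without treatment"
value; the untreated clinically-relevant state is nevertheless rewarded at
0.612, the value the first-cycle calibration forces, and 0.690 is kept as
`utilities$without_treatment_alt` without being wired to any state.

## Background mortality

Age-specific other-cause mortality comes from a period life table
(`age`, `qx`), scaled by `relative_risk_other_death` and clamped to
$[0,1]$. No published US table ships with R, so the bundled table
(`inst/extdata/life_table_us_synthetic.csv`, loaded by
`default_life_table()`) is a **synthetic** Gompertz–Makeham curve,
$q_x = \min(1,\, a + b e^{c\,x})$ with $a = 5\times10^{-4}$,
$b = 3\times10^{-5}$, $c = 0.09$ and $q_{100} = 1$: about 0.9 per 1,000 at
age 30, 2 per 1,000 at 40, rising to near-certainty by 100 — a plausible
approximation of a recent US period table for the adult ages the model
visits, not a reproduction of any specific vintage. Users with a real table
can pass it anywhere a `life_table` is accepted (`load_life_table()`).
Ages are integers and never interpolated, matching the 1-year cycle.

## Parameters and uncertainty

`default_net_config()` carries the complete base case: prevalence 5 %,
CT 77 %/86 %/\$787, SPECT/CT 70 %/96 %/\$1,242, PET/CT 91 %/92 %/\$1,375,
the acute and yearly costs and utilities above, 3 % discounting, WTP
\$100,000/QALY, ages 30→100. `load_config()` merges a partial YAML file
over these defaults and rejects unknown keys; the dialect is documented in
`inst/extdata/config-schema.yaml`.

Probabilistic sensitivity analysis needs a distribution per parameter, but
only families are specified by the sources (beta for probabilities and
utilities, gamma for costs) — never spreads. The defaults are an effective
sample size of 100 for every beta parameter
($\alpha = \mu\,ess,\ \beta = (1-\mu)\,ess$) and a coefficient of variation
of 0.2 for every gamma parameter ($k = 1/cv^2,\ \theta = \mu\,cv^2$) —
common practice for CEA models with unreported uncertainty — both
overridable per parameter in the config, so the sensitivity of conclusions
to the spreads is itself inspectable. Parameters whose point estimate sits
on the boundary of the family's support (the no-burden utility of 1, the
untreated-to-treated probability of 1, the life-table relative risk of 1,
zero-mean costs) are held fixed, as are the discount rate, WTP and ages.
Draws are independent across parameters; no correlation structure is
asserted.

## What the computations look like

```{r basecase}
res <- run_base_case(cfg)
res
icer_table(res)
```

PET/CT strictly dominates both comparators: its higher sensitivity moves
patients from the expensive, deadlier false-negative path to timely
treatment, and its specificity advantage over CT avoids unnecessary
workups; together these more than repay the higher tariff. The magnitudes
are larger than headline figures published for comparable models — with a
near-healthy majority cohort, lifetime discounted QALYs land near 14, not
4 — because the full structure behind models built in closed-source
decision-tree software is rarely recoverable from their published input
tables; the *ordinal* conclusion (strict dominance of PET/CT) is the
robust, reproducible result.

```{r dsa, eval = FALSE}
tor <- tornado(cfg)          # +/-20% one-way sweeps, 10 workup parameters
autoplot(tor)
psa <- sample_psa(cfg, n = 30000, seed = 1)
autoplot(ceac(psa))
```

The default tornado sweeps the ten diagnostic-workup parameters
(sensitivity, specificity, imaging cost per strategy, biopsy cost) by
±20 %, clipped to the parameter's domain, and reports the incremental NMB
of PET/CT against the best alternative — NMB rather than an ICER bar
because negative ratios are sign-ambiguous while the ordering decisions
coincide. ±20 % is a wide band for a test sensitivity, and at several
extremes (PET/CT performance down 20 %, comparator performance up 20 %)
the incremental NMB does go negative: the dominance conclusion is robust
to cost perturbations but, unsurprisingly, not to erasing the diagnostic
advantage itself.

In the 30,000-draw PSA (vectorized across draws; a run takes seconds),
PET/CT has the highest NMB at \$100,000/QALY in about 80 % of draws. Its
acceptability curve falls below 0.5 only at willingness-to-pay under about
\$5,000/QALY, where decisions are driven almost purely by cost and the
base-case cost margin over CT (≈\$13) is thin relative to parameter
uncertainty.

## Validation strategy

* **First-cycle identities** (above) validate the parameter wiring
  exactly, to the cent.
* **Microsimulation oracle.** `simulate_individuals()` replays the same
  transition matrices and rewards at the individual level;
  cohort expectations must agree with 200,000-individual means within 3
  standard errors across random configurations and all starting states.
  Because the oracle shares the transition/reward definitions, it
  validates the cohort expectation algebra (matrix propagation, discount
  indexing), not the wiring — which the calibration identities cover.
* **Closed-form limits.** With zero mortality, unit utilities and no
  discounting, QALYs equal the cycle count exactly; at zero prevalence,
  strategies differ in cost only through imaging tariffs and the
  false-positive workup burden.
* **Dual PSA route.** The vectorized PSA engine is checked for exact
  agreement with the matrix-based cohort engine on individual draws.

## Numerical and degenerate-input choices

Occupancy conservation is enforced to $10^{-10}$ per cycle in tests; the
engine itself uses plain double arithmetic (the 7×7 products are benign).
Frontier ties in cost are broken by higher effect; sequential ICERs must
increase strictly, equal-ICER middle points being removed as
extended-dominated. CEAC ties split the win equally among tied strategies.
A cohort started in `death` accrues nothing. The engine refuses life
tables that stop short of the horizon and configs failing any invariant
(all violations reported by field name).

Default problem sizes — 70 annual cycles, 30,000 PSA iterations, 200,000
microsimulated individuals for oracle checks — are the model's study
conditions; all complete in seconds to a few minutes on one core.

## Limitations

The synthetic data emulate parameter uncertainty and background mortality,
not real-world heterogeneity: no tumor grade or stage structure (the model
speaks to G1/G2, SSR-expressing disease), no sex- or cohort-specific life
tables, no imperfect reference standard for biopsy, no currency-year
adjustment, and independence of all sampled parameters. Passing tests
therefore demonstrate internal consistency and faithful arithmetic of the
stated model — not external validity for any particular clinical
population.
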