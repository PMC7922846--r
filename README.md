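# netcea

Decision-analytic cost-effectiveness modelling of diagnostic imaging
strategies for suspected neuroendocrine tumors (NETs): ⁶⁸Ga-DOTA-TATE
PET/CT versus ¹¹¹In-pentetreotide SPECT/CT versus CT alone, from a US-payer
perspective.

NETs express somatostatin receptors, so receptor-targeted nuclear imaging
(PET/CT, SPECT/CT) detects them more reliably than CT — at a higher tariff
per scan. `netcea` is for health-economics analysts who want that tradeoff
quantified and stress-tested: it chains a diagnostic decision tree into a
lifetime Markov cohort model and runs the standard toolkit of
cost-effectiveness analysis on top.

**Model core.** A patient imaged with a strategy of sensitivity *se* and
specificity *sp* under pre-test probability *p* lands in one of four
branches — TP (*p·se*), FN (*p(1−se)*), TN ((1−*p*)*sp*), FP
((1−*p*)(1−*sp*)) — each with an acute cost and a starting state in a
Markov model over *no relevant tumor burden*, *clinically relevant tumor
burden without treatment*, *clinically relevant tumor burden with
treatment*, and *death*. Annual cycles run from age 30 to 100 with
age-specific background mortality from a bundled (synthetic,
Gompertz–Makeham) life table; costs and QALYs are discounted at 3%/yr.
Strategies are compared by

&nbsp;&nbsp;ICER = (C₁ − C₀) / (E₁ − E₀),

dominance and the efficiency frontier, and by net monetary benefit
NMB = λ·E − C at willingness-to-pay λ = $100,000/QALY. One-way ±20% sweeps
give a tornado diagram; a 30,000-iteration Monte Carlo PSA (beta-distributed
probabilities/utilities, gamma-distributed costs) gives incremental
scatters and cost-effectiveness acceptability curves (CEAC). An
individual-level microsimulation oracle validates the cohort engine. See
`vignettes/net-imaging-cea.Rmd` for the full model account.

## Worked example

```r
library(netcea)

cfg <- default_net_config()
cfg
#> <netcea_config> v1.0
#>   prevalence 0.050 | ages 30-100 | discount 3.0% | WTP $100,000/QALY
#>   PET/CT     sens 0.91 spec 0.92 imaging $1,375
#>   SPECT/CT   sens 0.70 spec 0.96 imaging $1,242
#>   CT         sens 0.77 spec 0.86 imaging $787

res <- run_base_case(cfg)
res
#> <netcea_result> expected lifetime discounted cost and QALYs
#>     label       cost   qaly
#>    PET/CT $103751.67 14.306
#>  SPECT/CT $104350.41 14.298
#>        CT $103764.70 14.282

icer_table(res)
#>   strategy     cost     qaly delta_cost delta_effect icer      flag
#> 1   PET/CT 103751.7 14.30555         NA           NA   NA      <NA>
#> 2       CT 103764.7 14.28199         NA           NA   NA dominated
#> 3 SPECT/CT 104350.4 14.29751         NA           NA   NA dominated
```

PET/CT is cheaper **and** more effective than both comparators — it
strictly dominates, so no ICER is defined against it (a negative ratio is
reported as dominance, never as a number). The mechanism: higher
sensitivity moves patients off the expensive, deadlier false-negative path
into timely treatment, and better specificity than CT avoids unnecessary
workups; both savings outweigh the higher scan tariff.

```r
psa <- sample_psa(cfg, n = 30000, seed = 1)
glance(psa)
#> # A tibble: 1 × 4
#>   n_draws    wtp best_strategy p_best
#>     <int>  <dbl> <chr>          <dbl>
#> 1   30000 100000 PET/CT         0.801
```

At $100,000/QALY, PET/CT has the highest net monetary benefit in 80% of
Monte Carlo draws. `ceac(psa)`, `tornado(cfg)` and
`incremental_scatter(psa, "pet_ct", "ct")` produce the acceptability
curves, tornado diagram and incremental scatter, each with an
`autoplot()`/`plot_*()` companion; `run_basecase_report()`,
`run_dsa_report()` and `run_psa_report()` write everything as CSV plus a
JSON run manifest (also reachable from a shell via
`Rscript inst/scripts/netcea.R <basecase|dsa|psa> --out DIR`).

Custom scenarios are partial YAML files merged over the defaults
(`load_config("my.yaml")`; schema in `inst/extdata/config-schema.yaml`),
and any real period life table can replace the bundled synthetic one via
`load_life_table()`.

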