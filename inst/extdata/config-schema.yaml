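# Schema of the netcea model configuration file (YAML or JSON).
# Any subset of these keys may appear; missing keys keep their base-case
# defaults. Keys not listed here are rejected, except that new strategy names
# may be added under `strategies` and parameter paths under the PSA override
# maps. Units: costs in USD, rates per year, ages in years.
version: string            # constants-file version tag
prevalence: number         # pre-test probability of NET, in (0, 1)
start_age: integer         # cohort entry age, years
horizon_age: integer       # model horizon, years; > start_age
discount_rate: number      # annual discount rate, >= 0
wtp: number                # willingness-to-pay, USD per QALY
cycle_length: number       # years per Markov cycle (engine requires 1)
strategies:                # >= 2 entries; keys are strategy identifiers
  <name>:
    label: string          # unique display label
    imaging_cost: number   # USD, >= 0
    sensitivity: number    # in [0, 1]
    specificity: number    # in [0, 1]
costs:                     # all USD, >= 0
  timely_treatment: number         # acute, true positive
  delayed_treatment: number        # acute, false negative
  unnecessary_biopsy: number       # acute, false positive
  true_negative_acute: number      # acute, true negative
  biopsy: number                   # confirmatory workup, test-positives
  yearly_no_burden: number         # per year, no relevant tumor burden
  yearly_treated_non_relevant: number  # per year, remission after treatment
  yearly_clinically_relevant: number   # per year, clinically relevant disease
utilities:                 # all in [0, 1]; death must be 0
  no_burden: number
  no_clinically_relevant_burden: number  # post-workup / remission track
  clinically_relevant_treated: number
  progression_untreated: number
  without_treatment_alt: number    # recorded; not wired into any state
  death: number
transitions:               # annual probabilities in [0, 1]
  p_death_timely: number
  p_death_delayed: number
  p_death_untreated: number
  p_death_competing: number
  p_progression: number
  p_untreated_to_treated: number
  relative_risk_other_death: number  # multiplier on life-table qx, >= 0
charge_biopsy_tp: boolean  # charge confirmatory biopsy to true positives
life_table_ref: string     # source tag of the life table in use
psa:
  iterations: integer      # Monte Carlo draws, >= 1
  beta_ess: number         # effective sample size for beta parameters, > 0
  gamma_cv: number         # coefficient of variation for gamma parameters, > 0
  beta_ess_overrides:      # optional per-parameter overrides
    <parameter path>: number
  gamma_cv_overrides:
    <parameter path>: number
seed: integer              # default RNG seed for PSA runs
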