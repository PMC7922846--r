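outcome_levels <- c("TP", "FN", "TN", "FP")

#' Diagnostic outcome probabilities
#'
#' Branch probabilities of the diagnostic decision tree: a patient with
#' disease (probability `prevalence`) tests positive with probability
#' `sensitivity`; a patient without disease tests negative with probability
#' `specificity`.
#'
#' @param prevalence Pre-test probability of disease, in \[0, 1\].
#' @param sensitivity,specificity Test performance, each in \[0, 1\].
#' @return A tibble with columns `outcome` (TP/FN/TN/FP) and `probability`;
#'   the probabilities sum to 1.
#' @examples
#' outcome_probabilities(0.05, 0.91, 0.92)
#' @export
outcome_probabilities <- function(prevalence, sensitivity, specificity) {
  for (arg in c("prevalence", "sensitivity", "specificity")) {
    x <- get(arg)
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("`", arg, "` must be a probability in [0, 1]"),
            class = "netcea_domain_error")
    }
  }
  tibble::tibble(
    outcome = outcome_levels,
    probability = c(prevalence * sensitivity,
                    prevalence * (1 - sensitivity),
                    (1 - prevalence) * specificity,
                    (1 - prevalence) * (1 - specificity))
  )
}

#' Acute (cycle-0) cost of a diagnostic outcome
#'
#' Every patient pays the strategy's imaging cost. Test-positives proceed to
#' confirmatory workup: true positives incur the biopsy (when
#' `charge_biopsy_tp`, the default) plus timely surgery and treatment; false
#' positives incur the unnecessary biopsy. False negatives later present
#' clinically and incur delayed surgery and treatment; true negatives incur
#' no further action.
#'
#' @param strategy A strategy entry of a `netcea_config` (list with
#'   `imaging_cost`).
#' @param outcome One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @param costs The `costs` block of a `netcea_config`.
#' @param charge_biopsy_tp Charge the confirmatory biopsy to true positives?
#' @return Acute cost in USD.
#' @export
acute_cost <- function(strategy, outcome, costs, charge_biopsy_tp = TRUE) {
  if (!outcome %in% outcome_levels) {
    abort(paste0("Unknown outcome: ", outcome), class = "netcea_domain_error")
  }
  strategy$imaging_cost + switch(
    outcome,
    TP = (if (charge_biopsy_tp) costs$biopsy else 0) + costs$timely_treatment,
    FN = costs$delayed_treatment,
    FP = costs$unnecessary_biopsy,
    TN = costs$true_negative_acute
  )
}

#' Markov starting state of a diagnostic outcome
#'
#' True positives start in the clinically-relevant-with-treatment state on
#' the timely track; false negatives start clinically relevant without
#' treatment; true negatives and false positives start with no relevant tumor
#' burden, the false positives on the post-workup reward track (first-cycle
#' utility 0.779 instead of 1).
#'
#' @param outcome One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @return A health-state name (see [health_states()]).
#' @export
start_state <- function(outcome) {
  if (!outcome %in% outcome_levels) {
    abort(paste0("Unknown outcome: ", outcome), class = "netcea_domain_error")
  }
  switch(outcome,
         TP = "clinrel_treated_timely",
         FN = "clinrel_untreated",
         TN = "no_burden",
         FP = "no_burden_postwork")
}

#' Full outcome distribution for one strategy
#'
#' Combines [outcome_probabilities()], [acute_cost()] and [start_state()] for
#' one diagnostic strategy under a configuration.
#'
#' @param config A `netcea_config`.
#' @param strategy_name Name of an entry in `config$strategies`.
#' @return A tibble with one row per outcome: `outcome`, `probability`,
#'   `acute_cost`, `start_state`.
#' @examples
#' outcome_distribution(default_net_config(), "pet_ct")
#' @export
outcome_distribution <- function(config, strategy_name) {
  s <- config$strategies[[strategy_name]]
  if (is.null(s)) {
    abort(paste0("Unknown strategy: ", strategy_name), class = "netcea_domain_error")
  }
  op <- outcome_probabilities(config$prevalence, s$sensitivity, s$specificity)
  dplyr::mutate(
    op,
    acute_cost = vapply(.data$outcome, acute_cost, numeric(1),
                        strategy = s, costs = config$costs,
                        charge_biopsy_tp = config$charge_biopsy_tp),
    start_state = vapply(.data$outcome, start_state, character(1))
  )
}
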