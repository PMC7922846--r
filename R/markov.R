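#' Health states of the cohort model
#'
#' Seven concrete states. The three "no relevant tumor burden" columns are
#' reward tracks of the same clinical situation: `no_burden` (baseline,
#' utility 1, no yearly cost), `no_burden_postwork` (first cycle after an
#' unnecessary workup, utility 0.779), and `no_burden_posttreat` (remission
#' after treated disease: utility 0.779, yearly follow-up cost, 8.8%/yr
#' recurrence). The two treated clinically-relevant states encode the
#' timely/delayed track (4.0% vs 4.5% annual disease-specific death).
#' `death` is absorbing.
#'
#' @return Character vector of state names, in the canonical column order.
#' @export
health_states <- function() {
  c("no_burden", "no_burden_postwork", "no_burden_posttreat",
    "clinrel_untreated", "clinrel_treated_timely", "clinrel_treated_delayed",
    "death")
}

#' Annual transition matrix at a given age
#'
#' Death combines the state's disease-specific annual risk, the competing
#' cause risk and the life-table background risk as independent competing
#' risks: `p_die = 1 - (1 - p_disease) (1 - p_competing) (1 - p_background)`.
#' Conditional on survival: untreated clinically-relevant patients move to
#' treatment on the delayed track (probability
#' `transitions$p_untreated_to_treated`, 1 by default); treated
#' clinically-relevant patients enter remission; no-burden patients progress
#' to clinically relevant disease (timely track) with
#' `transitions$p_progression`, the remission state recurring at the same
#' rate. Non-progressing post-workup survivors return to the baseline
#' no-burden reward track.
#'
#' @param config A `netcea_config`.
#' @param age Age (whole years) at the start of the cycle; must be covered by
#'   the life table.
#' @param lt A `life_table` (default: the bundled synthetic US-style table).
#' @return A 7 x 7 row-stochastic matrix over [health_states()].
#' @export
transition_matrix <- function(config, age, lt = default_life_table()) {
  tr <- config$transitions
  p_bg <- background_death_prob(lt, age, tr$relative_risk_other_death)
  die <- function(p_disease) {
    p <- 1 - (1 - p_disease) * (1 - tr$p_death_competing) * (1 - p_bg)
    if (p > 1) {  # unreachable for valid inputs; kept as a guard
      warn("combined death probability clamped to 1")
      p <- 1
    }
    p
  }
  st <- health_states()
  m <- matrix(0, 7, 7, dimnames = list(st, st))
  p_prog <- tr$p_progression

  d0 <- die(0)
  m["no_burden", ] <- 0
  m["no_burden", "clinrel_treated_timely"] <- (1 - d0) * p_prog
  m["no_burden", "no_burden"] <- (1 - d0) * (1 - p_prog)
  m["no_burden", "death"] <- d0

  m["no_burden_postwork", "clinrel_treated_timely"] <- (1 - d0) * p_prog
  m["no_burden_postwork", "no_burden"] <- (1 - d0) * (1 - p_prog)
  m["no_burden_postwork", "death"] <- d0

  m["no_burden_posttreat", "clinrel_treated_timely"] <- (1 - d0) * p_prog
  m["no_burden_posttreat", "no_burden_posttreat"] <- (1 - d0) * (1 - p_prog)
  m["no_burden_posttreat", "death"] <- d0

  dut <- die(tr$p_death_untreated)
  m["clinrel_untreated", "clinrel_treated_delayed"] <-
    (1 - dut) * tr$p_untreated_to_treated
  m["clinrel_untreated", "clinrel_untreated"] <-
    (1 - dut) * (1 - tr$p_untreated_to_treated)
  m["clinrel_untreated", "death"] <- dut

  dtt <- die(tr$p_death_timely)
  m["clinrel_treated_timely", "no_burden_posttreat"] <- 1 - dtt
  m["clinrel_treated_timely", "death"] <- dtt

  dtd <- die(tr$p_death_delayed)
  m["clinrel_treated_delayed", "no_burden_posttreat"] <- 1 - dtd
  m["clinrel_treated_delayed", "death"] <- dtd

  m["death", "death"] <- 1
  m
}

#' Per-state cycle rewards
#'
#' Yearly cost and utility accrued by one cycle spent in each state:
#' clinically relevant states (treated or not) accrue the yearly
#' clinically-relevant cost; remission accrues the yearly after-treatment
#' cost; the no-burden tracks accrue the (zero) yearly no-burden cost.
#' Utilities: 1 baseline, 0.779 post-workup/remission, 0.768 treated
#' clinically relevant, 0.612 untreated clinically relevant, 0 dead.
#'
#' @param config A `netcea_config`.
#' @return A tibble with columns `state`, `yearly_cost`, `utility` in
#'   [health_states()] order.
#' @export
cycle_rewards <- function(config) {
  co <- config$costs
  u <- config$utilities
  tibble::tibble(
    state = health_states(),
    yearly_cost = c(co$yearly_no_burden, co$yearly_no_burden,
                    co$yearly_treated_non_relevant,
                    co$yearly_clinically_relevant,
                    co$yearly_clinically_relevant,
                    co$yearly_clinically_relevant, 0),
    utility = c(u$no_burden, u$no_clinically_relevant_burden,
                u$no_clinically_relevant_burden, u$progression_untreated,
                u$clinically_relevant_treated, u$clinically_relevant_treated,
                u$death)
  )
}

#' Discount factor for a cycle
#'
#' `1 / (1 + rate)^(cycle - 1)`: the first cycle is undiscounted, so
#' first-cycle rewards equal the raw state rewards.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle 1-based cycle index.
#' @return Discount multiplier in (0, 1\].
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 1))
  (1 + rate)^-(cycle - 1)
}

#' Evolve a cohort from one starting state
#'
#' Propagates a unit cohort through the annual transition matrices from
#' `start_age` to `horizon_age`, accumulating per-cycle costs and QALYs.
#' Rewards are applied to the start-of-cycle occupancy (no half-cycle
#' correction), the first cycle is undiscounted, and the acute cost enters
#' cycle 1 undiscounted. Cohort remaining at the horizon is truncated with no
#' terminal reward.
#'
#' @param config A `netcea_config` (requires `cycle_length == 1`).
#' @param start_state One of [health_states()].
#' @param acute_cost One-off cost added at cycle 1, USD.
#' @param lt A `life_table` covering `start_age` to `horizon_age - 1`.
#' @return A `markov_trace` tibble with one row per cycle: `cycle`, `age`,
#'   start-of-cycle occupancy per state, `cost`, `qaly` (undiscounted),
#'   `disc_cost`, `disc_qaly`, and running `cum_cost`, `cum_qaly`
#'   (discounted).
#' @examples
#' tr <- run_cohort(default_net_config(), "clinrel_treated_timely",
#'                  acute_cost = 85068)
#' tr$cum_cost[1]  # acute + one year of clinically relevant care
#' @export
run_cohort <- function(config, start_state, acute_cost = 0,
                       lt = default_life_table()) {
  validate_config(config)
  if (config$cycle_length != 1) {
    abort("the cohort engine uses 1-year cycles; set cycle_length = 1",
          class = "netcea_domain_error")
  }
  st <- health_states()
  if (!start_state %in% st) {
    abort(paste0("Unknown start state: ", start_state),
          class = "netcea_domain_error")
  }
  n_cycles <- config$horizon_age - config$start_age
  ages <- config$start_age + seq_len(n_cycles) - 1
  if (min(ages) < min(lt$age) || max(ages) > max(lt$age)) {
    abort("life table does not cover the modelled age range",
          class = "netcea_domain_error")
  }
  rw <- cycle_rewards(config)
  occ <- setNames(numeric(7), st)
  occ[start_state] <- 1
  occ_mat <- matrix(NA_real_, n_cycles, 7, dimnames = list(NULL, st))
  cost <- qaly <- numeric(n_cycles)
  for (k in seq_len(n_cycles)) {
    occ_mat[k, ] <- occ
    cost[k] <- sum(occ * rw$yearly_cost) + if (k == 1) acute_cost else 0
    qaly[k] <- sum(occ * rw$utility)
    occ <- drop(occ %*% transition_matrix(config, ages[k], lt))
  }
  df <- discount_factor(config$discount_rate, seq_len(n_cycles))
  out <- tibble::tibble(cycle = seq_len(n_cycles), age = ages,
                        tibble::as_tibble(occ_mat),
                        cost = cost, qaly = qaly,
                        disc_cost = cost * df, disc_qaly = qaly * df,
                        cum_cost = cumsum(cost * df),
                        cum_qaly = cumsum(qaly * df))
  attr(out, "start_state") <- start_state
  attr(out, "acute_cost") <- acute_cost
  class(out) <- c("markov_trace", class(out))
  out
}

# Lifetime discounted (cost, qaly) for each of the four branch start states,
# excluding acute costs (those are branch-specific and added by the caller).
branch_values <- function(config, lt = default_life_table()) {
  starts <- unique(vapply(outcome_levels, start_state, character(1)))
  purrr::map_dfr(starts, function(s) {
    tr <- run_cohort(config, s, acute_cost = 0, lt = lt)
    tibble::tibble(start_state = s,
                   cost = tr$cum_cost[nrow(tr)],
                   qaly = tr$cum_qaly[nrow(tr)])
  })
}

#' Expected lifetime result of one diagnostic strategy
#'
#' Probability-weighted sum over the TP/FN/TN/FP branches of the acute cost
#' plus the discounted lifetime Markov cost, and the discounted lifetime
#' QALYs.
#'
#' @param config A `netcea_config`.
#' @param strategy_name Name of an entry in `config$strategies`.
#' @param lt A `life_table`.
#' @param branches Optional precomputed [branch values][run_cohort]
#'   (internal use).
#' @return A one-row tibble: `strategy`, `label`, `cost`, `qaly`.
#' @export
expected_strategy_result <- function(config, strategy_name,
                                     lt = default_life_table(),
                                     branches = NULL) {
  if (is.null(branches)) branches <- branch_values(config, lt)
  od <- outcome_distribution(config, strategy_name)
  od <- dplyr::left_join(od, branches, by = "start_state")
  tibble::tibble(
    strategy = strategy_name,
    label = config$strategies[[strategy_name]]$label %||% strategy_name,
    cost = sum(od$probability * (od$acute_cost + od$cost)),
    qaly = sum(od$probability * od$qaly)
  )
}

#' Base-case cost-effectiveness results for all strategies
#'
#' Runs the full pipeline — decision tree, lifetime Markov cohort model,
#' discounting — for every configured strategy.
#'
#' @param config A `netcea_config` (default: [default_net_config()]).
#' @param lt A `life_table`.
#' @return A `netcea_result` tibble with one row per strategy (`strategy`,
#'   `label`, `cost`, `qaly`), carrying the willingness-to-pay as an
#'   attribute. Feed it to [icer_table()], [net_monetary_benefit()] or
#'   [frontier()].
#' @examples
#' res <- run_base_case(default_net_config())
#' icer_table(res)
#' @export
run_base_case <- function(config = default_net_config(),
                          lt = default_life_table()) {
  validate_config(config)
  branches <- branch_values(config, lt)
  out <- purrr::map_dfr(names(config$strategies), expected_strategy_result,
                        config = config, lt = lt, branches = branches)
  attr(out, "wtp") <- config$wtp
  class(out) <- c("netcea_result", class(out))
  out
}
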