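# Shared fixtures, built in code.

# Default config with a short horizon for cheap runs.
short_config <- function(horizon = 40) {
  cfg <- default_net_config()
  cfg$horizon_age <- horizon
  cfg
}

# Degenerate limit: nobody dies, every alive state has utility 1, no
# discounting. QALYs must then equal the cycle count exactly.
immortal_config <- function(horizon = 40) {
  cfg <- short_config(horizon)
  cfg$discount_rate <- 0
  cfg$transitions$p_death_timely <- 0
  cfg$transitions$p_death_delayed <- 0
  cfg$transitions$p_death_untreated <- 0
  cfg$transitions$p_death_competing <- 0
  cfg$transitions$relative_risk_other_death <- 0
  for (u in c("no_clinically_relevant_burden", "clinically_relevant_treated",
              "progression_untreated", "without_treatment_alt")) {
    cfg$utilities[[u]] <- 1
  }
  cfg
}

branch_starts <- function() {
  unique(vapply(c("TP", "FN", "TN", "FP"), start_state, character(1)))
}

expect_row_stochastic <- function(m, tol = 1e-12) {
  expect_true(all(m >= 0))
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = tol)
}
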