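test_that("transition matrices are row-stochastic with an absorbing death state", {
  cfg <- default_net_config()
  lt <- default_life_table()
  for (age in c(30, 50, 75, 99)) {
    m <- transition_matrix(cfg, age, lt)
    expect_row_stochastic(m)
    expect_equal(unname(m["death", ]), c(0, 0, 0, 0, 0, 0, 1))
  }
  set.seed(21)
  for (i in 1:10) {
    expect_row_stochastic(transition_matrix(random_config(seed = i),
                                            sample(30:99, 1), lt))
  }
})

test_that("death combines disease, competing and background risks independently", {
  cfg <- default_net_config()
  cfg$transitions$relative_risk_other_death <- 0  # switch background off
  m <- transition_matrix(cfg, 50)
  # untreated row: 1 - (1 - 0.1212) (1 - 0.025), remainder to delayed treatment
  expect_equal(m["clinrel_untreated", "death"], 1 - (1 - 0.1212) * (1 - 0.025))
  expect_equal(m["clinrel_untreated", "clinrel_treated_delayed"],
               (1 - 0.1212) * (1 - 0.025))
  # with background on, the three risks multiply
  lt <- default_life_table()
  cfg$transitions$relative_risk_other_death <- 1
  q50 <- background_death_prob(lt, 50)
  m2 <- transition_matrix(cfg, 50, lt)
  expect_equal(m2["clinrel_treated_timely", "death"],
               1 - (1 - 0.04) * (1 - 0.025) * (1 - q50))
})

test_that("cycle rewards wire each yearly cost and utility to its state", {
  rw <- cycle_rewards(default_net_config())
  expect_equal(rw$state, health_states())
  expect_equal(rw$yearly_cost, c(0, 0, 2107, 61375, 61375, 61375, 0))
  expect_equal(rw$utility, c(1, 0.779, 0.779, 0.612, 0.768, 0.768, 0))
})

test_that("discounting leaves the first cycle untouched", {
  expect_equal(discount_factor(0.03, 1), 1)
  expect_equal(discount_factor(0.03, 2), 1 / 1.03)
  expect_equal(discount_factor(0, 1:10), rep(1, 10))
})

test_that("first-cycle treatment-path accumulators reproduce the calibration identities", {
  cfg <- default_net_config()
  tp <- run_cohort(cfg, "clinrel_treated_timely", acute_cost = 85068)
  expect_equal(tp$cum_cost[1], 146443)
  expect_equal(tp$cum_qaly[1], 0.768)
  fn <- run_cohort(cfg, "clinrel_untreated", acute_cost = 127602)
  expect_equal(fn$cum_cost[1], 188977)
  expect_equal(fn$cum_qaly[1], 0.612)
})

test_that("traces conserve occupancy with monotone death and accumulators", {
  cfg <- short_config(70)
  for (s in branch_starts()) {
    tr <- run_cohort(cfg, s)
    occ <- as.matrix(tr[, health_states()])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(tr)), tolerance = 1e-10)
    expect_true(all(occ >= -1e-15))
    expect_true(all(diff(tr$death) >= -1e-15))
    expect_true(all(diff(tr$cum_cost) >= 0))
    expect_true(all(diff(tr$cum_qaly) >= 0))
  }
  dead <- run_cohort(cfg, "death")
  expect_equal(dead$cum_cost[nrow(dead)], 0)
  expect_equal(dead$cum_qaly[nrow(dead)], 0)
  expect_equal(dead$death, rep(1, nrow(dead)))
})

test_that("immortal unit-utility undiscounted cohorts accrue one QALY per cycle", {
  cfg <- immortal_config(40)  # 10 cycles
  for (s in branch_starts()) {
    tr <- run_cohort(cfg, s)
    expect_equal(tr$cum_qaly[nrow(tr)], 10)
  }
})

test_that("a one-cycle model equals the branch-weighted first-cycle values", {
  cfg <- short_config(31)
  rw <- cycle_rewards(cfg)
  res <- expected_strategy_result(cfg, "pet_ct")
  od <- outcome_distribution(cfg, "pet_ct")
  state_cost <- setNames(rw$yearly_cost, rw$state)
  state_util <- setNames(rw$utility, rw$state)
  expect_equal(res$cost,
               sum(od$probability * (od$acute_cost + state_cost[od$start_state])))
  expect_equal(res$qaly, sum(od$probability * state_util[od$start_state]))
})

test_that("a perfect test has no false-branch contribution", {
  cfg <- short_config(60)
  cfg$strategies$perfect <- list(label = "Perfect", imaging_cost = 1000,
                                 sensitivity = 1, specificity = 1)
  od <- outcome_distribution(cfg, "perfect")
  expect_equal(od$probability[od$outcome %in% c("FN", "FP")], c(0, 0))
  res <- expected_strategy_result(cfg, "perfect")
  tp <- run_cohort(cfg, "clinrel_treated_timely",
                   acute_cost = 1000 + 1375 + 85068)
  tn <- run_cohort(cfg, "no_burden", acute_cost = 1000)
  expect_equal(res$cost, 0.05 * tp$cum_cost[30] + 0.95 * tn$cum_cost[30])
  expect_equal(res$qaly, 0.05 * tp$cum_qaly[30] + 0.95 * tn$cum_qaly[30])
})

test_that("raising any state utility weakly raises every strategy's QALYs", {
  cfg <- short_config(55)
  base <- run_base_case(cfg)
  for (u in c("no_clinically_relevant_burden", "clinically_relevant_treated",
              "progression_untreated")) {
    cfg2 <- cfg
    cfg2$utilities[[u]] <- min(1, cfg$utilities[[u]] + 0.1)
    bumped <- run_base_case(cfg2)
    expect_true(all(bumped$qaly >= base$qaly - 1e-12))
    expect_equal(bumped$cost, base$cost)  # utilities never touch costs
  }
})

test_that("the engine refuses a life table that stops short of the horizon", {
  lt <- life_table(0:80, rep(0.01, 81))
  expect_error(run_cohort(default_net_config(), "no_burden", lt = lt),
               "life table", class = "netcea_domain_error")
  expect_error(run_cohort(default_net_config(), "nowhere"),
               class = "netcea_domain_error")
})
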