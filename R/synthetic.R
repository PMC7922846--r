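#' Generate a random valid model configuration
#'
#' Draws every uncertain parameter (see [psa_parameter_table()]) uniformly
#' from an interval around its base value and returns a validated
#' configuration. Useful for property-based testing of the pipeline.
#'
#' @param seed RNG seed; the same seed reproduces the same configuration.
#' @param rel_range Relative half-width of the default sampling interval
#'   (default 0.5, i.e. 50% around the base value, clipped to the
#'   parameter's domain). `rel_range = 0` collapses every interval to the
#'   base value and returns the defaults.
#' @param bounds Optional named list of explicit `c(low, high)` intervals per
#'   parameter path, overriding the default interval for those parameters.
#'   Bounds outside the parameter's domain (or with `low > high`) are an
#'   error.
#' @return A validated `netcea_config`.
#' @examples
#' random_config(seed = 1)$prevalence
#' @export
random_config <- function(seed, rel_range = 0.5, bounds = NULL) {
  config <- default_net_config()
  pt <- psa_parameter_table(config)
  set.seed(seed)
  for (i in seq_len(nrow(pt))) {
    p <- pt$parameter[i]
    base <- pt$mean[i]
    b <- bounds[[p]]
    if (is.null(b)) {
      b <- c(base * (1 - rel_range), base * (1 + rel_range))
      if (pt$family[i] == "beta") b <- pmin(pmax(b, 1e-6), 1 - 1e-6) else b <- pmax(b, 0)
    }
    if (length(b) != 2 || b[1] > b[2]) {
      abort(paste0("Infeasible bounds for ", p), class = "netcea_domain_error")
    }
    if (pt$family[i] == "beta" && (b[1] < 0 || b[2] > 1)) {
      abort(paste0("Bounds for ", p, " outside [0, 1]"), class = "netcea_domain_error")
    }
    if (b[1] < 0) {
      abort(paste0("Bounds for ", p, " must be >= 0"), class = "netcea_domain_error")
    }
    config <- config_set(config, p, runif(1, b[1], b[2]))
  }
  validate_config(config)
  config
}

#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n` independent annual state trajectories through the same
#' transition matrices and cycle rewards as [run_cohort()], accumulating
#' per-individual discounted cost and QALYs. This is the brute-force oracle
#' for the cohort engine: its means must agree with the cohort expectations
#' up to Monte Carlo error.
#'
#' @param config A `netcea_config`.
#' @param start_state One of [health_states()].
#' @param acute_cost One-off cost added at cycle 1, USD.
#' @param n Number of simulated individuals.
#' @param seed RNG seed.
#' @param lt A `life_table`.
#' @return A `netcea_microsim` list: `n`, per-individual `cost` and `qaly`
#'   vectors, and a one-row `summary` tibble with means and standard errors
#'   (`se = sd / sqrt(n)`).
#' @examples
#' ms <- simulate_individuals(default_net_config(), "clinrel_treated_timely",
#'                            acute_cost = 85068, n = 2000, seed = 1)
#' ms$summary
#' @export
simulate_individuals <- function(config, start_state, acute_cost = 0, n,
                                 seed = config$seed, lt = default_life_table()) {
  validate_config(config)
  if (n < 1) abort("`n` must be >= 1", class = "netcea_domain_error")
  st <- health_states()
  if (!start_state %in% st) {
    abort(paste0("Unknown start state: ", start_state), class = "netcea_domain_error")
  }
  rw <- cycle_rewards(config)
  n_cycles <- config$horizon_age - config$start_age
  ages <- config$start_age + seq_len(n_cycles) - 1
  disc <- discount_factor(config$discount_rate, seq_len(n_cycles))
  set.seed(seed)
  state <- rep(match(start_state, st), n)
  cost <- rep(acute_cost, n)
  qaly <- numeric(n)
  for (k in seq_len(n_cycles)) {
    cost <- cost + disc[k] * rw$yearly_cost[state]
    qaly <- qaly + disc[k] * rw$utility[state]
    m <- transition_matrix(config, ages[k], lt)
    nxt <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      nxt[idx] <- sample.int(7, length(idx), replace = TRUE, prob = m[s, ])
    }
    state <- nxt
  }
  out <- list(
    n = n, cost = cost, qaly = qaly,
    summary = tibble::tibble(
      n = n,
      mean_cost = mean(cost), se_cost = sd(cost) / sqrt(n),
      mean_qaly = mean(qaly), se_qaly = sd(qaly) / sqrt(n)
    )
  )
  class(out) <- "netcea_microsim"
  out
}

#' @export
print.netcea_microsim <- function(x, ...) {
  cat("<netcea_microsim> n =", x$n, "individuals\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.netcea_microsim <- function(x, ...) x$summary
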