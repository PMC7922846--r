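# Incremental NMB of one focal strategy against the best of the others.
incremental_nmb <- function(results, focal = "pet_ct", wtp = 1e5) {
  nm <- net_monetary_benefit(results, wtp)
  i <- match(focal, nm$strategy)
  if (is.na(i)) i <- match(focal, nm$label)
  if (is.na(i)) abort(paste0("Unknown strategy: ", focal), class = "netcea_domain_error")
  nm$nmb[i] - max(nm$nmb[-i])
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-runs the full pipeline with the parameter set to `low` and to `high`
#' (all other parameters at base values) and records the incremental net
#' monetary benefit of the focal strategy versus the best alternative at each
#' end.
#'
#' @param config A `netcea_config`.
#' @param parameter Parameter path as in [psa_parameter_table()], e.g.
#'   `"strategies$pet_ct$sensitivity"` or `"costs$biopsy"`.
#' @param low,high Values at the two ends of the sweep (`low <= high`), both
#'   within the parameter's domain.
#' @param focal Strategy whose incremental NMB is tracked (default
#'   `"pet_ct"`).
#' @param wtp Willingness-to-pay for the NMB (default: `config$wtp`).
#' @param lt A `life_table`.
#' @return A one-row tibble: `parameter`, `low`, `high`, `nmb_low`,
#'   `nmb_high`, `width` (absolute NMB swing).
#' @export
one_way_dsa <- function(config, parameter, low, high, focal = "pet_ct",
                        wtp = config$wtp, lt = default_life_table()) {
  base <- config_get(config, parameter)  # errors on unknown parameter
  if (low > high) abort("`low` must be <= `high`", class = "netcea_domain_error")
  at <- function(value) {
    cfg <- config_set(config, parameter, value)
    validate_config(cfg)
    incremental_nmb(run_base_case(cfg, lt), focal = focal, wtp = wtp)
  }
  nmb_low <- at(low)
  nmb_high <- if (high == low) nmb_low else at(high)
  tibble::tibble(parameter = parameter, low = low, high = high,
                 nmb_low = nmb_low, nmb_high = nmb_high,
                 width = abs(nmb_high - nmb_low))
}

#' Tornado analysis across the swept parameters
#'
#' Sweeps each diagnostic-workup parameter (sensitivity, specificity and
#' imaging cost of every strategy, plus the biopsy cost) by a relative range
#' around its base value — the default is +/-20%, with probabilities clipped
#' to \[0, 1\] — and stacks the [one_way_dsa()] bars, sorted by decreasing
#' width.
#'
#' @param config A `netcea_config`.
#' @param parameters Character vector of parameter paths; defaults to the ten
#'   test-performance and workup-cost parameters.
#' @param rel_range Relative half-width of the sweep (default 0.2).
#' @param focal,wtp,lt As in [one_way_dsa()].
#' @return A `netcea_tornado` tibble, one row per parameter, sorted by
#'   decreasing bar width; also records the base-case incremental NMB as the
#'   `base_nmb` attribute.
#' @export
tornado <- function(config, parameters = NULL, rel_range = 0.2,
                    focal = "pet_ct", wtp = config$wtp,
                    lt = default_life_table()) {
  if (is.null(parameters)) {
    parameters <- c(
      paste0("strategies$", rep(names(config$strategies), each = 3),
             c("$sensitivity", "$specificity", "$imaging_cost")),
      "costs$biopsy")
  }
  if (length(parameters) == 0) {
    warn("no parameters to sweep; returning an empty tornado")
    out <- tibble::tibble(parameter = character(), low = numeric(),
                          high = numeric(), nmb_low = numeric(),
                          nmb_high = numeric(), width = numeric())
    class(out) <- c("netcea_tornado", class(out))
    return(out)
  }
  is_prob <- grepl("sensitivity|specificity|^transitions|prevalence|^utilities",
                   parameters)
  out <- purrr::map_dfr(seq_along(parameters), function(i) {
    p <- parameters[i]
    base <- config_get(config, p)
    lo <- base * (1 - rel_range)
    hi <- base * (1 + rel_range)
    if (is_prob[i]) {
      lo <- max(0, lo)
      hi <- min(1, hi)
    } else {
      lo <- max(0, lo)
    }
    one_way_dsa(config, p, lo, hi, focal = focal, wtp = wtp, lt = lt)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$width))
  attr(out, "base_nmb") <- incremental_nmb(run_base_case(config, lt),
                                           focal = focal, wtp = wtp)
  attr(out, "focal") <- focal
  class(out) <- c("netcea_tornado", class(out))
  out
}

# --- probabilistic sensitivity analysis ------------------------------------

# Per-draw parameter column, falling back to the base value when fixed.
draw_par <- function(draws, config, path) {
  if (path %in% names(draws)) draws[[path]] else rep(config_get(config, path), nrow(draws))
}

# Vectorized cohort propagation across draws: occupancy is an n x 7 matrix
# and each transition is an elementwise expression mirroring
# transition_matrix(); agreement with run_cohort() is enforced by tests.
psa_branch_values <- function(config, draws, lt) {
  n <- nrow(draws)
  gp <- function(path) draw_par(draws, config, path)
  u_pw <- gp("utilities$no_clinically_relevant_burden")
  u_tr <- gp("utilities$clinically_relevant_treated")
  u_ut <- gp("utilities$progression_untreated")
  u_nb <- gp("utilities$no_burden")
  crem <- gp("costs$yearly_treated_non_relevant")
  cyr <- gp("costs$yearly_clinically_relevant")
  cnb <- gp("costs$yearly_no_burden")
  ptt <- gp("transitions$p_death_timely")
  ptd <- gp("transitions$p_death_delayed")
  put <- gp("transitions$p_death_untreated")
  pc <- gp("transitions$p_death_competing")
  pprog <- gp("transitions$p_progression")
  pu2t <- gp("transitions$p_untreated_to_treated")
  rr <- config$transitions$relative_risk_other_death

  n_cycles <- config$horizon_age - config$start_age
  ages <- config$start_age + seq_len(n_cycles) - 1
  disc <- discount_factor(config$discount_rate, seq_len(n_cycles))
  pbg <- background_death_prob(lt, ages, rr)

  run1 <- function(start) {
    occ <- matrix(0, n, 7)
    colnames(occ) <- health_states()
    occ[, start] <- 1
    C <- Q <- numeric(n)
    for (k in seq_len(n_cycles)) {
      C <- C + disc[k] * (occ[, 3] * crem + (occ[, 4] + occ[, 5] + occ[, 6]) * cyr +
                            (occ[, 1] + occ[, 2]) * cnb)
      Q <- Q + disc[k] * (occ[, 1] * u_nb + (occ[, 2] + occ[, 3]) * u_pw +
                            occ[, 4] * u_ut + (occ[, 5] + occ[, 6]) * u_tr)
      d0 <- 1 - (1 - pc) * (1 - pbg[k])
      dut <- 1 - (1 - put) * (1 - pc) * (1 - pbg[k])
      dtt <- 1 - (1 - ptt) * (1 - pc) * (1 - pbg[k])
      dtd <- 1 - (1 - ptd) * (1 - pc) * (1 - pbg[k])
      nxt <- occ
      nxt[, 1] <- (occ[, 1] + occ[, 2]) * (1 - d0) * (1 - pprog)
      nxt[, 2] <- 0
      nxt[, 3] <- occ[, 3] * (1 - d0) * (1 - pprog) +
        occ[, 5] * (1 - dtt) + occ[, 6] * (1 - dtd)
      nxt[, 4] <- occ[, 4] * (1 - dut) * (1 - pu2t)
      nxt[, 5] <- (occ[, 1] + occ[, 2] + occ[, 3]) * (1 - d0) * pprog
      nxt[, 6] <- occ[, 4] * (1 - dut) * pu2t
      nxt[, 7] <- occ[, 7] + (occ[, 1] + occ[, 2] + occ[, 3]) * d0 +
        occ[, 4] * dut + occ[, 5] * dtt + occ[, 6] * dtd
      occ <- nxt
    }
    list(cost = unname(C), qaly = unname(Q))
  }
  starts <- unique(vapply(outcome_levels, start_state, character(1)))
  setNames(lapply(starts, run1), starts)
}

# Per-draw per-strategy expected results given sampled parameters.
psa_evaluate <- function(config, draws, lt = default_life_table()) {
  n <- nrow(draws)
  br <- psa_branch_values(config, draws, lt)
  gp <- function(path) draw_par(draws, config, path)
  prev <- gp("prevalence")
  biopsy <- gp("costs$biopsy")
  unbx <- gp("costs$unnecessary_biopsy")
  ctp <- gp("costs$timely_treatment")
  cfn <- gp("costs$delayed_treatment")
  ctn <- gp("costs$true_negative_acute")
  purrr::map_dfr(names(config$strategies), function(nm) {
    sens <- gp(paste0("strategies$", nm, "$sensitivity"))
    spec <- gp(paste0("strategies$", nm, "$specificity"))
    img <- gp(paste0("strategies$", nm, "$imaging_cost"))
    p_tp <- prev * sens
    p_fn <- prev * (1 - sens)
    p_tn <- (1 - prev) * spec
    p_fp <- (1 - prev) * (1 - spec)
    ac_tp <- img + (if (config$charge_biopsy_tp) biopsy else 0) + ctp
    acute <- p_tp * ac_tp + p_fn * (img + cfn) + p_tn * (img + ctn) +
      p_fp * (img + unbx)
    tibble::tibble(
      .draw = seq_len(n),
      strategy = nm,
      label = config$strategies[[nm]]$label %||% nm,
      cost = unname(acute) +
        p_tp * br$clinrel_treated_timely$cost +
        p_fn * br$clinrel_untreated$cost +
        p_tn * br$no_burden$cost +
        p_fp * br$no_burden_postwork$cost,
      qaly = p_tp * br$clinrel_treated_timely$qaly +
        p_fn * br$clinrel_untreated$qaly +
        p_tn * br$no_burden$qaly +
        p_fp * br$no_burden_postwork$qaly
    )
  })
}

#' Sample the probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its configured distribution (beta
#' for probabilities and utilities, parameterized by mean and effective
#' sample size; gamma for costs, by mean and coefficient of variation; see
#' [psa_parameter_table()]), with independent draws across parameters, and
#' evaluates the full pipeline for every draw and strategy. The cohort
#' propagation is vectorized across draws, so the default 30,000 iterations
#' run in seconds.
#'
#' @param config A `netcea_config`.
#' @param n Number of Monte Carlo iterations (default
#'   `config$psa$iterations`, 30,000).
#' @param seed RNG seed; the run is reproducible under a fixed seed.
#' @param lt A `life_table`.
#' @return A `netcea_psa` tibble in long format (`.draw`, `strategy`,
#'   `label`, `cost`, `qaly`), with the sampled parameter draws in the
#'   `"parameters"` attribute and `seed`/`wtp` recorded.
#' @examples
#' psa <- sample_psa(default_net_config(), n = 500, seed = 7)
#' head(psa)
#' @export
sample_psa <- function(config, n = config$psa$iterations, seed = config$seed,
                       lt = default_life_table()) {
  validate_config(config)
  if (n < 1) abort("`n` must be >= 1", class = "netcea_domain_error")
  pt <- psa_parameter_table(config)
  set.seed(seed)
  draws <- tibble::as_tibble(
    setNames(lapply(seq_len(nrow(pt)), function(i) {
      if (pt$family[i] == "beta") {
        ab <- beta_params_from_mean(pt$mean[i], pt$spread[i])
        rbeta(n, ab[["alpha"]], ab[["beta"]])
      } else {
        sh <- gamma_params_from_mean(pt$mean[i], pt$spread[i])
        rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
      }
    }), pt$parameter)
  )
  out <- psa_evaluate(config, draws, lt)
  attr(out, "parameters") <- draws
  attr(out, "seed") <- seed
  attr(out, "wtp") <- config$wtp
  class(out) <- c("netcea_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For every willingness-to-pay value on the grid, the fraction of draws in
#' which each strategy attains the strictly highest net monetary benefit;
#' ties are split equally, so the probabilities at each grid point sum to 1.
#'
#' @param samples A `netcea_psa` from [sample_psa()].
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default $0 to
#'   $200,000 in $5,000 steps).
#' @return A `ceac_curve` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 200000, by = 5000)) {
  if (any(wtp_grid < 0)) abort("`wtp_grid` must be >= 0", class = "netcea_domain_error")
  if (nrow(samples) == 0) abort("need at least one draw", class = "netcea_domain_error")
  wide_c <- tidyr::pivot_wider(tibble::as_tibble(samples)[c(".draw", "label", "cost")],
                               names_from = "label", values_from = "cost")
  wide_q <- tidyr::pivot_wider(tibble::as_tibble(samples)[c(".draw", "label", "qaly")],
                               names_from = "label", values_from = "qaly")
  labels <- setdiff(names(wide_c), ".draw")
  cmat <- as.matrix(wide_c[labels])
  qmat <- as.matrix(wide_q[labels])
  out <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- w * qmat - cmat
    best <- nmb == matrixStats_rowMaxs(nmb)
    wts <- best / rowSums(best)  # tie-splitting
    tibble::tibble(wtp = w, strategy = labels, probability = colMeans(wts))
  })
  class(out) <- c("ceac_curve", class(out))
  out
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) as.numeric(do.call(pmax, asplit(m, 2)))

#' Incremental scatter of PSA draws
#'
#' One point per Monte Carlo draw on the incremental cost-effectiveness
#' plane: `delta_effect = E_strategy - E_comparator` against
#' `delta_cost = C_strategy - C_comparator`.
#'
#' @param samples A `netcea_psa`.
#' @param strategy,comparator Strategy names or labels present in `samples`.
#' @return A tibble: `.draw`, `delta_effect`, `delta_cost`.
#' @export
incremental_scatter <- function(samples, strategy, comparator) {
  pick <- function(id) {
    s <- dplyr::filter(tibble::as_tibble(samples),
                       .data$strategy == id | .data$label == id)
    if (nrow(s) == 0) {
      abort(paste0("Strategy not present in samples: ", id),
            class = "netcea_domain_error")
    }
    s
  }
  a <- pick(strategy)
  b <- pick(comparator)
  tibble::tibble(.draw = a$.draw,
                 delta_effect = a$qaly - b$qaly,
                 delta_cost = a$cost - b$cost)
}

#' @export
tidy.netcea_psa <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$strategy, .data$label),
                   mean_cost = mean(.data$cost), sd_cost = sd(.data$cost),
                   mean_qaly = mean(.data$qaly), sd_qaly = sd(.data$qaly),
                   .groups = "drop")
}

#' @export
glance.netcea_psa <- function(x, wtp = attr(x, "wtp") %||% 1e5, ...) {
  nmb <- net_monetary_benefit(x, wtp)
  wide <- tidyr::pivot_wider(nmb[c(".draw", "label", "nmb")],
                             names_from = "label", values_from = "nmb")
  labels <- setdiff(names(wide), ".draw")
  m <- as.matrix(wide[labels])
  winners <- labels[max.col(m, ties.method = "first")]
  tab <- table(factor(winners, levels = labels)) / nrow(m)
  tibble::tibble(n_draws = nrow(m), wtp = wtp,
                 best_strategy = names(which.max(tab)),
                 p_best = max(tab))
}
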