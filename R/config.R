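#' Model parameter defaults
#'
#' The base-case parameterization of the neuroendocrine-tumor (NET) imaging
#' cost-effectiveness model: a 5% pre-test probability of NET among imaged
#' patients, three diagnostic strategies (68Ga-DOTA-TATE PET/CT,
#' 111In-pentetreotide SPECT/CT, CT alone) with 2020 US Medicare imaging
#' tariffs, acute and yearly treatment costs, health-state utilities, annual
#' transition probabilities, a 3% yearly discount rate and a willingness-to-pay
#' of $100,000 per QALY. The cohort starts at age 30 and is followed in
#' 1-year cycles to age 100.
#'
#' Each uncertain parameter carries a distribution family for probabilistic
#' sensitivity analysis: `beta` for probabilities and utilities, `gamma` for
#' costs. The source literature gives point estimates without dispersion, so
#' spreads default to an effective sample size of 100 for beta parameters and
#' a coefficient of variation of 0.2 for gamma parameters; both are
#' overridable per parameter via `psa$beta_ess_overrides` /
#' `psa$gamma_cv_overrides` in the config.
#'
#' @return A validated `netcea_config` object (a named list).
#' @examples
#' cfg <- default_net_config()
#' cfg$prevalence
#' cfg$strategies$pet_ct
#' @export
default_net_config <- function() {
  cfg <- structure(netcea_defaults(), class = "netcea_config")
  validate_config(cfg)
  cfg
}

# Versioned constants block: every numeric below is a base-case model input.
netcea_defaults <- function() {
  list(
    version = "1.0",
    prevalence = 0.05,
    start_age = 30,
    horizon_age = 100,
    discount_rate = 0.03,
    wtp = 100000,
    cycle_length = 1,
    strategies = list(
      pet_ct = list(label = "PET/CT", imaging_cost = 1375,
                    sensitivity = 0.91, specificity = 0.92),
      spect_ct = list(label = "SPECT/CT", imaging_cost = 1242,
                      sensitivity = 0.70, specificity = 0.96),
      ct = list(label = "CT", imaging_cost = 787,
                sensitivity = 0.77, specificity = 0.86)
    ),
    costs = list(
      timely_treatment = 85068,
      delayed_treatment = 127602,
      unnecessary_biopsy = 1375,
      true_negative_acute = 0,
      biopsy = 1375,
      yearly_no_burden = 0,
      yearly_treated_non_relevant = 2107,
      yearly_clinically_relevant = 61375
    ),
    utilities = list(
      no_burden = 1,
      no_clinically_relevant_burden = 0.779,
      clinically_relevant_treated = 0.768,
      progression_untreated = 0.612,
      without_treatment_alt = 0.690,  # recorded; not wired into any state
      death = 0
    ),
    transitions = list(
      p_death_timely = 0.04,
      p_death_delayed = 0.045,
      p_death_untreated = 0.1212,
      p_death_competing = 0.025,
      p_progression = 0.088,
      p_untreated_to_treated = 1,
      relative_risk_other_death = 1
    ),
    charge_biopsy_tp = TRUE,
    life_table_ref = "us-synthetic",
    psa = list(
      iterations = 30000,
      beta_ess = 100,
      gamma_cv = 0.2,
      beta_ess_overrides = list(),
      gamma_cv_overrides = list()
    ),
    seed = 1
  )
}

#' Validate a model configuration
#'
#' Checks every invariant of the model parameterization: probabilities and
#' utilities in \[0, 1\], non-negative costs, at least two strategies with
#' unique labels, horizon beyond start age, positive cycle length. All
#' violations are collected and reported together, each naming the offending
#' field.
#'
#' @param config A `netcea_config` object (or plain list with the same shape).
#' @return `config`, invisibly, if valid; otherwise an error listing every
#'   violated field.
#' @export
validate_config <- function(config) {
  v <- config_violations(config)
  if (length(v) > 0) {
    abort(c("Invalid model configuration:", setNames(v, rep("x", length(v)))),
          class = "netcea_validation_error")
  }
  invisible(config)
}

config_violations <- function(config) {
  v <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  prob <- function(x) num(x) && x >= 0 && x <= 1

  need(num(config$prevalence) && config$prevalence > 0 && config$prevalence < 1,
       "prevalence must be in (0, 1)")
  need(num(config$start_age) && config$start_age >= 0, "start_age must be >= 0")
  need(num(config$horizon_age) && config$horizon_age > config$start_age,
       "horizon_age must exceed start_age")
  need(num(config$discount_rate) && config$discount_rate >= 0,
       "discount_rate must be >= 0")
  need(num(config$wtp) && config$wtp >= 0, "wtp must be >= 0")
  need(num(config$cycle_length) && config$cycle_length > 0,
       "cycle_length must be > 0")

  need(is.list(config$strategies) && length(config$strategies) >= 2,
       "strategies must list at least 2 strategies")
  labels <- character()
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    need(prob(s$sensitivity), paste0("strategies$", nm, "$sensitivity must be in [0, 1]"))
    need(prob(s$specificity), paste0("strategies$", nm, "$specificity must be in [0, 1]"))
    need(num(s$imaging_cost) && s$imaging_cost >= 0,
         paste0("strategies$", nm, "$imaging_cost must be >= 0"))
    labels <- c(labels, s$label %||% nm)
  }
  need(!anyDuplicated(labels), "strategy labels must be unique")

  for (nm in names(netcea_defaults()$costs)) {
    need(num(config$costs[[nm]]) && config$costs[[nm]] >= 0,
         paste0("costs$", nm, " must be >= 0"))
  }
  for (nm in names(netcea_defaults()$utilities)) {
    need(prob(config$utilities[[nm]]),
         paste0("utilities$", nm, " must be in [0, 1]"))
  }
  if (prob(config$utilities$death)) {
    need(config$utilities$death == 0, "utilities$death must be 0")
  }
  tr <- config$transitions
  for (nm in c("p_death_timely", "p_death_delayed", "p_death_untreated",
               "p_death_competing", "p_progression", "p_untreated_to_treated")) {
    need(prob(tr[[nm]]), paste0("transitions$", nm, " must be in [0, 1]"))
  }
  need(num(tr$relative_risk_other_death) && tr$relative_risk_other_death >= 0,
       "transitions$relative_risk_other_death must be >= 0")

  need(num(config$psa$iterations) && config$psa$iterations >= 1,
       "psa$iterations must be >= 1")
  need(num(config$psa$beta_ess) && config$psa$beta_ess > 0,
       "psa$beta_ess must be > 0")
  need(num(config$psa$gamma_cv) && config$psa$gamma_cv > 0,
       "psa$gamma_cv must be > 0")
  v
}

#' Load a model configuration from a YAML/JSON file
#'
#' Partial configurations are supported: any key present in the file replaces
#' the corresponding default, everything else keeps its base-case value. A key
#' not present in the default structure is an error (this protects against
#' silent typos), except under `strategies`, where new strategy names may be
#' introduced, and the PSA override maps. The merged configuration is
#' re-validated before it is returned.
#'
#' @param path Path to a YAML (or JSON) configuration file. An empty file
#'   yields the defaults unchanged.
#' @return A validated `netcea_config`.
#' @seealso [write_config()], [default_net_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "netcea_input_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    abort("Config file must contain a mapping of parameter names to values",
          class = "netcea_input_error")
  }
  cfg <- merge_config(netcea_defaults(), user, path = character())
  cfg <- structure(cfg, class = "netcea_config")
  validate_config(cfg)
  cfg
}

# Recursive merge of a partial user config over the defaults. `open` keys
# accept user-introduced names (strategy table, per-parameter PSA overrides).
merge_config <- function(base, user, path) {
  open <- c("strategies", "beta_ess_overrides", "gamma_cv_overrides")
  for (key in names(user)) {
    here <- c(path, key)
    known <- key %in% names(base) ||
      (length(path) > 0 && path[length(path)] %in% open)
    if (!known) {
      abort(paste0("Unknown config key: ", paste(here, collapse = "$")),
            class = "netcea_validation_error")
    }
    if (is.list(user[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Write a model configuration to YAML
#'
#' The written file round-trips: `load_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A `netcea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Beta shape parameters from a mean and effective sample size
#'
#' Moment-style parameterization used for probabilistic sensitivity analysis
#' of probability and utility parameters: `alpha = mean * ess`,
#' `beta = (1 - mean) * ess`, so the distribution has exactly the requested
#' mean and a variance shrinking with `ess`.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param ess Effective sample size (> 0); larger means tighter.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_params_from_mean(0.91, 100)
#' @export
beta_params_from_mean <- function(mean, ess) {
  if (!is.numeric(mean) || any(mean <= 0) || any(mean >= 1)) {
    abort("`mean` must lie strictly inside (0, 1)", class = "netcea_domain_error")
  }
  if (!is.numeric(ess) || any(ess <= 0)) {
    abort("`ess` must be > 0", class = "netcea_domain_error")
  }
  c(alpha = unname(mean * ess), beta = unname((1 - mean) * ess))
}

#' Gamma shape/scale from a mean and coefficient of variation
#'
#' Parameterization for cost parameters in probabilistic sensitivity analysis:
#' `shape = 1 / cv^2`, `scale = mean * cv^2`, giving a gamma distribution with
#' mean `mean` and standard deviation `mean * cv`.
#'
#' @param mean Target mean (> 0), in USD.
#' @param cv Coefficient of variation (> 0).
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_params_from_mean(1375, 0.2)
#' @export
gamma_params_from_mean <- function(mean, cv) {
  if (!is.numeric(mean) || any(mean <= 0)) {
    abort("`mean` must be > 0", class = "netcea_domain_error")
  }
  if (!is.numeric(cv) || any(cv <= 0)) {
    abort("`cv` must be > 0", class = "netcea_domain_error")
  }
  c(shape = unname(1 / cv^2), scale = unname(mean * cv^2))
}

#' Table of uncertain parameters and their PSA distributions
#'
#' Enumerates every model parameter that varies in the probabilistic
#' sensitivity analysis, with its base-case mean, distribution family and
#' spread. Probabilities and utilities are beta-distributed; costs are
#' gamma-distributed. Parameters whose point estimate sits on the boundary of
#' the family's support (the no-burden utility of 1, the untreated-to-treated
#' probability of 1, the life-table relative risk, zero-mean costs) are held
#' fixed, as are the discount rate, willingness-to-pay and ages.
#'
#' @param config A `netcea_config`.
#' @return A tibble with columns `parameter`, `mean`, `family`
#'   (`"beta"`/`"gamma"`), and `spread` (effective sample size for beta,
#'   coefficient of variation for gamma).
#' @export
psa_parameter_table <- function(config) {
  validate_config(config)
  ess <- function(p) config$psa$beta_ess_overrides[[p]] %||% config$psa$beta_ess
  cv <- function(p) config$psa$gamma_cv_overrides[[p]] %||% config$psa$gamma_cv

  rows <- list(tibble::tibble(parameter = "prevalence", mean = config$prevalence,
                              family = "beta"))
  for (nm in names(config$strategies)) {
    s <- config$strategies[[nm]]
    rows <- c(rows, list(tibble::tibble(
      parameter = paste0("strategies$", nm, c("$sensitivity", "$specificity",
                                              "$imaging_cost")),
      mean = c(s$sensitivity, s$specificity, s$imaging_cost),
      family = c("beta", "beta", "gamma")
    )))
  }
  cost_par <- c("biopsy", "timely_treatment", "delayed_treatment",
                "unnecessary_biopsy", "yearly_treated_non_relevant",
                "yearly_clinically_relevant")
  rows <- c(rows, list(tibble::tibble(
    parameter = paste0("costs$", cost_par),
    mean = vapply(cost_par, function(p) config$costs[[p]], numeric(1)),
    family = "gamma"
  )))
  util_par <- c("no_clinically_relevant_burden", "clinically_relevant_treated",
                "progression_untreated")
  trans_par <- c("p_death_timely", "p_death_delayed", "p_death_untreated",
                 "p_death_competing", "p_progression")
  rows <- c(rows, list(tibble::tibble(
    parameter = c(paste0("utilities$", util_par), paste0("transitions$", trans_par)),
    mean = c(vapply(util_par, function(p) config$utilities[[p]], numeric(1)),
             vapply(trans_par, function(p) config$transitions[[p]], numeric(1))),
    family = "beta"
  )))
  out <- dplyr::bind_rows(rows)
  # beta means on the open-interval boundary cannot be sampled; drop to fixed
  out <- dplyr::filter(out,
                       !(.data$family == "beta" & (.data$mean <= 0 | .data$mean >= 1)),
                       !(.data$family == "gamma" & .data$mean <= 0))
  out$mean <- unname(out$mean)
  dplyr::mutate(out, spread = ifelse(
    .data$family == "beta",
    vapply(.data$parameter, ess, numeric(1)),
    vapply(.data$parameter, cv, numeric(1))
  ))
}

# Read/assign one leaf of a config by "a$b$c" path.
config_get <- function(config, parameter) {
  node <- config
  for (k in strsplit(parameter, "$", fixed = TRUE)[[1]]) {
    node <- node[[k]]
    if (is.null(node)) {
      abort(paste0("Unknown parameter: ", parameter), class = "netcea_domain_error")
    }
  }
  node
}

config_set <- function(config, parameter, value) {
  keys <- strsplit(parameter, "$", fixed = TRUE)[[1]]
  config_get(config, parameter)  # existence check
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(config))
  eval(call("<-", expr, value))
  config
}

#' @export
print.netcea_config <- function(x, ...) {
  cat("<netcea_config> v", x$version, "\n", sep = "")
  cat(sprintf("  prevalence %.3f | ages %d-%d | discount %.1f%% | WTP $%s/QALY\n",
              x$prevalence, x$start_age, x$horizon_age, 100 * x$discount_rate,
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  for (nm in names(x$strategies)) {
    s <- x$strategies[[nm]]
    cat(sprintf("  %-10s sens %.2f spec %.2f imaging $%s\n", s$label,
                s$sensitivity, s$specificity, format(s$imaging_cost, big.mark = ",")))
  }
  invisible(x)
}
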