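test_that("default configuration is self-consistent and round-trips", {
  cfg <- default_net_config()
  expect_s3_class(cfg, "netcea_config")
  expect_silent(validate_config(cfg))
  expect_identical(cfg$prevalence, 0.05)
  expect_identical(cfg$start_age, 30)
  expect_identical(cfg$discount_rate, 0.03)
  expect_identical(cfg$wtp, 100000)
  expect_identical(cfg$strategies$pet_ct[c("sensitivity", "specificity")],
                   list(sensitivity = 0.91, specificity = 0.92))
  expect_identical(cfg$strategies$spect_ct[c("sensitivity", "specificity")],
                   list(sensitivity = 0.70, specificity = 0.96))
  expect_identical(cfg$strategies$ct[c("sensitivity", "specificity")],
                   list(sensitivity = 0.77, specificity = 0.86))
  expect_identical(cfg$cycle_length, 1)
  expect_identical(cfg$horizon_age, 100)
  expect_identical(cfg$psa$iterations, 30000)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(load_config(path), cfg)
})

test_that("partial configs merge over defaults and typos are rejected", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(load_config(empty), default_net_config())

  one <- withr::local_tempfile(fileext = ".yaml")
  writeLines("prevalence: 0.10", one)
  cfg <- load_config(one)
  expect_equal(cfg$prevalence, 0.10)
  cfg$prevalence <- 0.05
  expect_equal(cfg, default_net_config())

  typo <- withr::local_tempfile(fileext = ".yaml")
  writeLines("prevalance: 0.10", typo)
  expect_error(load_config(typo), "Unknown config key",
               class = "netcea_validation_error")

  expect_error(load_config(withr::local_tempfile()), "not found",
               class = "netcea_input_error")
})

test_that("invariant violations are reported by field name", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("strategies:", "  pet_ct:", "    sensitivity: 1.2"), bad)
  expect_error(load_config(bad), "sensitivity", class = "netcea_validation_error")

  cases <- list(
    list(yaml = "prevalence: 1.5", field = "prevalence"),
    list(yaml = "costs:\n  biopsy: -10", field = "biopsy"),
    list(yaml = "utilities:\n  death: 0.5", field = "death"),
    list(yaml = "transitions:\n  p_progression: -0.1", field = "p_progression"),
    list(yaml = "horizon_age: 20", field = "horizon_age")
  )
  for (case in cases) {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(case$yaml, f)
    expect_error(load_config(f), case$field, class = "netcea_validation_error")
  }
})

test_that("validation rejects out-of-range probabilities and negative costs (fuzz)", {
  set.seed(101)
  pt <- psa_parameter_table(default_net_config())
  for (i in 1:40) {
    row <- pt[sample(nrow(pt), 1), ]
    bad_value <- if (row$family == "beta") {
      sample(c(-runif(1), 1 + runif(1)), 1)
    } else {
      -runif(1, 1, 1000)
    }
    cfg <- netcea:::config_set(default_net_config(), row$parameter, bad_value)
    expect_error(validate_config(cfg), class = "netcea_validation_error")
  }
})

test_that("beta parameterization recovers the requested mean", {
  expect_equal(beta_params_from_mean(0.5, 100), c(alpha = 50, beta = 50))
  expect_equal(beta_params_from_mean(0.91, 100), c(alpha = 91, beta = 9))
  set.seed(7)
  for (i in 1:25) {
    m <- runif(1, 0.01, 0.99)
    ess <- runif(1, 1, 1000)
    ab <- beta_params_from_mean(m, ess)
    expect_equal(ab[["alpha"]] / (ab[["alpha"]] + ab[["beta"]]), m)
  }
  expect_error(beta_params_from_mean(1.2, 100), class = "netcea_domain_error")
  expect_error(beta_params_from_mean(0, 100), class = "netcea_domain_error")

  # Monte Carlo: sampled mean within 3 standard errors of the target
  set.seed(11)
  ab <- beta_params_from_mean(0.77, 100)
  x <- rbeta(2e5, ab[["alpha"]], ab[["beta"]])
  expect_lt(abs(mean(x) - 0.77), 3 * sd(x) / sqrt(length(x)))
})

test_that("gamma parameterization recovers mean and coefficient of variation", {
  expect_equal(gamma_params_from_mean(1375, 0.2), c(shape = 25, scale = 55))
  expect_error(gamma_params_from_mean(1375, 0), class = "netcea_domain_error")
  expect_error(gamma_params_from_mean(-5, 0.2), class = "netcea_domain_error")

  set.seed(12)
  sh <- gamma_params_from_mean(85068, 0.2)
  x <- rgamma(2e5, shape = sh[["shape"]], scale = sh[["scale"]])
  expect_lt(abs(mean(x) - 85068), 3 * sd(x) / sqrt(length(x)))
  expect_equal(sd(x) / mean(x), 0.2, tolerance = 0.01)
})

test_that("uncertain-parameter table covers the distribution plan", {
  pt <- psa_parameter_table(default_net_config())
  expect_true(all(pt$family %in% c("beta", "gamma")))
  expect_true(all(pt$spread > 0))
  # boundary-mean parameters are excluded from sampling
  expect_false("utilities$no_burden" %in% pt$parameter)
  expect_false("transitions$p_untreated_to_treated" %in% pt$parameter)
  expect_false("costs$true_negative_acute" %in% pt$parameter)
  # spreads are overridable per parameter
  cfg <- default_net_config()
  cfg$psa$gamma_cv_overrides <- list("costs$biopsy" = 0.5)
  pt2 <- psa_parameter_table(cfg)
  expect_equal(pt2$spread[pt2$parameter == "costs$biopsy"], 0.5)
  expect_equal(pt2$spread[pt2$parameter == "costs$timely_treatment"], 0.2)
})
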