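test_that("a zero-width sweep reproduces the base case bit-identically", {
  cfg <- short_config(60)
  base <- netcea:::incremental_nmb(run_base_case(cfg), wtp = cfg$wtp)
  bar <- one_way_dsa(cfg, "strategies$pet_ct$sensitivity", 0.91, 0.91)
  expect_identical(bar$nmb_low, base)
  expect_identical(bar$nmb_high, base)
  expect_identical(bar$width, 0)
  expect_error(one_way_dsa(cfg, "strategies$pet_ct$nonsense", 0, 1),
               class = "netcea_domain_error")
  expect_error(one_way_dsa(cfg, "prevalence", 0.2, 0.1),
               class = "netcea_domain_error")
})

test_that("incremental NMB is monotone in the focal test's own sensitivity", {
  cfg <- short_config(60)
  grid <- seq(0.7, 1, length.out = 5)
  nmbs <- vapply(grid, function(s) {
    one_way_dsa(cfg, "strategies$pet_ct$sensitivity", s, s)$nmb_low
  }, numeric(1))
  expect_true(all(diff(nmbs) >= 0))
})

test_that("the default tornado sweeps ten parameters sorted by bar width", {
  cfg <- short_config(45)
  tor <- tornado(cfg)
  expect_equal(nrow(tor), 10)
  expect_true(all(grepl("sensitivity|specificity|imaging_cost|biopsy",
                        tor$parameter)))
  expect_true(all(diff(tor$width) <= 0))
  expect_true(all(tor$high <= 1 | !grepl("sensitivity|specificity", tor$parameter)))
  expect_warning(empty <- tornado(cfg, parameters = character()), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("PSA draws are reproducible and centred on the base values", {
  cfg <- default_net_config()
  p1 <- sample_psa(cfg, n = 400, seed = 99)
  p2 <- sample_psa(cfg, n = 400, seed = 99)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  expect_identical(attr(p1, "parameters"), attr(p2, "parameters"))
  expect_false(identical(tibble::as_tibble(p1),
                         tibble::as_tibble(sample_psa(cfg, n = 400, seed = 100))))

  # law of large numbers: each sampled parameter mean near its base value
  draws <- attr(sample_psa(cfg, n = 30000, seed = 5), "parameters")
  pt <- psa_parameter_table(cfg)
  for (i in seq_len(nrow(pt))) {
    x <- draws[[pt$parameter[i]]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - pt$mean[i]), 3 * se)
  }
})

test_that("the vectorized PSA engine agrees with the cohort engine", {
  cfg <- default_net_config()
  pt <- psa_parameter_table(cfg)
  # base-value draw must reproduce the base case exactly
  base_draw <- tibble::as_tibble(setNames(as.list(pt$mean), pt$parameter))
  ev <- netcea:::psa_evaluate(cfg, base_draw)
  bc <- run_base_case(cfg)
  expect_equal(ev$cost, bc$cost, tolerance = 1e-10)
  expect_equal(ev$qaly, bc$qaly, tolerance = 1e-12)
  # and a perturbed draw must match a config carrying the same values
  set.seed(31)
  pert <- tibble::as_tibble(setNames(as.list(pt$mean * runif(nrow(pt), 0.9, 1.1)),
                                     pt$parameter))
  pert_in_domain <- pmin(as.numeric(pert[1, ]), ifelse(pt$family == "beta", 0.999, Inf))
  pert[1, ] <- as.list(pert_in_domain)
  cfg2 <- cfg
  for (i in seq_len(nrow(pt))) {
    cfg2 <- netcea:::config_set(cfg2, pt$parameter[i], pert[[i]][1])
  }
  ev2 <- netcea:::psa_evaluate(cfg, pert)
  bc2 <- run_base_case(cfg2)
  expect_equal(ev2$cost, bc2$cost, tolerance = 1e-10)
  expect_equal(ev2$qaly, bc2$qaly, tolerance = 1e-12)
})

test_that("shrinking all PSA spreads converges on the base-case point estimate", {
  cfg <- default_net_config()
  cfg$psa$beta_ess <- 1e9
  cfg$psa$gamma_cv <- 1e-5
  psa <- sample_psa(cfg, n = 200, seed = 17)
  bc <- run_base_case(cfg)
  agg <- tidy(psa)
  expect_equal(agg$mean_cost[match(bc$strategy, agg$strategy)], bc$cost,
               tolerance = 1e-3)
  expect_equal(agg$mean_qaly[match(bc$strategy, agg$strategy)], bc$qaly,
               tolerance = 1e-4)
})

test_that("CEAC probabilities partition to one and degenerate cases are sharp", {
  psa <- sample_psa(default_net_config(), n = 500, seed = 23)
  cc <- ceac(psa, seq(0, 200000, by = 20000))
  sums <- dplyr::summarise(dplyr::group_by(cc, .data$wtp),
                           total = sum(.data$probability))
  expect_equal(sums$total, rep(1, nrow(sums)))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))

  one <- dplyr::filter(tibble::as_tibble(psa), .data$.draw == 1)
  class(one) <- c("netcea_psa", class(one))
  cc1 <- ceac(one, c(0, 1e5))
  expect_true(all(cc1$probability %in% c(0, 1)))
  # wtp = 0: winner is the cheapest strategy of the draw
  cheapest <- one$label[which.min(one$cost)]
  expect_equal(cc1$strategy[cc1$wtp == 0 & cc1$probability == 1], cheapest)
  expect_error(ceac(psa, c(-1, 0)), class = "netcea_domain_error")
})

test_that("incremental scatter has one point per draw in the right quadrant", {
  psa <- sample_psa(default_net_config(), n = 2000, seed = 41)
  sc <- incremental_scatter(psa, "pet_ct", "ct")
  expect_equal(nrow(sc), 2000)
  # mean point consistent with base-case dominance: more QALYs, lower cost
  expect_gt(mean(sc$delta_effect), 0)
  expect_lt(mean(sc$delta_cost), 0)
  expect_error(incremental_scatter(psa, "pet_ct", "mri"),
               class = "netcea_domain_error")

  # identical strategies collapse to the origin
  same <- dplyr::bind_rows(
    tibble::tibble(.draw = 1:3, strategy = "a", label = "A", cost = 10, qaly = 1),
    tibble::tibble(.draw = 1:3, strategy = "b", label = "B", cost = 10, qaly = 1)
  )
  class(same) <- c("netcea_psa", class(same))
  sc0 <- incremental_scatter(same, "A", "B")
  expect_equal(sc0$delta_cost, rep(0, 3))
  expect_equal(sc0$delta_effect, rep(0, 3))
})
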