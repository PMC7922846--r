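# Resolve a config argument that may be a path or an object.
as_net_config <- function(config) {
  if (inherits(config, "netcea_config")) {
    validate_config(config)
    config
  } else if (is.character(config) && length(config) == 1) {
    load_config(config)
  } else {
    abort("`config` must be a netcea_config or a path to a config file",
          class = "netcea_input_error")
  }
}

write_manifest <- function(out_dir, config, seed, outputs) {
  manifest <- list(
    package = "netcea",
    version = as.character(utils::packageVersion("netcea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = basename(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  c(outputs, path)
}

#' Run and export the base-case analysis
#'
#' Computes the expected lifetime cost and QALYs of every strategy, the
#' ICER/dominance table, and the per-branch Markov traces, and writes them as
#' CSV (full precision) plus a JSON run manifest. Reruns with the same config
#' produce byte-identical result CSVs.
#'
#' @param config A `netcea_config` or the path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
run_basecase_report <- function(config = default_net_config(), out_dir) {
  config <- as_net_config(config)
  lt <- default_life_table()
  res <- run_base_case(config, lt)
  it <- icer_table(res)
  traces <- lapply(unique(vapply(outcome_levels, start_state, character(1))),
                   function(s) run_cohort(config, s, acute_cost = 0, lt = lt))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    file.path(out_dir, "strategy_results.csv"),
    file.path(out_dir, "icer_table.csv")
  )
  readr::write_csv(tibble::as_tibble(res), files[1])
  readr::write_csv(tibble::as_tibble(it), files[2])
  for (tr in traces) {
    f <- file.path(out_dir, paste0("trace_", attr(tr, "start_state"), ".csv"))
    readr::write_csv(tibble::as_tibble(tr), f)
    files <- c(files, f)
  }
  files <- write_manifest(out_dir, config, config$seed, files)
  invisible(files)
}

#' Run and export the deterministic sensitivity analysis
#'
#' @param config A `netcea_config` or config file path.
#' @param out_dir Output directory.
#' @param parameters,rel_range Passed to [tornado()].
#' @return Invisibly, the vector of files written.
#' @export
run_dsa_report <- function(config = default_net_config(), out_dir,
                           parameters = NULL, rel_range = 0.2) {
  config <- as_net_config(config)
  tor <- tornado(config, parameters = parameters, rel_range = rel_range)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(out_dir, "tornado.csv")
  readr::write_csv(tibble::as_tibble(tor), f)
  files <- write_manifest(out_dir, config, config$seed, f)
  invisible(files)
}

#' Run and export the probabilistic sensitivity analysis
#'
#' Writes the PSA draws (long format), the cost-effectiveness acceptability
#' curve over the WTP grid, and the incremental scatter of the focal strategy
#' against its comparator, plus the run manifest.
#'
#' @param config A `netcea_config` or config file path.
#' @param out_dir Output directory.
#' @param n Monte Carlo iterations (default `config$psa$iterations`).
#' @param seed RNG seed (default `config$seed`).
#' @param wtp_grid WTP grid for the CEAC.
#' @param scatter Length-2 character vector: strategy and comparator for the
#'   incremental scatter (default PET/CT vs CT).
#' @return Invisibly, the vector of files written.
#' @export
run_psa_report <- function(config = default_net_config(), out_dir,
                           n = NULL, seed = NULL,
                           wtp_grid = seq(0, 200000, by = 5000),
                           scatter = c("pet_ct", "ct")) {
  config <- as_net_config(config)
  n <- n %||% config$psa$iterations
  seed <- seed %||% config$seed
  psa <- sample_psa(config, n = n, seed = seed)
  cc <- ceac(psa, wtp_grid)
  sc <- incremental_scatter(psa, scatter[1], scatter[2])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, c("psa_draws.csv", "ceac.csv", "psa_scatter.csv"))
  readr::write_csv(tibble::as_tibble(psa), files[1])
  readr::write_csv(tibble::as_tibble(cc), files[2])
  readr::write_csv(sc, files[3])
  files <- write_manifest(out_dir, config, seed, files)
  invisible(files)
}
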