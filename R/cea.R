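#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes `delta_cost = C_a - C_b` and `delta_effect = E_a - E_b`, and
#' either the ICER `delta_cost / delta_effect` or a dominance flag. A
#' strategy that is cheaper and more effective is `dominant`; dearer and less
#' effective is `dominated`; with equal effects the flag follows the cost
#' sign (`equivalent` when both deltas vanish). A negative ratio is never
#' reported as a number — negative ICERs are ambiguous — it becomes a flag.
#'
#' @param a,b One-row data frames (or lists) with elements `cost` and `qaly`,
#'   e.g. rows of [run_base_case()] output; `a` is compared against `b`.
#' @return A one-row tibble: `strategy`, `comparator`, `delta_cost`,
#'   `delta_effect`, `icer` (NA when flagged), `flag` (NA when the ICER is a
#'   well-defined positive ratio).
#' @examples
#' pet <- list(label = "PET/CT", cost = 88003.07, qaly = 4.179)
#' ct <- list(label = "CT", cost = 88894.71, qaly = 4.165)
#' icer(pet, ct)  # cheaper and more effective: dominant
#' @export
icer <- function(a, b) {
  dc <- a$cost - b$cost
  de <- a$qaly - b$qaly
  flag <- NA_character_
  ratio <- NA_real_
  if (dc == 0 && de == 0) {
    flag <- "equivalent"
  } else if (de == 0) {
    flag <- if (dc < 0) "dominant" else "dominated"
  } else if (dc <= 0 && de > 0) {
    flag <- "dominant"
  } else if (dc >= 0 && de < 0) {
    flag <- "dominated"
  } else {
    ratio <- dc / de
  }
  tibble::tibble(
    strategy = as.character(a$label %||% a$strategy %||% "a"),
    comparator = as.character(b$label %||% b$strategy %||% "b"),
    delta_cost = dc, delta_effect = de, icer = ratio, flag = flag
  )
}

#' Efficiency frontier with sequential ICERs
#'
#' Orders strategies by cost (ties broken by higher effect), removes
#' strategies dominated outright (some other strategy is no dearer and no
#' less effective, strictly better in one) and by extended dominance
#' (sequential ICERs must be strictly increasing along the frontier), and
#' reports the sequential ICER of each retained strategy against its
#' predecessor.
#'
#' @param results A data frame of strategy results (`strategy` or `label`,
#'   `cost`, `qaly`), e.g. from [run_base_case()].
#' @return A tibble of frontier strategies in increasing cost order with
#'   `icer` against the previous frontier strategy (NA for the cheapest).
#' @export
frontier <- function(results) {
  res <- tibble::as_tibble(results)
  if (nrow(res) == 0) abort("need at least one strategy", class = "netcea_domain_error")
  if (!"label" %in% names(res)) res$label <- res$strategy
  res <- dplyr::arrange(res, .data$cost, dplyr::desc(.data$qaly))
  dominated <- vapply(seq_len(nrow(res)), function(i) {
    any(res$cost <= res$cost[i] & res$qaly >= res$qaly[i] &
          (res$cost < res$cost[i] | res$qaly > res$qaly[i]))
  }, logical(1))
  res <- res[!dominated, , drop = FALSE]
  # extended dominance: drop points until sequential ICERs strictly increase
  repeat {
    if (nrow(res) < 3) break
    ic <- diff(res$cost) / diff(res$qaly)
    bad <- which(diff(ic) <= 0)
    if (length(bad) == 0) break
    res <- res[-(bad[1] + 1), , drop = FALSE]
  }
  res$icer <- c(NA_real_, if (nrow(res) > 1) diff(res$cost) / diff(res$qaly))
  res
}

#' Incremental cost-effectiveness table
#'
#' One row per strategy, ordered by cost: the frontier strategies carry their
#' sequential ICER, all others a dominance flag (`dominated` or
#' `extended-dominated`).
#'
#' @param results A `netcea_result` (or any data frame with `strategy`/
#'   `label`, `cost`, `qaly`).
#' @return An `icer_table` tibble with columns `strategy`, `cost`, `qaly`,
#'   `delta_cost`, `delta_effect`, `icer`, `flag`.
#' @examples
#' icer_table(run_base_case())
#' @export
icer_table <- function(results) {
  res <- tibble::as_tibble(results)
  if (!"label" %in% names(res)) res$label <- res$strategy
  fr <- frontier(res)
  res <- dplyr::arrange(res, .data$cost, dplyr::desc(.data$qaly))
  strictly_dom <- vapply(seq_len(nrow(res)), function(i) {
    any(res$cost <= res$cost[i] & res$qaly >= res$qaly[i] &
          (res$cost < res$cost[i] | res$qaly > res$qaly[i]))
  }, logical(1))
  on_frontier <- res$label %in% fr$label
  out <- tibble::tibble(
    strategy = res$label, cost = res$cost, qaly = res$qaly,
    delta_cost = NA_real_, delta_effect = NA_real_, icer = NA_real_,
    flag = dplyr::case_when(!on_frontier & strictly_dom ~ "dominated",
                            !on_frontier ~ "extended-dominated",
                            TRUE ~ NA_character_)
  )
  idx <- match(fr$label, out$strategy)
  if (length(idx) > 1) {
    out$delta_cost[idx[-1]] <- diff(fr$cost)
    out$delta_effect[idx[-1]] <- diff(fr$qaly)
    out$icer[idx[-1]] <- fr$icer[-1]
  }
  class(out) <- c("icer_table", class(out))
  out
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`. At a given willingness-to-pay the strategy with
#' the highest NMB is the cost-effective choice; for point estimates this is
#' the same decision rule as the cost-effectiveness acceptability curve.
#'
#' @param results A data frame with `cost` and `qaly` columns (one or more
#'   strategies).
#' @param wtp Willingness-to-pay in USD per QALY (>= 0).
#' @return `results` with an `nmb` column appended (USD).
#' @examples
#' net_monetary_benefit(run_base_case(), wtp = 1e5)
#' @export
net_monetary_benefit <- function(results, wtp) {
  if (!is.numeric(wtp) || any(wtp < 0)) {
    abort("`wtp` must be >= 0", class = "netcea_domain_error")
  }
  dplyr::mutate(tibble::as_tibble(results), nmb = wtp * .data$qaly - .data$cost)
}

#' @export
tidy.netcea_result <- function(x, wtp = attr(x, "wtp") %||% 1e5, ...) {
  net_monetary_benefit(tibble::as_tibble(x), wtp)
}

#' @export
glance.netcea_result <- function(x, wtp = attr(x, "wtp") %||% 1e5, ...) {
  nmb <- net_monetary_benefit(x, wtp)
  best <- nmb$label[which.max(nmb$nmb)]
  fr <- frontier(x)
  tibble::tibble(
    n_strategies = nrow(x),
    wtp = wtp,
    best_strategy = best,
    n_frontier = nrow(fr),
    best_dominates_all = nrow(fr) == 1 && fr$label[1] == best
  )
}

#' @export
print.netcea_result <- function(x, ...) {
  cat("<netcea_result> expected lifetime discounted cost and QALYs\n")
  df <- tibble::as_tibble(x)
  df$cost <- sprintf("$%.2f", df$cost)
  df$qaly <- sprintf("%.3f", df$qaly)
  print(as.data.frame(df[, c("label", "cost", "qaly")]), row.names = FALSE)
  invisible(x)
}
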