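#' Cost-effectiveness plane of the base-case results
#'
#' Strategies as points on the (QALY, cost) plane with the efficiency
#' frontier drawn through the non-dominated set.
#'
#' @param object A `netcea_result` from [run_base_case()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netcea_result <- function(object, ...) {
  fr <- frontier(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = fr, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3.2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("$%s", format(x, big.mark = ","))) +
    ggplot2::labs(x = "Expected QALYs", y = "Expected lifetime cost",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("$%sk", x / 1000)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay per QALY",
                  y = "Probability cost-effective",
                  colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the incremental net monetary benefit of the focal
#' strategy at the low and high end of each one-way sweep, widest at the top;
#' the dashed line marks the base-case incremental NMB.
#'
#' @param object A `netcea_tornado` from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netcea_tornado <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)),
                      ymin = pmin(.data$nmb_low, .data$nmb_high),
                      ymax = pmax(.data$nmb_low, .data$nmb_high))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                            linewidth = 5, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "base_nmb") %||% NA_real_,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Incremental net monetary benefit (USD)",
                  title = "One-way deterministic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Plot the incremental PSA scatter
#'
#' One point per Monte Carlo draw on the incremental cost-effectiveness
#' plane, with the willingness-to-pay threshold as a reference line.
#'
#' @param scatter Output of [incremental_scatter()].
#' @param wtp Willingness-to-pay threshold to draw (USD/QALY).
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(scatter, wtp = 1e5) {
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$delta_effect,
                                        y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Incremental cost-effectiveness scatter") +
    ggplot2::theme_minimal()
}
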