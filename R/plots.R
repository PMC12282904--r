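#' Cost-effectiveness plane with the efficiency frontier
#'
#' Strategies as points (colour-coded by dominance status), the frontier as a
#' line, and optionally the willingness-to-pay slope through the optimal
#' strategy.
#'
#' @param object A `cea_frontier`.
#' @param wtp Optional willingness-to-pay; when given, the tangent line at
#'   the optimal strategy is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_frontier <- function(object, wtp = NULL, ...) {
  rows <- object$rows
  lad <- object$frontier
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = lad, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::labs(x = "Effectiveness (QALY)", y = "Cost per person",
                  colour = "Status") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    opt <- optimal_at_wtp(object, wtp)
    o <- rows[rows$strategy == opt, ]
    p <- p + ggplot2::geom_abline(intercept = o$cost - wtp * o$qaly,
                                  slope = wtp, linetype = "dashed")
  }
  p
}

#' Acceptability curves from a PSA
#'
#' @param object An `htn_psa`.
#' @param wtp_grid Willingness-to-pay grid (defaults to 0 to 50,000 in 51
#'   steps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.htn_psa <- function(object, wtp_grid = seq(0, 5e4, length.out = 51),
                             ...) {
  cc <- ceac(object, wtp_grid)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Tornado diagram from one-way sensitivity results
#'
#' @param tornado Output of [run_owsa()].
#' @param strategy Strategy to display (default: the widest-bar strategy
#'   set, summed — pass a label to restrict).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, strategy = NULL) {
  df <- tornado
  if (!is.null(strategy)) df <- df[df$strategy == strategy, , drop = FALSE]
  df <- df %>%
    group_by(.data$parameter) %>%
    summarise(outcome_low = sum(.data$outcome_low),
              outcome_base = sum(.data$outcome_base),
              outcome_high = sum(.data$outcome_high),
              width = sum(.data$width)) %>%
    arrange(.data$width) %>%
    mutate(parameter = factor(.data$parameter, levels = .data$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$outcome_base[1]),
                        linetype = "dashed") +
    ggplot2::labs(x = "Outcome", y = NULL) +
    ggplot2::theme_minimal()
}

#' PSA scatter on the cost-effectiveness plane
#'
#' @param psa An `htn_psa`.
#' @param baseline Baseline strategy label.
#' @return A ggplot object.
#' @export
plot_ce_scatter <- function(psa, baseline = "No screening") {
  sc <- scatter_data(psa, baseline)
  sc <- sc[sc$strategy != baseline, , drop = FALSE]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                   colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Incremental QALY", y = "Incremental cost",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}
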