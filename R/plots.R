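#' Cost-effectiveness plane for a strategy comparison
#'
#' Incremental discounted cost against DALYs averted, one point per
#' strategy and eligibility level (the published figure style).
#'
#' @param object A `hef_compare` from [compare_strategies()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hef_compare
#' @export
autoplot.hef_compare <- function(object, ...) {
  df <- dplyr::filter(object$daly_table, .data$strategy != "current_standard")
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$incremental_dalys,
                                   y = .data$incremental_cost,
                                   colour = .data$strategy,
                                   shape = factor(.data$eligibility))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "DALYs averted vs current standard",
                  y = "Incremental cost (USD, discounted)",
                  colour = "Strategy", shape = "Eligibility") +
    ggplot2::theme_minimal()
}

#' Uncertainty scatter with 95% ellipses
#'
#' One point per bootstrap population x parameter set, DALYs averted
#' against incremental cost, with a normal-theory 95% ellipse per strategy.
#'
#' @param object A `hef_psa` tibble from [run_uncertainty()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hef_psa
#' @export
autoplot.hef_psa <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$delta_dalys, y = .data$delta_cost,
                                   colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = "DALYs averted vs current standard",
                  y = "Incremental cost (USD, discounted)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' State occupancy over time
#'
#' Person counts by disease state and cycle, the standard diagnostic view of
#' a cohort state-transition model.
#'
#' @param object A `hef_sim` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hef_sim
#' @export
autoplot.hef_sim <- function(object, ...) {
  occ <- dplyr::count(object$ledger, .data$year, .data$disease_state)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$year, y = .data$n,
                                    fill = .data$disease_state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (year)", y = "Persons alive",
                  fill = "Disease state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
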