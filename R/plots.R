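#' Plot an AP/AL time course
#'
#' @param trajectory A tibble with columns `time`, `ap`, `al` (from
#'   [closed_form_timecourse()] or [simulate_timecourse()]).
#' @param params Optional [kinetic_params()]; when supplied, the analytic
#'   steady-state pools are drawn as horizontal reference lines.
#' @return A ggplot object.
#' @examples
#' p <- kinetic_params(12, 4, 2)
#' tr <- closed_form_timecourse(p, pool_state(0, 0), seq(0, 4, by = 0.05))
#' plot_timecourse(tr, p)
#' @export
plot_timecourse <- function(trajectory, params = NULL) {
  long <- tidyr::pivot_longer(trajectory, c("ap", "al"),
                              names_to = "pool", values_to = "size")
  long$pool <- toupper(long$pool)
  g <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$size,
                                          colour = .data$pool)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "expected vesicle count",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    ss <- steady_state_pools(params)
    g <- g + ggplot2::geom_hline(yintercept = c(ss$ap, ss$al),
                                 linetype = "dashed", colour = "grey60")
  }
  g
}

#' Plot a non-identifiability scenario table
#'
#' Rate constants beta and gamma against assumed flux: every point is a
#' parameter set reproducing the identical observed pools.
#'
#' @param scenarios A tibble from [scenario_table()].
#' @return A ggplot object.
#' @export
plot_scenarios <- function(scenarios) {
  long <- tidyr::pivot_longer(scenarios, c("beta", "gamma"),
                              names_to = "rate_constant", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$assumed_flux, .data$value,
                                     colour = .data$rate_constant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "assumed flux (vesicles/h)", y = "rate constant (1/h)",
                  colour = NULL,
                  subtitle = "every point reproduces the same observed pools") +
    ggplot2::theme_minimal()
}

#' Plot a flux profile log-likelihood
#'
#' @param profile A tibble from [profile_flux_loglik()].
#' @return A ggplot object.
#' @export
plot_flux_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$flux, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "flux J (vesicles/h)", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}

#' Autoplot method for flux-assay results
#'
#' Tile map of flux classification by tissue and day, one facet per genotype.
#'
#' @param object A `flux_assay_result` from [flux_assay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot flux_assay_result
#' @export
autoplot.flux_assay_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$day), .data$tissue,
                                       fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "adult day", y = NULL, fill = "flux") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
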