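#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' @param x A `gbm_sim`.
#' @param ... Unused.
#' @return The observable time series as a long tibble
#'   (`step`, `t`, `metric`, `value`).
#' @export
tidy.gbm_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, cols = -c("step", "t"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x A `gbm_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the final observables and the protocol.
#' @export
glance.gbm_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  dplyr::bind_cols(
    tibble::tibble(mode = x$schedule$mode, n_steps = x$n_steps),
    last[, c("P_mass", "I_mass", "pct_necrosis", "pct_invasion",
             "pct_proliferation")]
  )
}

#' @export
tidy.lar_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.lar_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, degree = x$degree,
                 iterations = x$iterations, converged = x$converged,
                 nobs = length(x$y))
}

#' @export
tidy.gbm_logrank <- function(x, ...) {
  tibble::tibble(group = c("A", "B"),
                 observed = as.numeric(x$observed),
                 expected = as.numeric(x$expected))
}

#' @export
glance.gbm_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, df = 1)
}

#' Plot the observable time series of a simulation
#'
#' @param object A `gbm_sim`.
#' @param metrics Which series to draw (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbm_sim <- function(object,
                             metrics = c("P_mass", "I_mass", "pct_necrosis",
                                         "pct_invasion"),
                             ...) {
  dat <- dplyr::filter(tidy(object), .data$metric %in% metrics)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL,
                  title = paste0(object$schedule$mode, " protocol")) +
    ggplot2::theme_minimal()
}

#' Raster plot of a tissue-state field
#'
#' @param state A `tissue_state`.
#' @param field One of `"P"`, `"I"`, `"B"`, `"N"`, `"tau_h"`, `"tau_l"`.
#' @return A ggplot.
#' @export
plot_state <- function(state, field = c("P", "I", "B", "N", "tau_h", "tau_l")) {
  field <- match.arg(field)
  m <- state[[field]]
  dat <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  dat$value <- as.vector(t(m))  # row-major to match raster convention
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Heatmap of a parameter sweep metric
#'
#' @param table Output of [parameter_sweep()].
#' @param metric Column to display (default `"pct_necrosis"`).
#' @return A ggplot.
#' @export
plot_sweep <- function(table, metric = "pct_necrosis") {
  pars <- names(table)[1:2]
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data[[pars[1]]]),
                                      y = factor(.data[[pars[2]]]),
                                      fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = pars[1], y = pars[2]) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
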