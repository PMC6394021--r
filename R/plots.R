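#' Plot a turtle-day density map
#'
#' @param object A `stamm_density` tibble from [turtle_days_map()].
#' @param trans Transformation for the fill scale (`"log10"` suits the heavy
#'   right tail of turtle-day counts).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stamm_density <- function(object, trans = "log10", ...) {
  cell <- attr(object, "cell_deg") %||% 1
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat,
                                       fill = .data$n_days)) +
    ggplot2::geom_tile(width = cell, height = cell) +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "turtle-days") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude (°E)", y = "latitude (°N)") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative mortality curve
#'
#' @param object A `stamm_mortality` tibble from [cumulative_mortality()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stamm_mortality <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$day / 365, .data$frac_dead)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (years)", y = "cumulative cold-induced mortality") +
    ggplot2::theme_minimal()
}

#' Plot monthly cohort environment series
#'
#' Mean latitude, ambient temperature and ambient NPP of the surviving
#' cohort by month, faceted.
#'
#' @param object A `stamm_env_series` tibble from
#'   [cohort_environment_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stamm_env_series <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("mean_lat", "mean_tw", "mean_npp"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
      mean_lat = "latitude (°N)",
      mean_tw = "water temperature (°C)",
      mean_npp = "NPP (mmol C m⁻² day⁻¹)"
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_mid / 365, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot individual trajectories
#'
#' A thinned spaghetti map of trajectories coloured by age.
#'
#' @param run A `stamm_run` or archive tibble.
#' @param max_ids Number of individuals plotted (first ids kept).
#' @return A ggplot.
#' @export
plot_trajectories <- function(run, max_ids = 50) {
  archive <- as_archive(run)
  ids <- utils::head(unique(archive$id), max_ids)
  dat <- dplyr::filter(archive, .data$id %in% ids)
  ggplot2::ggplot(dat, ggplot2::aes(.data$lon, .data$lat, group = .data$id,
                                    colour = .data$age)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "age (yr)") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude (°E)", y = "latitude (°N)") +
    ggplot2::theme_minimal()
}
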