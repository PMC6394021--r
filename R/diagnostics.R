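#' Turtle-day density map
#'
#' Counts daily positions ("turtle-days") in regular lon/lat boxes.
#' Individuals that die of cold at any point are excluded entirely: maps
#' describe the dispersal of the surviving cohort.
#'
#' @param archive A run archive tibble ([tidy.stamm_run()]) or a `stamm_run`.
#' @param cell_deg Box size (degrees).
#' @return A tibble (`stamm_density`) with columns `lon`, `lat` (cell
#'   centres) and `n_days`.
#' @export
turtle_days_map <- function(archive, cell_deg = 1) {
  archive <- as_archive(archive)
  if (!nrow(archive)) stop("archive is empty")
  dat <- drop_dead(archive)
  out <- dat |>
    dplyr::mutate(
      lon = (floor(.data$lon / cell_deg) + 0.5) * cell_deg,
      lat = (floor(.data$lat / cell_deg) + 0.5) * cell_deg
    ) |>
    dplyr::count(.data$lon, .data$lat, name = "n_days")
  attr(out, "cell_deg") <- cell_deg
  class(out) <- c("stamm_density", class(out))
  out
}

#' Cumulative cold-induced mortality curve
#'
#' Fraction of the released cohort dead of cold by each simulated day.
#'
#' @param archive A run archive tibble or a `stamm_run`.
#' @param n_released Cohort size; defaults to the number of distinct ids in
#'   the archive.
#' @return A tibble (`stamm_mortality`) with columns `day`, `n_dead`,
#'   `frac_dead` (non-decreasing, final value in `[0, 1]`).
#' @export
cumulative_mortality <- function(archive, n_released = NULL) {
  run_obj <- if (inherits(archive, "stamm_run")) archive else NULL
  archive <- as_archive(archive)
  if (!nrow(archive)) stop("archive is empty")
  if (is.null(n_released)) {
    n_released <- if (!is.null(run_obj)) nrow(run_obj$cohort)
      else dplyr::n_distinct(archive$id)
  }
  days <- seq(min(archive$day), max(archive$day))
  dead <- dplyr::filter(archive, .data$status == "dead_cold")
  death_days <- if (nrow(dead)) {
    dplyr::summarise(dead, death_day = min(.data$day), .by = "id")
  } else {
    tibble::tibble(id = integer(), death_day = numeric())
  }
  n_dead <- vapply(days, function(d) sum(death_days$death_day <= d), numeric(1))
  out <- tibble::tibble(day = days, n_dead = n_dead,
                        frac_dead = n_dead / n_released)
  class(out) <- c("stamm_mortality", class(out))
  out
}

#' First-arrival ages in named areas
#'
#' Age (decimal years, 365-day year) of the youngest individual first
#' entering each named polygon, over the surviving cohort (cold-killed
#' individuals are discarded). Polygon membership uses an even-odd rule with
#' boundary points counted as inside; longitudes are normalized to
#' (-180, 180].
#'
#' @param archive A run archive tibble or a `stamm_run`.
#' @param areas Areas as a long tibble with columns `area`, `lon`, `lat`
#'   (ordered vertices per area), e.g. from [read_arrival_areas()].
#' @return A tibble with columns `area`, `arrived`, `first_age` (NA when the
#'   area is never entered) and `n_turtles` (number of distinct individuals
#'   ever recorded inside).
#' @export
first_arrival_ages <- function(archive, areas) {
  archive <- as_archive(archive)
  dat <- drop_dead(archive)
  dat$lon <- wrap_lon(dat$lon)
  areas |>
    dplyr::group_by(.data$area) |>
    dplyr::group_modify(function(g, key) {
      inside <- point_in_polygon(dat$lon, dat$lat,
                                 wrap_lon(g$lon), g$lat)
      hits <- dat[inside, ]
      tibble::tibble(
        arrived = nrow(hits) > 0,
        first_age = if (nrow(hits)) min(hits$age) else NA_real_,
        n_turtles = dplyr::n_distinct(hits$id)
      )
    }) |>
    dplyr::ungroup()
}

#' Point-in-polygon membership
#'
#' Even-odd membership via `mgcv::in.out()`, with points lying on a polygon
#' edge (within `tol` degrees) counted as inside.
#'
#' @param x,y Point coordinates.
#' @param px,py Polygon vertices (ordered; closure is implicit).
#' @param tol Boundary tolerance (degrees).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, px, py, tol = 1e-9) {
  if (anyNA(px) || anyNA(py) || length(px) < 3) stop("invalid polygon")
  bnd <- cbind(c(px, px[1]), c(py, py[1]))
  ok <- is.finite(x) & is.finite(y)
  out <- rep(FALSE, length(x))
  if (any(ok)) {
    out[ok] <- mgcv::in.out(bnd, cbind(x[ok], y[ok]))
    border <- on_segment(x[ok], y[ok], bnd, tol)
    out[ok] <- out[ok] | border
  }
  out
}

# distance-based check for points on any polygon edge
on_segment <- function(x, y, bnd, tol) {
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(bnd) - 1)) {
    ax <- bnd[k, 1]; ay <- bnd[k, 2]; bx <- bnd[k + 1, 1]; by <- bnd[k + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx^2 + dy^2
    if (L2 == 0) next
    t <- pmin(pmax(((x - ax) * dx + (y - ay) * dy) / L2, 0), 1)
    d2 <- (x - (ax + t * dx))^2 + (y - (ay + t * dy))^2
    hit <- hit | d2 <= tol^2
  }
  hit
}

#' Monthly cohort environment series
#'
#' Monthly means, over the surviving cohort's daily records, of latitude,
#' ambient water temperature and ambient NPP — the cohort-level view of the
#' seasonal migration and of the habitat quality encountered while crossing
#' the basin. Months are 365-day calendar months.
#'
#' @param archive A run archive tibble or a `stamm_run`.
#' @return A tibble (`stamm_env_series`) with columns `year`, `month`,
#'   `t_mid` (days), `mean_lat`, `mean_tw`, `mean_npp`, `n_records`.
#' @export
cohort_environment_series <- function(archive) {
  archive <- as_archive(archive)
  if (!nrow(archive)) stop("archive is empty")
  dat <- drop_dead(archive)
  mb <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))
  out <- dat |>
    dplyr::mutate(
      year = .data$day %/% 365,
      month = findInterval(.data$day %% 365, mb)
    ) |>
    dplyr::summarise(
      mean_lat = mean(.data$lat),
      mean_tw = mean(.data$tw, na.rm = TRUE),
      mean_npp = mean(.data$npp, na.rm = TRUE),
      n_records = dplyr::n(),
      .by = c("year", "month")
    ) |>
    dplyr::mutate(t_mid = .data$year * 365 + mb[.data$month] + 15) |>
    dplyr::arrange(.data$year, .data$month)
  class(out) <- c("stamm_env_series", class(out))
  out
}

#' Seasonality of the cohort's mean latitude
#'
#' Lag-12-month autocorrelation of the monthly mean-latitude series of
#' individuals older than `min_age`, after removing a quadratic trend. The
#' cohort's mean latitude carries a known low-frequency arc — tropical exit,
#' poleward drift, then settlement on the arrival grounds — and a quadratic
#' is the minimal polynomial capturing that rise-and-settle shape; removing
#' it isolates the annual oscillation. Values near 1 indicate strong
#' north-south seasonal migration.
#'
#' @param archive A run archive tibble or a `stamm_run`.
#' @param min_age Minimum age (years) of records entering the series.
#' @return The lag-12 autocorrelation (scalar; NA if the series is shorter
#'   than 24 months).
#' @export
seasonal_latitude_autocorr <- function(archive, min_age = 2) {
  archive <- as_archive(archive)
  ser <- cohort_environment_series(dplyr::filter(archive, .data$age >= min_age))
  s <- ser$mean_lat
  if (length(s) < 24) return(NA_real_)
  tt <- seq_along(s)
  resid <- stats::residuals(stats::lm(s ~ tt + I(tt^2)))
  # pairwise (Pearson) estimator at lag 12: the windowed ACF estimator is
  # biased toward zero by a factor ~(n-12)/n on series this short
  stats::cor(resid[seq_len(length(resid) - 12)],
             resid[-seq_len(12)])
}

#' Parameter sensitivity sweep
#'
#' Re-runs the simulation for each value of one model parameter (common
#' seed, cohort and forcing) and returns comparable turtle-day density maps
#' together with the runs. The canonical use is the NPP-scale sweep
#' (`P0` in 40, 60, 80, 100) probing how the feeding-habitat saturation
#' shapes attraction to productive boundary zones.
#'
#' @param forcing,cohort,params,mode,duration_years,seed,sense_deg As in
#'   [run_stamm()].
#' @param parameter Name of a `stamm_params` entry.
#' @param values Numeric values to sweep.
#' @param cell_deg Density-map cell size (degrees).
#' @return A tibble with one row per value: `parameter`, `value`, `map`
#'   (list of `stamm_density`), `run` (list of `stamm_run`).
#' @export
sensitivity_sweep <- function(forcing, cohort, parameter, values,
                              params = stamm_params(),
                              mode = "active", duration_years = 1,
                              seed = 1L, cell_deg = 1, sense_deg = NULL) {
  if (!parameter %in% names(params)) {
    stop(sprintf("unknown parameter '%s'", parameter))
  }
  stopifnot(all(is.finite(values)))
  rows <- purrr::map(values, function(val) {
    p <- params
    p[[parameter]] <- val
    validate_params(p)
    run <- run_stamm(forcing, cohort, p, mode = mode,
                     duration_years = duration_years, seed = seed,
                     sense_deg = sense_deg)
    tibble::tibble(parameter = parameter, value = val,
                   map = list(turtle_days_map(run, cell_deg)),
                   run = list(run))
  })
  dplyr::bind_rows(rows)
}

#' Distance to the eastern water boundary
#'
#' Zonal over-water distance (km) from points to the easternmost water cell
#' at their latitude — a scalar measure of how closely a cohort hugs the
#' productive eastern boundary.
#'
#' @param forcing A [forcing_fields()] object.
#' @param lon,lat Point coordinates (degrees).
#' @return Distances in km (NA for latitudes with no water).
#' @export
distance_to_eastern_boundary <- function(forcing, lon, lat) {
  ny <- length(forcing$lat)
  east_lon <- vapply(seq_len(ny), function(j) {
    w <- which(forcing$mask[, j])
    if (length(w)) forcing$lon[max(w)] else NA_real_
  }, numeric(1))
  jy <- pmin(pmax(round(approx_index(forcing$lat, lat)), 1), ny)
  el <- east_lon[jy]
  (el - lon) * 111.195 * cos(lat * pi / 180)
}

#' Final positions of a run
#'
#' Last archived position of each surviving individual.
#'
#' @param run A `stamm_run` or archive tibble.
#' @return A tibble with columns `id`, `day`, `lon`, `lat`, `age`.
#' @export
final_positions <- function(run) {
  archive <- as_archive(run)
  drop_dead(archive) |>
    dplyr::slice_max(.data$day, n = 1, by = "id", with_ties = FALSE) |>
    dplyr::select("id", "day", "lon", "lat", "age")
}

as_archive <- function(x) {
  if (inherits(x, "stamm_run")) x$archive else tibble::as_tibble(x)
}

# discard the full trajectory of any individual that died of cold
drop_dead <- function(archive) {
  dead_ids <- unique(archive$id[archive$status == "dead_cold"])
  dplyr::filter(archive, !.data$id %in% dead_ids)
}
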