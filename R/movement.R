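#' Sample a swimming heading from the habitat gradient
#'
#' The heading (angle from North, clockwise positive) is a von Mises draw
#' whose mean is the direction of the habitat gradient and whose
#' concentration is `kappa = alpha * ||grad h||`. A vanishing gradient gives
#' `kappa = 0`, i.e. a uniform heading: the walk degenerates to an isotropic
#' random walk in flat habitat and becomes increasingly directed as the
#' gradient steepens.
#'
#' @param dh_east,dh_north Habitat gradient components (m^-1).
#' @param params A [stamm_params()] object (uses `alpha`).
#' @return A tibble with columns `theta` (sampled heading, radians), `mu`
#'   (mean direction) and `kappa`.
#' @examples
#' set.seed(7)
#' sample_heading(0, 1e-6, stamm_params())   # gradient due North, kappa = 3
#' @export
sample_heading <- function(dh_east, dh_north, params = stamm_params()) {
  n <- max(length(dh_east), length(dh_north))
  dh_east <- rep_len(dh_east, n); dh_north <- rep_len(dh_north, n)
  if (any(!is.finite(dh_east) | !is.finite(dh_north))) {
    stop("gradient components must be finite")
  }
  norm <- sqrt(dh_east^2 + dh_north^2)
  mu <- ifelse(norm > 0, atan2(dh_east, dh_north), 0)
  kappa <- params$alpha * norm
  theta <- vapply(seq_len(n),
                  function(i) rvonmises(1, mu[i], kappa[i]),
                  numeric(1))
  tibble::tibble(theta = theta, mu = mu, kappa = kappa)
}

#' Swimming velocity
#'
#' `Vs = Vm * (1 - h) * (sin theta, cos theta)`: individuals swim at full
#' sustainable speed through worthless habitat (`h = 0`) and stop swimming in
#' perfect habitat (`h = 1`).
#'
#' @param h Habitat suitability in `[0, 1]`.
#' @param Vm Maximum sustainable speed (m s^-1).
#' @param theta Heading (radians from North, clockwise).
#' @return A tibble with columns `vs_east`, `vs_north` (m s^-1).
#' @export
swim_velocity <- function(h, Vm, theta) {
  if (any(h < 0 | h > 1, na.rm = TRUE)) stop("h must lie in [0, 1]")
  speed <- Vm * (1 - h)
  tibble::tibble(vs_east = speed * sin(theta), vs_north = speed * cos(theta))
}

#' Advance a position by a ground velocity
#'
#' Forward-Euler displacement on the sphere:
#' `dlon = Ve * dt / (R cos(lat))`, `dlat = Vn * dt / R` (converted to
#' degrees; Earth radius 6371 km). Longitudes wrap to (-180, 180].
#'
#' @param lon,lat Positions (degrees), vectorized.
#' @param vg_east,vg_north Ground velocity components (m s^-1).
#' @param dt Step length (s), default one day.
#' @return A tibble with columns `lon`, `lat`.
#' @examples
#' advance_position(-40, 30, 0, 1.286)  # ~1 degree North in one day
#' @export
advance_position <- function(lon, lat, vg_east, vg_north, dt = 86400) {
  stopifnot(dt > 0)
  if (any(!is.finite(vg_east) | !is.finite(vg_north))) {
    stop("ground velocity must be finite")
  }
  rad <- pi / 180
  new_lat <- lat + vg_north * dt / EARTH_RADIUS_M / rad
  new_lon <- lon + vg_east * dt / (EARTH_RADIUS_M * cos(lat * rad)) / rad
  new_lon <- wrap_lon(new_lon)
  tibble::tibble(lon = new_lon, lat = new_lat)
}

#' Wrap longitudes to (-180, 180]
#' @param lon Longitude(s), degrees.
#' @return Wrapped longitude(s).
#' @export
wrap_lon <- function(lon) {
  out <- lon - 360 * floor((lon + 180) / 360)
  out[out <= -180] <- 180
  out
}

#' Resolve a proposed step against the coastline
#'
#' Coastal sliding: if the proposed position is on land, retain whichever
#' displacement component (zonal or meridional) keeps the individual on
#' water — preferring the larger one when both work alone; if neither does,
#' stay put. Never returns a land position (given a water start).
#'
#' @param forcing A [forcing_fields()] object (supplies the land mask).
#' @param lon0,lat0 Start-of-step positions (on water).
#' @param lon1,lat1 Proposed end-of-step positions.
#' @return A tibble with columns `lon`, `lat`.
#' @export
resolve_coast <- function(forcing, lon0, lat0, lon1, lat1) {
  n <- max(length(lon0), length(lat0), length(lon1), length(lat1))
  lon0 <- rep_len(lon0, n); lat0 <- rep_len(lat0, n)
  lon1 <- rep_len(lon1, n); lat1 <- rep_len(lat1, n)
  ok <- on_water(forcing, lon1, lat1)
  out_lon <- ifelse(ok, lon1, lon0)
  out_lat <- ifelse(ok, lat1, lat0)
  blocked <- which(!ok)
  if (length(blocked)) {
    zon_ok <- on_water(forcing, lon1[blocked], lat0[blocked])
    mer_ok <- on_water(forcing, lon0[blocked], lat1[blocked])
    # compare displacement magnitudes in metres when both single-component
    # moves are viable
    rad <- pi / 180
    dzon <- abs(lon1[blocked] - lon0[blocked]) * cos(lat0[blocked] * rad)
    dmer <- abs(lat1[blocked] - lat0[blocked])
    take_zon <- zon_ok & (!mer_ok | dzon >= dmer)
    take_mer <- mer_ok & !take_zon
    out_lon[blocked[take_zon]] <- lon1[blocked][take_zon]
    out_lat[blocked[take_mer]] <- lat1[blocked][take_mer]
  }
  tibble::tibble(lon = out_lon, lat = out_lat)
}
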