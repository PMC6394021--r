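#' Specification of the idealized synthetic ocean
#'
#' Parameters of a self-contained idealized basin emulating the large-scale
#' structure the dispersal analysis relies on: a single clockwise subtropical
#' gyre with a narrow, fast western boundary current and a broad eastward
#' return flow at mid-latitudes (currents derived from a streamfunction, so
#' the flow is numerically near non-divergent and has no coastline-normal
#' component by construction); a meridional SST gradient with a seasonal
#' cycle whose amplitude grows poleward; and an NPP field with an
#' oligotrophic gyre interior, productive western and eastern boundary bands
#' and a high-latitude seasonal bloom. Land is reduced to simple meridional
#' margins on the western and eastern edges.
#'
#' Default NPP amplitudes place the 90th percentile of the NPP distribution
#' over water near 80 mmol C m^-2 day^-1, so the percentile rule used to set
#' `P0` is exercised at its nominal value.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds (degrees).
#' @param dx Grid spacing (degrees) for both axes.
#' @param n_years Years of forcing stored (the record loops with period
#'   `365 * n_years` days when `loop = TRUE`).
#' @param time_step_days Days between stored time slices.
#' @param land_width Width (degrees) of the western and eastern land margins.
#' @param psi_amp Gyre streamfunction amplitude (m^2 s^-1).
#' @param wbc_width_deg e-folding width (degrees) of the western boundary
#'   current at the gyre's northern flank, where the jet is narrowest and
#'   fastest.
#' @param wbc_south_width_deg e-folding width (degrees) of the western
#'   boundary flow at the southern edge. Real basins concentrate their
#'   boundary transport poleward: the broad, slow tropical boundary flow
#'   keeps hatchlings in warm water for roughly their first year before the
#'   fast mid-latitude jet carries them north, which is what makes a
#'   second-winter cold-mortality peak (rather than total first-autumn loss)
#'   possible.
#' @param gyre_center_lat Latitude (degrees) of the gyre centre.
#' @param gyre_north_lat Northern limit (degrees) of the gyre; the
#'   streamfunction vanishes poleward of it, leaving a quiescent subpolar
#'   band.
#' @param sst_eq Mean SST at the southern edge (degC).
#' @param sst_range Equator-to-pole mean SST drop across the domain (degC).
#' @param sst_profile_exp Exponent of the meridional mean-SST profile
#'   (`sst = sst_eq - sst_range * latfrac^exp`); the default 3 keeps the
#'   subtropical interior warm with a steep subpolar drop, as in real
#'   basins.
#' @param sst_seasonal_amp Seasonal SST amplitude at the northern edge (degC);
#'   scales linearly to 0 at the southern edge.
#' @param sst_phase_day Day of year of the northern-hemisphere SST maximum.
#' @param npp_background Oligotrophic interior NPP (mmol C m^-2 day^-1).
#' @param npp_west_amp,npp_east_amp Boundary-band NPP enhancements
#'   (mmol C m^-2 day^-1).
#' @param npp_west_lat_scale Gaussian latitude scale (degrees) confining the
#'   western band to the tropics (tropical-shelf analog); the eastern band
#'   spans the upwelling latitudes.
#' @param npp_band_width_km e-folding width of the boundary bands (km).
#' @param npp_bloom_amp High-latitude seasonal bloom amplitude
#'   (mmol C m^-2 day^-1).
#' @param npp_bloom_lat0 Latitude where the bloom starts (degrees).
#' @param npp_bloom_peak_day Day of year of the bloom maximum.
#' @param loop Whether the record is cyclic.
#' @param seed Seed stored with the spec (the generator is fully
#'   deterministic; the seed is carried for provenance).
#' @return An object of class `synthetic_ocean_spec`.
#' @export
synthetic_ocean_spec <- function(lon_min = -60, lon_max = 0,
                                 lat_min = 0, lat_max = 60,
                                 dx = 1,
                                 n_years = 1,
                                 time_step_days = 5,
                                 land_width = 2,
                                 psi_amp = 1.05e5,
                                 wbc_width_deg = 4,
                                 wbc_south_width_deg = 30,
                                 gyre_center_lat = 20,
                                 gyre_north_lat = 42,
                                 sst_eq = 28, sst_range = 22,
                                 sst_profile_exp = 3,
                                 sst_seasonal_amp = 7,
                                 sst_phase_day = 245,
                                 npp_background = 15,
                                 npp_west_amp = 90,
                                 npp_east_amp = 150,
                                 npp_west_lat_scale = 8,
                                 npp_band_width_km = 400,
                                 npp_bloom_amp = 80,
                                 npp_bloom_lat0 = 30,
                                 npp_bloom_peak_day = 160,
                                 loop = TRUE,
                                 seed = 1L) {
  spec <- as.list(environment())
  stopifnot(
    lon_max > lon_min, lat_max > lat_min, dx > 0,
    n_years >= 1, time_step_days >= 1,
    sst_eq - sst_range >= -2, sst_eq <= 35,
    npp_background >= 0, npp_west_amp >= 0, npp_east_amp >= 0,
    npp_bloom_amp >= 0
  )
  nx <- (lon_max - lon_min) / dx
  if (abs(nx - round(nx)) > 1e-8 ||
      abs((lat_max - lat_min) / dx - round((lat_max - lat_min) / dx)) > 1e-8) {
    stop("grid spacing must divide the domain extent")
  }
  class(spec) <- "synthetic_ocean_spec"
  spec
}

#' Generate the idealized synthetic ocean
#'
#' Builds a [forcing_fields()] object from a [synthetic_ocean_spec()];
#' optionally writes it to the package's netCDF forcing dialect.
#'
#' @param spec A [synthetic_ocean_spec()].
#' @param path Optional netCDF output path (see [write_forcing()]).
#' @return A `stamm_forcing` object.
#' @examples
#' oc <- synthetic_ocean(synthetic_ocean_spec(dx = 2))
#' @export
synthetic_ocean <- function(spec = synthetic_ocean_spec(), path = NULL) {
  stopifnot(inherits(spec, "synthetic_ocean_spec"))
  lon <- seq(spec$lon_min, spec$lon_max, by = spec$dx)
  lat <- seq(spec$lat_min, spec$lat_max, by = spec$dx)
  nx <- length(lon); ny <- length(lat)
  span <- 365 * spec$n_years
  time <- seq(spec$time_step_days / 2, span, by = spec$time_step_days)
  nt <- length(time)

  west_coast <- spec$lon_min + spec$land_width
  east_coast <- spec$lon_max - spec$land_width
  mask <- outer(lon, lat, function(lo, la) lo > west_coast & lo < east_coast)

  # --- currents from a Stommel-like gyre streamfunction -------------------
  xprime <- pmin(pmax((lon - west_coast) / (east_coast - west_coast), 0), 1)
  yprime <- ifelse(
    lat <= spec$gyre_center_lat,
    0.5 * (lat - spec$lat_min) / (spec$gyre_center_lat - spec$lat_min),
    0.5 + 0.5 * (lat - spec$gyre_center_lat) /
      (spec$gyre_north_lat - spec$gyre_center_lat)
  )
  yprime <- pmin(pmax(yprime, 0), 1)   # quiescent poleward of the gyre
  # boundary-layer width narrows poleward: broad slow tropical flow, fast jet
  # on the northern flank
  lam <- (spec$wbc_south_width_deg +
            (spec$wbc_width_deg - spec$wbc_south_width_deg) * yprime) /
    (east_coast - west_coast)
  sx <- 1 - outer(xprime, lam, function(x, l) exp(-x / l))
  psi <- spec$psi_amp * sx * (1 - xprime) *
    matrix(sin(pi * yprime), length(lon), length(lat), byrow = TRUE)
  psi[!mask] <- 0
  # u = -(1/R) dpsi/dphi ; v = (1/(R cos(phi))) dpsi/dlambda, by centred
  # differences of psi on the grid itself so the compatible discrete
  # divergence vanishes in the interior
  rad <- pi / 180
  dpsi_dlam <- apply_centered_diff(psi, along = 1, spacing = spec$dx * rad)
  dpsi_dphi <- apply_centered_diff(psi, along = 2, spacing = spec$dx * rad)
  coslat <- matrix(cos(lat * rad), nx, ny, byrow = TRUE)
  u2 <- -dpsi_dphi / EARTH_RADIUS_M
  v2 <- dpsi_dlam / (EARTH_RADIUS_M * coslat)
  u2[!mask] <- 0; v2[!mask] <- 0

  # --- SST and NPP --------------------------------------------------------
  latfrac <- (lat - spec$lat_min) / (spec$lat_max - spec$lat_min)
  sst_mean <- spec$sst_eq - spec$sst_range * latfrac^spec$sst_profile_exp
  dist_w_km <- outer(lon - west_coast, cos(lat * rad)) * 111.195
  dist_e_km <- outer(east_coast - lon, cos(lat * rad)) * 111.195
  # the western productive band is confined to the tropics (tropical-shelf
  # analog); the eastern band spans the upwelling latitudes
  latdecay <- matrix(exp(-(lat / spec$npp_west_lat_scale)^2),
                     length(lon), length(lat), byrow = TRUE)
  band <- spec$npp_west_amp * exp(-pmax(dist_w_km, 0) / spec$npp_band_width_km) *
    latdecay +
    spec$npp_east_amp * exp(-pmax(dist_e_km, 0) / spec$npp_band_width_km)
  bloom_lat <- pmax(0, (lat - spec$npp_bloom_lat0) /
                         (spec$lat_max - spec$npp_bloom_lat0))

  u <- array(rep(u2, nt), dim = c(nx, ny, nt))
  v <- array(rep(v2, nt), dim = c(nx, ny, nt))
  tw <- array(0, dim = c(nx, ny, nt))
  npp <- array(0, dim = c(nx, ny, nt))
  for (k in seq_len(nt)) {
    doy <- time[k] %% 365
    seas <- cos(2 * pi * (doy - spec$sst_phase_day) / 365)
    tw[, , k] <- matrix(sst_mean + spec$sst_seasonal_amp * latfrac * seas,
                        nx, ny, byrow = TRUE)
    bloom_seas <- (1 + cos(2 * pi * (doy - spec$npp_bloom_peak_day) / 365)) / 2
    npp[, , k] <- spec$npp_background + band +
      matrix(spec$npp_bloom_amp * bloom_lat * bloom_seas, nx, ny, byrow = TRUE)
  }
  npp[npp < 0] <- 0

  out <- forcing_fields(lon, lat, time, u, v, tw, npp, mask,
                        loop_period = if (spec$loop) span else NULL)
  if (!is.null(path)) write_forcing(out, path)
  out
}

# centred differences along one dimension of a matrix, one-sided at edges
apply_centered_diff <- function(m, along, spacing) {
  n <- dim(m)[along]
  out <- m * 0
  if (n < 2) return(out)
  if (along == 1) {
    out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * spacing)
    out[1, ] <- (m[2, ] - m[1, ]) / spacing
    out[n, ] <- (m[n, ] - m[n - 1, ]) / spacing
  } else {
    out[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * spacing)
    out[, 1] <- (m[, 2] - m[, 1]) / spacing
    out[, n] <- (m[, n] - m[, n - 1]) / spacing
  }
  out
}

#' NPP percentile over water
#'
#' Percentile of the NPP distribution over all water cells and stored time
#' slices; used to choose the feeding-habitat scale `P0` (the published rule
#' takes the 90th percentile over the basin of interest).
#'
#' @param forcing A [forcing_fields()] object.
#' @param q Percentile in (0, 100).
#' @return The NPP value (mmol C m^-2 day^-1).
#' @examples
#' npp_percentile(synthetic_ocean(synthetic_ocean_spec(dx = 4)), 90)
#' @export
npp_percentile <- function(forcing, q) {
  stopifnot(q > 0, q < 100)
  if (!any(forcing$mask)) stop("empty water mask")
  wat <- array(forcing$mask, dim = dim(forcing$npp))
  stats::quantile(forcing$npp[wat], probs = q / 100, names = FALSE, type = 7)
}
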