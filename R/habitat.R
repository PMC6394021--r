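#' Thermal habitat suitability
#'
#' Bounded thermal niche built on four pivotal temperatures
#' `T1 < T2 <= T3 < T4`: suitability is 1 on the preferendum `[T2, T3]`, with
#' a Gaussian tail below `T2` scaled by the cold range `T2 - T1` (so the index
#' is `exp(-2) ~ 0.135` at the cold critical temperature `T1`) and a symmetric
#' tail above `T3` scaled by `T4 - T3`. For leatherbacks the upper branch is
#' effectively inert as surface ocean temperatures never approach `T3`.
#'
#' @param Tw Water temperature(s), degC.
#' @param T1,T2,T3,T4 Pivotal temperatures (degC), `T1 < T2 <= T3 < T4`.
#'   `T1`/`T2` may be vectors (mass-dependent), recycled against `Tw`.
#' @return Suitability in `[0, 1]`.
#' @examples
#' thermal_habitat(c(5, 15, 25), T1 = 10, T2 = 20)
#' @export
thermal_habitat <- function(Tw, T1, T2, T3 = 45, T4 = 50) {
  if (any(T1 >= T2)) stop("degenerate pivots: T1 must be < T2")
  if (any(T2 > T3) || any(T3 >= T4)) stop("pivots must satisfy T2 <= T3 < T4")
  n <- max(length(Tw), length(T1), length(T2))
  Tw <- rep_len(Tw, n); T1 <- rep_len(T1, n); T2 <- rep_len(T2, n)
  h <- rep(1, n)
  cold <- !is.na(Tw) & Tw < T2
  h[cold] <- exp(-2 * ((Tw[cold] - T2[cold]) / (T2[cold] - T1[cold]))^2)
  hot <- !is.na(Tw) & Tw > T3
  h[hot] <- exp(-2 * ((Tw[hot] - T3) / (T4 - T3))^2)
  h[is.na(Tw)] <- NA_real_
  h
}

#' Feeding habitat suitability
#'
#' Prey availability relative to age-dependent demand:
#' `hF = min(1, P / (P0 * F0(age)))`. Net primary production is used directly
#' as the prey proxy `P`.
#'
#' @param P Net primary production (mmol C m^-2 day^-1, >= 0).
#' @param age Age in years (recycled against `P`).
#' @param params A [stamm_params()] object.
#' @return Suitability in `[0, 1]`.
#' @export
feeding_habitat <- function(P, age, params = stamm_params()) {
  if (any(P < 0, na.rm = TRUE)) stop("P must be >= 0")
  pmin(1, P / (params$P0 * food_norm(age, params)))
}

#' Composite habitat suitability at sampled environments
#'
#' The habitat index is the product `h = hT * hF` of the thermal and feeding
#' indices. Land samples (`valid = FALSE`, or `NA` temperature) yield `NA`:
#' the caller must handle the coastline.
#'
#' @param env A tibble with columns `tw`, `npp` and optionally `valid`
#'   (as returned by [sample_forcing()]).
#' @param physio A one-row (or `nrow(env)`-row) tibble with columns `T1`,
#'   `T2`, `age` (as from [physiology_at_age()]).
#' @param params A [stamm_params()] object.
#' @return A tibble with columns `hT`, `hF`, `h`.
#' @examples
#' p <- stamm_params()
#' env <- tibble::tibble(tw = 22, npp = 40, valid = TRUE)
#' habitat_index(env, physiology_at_age(5, p), p)
#' @export
habitat_index <- function(env, physio, params = stamm_params()) {
  n <- nrow(env)
  T1 <- rep_len(physio$T1, n); T2 <- rep_len(physio$T2, n)
  age <- rep_len(physio$age, n)
  hT <- thermal_habitat(env$tw, T1, T2, params$T3, params$T4)
  hF <- feeding_habitat(env$npp, age, params)
  h <- hT * hF
  if (!is.null(env$valid)) {
    h[!env$valid] <- NA_real_
    hT[!env$valid] <- NA_real_
    hF[!env$valid] <- NA_real_
  }
  tibble::tibble(hT = hT, hF = hF, h = h)
}

# mean Earth radius (m) used for all metric conversions
EARTH_RADIUS_M <- 6371000

#' Habitat value and gradient at positions
#'
#' Evaluates the habitat index and its spatial gradient (per metre, eastward
#' and northward components) by centred finite differences over a sensing
#' distance of one forcing-grid cell by default. East-west spacing is scaled
#' by `cos(latitude)`. When a stencil point is on land (or outside the grid)
#' a one-sided difference toward open water is used; if both sides are
#' blocked the component is zero, so coastal and degenerate stencils degrade
#' gracefully to a zero gradient.
#'
#' @param forcing A [forcing_fields()] object.
#' @param lon,lat,t_days Positions (degrees) and time (days), vectorized.
#' @param physio Tibble with `T1`, `T2`, `age` rows matching positions (or a
#'   single row, recycled).
#' @param params A [stamm_params()] object.
#' @param sense_deg Stencil half-width in degrees; default one grid cell.
#' @return A tibble with columns `h`, `hT`, `hF`, `dh_east`, `dh_north`
#'   (m^-1) and `grad_norm`.
#' @export
habitat_gradient <- function(forcing, lon, lat, t_days, physio,
                             params = stamm_params(), sense_deg = NULL) {
  n <- max(length(lon), length(lat), length(t_days))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t_days <- rep_len(t_days, n)
  out <- habitat_grad_list(forcing, lon, lat, t_days,
                           T1 = rep_len(physio$T1, n),
                           T2 = rep_len(physio$T2, n),
                           age = rep_len(physio$age, n),
                           params = params, sense_deg = sense_deg)
  tibble::as_tibble(out)
}

# internal fast path used by the engine (plain lists, no tibbles)
habitat_grad_list <- function(forcing, lon, lat, t_days, T1, T2, age, params,
                              sense_deg = NULL) {
  if (is.null(sense_deg)) {
    sense_deg <- c(
      if (length(forcing$lon) > 1) forcing$lon[2] - forcing$lon[1] else 1,
      if (length(forcing$lat) > 1) forcing$lat[2] - forcing$lat[1] else 1
    )
  } else {
    sense_deg <- rep_len(sense_deg, 2)
  }
  hab_at <- function(qlon, qlat, keep = FALSE) {
    env <- sample_env(forcing, qlon, qlat, t_days, vars = c("tw", "npp"))
    hT <- thermal_habitat(env$tw, T1, T2, params$T3, params$T4)
    hF <- feeding_habitat(env$npp, age, params)
    h <- hT * hF
    h[!env$valid] <- NA_real_
    if (keep) {
      hT[!env$valid] <- NA_real_; hF[!env$valid] <- NA_real_
      list(h = h, hT = hT, hF = hF)
    } else h
  }
  h0 <- hab_at(lon, lat, keep = TRUE)
  hE <- hab_at(lon + sense_deg[1], lat)
  hW <- hab_at(lon - sense_deg[1], lat)
  hN <- hab_at(lon, lat + sense_deg[2])
  hS <- hab_at(lon, lat - sense_deg[2])
  dx_m <- sense_deg[1] * pi / 180 * EARTH_RADIUS_M * cos(lat * pi / 180)
  dy_m <- sense_deg[2] * pi / 180 * EARTH_RADIUS_M
  dh_east <- fd_component(hW, h0$h, hE, dx_m)
  dh_north <- fd_component(hS, h0$h, hN, dy_m)
  list(h = h0$h, hT = h0$hT, hF = h0$hF,
       dh_east = dh_east, dh_north = dh_north,
       grad_norm = sqrt(dh_east^2 + dh_north^2))
}

# centred difference, degrading to one-sided near land, zero when blocked
fd_component <- function(h_minus, h_centre, h_plus, spacing) {
  spacing <- rep_len(spacing, length(h_centre))
  both <- !is.na(h_minus) & !is.na(h_plus)
  only_plus <- is.na(h_minus) & !is.na(h_plus) & !is.na(h_centre)
  only_minus <- !is.na(h_minus) & is.na(h_plus) & !is.na(h_centre)
  out <- numeric(length(h_centre))
  out[both] <- (h_plus[both] - h_minus[both]) / (2 * spacing[both])
  out[only_plus] <- (h_plus[only_plus] - h_centre[only_plus]) / spacing[only_plus]
  out[only_minus] <- (h_centre[only_minus] - h_minus[only_minus]) / spacing[only_minus]
  out
}
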