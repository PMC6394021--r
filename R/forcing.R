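#' Gridded environmental forcing fields
#'
#' Container for the surface forcing driving the simulation: eastward and
#' northward current components `u`, `v` (m s^-1), surface water temperature
#' `tw` (degC) and net primary production `npp` (mmol C m^-2 day^-1) on a
#' common regular lon/lat mesh with a (strictly increasing) time axis in days.
#' A logical land mask (`TRUE` = water) is shared by all fields. An optional
#' `loop_period` (days) declares the fields cyclic, so simulations longer than
#' the stored span reuse the record modularly.
#'
#' @param lon,lat Axis values (degrees), strictly increasing.
#' @param time Time axis (days), strictly increasing.
#' @param u,v,tw,npp Numeric arrays of dim `c(length(lon), length(lat),
#'   length(time))`. Values on land cells are ignored.
#' @param mask Logical matrix `length(lon) x length(lat)`, `TRUE` on water.
#' @param loop_period Optional loop period in days (> 0).
#' @return An object of class `stamm_forcing`.
#' @export
forcing_fields <- function(lon, lat, time, u, v, tw, npp, mask,
                           loop_period = NULL) {
  dims <- c(length(lon), length(lat), length(time))
  for (nm in c("u", "v", "tw", "npp")) {
    f <- get(nm)
    if (!identical(dim(f), as.integer(dims))) {
      stop(sprintf("field '%s' must have dim (nlon, nlat, ntime) = (%d, %d, %d)",
                   nm, dims[1], dims[2], dims[3]))
    }
  }
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop("lon and lat axes must be strictly increasing")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("time axis must be strictly increasing")
  }
  if (!is.logical(mask) || !identical(dim(mask), as.integer(dims[1:2]))) {
    stop("mask must be a logical nlon x nlat matrix")
  }
  if (!is.null(loop_period)) {
    stopifnot(loop_period > 0)
    if (length(time) > 1 && diff(range(time)) >= loop_period) {
      stop("time axis span must be shorter than loop_period")
    }
  }
  wat <- as.vector(mask)
  npp_w <- matrix(npp, nrow = dims[1] * dims[2])[wat, , drop = FALSE]
  if (any(npp_w < 0, na.rm = TRUE)) stop("npp must be non-negative on water")
  structure(
    list(lon = as.numeric(lon), lat = as.numeric(lat), time = as.numeric(time),
         u = u, v = v, tw = tw, npp = npp, mask = mask,
         loop_period = loop_period),
    class = "stamm_forcing"
  )
}

#' @export
print.stamm_forcing <- function(x, ...) {
  cat("<stamm_forcing>\n")
  cat(sprintf("  grid : %d x %d (lon %.2f..%.2f, lat %.2f..%.2f)\n",
              length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  time : %d slice(s), day %.1f..%.1f%s\n",
              length(x$time), min(x$time), max(x$time),
              if (!is.null(x$loop_period))
                sprintf(", looped every %g days", x$loop_period) else ""))
  cat(sprintf("  water: %d / %d cells\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Map a simulation time into the stored forcing span
#'
#' When forcing is cyclic, a query time beyond the stored record maps
#' modularly back into it: `t_eff = origin + (t - origin) %% loop_period`.
#'
#' @param t_days Query time(s) in days.
#' @param loop_period Loop period in days (> 0).
#' @param origin Start of the stored span (days).
#' @return Effective time(s) within `[origin, origin + loop_period)`.
#' @examples
#' loop_time(10 * 365, 7 * 365)  # year 10 maps into stored year 3
#' @export
loop_time <- function(t_days, loop_period, origin = 0) {
  stopifnot(loop_period > 0)
  origin + (t_days - origin) %% loop_period
}

#' Is a point on water?
#'
#' Nearest-node land-mask lookup; points outside the grid are not water.
#'
#' @param forcing A [forcing_fields()] object.
#' @param lon,lat Point coordinates (degrees), vectorized.
#' @return Logical vector.
#' @export
on_water <- function(forcing, lon, lat) {
  nx <- length(forcing$lon); ny <- length(forcing$lat)
  inside <- lon >= forcing$lon[1] & lon <= forcing$lon[nx] &
    lat >= forcing$lat[1] & lat <= forcing$lat[ny]
  ix <- pmin(pmax(round(approx_index(forcing$lon, lon)), 1), nx)
  iy <- pmin(pmax(round(approx_index(forcing$lat, lat)), 1), ny)
  out <- rep(FALSE, length(lon))
  ok <- inside & !is.na(ix) & !is.na(iy)
  out[ok] <- forcing$mask[cbind(ix[ok], iy[ok])]
  out
}

# fractional index of x on a monotone axis (1-based); NA outside hull
approx_index <- function(axis, x) {
  n <- length(axis)
  if (n == 1) return(ifelse(x == axis, 1, NA_real_))
  stats::approx(axis, seq_len(n), xout = x, rule = 1)$y
}

# Bilinear spatial weights with land-mask exclusion and renormalization.
# Returns list(idx = npts x 4 node linear index into an nlon x nlat slice,
#              w = npts x 4 weights summing to 1 (or 0 if all-land / outside))
bilinear_weights <- function(forcing, lon, lat) {
  nx <- length(forcing$lon); ny <- length(forcing$lat)
  fx <- approx_index(forcing$lon, lon)
  fy <- approx_index(forcing$lat, lat)
  bad <- is.na(fx) | is.na(fy)
  fx[bad] <- 1; fy[bad] <- 1
  ix <- pmin(floor(fx), nx - 1); ix <- pmax(ix, 1)
  iy <- pmin(floor(fy), ny - 1); iy <- pmax(iy, 1)
  tx <- fx - ix; ty <- fy - iy
  if (nx == 1) { ix <- rep(1, length(lon)); tx <- 0 * fx }
  if (ny == 1) { iy <- rep(1, length(lat)); ty <- 0 * fy }
  idx <- cbind(ix + (iy - 1) * nx,
               pmin(ix + 1, nx) + (iy - 1) * nx,
               ix + (pmin(iy + 1, ny) - 1) * nx,
               pmin(ix + 1, nx) + (pmin(iy + 1, ny) - 1) * nx)
  w <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  wat <- matrix(forcing$mask[idx], ncol = 4)
  w <- w * wat
  w[bad, ] <- 0
  s <- rowSums(w)
  pos <- s > 0
  w[pos, ] <- w[pos, , drop = FALSE] / s[pos]
  list(idx = idx, w = w, valid = pos)
}

# time bracketing with optional looping; returns i1, i2, wt (weight on i2)
time_weights <- function(forcing, t) {
  tm <- forcing$time
  nt <- length(tm)
  if (nt == 1) {
    if (is.null(forcing$loop_period) && any(t != tm)) {
      # single slice with no loop: treat field as stationary
    }
    return(list(i1 = rep(1, length(t)), i2 = rep(1, length(t)),
                wt = rep(0, length(t))))
  }
  if (!is.null(forcing$loop_period)) {
    t <- loop_time(t, forcing$loop_period, origin = tm[1])
  } else if (any(t < tm[1] - 1e-9 | t > tm[nt] + 1e-9)) {
    stop("query time outside the forcing span (no loop_period set)")
  }
  i1 <- findInterval(t, tm, rightmost.closed = TRUE)
  i1 <- pmin(pmax(i1, 1), nt)   # t == tm[1] etc.
  seam <- t > tm[nt]            # only possible when looping
  i2 <- pmin(i1 + 1, nt)
  dt <- tm[i2] - tm[i1]
  wt <- ifelse(dt > 0, (t - tm[i1]) / dt, 0)
  if (any(seam)) {
    gap <- tm[1] + forcing$loop_period - tm[nt]
    i1[seam] <- nt; i2[seam] <- 1
    wt[seam] <- (t[seam] - tm[nt]) / gap
  }
  list(i1 = i1, i2 = i2, wt = wt)
}

# internal fast path: same interpolation as sample_forcing() but returning a
# plain list of vectors (no tibble allocation in the daily loop)
sample_env <- function(forcing, lon, lat, t_days,
                       vars = c("u", "v", "tw", "npp")) {
  n <- max(length(lon), length(lat), length(t_days))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t_days <- rep_len(t_days, n)
  sw <- bilinear_weights(forcing, lon, lat)
  tw_ <- time_weights(forcing, t_days)
  nxy <- length(forcing$lon) * length(forcing$lat)
  out <- list()
  for (v in vars) {
    fld <- forcing[[v]]
    f1 <- matrix(fld[sw$idx + (tw_$i1 - 1) * nxy], ncol = 4)
    f2 <- matrix(fld[sw$idx + (tw_$i2 - 1) * nxy], ncol = 4)
    f1[sw$w == 0] <- 0; f2[sw$w == 0] <- 0
    val <- (1 - tw_$wt) * rowSums(sw$w * f1) + tw_$wt * rowSums(sw$w * f2)
    val[!sw$valid] <- NA_real_
    out[[v]] <- val
  }
  out$valid <- sw$valid
  out
}

#' Sample forcing fields at points
#'
#' Bilinear interpolation in space and linear interpolation in time. Land
#' neighbours are excluded with weight renormalization; a point whose four
#' surrounding nodes are all land (or that lies outside the grid) is invalid.
#' Query times beyond a cyclic record are looped via [loop_time()].
#'
#' @param forcing A [forcing_fields()] object.
#' @param lon,lat,t_days Point coordinates and times, vectorized (recycled to
#'   a common length).
#' @param vars Which fields to sample.
#' @return A tibble with columns `lon`, `lat`, `t`, the requested fields, and
#'   `valid`.
#' @export
sample_forcing <- function(forcing, lon, lat, t_days,
                           vars = c("u", "v", "tw", "npp")) {
  n <- max(length(lon), length(lat), length(t_days))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t_days <- rep_len(t_days, n)
  nx <- length(forcing$lon); ny <- length(forcing$lat)
  if (any(lon < forcing$lon[1] | lon > forcing$lon[nx] |
            lat < forcing$lat[1] | lat > forcing$lat[ny])) {
    stop("point outside the forcing grid")
  }
  env <- sample_env(forcing, lon, lat, t_days, vars)
  tibble::as_tibble(c(list(lon = lon, lat = lat, t = t_days), env))
}

#' Write / read forcing as a CF-style netCDF file
#'
#' The on-disk dialect: dimensions `(lon, lat, time)`; variables `u`, `v`,
#' `temperature`, `npp`, `mask` (1 = water); global attribute
#' `loop_period_days` when the record is cyclic. Land cells are stored as the
#' fill value. `read_forcing()` accepts a `name_map` to load files with other
#' variable names, and an optional secondary file for `npp` on its own grid,
#' which is bilinearly regridded to the current grid at load.
#'
#' @param forcing A [forcing_fields()] object.
#' @param path Path to a netCDF file.
#' @param name_map Named character vector mapping internal names
#'   (`u`, `v`, `tw`, `npp`) to variable names in the file.
#' @param npp_path Optional second netCDF file holding `npp` on its own grid.
#' @return `write_forcing()`: `path`, invisibly. `read_forcing()`: a
#'   `stamm_forcing`.
#' @export
write_forcing <- function(forcing, path) {
  dl <- ncdf4::ncdim_def("lon", "degrees_east", forcing$lon)
  dp <- ncdf4::ncdim_def("lat", "degrees_north", forcing$lat)
  dt <- ncdf4::ncdim_def("time", "days since simulation origin", forcing$time,
                         unlim = TRUE)
  fill <- 1e20
  defs <- list(
    u = ncdf4::ncvar_def("u", "m s-1", list(dl, dp, dt), fill, prec = "double"),
    v = ncdf4::ncvar_def("v", "m s-1", list(dl, dp, dt), fill, prec = "double"),
    tw = ncdf4::ncvar_def("temperature", "degC", list(dl, dp, dt), fill,
                          prec = "double"),
    npp = ncdf4::ncvar_def("npp", "mmol C m-2 day-1", list(dl, dp, dt), fill,
                           prec = "double"),
    mask = ncdf4::ncvar_def("mask", "1 = water", list(dl, dp), prec = "integer")
  )
  nc <- ncdf4::nc_create(path, defs)
  on.exit(ncdf4::nc_close(nc))
  wat <- array(forcing$mask, dim = dim(forcing$u))
  for (nm in c("u", "v", "tw", "npp")) {
    f <- forcing[[nm]]
    f[!wat] <- NA
    ncdf4::ncvar_put(nc, defs[[nm]], f)
  }
  ncdf4::ncvar_put(nc, defs$mask, forcing$mask + 0L)
  if (!is.null(forcing$loop_period)) {
    ncdf4::ncatt_put(nc, 0, "loop_period_days", forcing$loop_period)
  }
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path,
                         name_map = c(u = "u", v = "v", tw = "temperature",
                                      npp = "npp"),
                         npp_path = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lon <- as.numeric(nc$dim$lon$vals)
  lat <- as.numeric(nc$dim$lat$vals)
  time <- as.numeric(nc$dim$time$vals)
  have <- names(nc$var)
  fields <- list()
  for (nm in c("u", "v", "tw", "npp")) {
    if (nm == "npp" && !is.null(npp_path)) next
    file_nm <- unname(name_map[[nm]])
    if (!file_nm %in% have) {
      stop(sprintf("forcing file is missing variable '%s' (internal field '%s')",
                   file_nm, nm))
    }
    f <- ncdf4::ncvar_get(nc, file_nm, collapse_degen = FALSE)
    dim(f) <- c(length(lon), length(lat), length(time))
    fields[[nm]] <- f
  }
  if ("mask" %in% have) {
    msk <- ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE)
    dim(msk) <- c(length(lon), length(lat))
    mask <- msk > 0
  } else {
    mask <- !is.na(fields$tw[, , 1, drop = TRUE])
    dim(mask) <- c(length(lon), length(lat))
  }
  lp <- ncdf4::ncatt_get(nc, 0, "loop_period_days")
  loop_period <- if (lp$hasatt) as.numeric(lp$value) else NULL
  if (!is.null(npp_path)) {
    fields$npp <- read_regrid_npp(npp_path, name_map[["npp"]], lon, lat, time,
                                  mask)
  }
  for (nm in names(fields)) fields[[nm]][is.na(fields[[nm]])] <- 0
  forcing_fields(lon, lat, time, fields$u, fields$v, fields$tw, fields$npp,
                 mask, loop_period)
}

# Load NPP from its own (possibly finer) grid and regrid bilinearly to the
# current grid; linear interpolation onto the current-time slices.
read_regrid_npp <- function(path, var, lon, lat, time, mask) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!var %in% names(nc$var)) {
    stop(sprintf("forcing file is missing variable '%s' (internal field 'npp')", var))
  }
  slon <- as.numeric(nc$dim$lon$vals)
  slat <- as.numeric(nc$dim$lat$vals)
  stime <- as.numeric(nc$dim$time$vals)
  f <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  dim(f) <- c(length(slon), length(slat), length(stime))
  f[is.na(f)] <- 0
  src <- forcing_fields(slon, slat, stime, f, f, f, f,
                        mask = matrix(TRUE, length(slon), length(slat)))
  pts <- expand.grid(lon = lon, lat = lat)
  out <- array(0, dim = c(length(lon), length(lat), length(time)))
  for (k in seq_along(time)) {
    tq <- min(max(time[k], stime[1]), stime[length(stime)])
    out[, , k] <- sample_forcing(src, pts$lon, pts$lat, tq, vars = "npp")$npp
  }
  out
}

#' Load forcing per configuration
#'
#' Thin front end over [read_forcing()] taking a list of paths and a config
#' with a variable-name map, so reanalysis-style files and synthetic files
#' load without code changes.
#'
#' @param paths Named list: `main` (required), `npp` (optional separate file).
#' @param config Optional list with element `name_map` as in [read_forcing()].
#' @return A `stamm_forcing`.
#' @export
load_forcing <- function(paths, config = list()) {
  if (is.character(paths)) paths <- list(main = paths)
  stopifnot(!is.null(paths$main))
  nm <- config$name_map %||%
    c(u = "u", v = "v", tw = "temperature", npp = "npp")
  read_forcing(paths$main, name_map = nm, npp_path = paths$npp)
}
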