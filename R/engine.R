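#' Run the dispersal simulation
#'
#' Daily loop over the cohort: physiology is refreshed from age, the
#' environment is sampled at the current position, the cold-mortality rule is
#' applied (before movement, on the day's environment), and — in active
#' mode — the habitat index, its gradient, a von Mises heading and the
#' swimming velocity are computed. The position is then advanced by the
#' ground velocity (current + swimming) with forward Euler over one day, with
#' coastal sliding against the land mask. Passive mode sets the swimming
#' velocity to zero but still applies the mortality rule. Each individual
#' enters the loop on its own release date and is followed for
#' `duration_years` (365-day years) or until death; dead individuals stop
#' moving and stop accruing records.
#'
#' Headings are drawn from per-individual, per-day RNG substreams derived
#' from `seed` and each individual's substream key, so results are
#' reproducible and independent of cohort ordering, and a run with `v0 = 0`
#' is bit-identical to a passive run. The global RNG state is modified.
#'
#' @param forcing A [forcing_fields()] object covering (directly or via its
#'   loop period) the full simulated span.
#' @param cohort A cohort tibble from [make_cohort()] (columns `id`, `lon`,
#'   `lat`, `release_day`; optional `key`).
#' @param params A [stamm_params()] object.
#' @param mode `"active"` (habitat-driven swimming) or `"passive"` (currents
#'   only).
#' @param duration_years Years each individual is followed after release.
#' @param seed Integer seed for heading substreams.
#' @param sense_deg Gradient sensing half-width, degrees (default: one
#'   forcing-grid cell); see [habitat_gradient()].
#' @return A `stamm_run` object; its daily records are in `$archive`
#'   (also via [tidy()]): one row per individual per simulated day with
#'   position, habitat indices, swim speed, ambient temperature and NPP, and
#'   status (`"alive"` or `"dead_cold"`).
#' @examples
#' oc <- synthetic_ocean(synthetic_ocean_spec(dx = 2))
#' cohort <- make_cohort(release_spec_synthetic(n = 5), oc)
#' run <- run_stamm(oc, cohort, duration_years = 0.2, seed = 1)
#' glance(run)
#' @export
run_stamm <- function(forcing, cohort, params = stamm_params(),
                      mode = c("active", "passive"),
                      duration_years = 1, seed = 1L, sense_deg = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(forcing, "stamm_forcing"), duration_years >= 0)
  n <- nrow(cohort)
  key <- if (!is.null(cohort$key)) cohort$key else as.numeric(cohort$id)
  m31 <- 2147483647
  base_seed <- (as.numeric(seed) %% m31 * 48271 + key * 7919) %% m31

  duration_days <- round(duration_years * 365)
  start_day <- min(cohort$release_day)
  end_day <- max(cohort$release_day) + duration_days
  ndays <- end_day - start_day + 1

  lon <- cohort$lon; lat <- cohort$lat
  cold_days <- integer(n)
  alive <- rep(TRUE, n)
  rec <- function() matrix(NA_real_, n, ndays)
  A <- list(lon = rec(), lat = rec(), age = rec(), h = rec(), hT = rec(),
            hF = rec(), swim = rec(), tw = rec(), npp = rec(), dead = rec())

  for (d in seq_len(ndays)) {
    day <- start_day + d - 1
    act <- which(alive &
                   cohort$release_day <= day &
                   day <= cohort$release_day + duration_days)
    if (!length(act)) next
    age_yr <- (day - cohort$release_day[act]) / 365
    phys <- physiology_list(age_yr, params)
    env <- sample_env(forcing, lon[act], lat[act], day)

    # --- cold-induced mortality (before movement) -------------------------
    is_cold <- env$valid & !is.na(env$tw) & env$tw < phys$T1
    cold_days[act] <- update_cold_counter(cold_days[act], is_cold,
                                          params$cold_rule)
    died <- cold_days[act] >= params$mortality_window
    alive[act[died]] <- FALSE

    # --- habitat and swimming --------------------------------------------
    vs_e <- numeric(length(act)); vs_n <- numeric(length(act))
    if (mode == "active") {
      hab <- habitat_grad_list(forcing, lon[act], lat[act], day,
                               T1 = phys$T1, T2 = phys$T2, age = phys$age,
                               params = params, sense_deg = sense_deg)
      mv <- which(!died & env$valid & !is.na(hab$h))
      for (i in mv) {
        set.seed((base_seed[act[i]] + day * 15485863) %% m31)
        gnorm <- hab$grad_norm[i]
        mu <- if (gnorm > 0) atan2(hab$dh_east[i], hab$dh_north[i]) else 0
        theta <- rvonmises(1, mu, params$alpha * gnorm)
        sp <- phys$Vm[i] * (1 - hab$h[i])
        vs_e[i] <- sp * sin(theta)
        vs_n[i] <- sp * cos(theta)
      }
    } else {
      hT <- thermal_habitat(env$tw, phys$T1, phys$T2, params$T3, params$T4)
      hF <- feeding_habitat(env$npp, phys$age, params)
      h <- hT * hF
      h[!env$valid] <- NA_real_
      hab <- list(h = h, hT = hT, hF = hF)
    }

    # --- archive the day (state at start of step) -------------------------
    cells <- cbind(act, d)
    A$lon[cells] <- lon[act]; A$lat[cells] <- lat[act]
    A$age[cells] <- age_yr
    A$h[cells] <- hab$h; A$hT[cells] <- hab$hT; A$hF[cells] <- hab$hF
    A$swim[cells] <- sqrt(vs_e^2 + vs_n^2)
    A$tw[cells] <- env$tw; A$npp[cells] <- env$npp
    A$dead[cells] <- as.numeric(died)

    # --- advance survivors ------------------------------------------------
    mv <- which(!died)
    if (length(mv)) {
      im <- act[mv]
      ue <- ifelse(env$valid[mv], env$u[mv], 0)
      vn <- ifelse(env$valid[mv], env$v[mv], 0)
      rad <- pi / 180
      vg_e <- ue + vs_e[mv]; vg_n <- vn + vs_n[mv]
      plat <- lat[im] + vg_n * 86400 / EARTH_RADIUS_M / rad
      plon <- wrap_lon(lon[im] + vg_e * 86400 /
                         (EARTH_RADIUS_M * cos(lat[im] * rad)) / rad)
      res <- resolve_coast(forcing, lon[im], lat[im], plon, plat)
      lon[im] <- res$lon; lat[im] <- res$lat
    }
  }

  archive <- archive_to_tibble(A, cohort, start_day)
  structure(
    list(archive = archive, cohort = cohort, params = params, mode = mode,
         duration_years = duration_years, seed = seed,
         start_day = start_day, end_day = end_day),
    class = "stamm_run"
  )
}

# consecutive rule: any warm day resets the counter; cumulative: it never resets
update_cold_counter <- function(cold_days, is_cold, rule) {
  if (rule == "consecutive") {
    ifelse(is_cold, cold_days + 1L, 0L)
  } else {
    cold_days + as.integer(is_cold)
  }
}

#' Apply the cold-mortality rule to a state table
#'
#' One day's update of the cold-exposure counter and status for a table of
#' individuals: the counter increments on days with `Tw < T1(M)` (T1 from the
#' individual's current mass, so the threshold relaxes as it grows) and —
#' under the default consecutive-day rule — resets on any warmer day; death
#' occurs when the counter reaches `mortality_window` days.
#'
#' @param state A tibble with columns `M` (kg), `cold_days`, `status`.
#' @param Tw Ambient water temperature(s), degC (recycled).
#' @param params A [stamm_params()] object.
#' @return The updated state tibble.
#' @examples
#' st <- tibble::tibble(M = 20, cold_days = 9, status = "alive")
#' apply_cold_mortality(st, Tw = 5, stamm_params())
#' @export
apply_cold_mortality <- function(state, Tw, params = stamm_params()) {
  stopifnot(all(c("M", "cold_days", "status") %in% names(state)))
  alive <- state$status == "alive"
  T1 <- pivotal_temps(state$M, params)$T1
  is_cold <- rep_len(Tw, nrow(state)) < T1
  new_cold <- update_cold_counter(state$cold_days, is_cold, params$cold_rule)
  state$cold_days[alive] <- new_cold[alive]
  state$status[alive & state$cold_days >= params$mortality_window] <- "dead_cold"
  state
}

archive_to_tibble <- function(A, cohort, start_day) {
  n <- nrow(A$lon); ndays <- ncol(A$lon)
  keep <- !is.na(A$lon)
  ij <- which(keep, arr.ind = TRUE)
  ord <- order(ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  flat <- function(m) m[cbind(ij[, 1], ij[, 2])]
  tibble::tibble(
    id = cohort$id[ij[, 1]],
    day = start_day + ij[, 2] - 1,
    age = flat(A$age),
    lon = flat(A$lon), lat = flat(A$lat),
    h = flat(A$h), hT = flat(A$hT), hF = flat(A$hF),
    swim_speed = flat(A$swim),
    tw = flat(A$tw), npp = flat(A$npp),
    status = ifelse(flat(A$dead) > 0, "dead_cold", "alive")
  )
}

#' @export
print.stamm_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<stamm_run: %s mode, %d individuals, %.1f yr, seed %d>\n",
              x$mode, g$n_released, x$duration_years, as.integer(x$seed)))
  cat(sprintf("  alive %d | dead (cold) %d | cumulative mortality %.1f%%\n",
              g$n_alive, g$n_dead_cold, 100 * g$mortality_frac))
  cat(sprintf("  archive: %d daily records over days %d..%d\n",
              nrow(x$archive), x$start_day, x$end_day))
  invisible(x)
}

#' Tidy and summarize a simulation run
#'
#' `tidy()` returns the daily trajectory archive (one row per individual per
#' day). `glance()` returns a one-row summary: cohort size, survivors, cold
#' deaths, final cumulative mortality fraction, mode and duration.
#'
#' @param x A `stamm_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.stamm_run <- function(x, ...) x$archive

#' @rdname tidy.stamm_run
#' @exportS3Method generics::glance
glance.stamm_run <- function(x, ...) {
  dead_ids <- unique(x$archive$id[x$archive$status == "dead_cold"])
  n <- nrow(x$cohort)
  tibble::tibble(
    n_released = n,
    n_alive = n - length(dead_ids),
    n_dead_cold = length(dead_ids),
    mortality_frac = length(dead_ids) / n,
    mode = x$mode,
    duration_years = x$duration_years,
    seed = as.integer(x$seed)
  )
}

#' Export a run archive as delimited text
#'
#' @param run A `stamm_run`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_archive <- function(run, path) {
  utils::write.table(run$archive, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
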