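test_that("turtle-day maps count daily positions of never-dead turtles", {
  # one stationary turtle alive N days: a single cell with count N
  a <- arch_row(1, 0:19, lon = -30.2, lat = 25.3)
  m <- turtle_days_map(a, cell_deg = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_days, 20)
  expect_equal(c(m$lon, m$lat), c(-30.5, 25.5))
  # turtles that die of cold are excluded entirely
  dead <- arch_row(2, 0:4, lon = -10, lat = 10,
                   status = c(rep("alive", 4), "dead_cold"))
  m2 <- turtle_days_map(dplyr::bind_rows(a, dead))
  expect_equal(sum(m2$n_days), 20)
  expect_error(turtle_days_map(a[0, ]), "empty")
})

test_that("turtle-day maps match a brute-force tally on a random fixture", {
  set.seed(9)
  rows <- purrr::map(1:10, function(i) {
    nd <- sample(5:40, 1)
    arch_row(i, seq_len(nd) - 1, lon = runif(nd, -40, -20),
             lat = runif(nd, 10, 30),
             status = if (i <= 3) c(rep("alive", nd - 1), "dead_cold")
                      else "alive")
  })
  arch <- dplyr::bind_rows(rows)
  m <- turtle_days_map(arch, cell_deg = 2)
  live <- arch[!arch$id %in% 1:3, ]
  # oracle: independent double loop over cells
  for (k in sample(nrow(m), 5)) {
    cnt <- sum(live$lon >= m$lon[k] - 1 & live$lon < m$lon[k] + 1 &
                 live$lat >= m$lat[k] - 1 & live$lat < m$lat[k] + 1)
    expect_equal(m$n_days[k], cnt)
  }
  expect_equal(sum(m$n_days), nrow(live))
  # bookkeeping reconciles: never-dead days + dead-turtle days = all records
  expect_equal(sum(m$n_days) + sum(arch$id %in% 1:3), nrow(arch))
})

test_that("cumulative mortality is a non-decreasing fraction of the cohort", {
  alive <- dplyr::bind_rows(purrr::map(1:7, ~ arch_row(.x, 0:29, -30, 20)))
  dead <- dplyr::bind_rows(purrr::map(8:10, function(i) {
    arch_row(i, 0:(9 + i), -30, 20,
             status = c(rep("alive", 9 + i), "dead_cold"))
  }))
  cm <- cumulative_mortality(dplyr::bind_rows(alive, dead))
  expect_true(all(diff(cm$frac_dead) >= 0))
  expect_equal(max(cm$frac_dead), 0.3)   # 3 of 10 die
  expect_equal(cm$frac_dead[cm$day == 0], 0)
  # no deaths: an all-zero series
  cm0 <- cumulative_mortality(alive)
  expect_true(all(cm0$frac_dead == 0))
  # everyone dies on release + 10: a step to 1
  step <- dplyr::bind_rows(purrr::map(1:5, function(i)
    arch_row(i, 0:10, -30, 20, status = c(rep("alive", 10), "dead_cold"))))
  cms <- cumulative_mortality(step)
  expect_equal(max(cms$frac_dead), 1)
  expect_equal(cms$frac_dead[cms$day == 9], 0)
})

test_that("point-in-polygon agrees with a ray-casting oracle", {
  set.seed(21)
  px <- c(-30, -20, -20, -30); py <- c(11, 11, 22, 22)
  x <- runif(1000, -35, -15); y <- runif(1000, 8, 25)
  got <- point_in_polygon(x, y, px, py)
  oracle <- pip_raycast(x, y, px, py)
  expect_identical(got, oracle)
  # a non-convex polygon too
  px2 <- c(0, 4, 4, 2, 2, 0); py2 <- c(0, 0, 4, 4, 2, 2)
  x2 <- runif(1000, -1, 5); y2 <- runif(1000, -1, 5)
  expect_identical(point_in_polygon(x2, y2, px2, py2),
                   pip_raycast(x2, y2, px2, py2))
  # boundary counts as inside
  expect_true(point_in_polygon(-30, 15, px, py))
  expect_true(point_in_polygon(-25, 11, px, py))
  expect_error(point_in_polygon(0, 0, c(1, 2), c(1, 2)), "polygon")
})

test_that("first-arrival ages report the youngest entrant per area", {
  areas <- tibble::tibble(
    area = rep(c("inside", "never"), each = 4),
    lon = c(-31, -29, -29, -31, 10, 12, 12, 10),
    lat = c(19, 19, 21, 21, 0, 0, 2, 2)
  )
  # turtle 1 released inside -> age 0; turtle 2 enters at age 5/365
  a1 <- arch_row(1, 0:9, lon = -30, lat = 20)
  a2 <- arch_row(2, 0:9, lon = seq(-35, -26, 1), lat = 20)
  a2$age <- a2$day / 365
  got <- first_arrival_ages(dplyr::bind_rows(a1, a2), areas)
  expect_equal(got$first_age[got$area == "inside"], 0)
  expect_equal(got$n_turtles[got$area == "inside"], 2)
  # a polygon never visited is reported as no-arrival, not zero
  expect_false(got$arrived[got$area == "never"])
  expect_true(is.na(got$first_age[got$area == "never"]))
  # dead turtles are discarded: their entries do not count
  a3 <- arch_row(3, 0:9, lon = -30, lat = 20,
                 status = c(rep("alive", 9), "dead_cold"))
  got3 <- first_arrival_ages(dplyr::bind_rows(a2, a3), areas)
  # turtle 2 first touches the western edge of the box (boundary counts
  # as inside) on day 4
  expect_equal(got3$first_age[got3$area == "inside"], 4 / 365)
})

test_that("bundled arrival areas load with the published Mauritania box", {
  areas <- read_arrival_areas()
  expect_equal(dplyr::n_distinct(areas$area), 6)
  expect_setequal(unique(areas$area),
                  c("mauritania", "portugal", "gulf_of_cadiz", "tunisia",
                    "bay_of_biscay", "galicia"))
  mau <- areas[areas$area == "mauritania", ]
  expect_equal(range(mau$lon), c(-30, -20))
  expect_equal(range(mau$lat), c(11, 22))
  expect_match(mau$provenance[1], "published")
})

test_that("monthly cohort environment series averages the daily records", {
  # single stationary turtle: series constant at its sampled values
  a <- arch_row(1, 0:59, lon = -30, lat = 25.5, tw = 21.5, npp = 44)
  ser <- cohort_environment_series(a)
  expect_true(all(ser$mean_lat == 25.5))
  expect_true(all(ser$mean_tw == 21.5))
  expect_true(all(ser$mean_npp == 44))
  expect_equal(ser$n_records[1], 31)   # January of a 365-day calendar
  # two turtles at 30N and 40N: mean latitude 35N
  b <- dplyr::bind_rows(arch_row(1, 0:29, -30, 30), arch_row(2, 0:29, -30, 40))
  expect_true(all(cohort_environment_series(b)$mean_lat == 35))
  # weighted hand computation on an unbalanced fixture
  cc <- dplyr::bind_rows(arch_row(1, 0:2, -30, 10), arch_row(2, 0:1, -30, 40))
  expect_equal(cohort_environment_series(cc)$mean_lat, (3 * 10 + 2 * 40) / 5)
})

test_that("diagnostics are pure functions of the archive", {
  set.seed(13)
  arch <- dplyr::bind_rows(purrr::map(1:5, ~ arch_row(.x, 0:49,
    lon = runif(50, -40, -20), lat = runif(50, 10, 30))))
  expect_identical(turtle_days_map(arch), turtle_days_map(arch))
  expect_identical(cumulative_mortality(arch), cumulative_mortality(arch))
  expect_identical(cohort_environment_series(arch),
                   cohort_environment_series(arch))
})

test_that("sensitivity sweep runs the engine per value with a common seed", {
  oc <- synthetic_ocean(synthetic_ocean_spec(dx = 2))
  cohort <- make_cohort(release_spec_synthetic(n = 8), oc)
  sw <- sensitivity_sweep(oc, cohort, "P0", 80, duration_years = 0.3, seed = 5)
  expect_equal(nrow(sw), 1)
  # a sweep of length one equals a single run
  single <- run_stamm(oc, cohort, stamm_params(P0 = 80),
                      duration_years = 0.3, seed = 5)
  expect_equal(sw$map[[1]]$n_days, turtle_days_map(single)$n_days)
  expect_identical(sw$run[[1]]$archive, single$archive)
  expect_error(sensitivity_sweep(oc, cohort, "nope", c(1, 2)), "unknown")
  expect_error(sensitivity_sweep(oc, cohort, "P0", c(40, Inf)))
})

test_that("distance to the eastern water boundary uses the local metric", {
  mask <- matrix(TRUE, 11, 11)
  mask[10:11, ] <- FALSE   # land for lon >= -1
  fc <- make_forcing(lon = seq(-10, 0, 1), lat = seq(0, 60, 6), mask = mask)
  d_eq <- distance_to_eastern_boundary(fc, -12, 0)
  expect_equal(d_eq, 10 * 111.195, tolerance = 1e-6)
  d_60 <- distance_to_eastern_boundary(fc, -12, 60)
  expect_equal(d_60 / d_eq, cos(60 * pi / 180), tolerance = 1e-9)
})

test_that("autoplot methods return ggplot objects", {
  a <- dplyr::bind_rows(purrr::map(1:3, ~ arch_row(.x, 0:30,
    lon = runif(31, -40, -20), lat = runif(31, 10, 30))))
  expect_s3_class(ggplot2::autoplot(turtle_days_map(a)), "ggplot")
  expect_s3_class(ggplot2::autoplot(cumulative_mortality(a)), "ggplot")
  expect_s3_class(ggplot2::autoplot(cohort_environment_series(a)), "ggplot")
  expect_s3_class(plot_trajectories(a), "ggplot")
})
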