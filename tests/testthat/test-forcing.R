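test_that("netCDF forcing files round-trip", {
  fc <- make_forcing(lon = seq(-6, 0, 2), lat = seq(0, 6, 2),
                     time = c(2.5, 7.5, 12.5),
                     u = function(lon, lat, t) lon + t,
                     v = function(lon, lat, t) lat - t,
                     tw = function(lon, lat, t) 20 + lat / 2,
                     npp = function(lon, lat, t) 40 + lon,
                     loop_period = 15)
  path <- withr::local_tempfile(fileext = ".nc")
  write_forcing(fc, path)
  fc2 <- read_forcing(path)
  for (nm in c("lon", "lat", "time", "u", "v", "tw", "npp")) {
    expect_equal(fc2[[nm]], fc[[nm]], tolerance = 1e-12, label = nm)
  }
  expect_identical(fc2$mask, fc$mask)
  expect_equal(fc2$loop_period, 15)
})

test_that("land cells survive the file round-trip as masked values", {
  mask <- matrix(TRUE, 4, 4); mask[1, ] <- FALSE
  fc <- make_forcing(lon = 1:4, lat = 1:4, time = 0, tw = 21, mask = mask)
  path <- withr::local_tempfile(fileext = ".nc")
  write_forcing(fc, path)
  fc2 <- read_forcing(path)
  expect_identical(fc2$mask, mask)
  expect_false(on_water(fc2, 1, 2))
  expect_true(on_water(fc2, 3, 2))
})

test_that("missing variables are reported by name", {
  fc <- make_forcing()
  path <- withr::local_tempfile(fileext = ".nc")
  write_forcing(fc, path)
  expect_error(read_forcing(path, name_map = c(u = "u", v = "v_missing",
                                               tw = "temperature", npp = "npp")),
               "v_missing")
})

test_that("a coarse-cadence NPP file is regridded and time-interpolated", {
  fc <- make_forcing(lon = seq(-8, 0, 1), lat = seq(0, 8, 1),
                     time = c(0, 4, 8, 12, 16), npp = 1)
  # npp on its own coarser grid, 8-day cadence, plane field (bilinear-exact)
  npp_src <- make_forcing(lon = seq(-8, 0, 2), lat = seq(0, 8, 2),
                          time = c(0, 8, 16),
                          npp = function(lon, lat, t) 10 + lon + 2 * lat + t)
  p_main <- withr::local_tempfile(fileext = ".nc")
  p_npp <- withr::local_tempfile(fileext = ".nc")
  write_forcing(fc, p_main); write_forcing(npp_src, p_npp)
  fc2 <- load_forcing(list(main = p_main, npp = p_npp))
  # value at a node of the fine grid, slice t = 4: mean of the 8-day slices
  got <- sample_forcing(fc2, -3, 5, 4)$npp
  expect_equal(got, 10 - 3 + 10 + 4, tolerance = 1e-9)
})

test_that("interpolation is exact where it should be and convex otherwise", {
  fc <- make_forcing(lon = seq(-10, 0, 1), lat = seq(0, 10, 1),
                     time = c(0, 10),
                     tw = function(lon, lat, t) 3 * lon + 2 * lat + t)
  # at a node, on a stored slice: stored value exactly
  expect_equal(sample_forcing(fc, -4, 6, 0)$tw, -12 + 12 + 0)
  # halfway in time: mean of the two slices
  expect_equal(sample_forcing(fc, -4, 6, 5)$tw, mean(c(0, 10)) + 0)
  # plane field recovered exactly at interior off-node points
  expect_equal(sample_forcing(fc, -4.37, 6.21, 2.5)$tw,
               3 * -4.37 + 2 * 6.21 + 2.5, tolerance = 1e-12)
  # convexity: interpolated values within nodal extrema
  set.seed(3)
  fcr <- make_forcing(lon = seq(-10, 0, 1), lat = seq(0, 10, 1),
                      time = c(0, 10),
                      tw = function(lon, lat, t) sin(lon * 3 + t) * cos(lat * 2))
  pts <- tibble::tibble(lon = runif(50, -10, 0), lat = runif(50, 0, 10),
                        t = runif(50, 0, 10))
  got <- sample_forcing(fcr, pts$lon, pts$lat, pts$t)$tw
  expect_true(all(got <= max(fcr$tw) + 1e-12 & got >= min(fcr$tw) - 1e-12))
  expect_error(sample_forcing(fc, -11, 5, 0), "outside")
})

test_that("land neighbours are excluded with weight renormalization", {
  mask <- matrix(TRUE, 3, 3); mask[, 1] <- FALSE   # southern row is land
  fc <- make_forcing(lon = 0:2, lat = 0:2, time = 0,
                     tw = function(lon, lat, t) ifelse(lat == 0, 999, 20 + lon),
                     mask = mask)
  # halfway between a land and a water node: water value only
  got <- sample_forcing(fc, 1, 0.5, 0)
  expect_true(got$valid)
  expect_equal(got$tw, 21)
  # all four neighbours on land: invalid
  only_corner <- matrix(FALSE, 3, 3); only_corner[1, 1] <- TRUE
  fc2 <- make_forcing(lon = 0:2, lat = 0:2, time = 0, mask = only_corner)
  got <- sample_forcing(fc2, 1.5, 1.5, 0)
  expect_false(got$valid)
  expect_true(is.na(got$tw))
})

test_that("time looping maps queries modularly into the stored span", {
  expect_equal(loop_time(100, 2555), 100)
  expect_equal(loop_time(2555, 2555), 0)
  # with a 7-year span, a date in simulated year 10 maps into stored year 3
  t10 <- 9.4 * 365
  expect_equal(loop_time(t10, 7 * 365), t10 - 7 * 365)
  expect_gt(loop_time(t10, 7 * 365) / 365, 2)
  expect_lt(loop_time(t10, 7 * 365) / 365, 3)
  expect_error(loop_time(1, 0))
})

test_that("forcing repeats with its loop period (modular forcing property)", {
  fc <- make_forcing(lon = seq(-10, 0, 1), lat = seq(0, 10, 1),
                     time = seq(5, 355, by = 10),
                     tw = function(lon, lat, t) 20 + 5 * sin(2 * pi * t / 365) + lon,
                     loop_period = 365)
  set.seed(11)
  pts <- tibble::tibble(lon = runif(20, -10, 0), lat = runif(20, 0, 10),
                        t = runif(20, 0, 3000))
  a <- sample_forcing(fc, pts$lon, pts$lat, pts$t)$tw
  b <- sample_forcing(fc, pts$lon, pts$lat, pts$t + 365)$tw
  expect_equal(a, b, tolerance = 1e-12)
  # the seam between the last and (looped) first slice interpolates smoothly
  s_end <- sample_forcing(fc, -5, 5, 355)$tw
  s_start <- sample_forcing(fc, -5, 5, 365 + 5)$tw
  s_mid <- sample_forcing(fc, -5, 5, 362.5)$tw   # midpoint of the seam gap
  expect_equal(s_mid, (s_end + s_start) / 2, tolerance = 1e-12)
  # out-of-span queries without a loop period are an error
  fc_noloop <- make_forcing(time = c(0, 10))
  expect_error(sample_forcing(fc_noloop, -5, 5, 11), "loop_period")
})

test_that("constructor validates axes, masks and field dimensions", {
  expect_error(make_forcing(lon = c(0, 2, 1)), "increasing")
  expect_error(
    forcing_fields(0:1, 0:1, 0, array(0, c(2, 2, 2)), array(0, c(2, 2, 1)),
                   array(0, c(2, 2, 1)), array(0, c(2, 2, 1)),
                   matrix(TRUE, 2, 2)),
    "dim")
  expect_error(make_forcing(npp = -5), "non-negative")
  # negative NPP on land cells is tolerated (masked)
  mask <- matrix(c(FALSE, rep(TRUE, 120)), 11, 11)
  expect_s3_class(make_forcing(npp = function(lon, lat, t)
    ifelse(lon == -10 & lat == 0, -1, 5), mask = mask), "stamm_forcing")
})
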