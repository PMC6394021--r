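# Small forcing builders and independent oracles used across tests.

# forcing on a regular grid from field functions f(lon, lat, t)
make_forcing <- function(lon = seq(-10, 0, by = 1), lat = seq(0, 10, by = 1),
                         time = 0, u = 0, v = 0, tw = 20, npp = 50,
                         mask = NULL, loop_period = NULL) {
  nx <- length(lon); ny <- length(lat); nt <- length(time)
  fld <- function(f) {
    if (is.function(f)) {
      out <- array(0, c(nx, ny, nt))
      for (k in seq_len(nt)) out[, , k] <- outer(lon, lat, f, t = time[k])
      out
    } else {
      array(f, c(nx, ny, nt))
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  forcing_fields(lon, lat, time, fld(u), fld(v), fld(tw), fld(npp), mask,
                 loop_period = loop_period)
}

# uniform-environment ocean with controllable temperature time series:
# one slice per integer day so engine samples hit stored values exactly
make_tw_series_forcing <- function(tw_by_day, lon = seq(-4, 4, 2),
                                   lat = seq(-4, 4, 2), npp = 500) {
  time <- seq_along(tw_by_day) - 1
  nx <- length(lon); ny <- length(lat); nt <- length(time)
  tw <- array(rep(tw_by_day, each = nx * ny), c(nx, ny, nt))
  zero <- array(0, c(nx, ny, nt))
  forcing_fields(lon, lat, time, zero, zero, tw,
                 array(npp, c(nx, ny, nt)), matrix(TRUE, nx, ny))
}

# hand-built archive row
arch_row <- function(id, day, lon, lat, age = day / 365, status = "alive",
                     h = 1, tw = 25, npp = 50) {
  tibble::tibble(id = id, day = day, age = age, lon = lon, lat = lat,
                 h = h, hT = h, hF = 1, swim_speed = 0, tw = tw, npp = npp,
                 status = status)
}

# ray-casting point-in-polygon oracle (crossing parity; open boundary)
pip_raycast <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rayleigh test p-value (approximation, fine at n = 1e4)
rayleigh_p <- function(theta) {
  n <- length(theta)
  R2 <- (mean(cos(theta)))^2 + (mean(sin(theta)))^2
  z <- n * R2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# circular mean direction
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))
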