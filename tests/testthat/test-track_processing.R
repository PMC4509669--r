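# Brute-force oracles: implied-speed re-check against haversine speeds
# computed independently, and spike re-check from bearings.

oracle_speed_ok <- function(locs, vmax) {
  n <- nrow(locs)
  if (n < 3) return(TRUE)
  d <- oracle_dist_km(locs$lon[-n], locs$lat[-n], locs$lon[-1], locs$lat[-1]) * 1000
  v <- d / pmax(diff(as.numeric(locs$time)), 1)
  ok <- TRUE
  for (i in 2:n) {
    viol <- if (i < n) v[i - 1] > vmax && v[i] > vmax else v[i - 1] > vmax
    if (viol) ok <- FALSE
  }
  ok
}

oracle_no_spikes <- function(locs, rules) {
  n <- nrow(locs)
  if (n < 3) return(TRUE)
  for (i in 2:(n - 1)) {
    ang <- sealdive:::.interior_angle(locs$lon[i - 1], locs$lat[i - 1],
                                      locs$lon[i], locs$lat[i],
                                      locs$lon[i + 1], locs$lat[i + 1])
    l1 <- oracle_dist_km(locs$lon[i - 1], locs$lat[i - 1], locs$lon[i], locs$lat[i])
    l2 <- oracle_dist_km(locs$lon[i], locs$lat[i], locs$lon[i + 1], locs$lat[i + 1])
    for (r in rules) if (ang < r[1] && l1 > r[2] && l2 > r[2]) return(FALSE)
  }
  TRUE
}

test_that("SDA filter speed rule on constructed triples", {
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  # 3 collinear points at 0.5 m/s: kept
  slow <- make_argos(lon = c(11, 11, 11), lat = 78.5 + c(0, 1, 2) * 0.5 * 3600 / 111194.9,
                     t = t0 + c(0, 3600, 7200))
  r <- sda_filter(as_argos(slow))
  expect_equal(nrow(r$locs), 3)
  expect_equal(r$report$n_removed_speed, 0)

  # middle point displaced so both legs imply 3 m/s: removed
  fast <- slow
  fast$lat[2] <- fast$lat[1] + 3 * 3600 / 111194.9
  fast$lat[3] <- fast$lat[1] + 2 * 0.5 * 3600 / 111194.9
  r2 <- sda_filter(as_argos(fast))
  expect_equal(r2$report$n_removed_speed, 1)
  expect_equal(nrow(r2$locs), 2)
  # haversine speed oracle confirms the violation on the input
  d12 <- oracle_dist_km(fast$lon[1], fast$lat[1], fast$lon[2], fast$lat[2]) * 1000
  expect_gt(d12 / 3600, 2)
})

test_that("SDA filter spike rule on constructed V-spikes", {
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  # V-spike: out 3 km at bearing 5 deg off the return: angle ~10 deg, legs 3 km
  kpd <- 111.1949
  lat0 <- 78.5
  apex_lat <- lat0 + 3 * cos(5 * pi / 180) / kpd
  apex_lon <- 11 + 3 * sin(5 * pi / 180) / (kpd * cos(lat0 * pi / 180))
  v <- make_argos(lon = c(11, apex_lon, 11, 11.001),
                  lat = c(lat0, apex_lat, lat0, lat0),
                  t = t0 + c(0, 6, 12, 13) * 3600)
  ang <- sealdive:::.interior_angle(v$lon[1], v$lat[1], v$lon[2], v$lat[2],
                                    v$lon[3], v$lat[3])
  expect_lt(ang, 15)
  r <- sda_filter(as_argos(v))
  expect_equal(r$report$n_removed_spike, 1)
  expect_false(apex_lat %in% r$locs$lat)

  # same geometry with 2 km legs: below the (15, 2.5 km) rule, kept
  apex_lat2 <- lat0 + 2 * cos(5 * pi / 180) / kpd
  v2 <- v; v2$lat[2] <- apex_lat2
  v2$lon[2] <- 11 + 2 * sin(5 * pi / 180) / (kpd * cos(lat0 * pi / 180))
  r2 <- sda_filter(as_argos(v2))
  expect_equal(r2$report$n_removed_spike, 0)
})

test_that("SDA filter equals brute-force re-check and is idempotent", {
  set.seed(13)
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  # noisy random walk with outliers, 200 points
  n <- 200
  lat <- 78.5 + cumsum(rnorm(n, 0, 0.005))
  lon <- 11 + cumsum(rnorm(n, 0, 0.02))
  out <- sample(2:n, 12)
  lat[out] <- lat[out] + runif(12, 0.2, 0.6) * sample(c(-1, 1), 12, TRUE)
  locs <- as_argos(make_argos(lon, lat, t0 + (0:(n - 1)) * 1800))
  r <- sda_filter(locs)
  expect_true(oracle_speed_ok(r$locs, 2))
  expect_true(oracle_no_spikes(r$locs, list(c(15, 2.5), c(25, 5))))
  # idempotent: filtering the output removes nothing
  r2 <- sda_filter(r$locs)
  expect_equal(nrow(r2$locs), nrow(r$locs))
  expect_equal(r2$report$n_removed_speed + r2$report$n_removed_spike, 0)
  # report accounting
  expect_equal(r$report$n_input,
               nrow(r$locs) + r$report$n_removed_speed + r$report$n_removed_spike)
  # first location never removed
  expect_equal(r$locs$time[1], locs$time[1])

  expect_warning(sda_filter(locs[1:2, ]), "<3 locations")
})

test_that("noiseless straight-line track is reproduced and interpolated", {
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  n <- 30
  locs <- make_argos(lon = seq(10, 10.6, length.out = n),
                     lat = seq(78, 78.12, length.out = n),
                     t = t0 + (0:(n - 1)) * 3600)
  tm <- fit_track(as_argos(locs),
                  err_sd_km = c("3" = 1e-4, "2" = 1e-4, "1" = 1e-4,
                                "0" = 1e-4, "A" = 1e-4, "B" = 1e-4),
                  fixed = c(0.001, 0.05))
  # at observation times: the observation itself
  at_obs <- locate(tm, "A", locs$t[5])
  expect_lt(gc_dist_km(at_obs$lon, at_obs$lat, locs$lon[5], locs$lat[5]), 1e-5)
  # midway: linear interpolation limit
  mid <- locate(tm, "A", locs$t[5] + 1800)
  expect_lt(gc_dist_km(mid$lon, mid$lat, (locs$lon[5] + locs$lon[6]) / 2,
                       (locs$lat[5] + locs$lat[6]) / 2), 1e-3)
  # monotone in t between observations
  tt <- locs$t[10] + seq(0, 3600, by = 300)
  seq_loc <- locate(tm, "A", tt)
  expect_true(all(diff(seq_loc$lon) > 0))
  # out of range errors
  expect_error(locate(tm, "A", t0 + 40 * 86400), "outside")
})

test_that("haul-out predictions return the anchor location exactly", {
  sim <- small_sim()
  a <- sim$animals$id[1]
  ho <- sim$haulouts[sim$haulouts$id == a, ]
  ho <- ho[as.numeric(ho$end - ho$start) > 0, ]
  f <- sda_filter(sim$argos[sim$argos$id == a, ])
  tm <- fit_track(f$locs, sim$haulouts)
  k <- which.max(as.numeric(ho$end) - as.numeric(ho$start))
  mid1 <- ho$start[k] + 0.3 * (ho$end[k] - ho$start[k])
  mid2 <- ho$start[k] + 0.8 * (ho$end[k] - ho$start[k])
  p <- locate(tm, a, c(mid1, mid2))
  expect_equal(p$lon[1], p$lon[2], tolerance = 1e-12)
  expect_equal(p$lat[1], p$lat[2], tolerance = 1e-12)
})

test_that("smoothing beats raw observations against the true track", {
  sim <- small_sim()
  tr <- sim$truth$tracks
  f <- sda_filter(sim$argos)
  tm <- fit_track(f$locs, sim$haulouts)
  raw_err <- sm_err <- numeric(0)
  for (a in sim$animals$id) {
    ta <- tr[tr$id == a, ]
    ob <- f$locs[f$locs$id == a, ]
    ob <- ob[ob$time >= min(ta$time) & ob$time <= max(ta$time), ]
    h <- as.numeric(difftime(ob$time, ta$time[1], units = "secs")) / 600
    i0 <- pmin(floor(h), nrow(ta) - 2); w <- h - i0
    tlon <- ta$lon[i0 + 1] * (1 - w) + ta$lon[i0 + 2] * w
    tlat <- ta$lat[i0 + 1] * (1 - w) + ta$lat[i0 + 2] * w
    raw_err <- c(raw_err, gc_dist_km(ob$lon, ob$lat, tlon, tlat))
    sm <- locate(tm, a, ob$time)
    sm_err <- c(sm_err, gc_dist_km(sm$lon, sm$lat, tlon, tlat))
  }
  expect_lt(sqrt(mean(sm_err^2)), sqrt(mean(raw_err^2)))
  # mean error stays below the class-B measurement SD
  expect_lt(mean(sm_err), argos_error_sd_km["B"])
})

test_that("CTCRW parameters are recovered from a model-generated track", {
  set.seed(17)
  beta <- 0.8; sigma <- 2.0
  n <- 10000; dt <- 0.25  # hours
  v <- numeric(n); x <- numeric(n)
  a <- exp(-beta * dt)
  sv <- sigma * sqrt((1 - a^2) / (2 * beta))
  for (i in 2:n) {
    x[i] <- x[i - 1] + v[i - 1] * (1 - a) / beta +
      rnorm(1, 0, sigma / beta * sqrt(max(dt - 2 * (1 - a) / beta +
                                            (1 - a^2) / (2 * beta), 0)))
    v[i] <- a * v[i - 1] + rnorm(1, 0, sv)
  }
  y <- numeric(n)
  vy <- numeric(n)
  for (i in 2:n) {
    y[i] <- y[i - 1] + vy[i - 1] * (1 - a) / beta +
      rnorm(1, 0, sigma / beta * sqrt(max(dt - 2 * (1 - a) / beta +
                                            (1 - a^2) / (2 * beta), 0)))
    vy[i] <- a * vy[i - 1] + rnorm(1, 0, sv)
  }
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  kpd <- 111.1949; lat0 <- 78.5
  locs <- make_argos(lon = 11 + (x + rnorm(n, 0, 1)) / (kpd * cos(lat0 * pi / 180)),
                     lat = lat0 + (y + rnorm(n, 0, 1)) / kpd,
                     t = t0 + (0:(n - 1)) * dt * 3600, lc = "1")
  tm <- fit_track(as_argos(locs),
                  err_sd_km = c("3" = 1, "2" = 1, "1" = 1, "0" = 1,
                                "A" = 1, "B" = 1))
  f <- tm$fits[[1]]
  expect_lt(abs(f$beta - beta) / beta, 0.25)
  expect_lt(abs(f$sigma - sigma) / sigma, 0.25)
})

test_that("haul-out detection follows the dry-for-10-minutes rule", {
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  wd <- data.frame(id = "A", time = t0 + seq(0, 7200, by = 300),
                   dry = FALSE)
  wd$dry[wd$time >= t0 + 1800 & wd$time < t0 + 4500] <- TRUE
  ho <- detect_haulouts(wd)
  expect_equal(nrow(ho), 1)
  expect_equal(as.numeric(ho$start - t0, units = "secs"), 1800)
  expect_equal(as.numeric(ho$end - t0, units = "secs"), 4500)
  # a 5-minute dry spell is not a haul-out
  wd2 <- wd; wd2$dry <- FALSE; wd2$dry[5] <- TRUE
  expect_null(detect_haulouts(wd2))
})
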