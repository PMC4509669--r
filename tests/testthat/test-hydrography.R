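# Frozen oracle values for the equation of state are the published UNESCO
# check table (density and potential temperature), which fully pins down the
# EOS-80 polynomials.

test_that("seawater density and potential temperature match UNESCO checks", {
  expect_equal(sw_dens(0, 5, 0), 999.96675, tolerance = 1e-8)
  expect_equal(sw_dens(35, 5, 0), 1027.67547, tolerance = 1e-8)
  expect_equal(sw_dens(35, 25, 10000), 1062.53817, tolerance = 1e-8)
  expect_equal(sw_dens(0, 25, 10000), 1037.90204, tolerance = 1e-8)
  expect_equal(sw_ptmp(40, 40, 10000, 0), 36.89073, tolerance = 1e-5)
  # at surface pressure sigma-theta is the density anomaly itself
  expect_equal(potential_density(35, 15, 0), sw_dens(35, 15, 0) - 1000,
               tolerance = 1e-12)
})

test_that("potential density is monotone in salinity and temperature", {
  # salty cold denser than fresh cold
  expect_gt(potential_density(34.9, 1, 50), potential_density(34.3, 1, 50))
  # warmer is lighter above the temperature of maximum density at S ~ 34
  expect_lt(potential_density(34.3, 5, 0), potential_density(34.3, 1, 0))
  expect_error(potential_density(50, 5, 0), "range")
  expect_error(potential_density(35, -3, 0), "range")
})

test_that("mixed-layer depth locates a sharp two-layer interface", {
  cast <- make_two_layer_cast(interface = 40, max_depth = 120, dz = 5)
  m <- mixed_layer_depth(cast, dsigma = 0.03)
  expect_true(m$valid); expect_false(m$bottom_limited)
  expect_lt(abs(m$mld - 40), 5)

  # homogeneous cast: bottom-limited at the deepest level
  hom <- make_two_layer_cast(interface = 500, max_depth = 120)
  m2 <- mixed_layer_depth(hom, dsigma = 0.03)
  expect_true(m2$bottom_limited)
  expect_equal(m2$mld, max(hom$depth_m))

  # cast shallower than the reference depth is invalid
  sh <- make_two_layer_cast(max_depth = 6)
  expect_false(mixed_layer_depth(sh)$valid)
})

test_that("mixed-layer depth crossing is exact on a linear density ramp", {
  # construct salinity so that sigma-theta rises linearly by exactly dsigma
  # between the 6 m reference and 100 m
  z <- seq(6, 120, by = 2)
  Tconst <- 2
  s_lo <- 34.3
  sig_lo <- potential_density(s_lo, Tconst, 0)
  dsig_ds <- (potential_density(s_lo + 0.01, Tconst, 0) - sig_lo) / 0.01
  dsigma <- 0.03
  target_sig <- sig_lo + dsigma * pmin((z - 6) / (100 - 6), 1.3)
  sal <- s_lo + (target_sig - sig_lo) / dsig_ds
  cast <- data.frame(cast_id = "r", id = "A",
                     time = as.POSIXct("2010-10-01", tz = "UTC"),
                     lon = 11, lat = 78.5, depth_m = z, temp_c = Tconst,
                     sal_psu = sal)
  m <- mixed_layer_depth(cast, dsigma = dsigma)
  # pressure correction in sigma-theta is tiny but nonzero; allow the level
  # spacing as tolerance
  expect_lt(abs(m$mld - 100), 2)
})

test_that("MLD recovery on noisy synthetic two-layer casts", {
  set.seed(21)
  hits <- 0; n <- 200
  for (k in seq_len(n)) {
    h <- runif(1, 20, 90)
    cast <- make_two_layer_cast(interface = h, max_depth = 130, dz = 5)
    cast$temp_c <- cast$temp_c + rnorm(nrow(cast), 0, 0.02)
    cast$sal_psu <- cast$sal_psu + rnorm(nrow(cast), 0, 0.005)
    m <- mixed_layer_depth(cast, dsigma = 0.03)
    if (m$valid && !m$bottom_limited && abs(m$mld - h) <= 5) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("3-D Gaussian interpolation matches a direct double-loop oracle", {
  set.seed(31)
  t0 <- as.POSIXct("2010-10-01", tz = "UTC")
  casts <- do.call(rbind, lapply(1:50, function(k) {
    make_two_layer_cast(interface = runif(1, 20, 80),
                        max_depth = runif(1, 40, 150),
                        cast_id = sprintf("c%02d", k),
                        time = t0 + runif(1, 0, 20) * 86400,
                        lon = runif(1, 10, 12), lat = runif(1, 78, 79))
  }))
  casts$temp_c <- casts$temp_c + rnorm(nrow(casts), 0, 0.3)
  targets <- data.frame(time = t0 + runif(20, 0, 20) * 86400,
                        lon = runif(20, 10, 12), lat = runif(20, 78, 79),
                        depth_m = runif(20, 6, 140))
  got <- interpolate_ts(targets, casts)
  for (i in seq_len(nrow(targets))) {
    w <- tt <- ss <- 0
    for (j in seq_len(nrow(casts))) {
      dt <- as.numeric(difftime(casts$time[j], targets$time[i],
                                units = "days")) / 3
      dd <- oracle_dist_km(casts$lon[j], casts$lat[j],
                           targets$lon[i], targets$lat[i]) / 25
      dz <- (casts$depth_m[j] - targets$depth_m[i]) / 5
      wj <- exp(-0.5 * (dt^2 + dd^2 + dz^2))
      w <- w + wj; tt <- tt + wj * casts$temp_c[j]; ss <- ss + wj * casts$sal_psu[j]
    }
    expect_equal(got$temp[i], tt / w, tolerance = 1e-9)
    expect_equal(got$sal[i], ss / w, tolerance = 1e-9)
    expect_equal(got$eff_weight[i], w, tolerance = 1e-7)
  }
})

test_that("interpolation is exact at an isolated cast point and convex", {
  t0 <- as.POSIXct("2010-10-01", tz = "UTC")
  one <- data.frame(cast_id = "c1", id = "A", time = t0, lon = 11, lat = 78.5,
                    depth_m = 50, temp_c = 2.5, sal_psu = 34.6)
  tg <- data.frame(time = t0, lon = 11, lat = 78.5, depth_m = 50)
  r <- interpolate_ts(tg, one)
  expect_equal(r$temp, 2.5, tolerance = 1e-12)
  expect_equal(r$sal, 34.6, tolerance = 1e-12)

  # two equidistant levels with T 2 and 4 -> exactly 3
  two <- rbind(one, one)
  two$cast_id <- c("c1", "c2")
  two$depth_m <- c(40, 60); two$temp_c <- c(2, 4)
  r2 <- interpolate_ts(tg, two)
  expect_equal(r2$temp, 3, tolerance = 1e-12)
  expect_equal(r2$n_casts, 2)

  # convex combination: result inside the contributing range
  set.seed(4)
  many <- do.call(rbind, lapply(1:10, function(k) {
    o <- one; o$cast_id <- paste0("k", k)
    o$time <- t0 + runif(1, -5, 5) * 86400
    o$depth_m <- runif(1, 10, 100); o$temp_c <- runif(1, -1, 5); o
  }))
  r3 <- interpolate_ts(tg, many)
  expect_gte(r3$temp, min(many$temp_c)); expect_lte(r3$temp, max(many$temp_c))

  # no support below the weight floor
  far <- one; far$time <- t0 + 400 * 86400
  r4 <- interpolate_ts(tg, far)
  expect_false(r4$ok); expect_true(is.na(r4$temp))
})

test_that("region assignment and series behave with the half-open convention", {
  boxes <- region_boxes()
  expect_equal(assign_region(10, 78.3, boxes), "B")  # south edge inclusive
  expect_equal(assign_region(10, 78.29999, boxes), "C")
  expect_equal(assign_region(9, 78.5, boxes), "B")   # west edge inclusive
  expect_true(is.na(assign_region(13.5, 78.5, boxes)))

  # constant-T casts give a flat series equal to that T, smoothing preserves
  # the mean of a constant series exactly
  t0 <- as.POSIXct("2010-10-01", tz = "UTC")
  casts <- do.call(rbind, lapply(1:12, function(k) {
    cc <- make_two_layer_cast(interface = 500, max_depth = 120,
                              cast_id = sprintf("c%02d", k),
                              time = t0 + k * 86400 / 2,
                              lon = 10.5, lat = 78.5)
    cc$temp_c <- 1.7
    cc
  }))
  rs <- region_series(casts, var = "temp", depth_levels = c(6, 50, 100))
  expect_true(all(abs(rs$value - 1.7) < 1e-9))
  expect_true(all(rs$box == "B"))

  # a single warm cast among cold ones: smoothed bump centred on its date,
  # kernel weights checked by hand
  casts2 <- casts
  casts2$temp_c <- 1
  warm_day <- as.POSIXct("2010-10-04", tz = "UTC")
  casts2$temp_c[abs(as.numeric(difftime(casts2$time, warm_day,
                                        units = "days"))) < 0.26] <- 3
  rs2 <- region_series(casts2, var = "temp", depth_levels = 50)
  peak <- rs2$date[which.max(rs2$value)]
  expect_lte(abs(as.numeric(peak - as.Date("2010-10-04"))), 1)
  # hand-computed kernel weights at the warm cast's day (one value per cast)
  meta <- casts2[!duplicated(casts2$cast_id), ]
  d_all <- as.numeric(difftime(meta$time, as.POSIXct("2010-10-04", tz = "UTC"),
                               units = "days"))
  w <- exp(-0.5 * d_all^2); w[abs(d_all) > 2] <- 0
  expect_equal(rs2$value[rs2$date == as.Date("2010-10-04")],
               sum(w * meta$temp_c) / sum(w), tolerance = 1e-9)
})

test_that("water-mass labels follow the descriptive thresholds", {
  expect_equal(as.character(water_mass_label(4.0, 35.0)), "AW")
  expect_equal(as.character(water_mass_label(-1.5, 34.3)), "ArW")
  expect_equal(as.character(water_mass_label(2.0, 34.8)), "mixed")
  expect_equal(as.character(water_mass_label(3.5, 34.5)), "mixed")
})
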