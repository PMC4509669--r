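# Shared fixtures built in code. The small simulated deployment is generated
# once per test run and reused across files; the full-scale deployment used by
# the acceptance suite is built lazily on first request.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_animals = 3, end = "2010-11-15", seed = 101)
    .fixture_env$small <- simulate_deployment(cfg)
  }
  .fixture_env$small
}

full_sim <- function(seed = 20260922) {
  key <- paste0("full_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_deployment(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}

# independent haversine oracle (different formula arrangement than the
# implementation: spherical law of cosines on unit vectors)
oracle_dist_km <- function(lon1, lat1, lon2, lat2) {
  d2r <- pi / 180
  v1 <- cbind(cos(lat1 * d2r) * cos(lon1 * d2r),
              cos(lat1 * d2r) * sin(lon1 * d2r), sin(lat1 * d2r))
  v2 <- cbind(cos(lat2 * d2r) * cos(lon2 * d2r),
              cos(lat2 * d2r) * sin(lon2 * d2r), sin(lat2 * d2r))
  cr <- sqrt(rowSums((v1 * rep(1, 1))^2)) # guard: unit by construction
  dotp <- pmin(pmax(rowSums(v1 * v2), -1), 1)
  6371 * acos(dotp)
}

# build an Argos data frame from raw vectors
make_argos <- function(lon, lat, t, id = "A", lc = "3") {
  data.frame(id = id, time = t, lon = lon, lat = lat,
             lc = rep_len(lc, length(lon)))
}

# a simple broken-stick dive table row
make_dive <- function(id = "A", start = as.POSIXct("2010-09-01 12:00:00", tz = "UTC"),
                      duration = 300, max_depth = 100,
                      t_off = c(75, 120, 180, 225),
                      depth = c(95, 100, 98, 96)) {
  data.frame(id = id, start = start, duration_s = duration,
             max_depth_m = max_depth,
             t1 = t_off[1], t2 = t_off[2], t3 = t_off[3], t4 = t_off[4],
             d1 = depth[1], d2 = depth[2], d3 = depth[3], d4 = depth[4])
}

# synthetic two-layer cast sampled every `dz` metres
make_two_layer_cast <- function(interface = 40, max_depth = 120, dz = 5,
                                t_top = 4, t_bot = 1, s_top = 34.3,
                                s_bot = 34.9, width = 0.5, cast_id = "c1",
                                id = "A",
                                time = as.POSIXct("2010-10-01", tz = "UTC"),
                                lon = 11, lat = 78.5) {
  z <- seq(6, max_depth, by = dz)
  l <- plogis((z - interface) / width)
  data.frame(cast_id = cast_id, id = id, time = time, lon = lon, lat = lat,
             depth_m = z, temp_c = t_top + (t_bot - t_top) * l,
             sal_psu = s_top + (s_bot - s_top) * l)
}
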