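# Synthetic telemetry generator. Produces Argos locations, transmitted dive
# records, 6-h dive summaries, CTD casts, a wind series and bathymetry/ice
# grids with the statistical structure the analysis assumes, plus the ground
# truth every recovery check compares against: true tracks, true mixed-layer
# depth, true dive classes, the divergence onset date and the wind-intrusion
# lag.
#
# Design notes (see the methods vignette for rationale):
# * Population heterogeneity is stratified: per-animal depth multipliers are
#   lognormal quantiles, so the realised between-animal spread is stable
#   across seeds while per-animal noise streams stay independent.
# * The shelf is terraced (flat benches at 35/75/120/185 m joined by short
#   ramps) so that bathymetry at a dive location is insensitive to residual
#   location error away from the narrow ramps.
# * Deep-layer warm/saline anomalies are driven by the mean northerly wind
#   over the preceding `wind_lag` days, giving the lag an unambiguous
#   generative definition.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: ten animals
#' tracked from September through early May, autumn dive depths averaging
#' 41 m (SD 24) across a heterogeneous population, a mixed layer deepening
#' from ~38 m to ~105 m in mid February, a divergence onset in late December
#' after which seals dive ~45 m below the mixed layer (winter peak depths
#' ~150 m), a night-time diel effect in September-November only, and
#' episodic Atlantic Water intrusions (T 3-4.8 degC, S >= 34.9, below
#' 100-135 m) lagged `wind_lag` days behind northerly wind events.
#'
#' @param n_animals number of animals.
#' @param start,end deployment dates (Date or string).
#' @param seed integer; fully determines every output.
#' @param autumn_depth_mean,autumn_depth_sd target marginal mean/SD (m) of
#'   transmitted dive depths in September-November.
#' @param mld_autumn,mld_peak,mld_end,mld_peak_day mixed-layer-depth seasonal
#'   curve (m; day index of the winter maximum).
#' @param mld_box_offset named per-region offsets (m) added to the curve.
#' @param divergence_onset date after which dives exceed the mixed layer.
#' @param divergence_offset depth below the mixed layer after onset, m.
#' @param diel_depth_mult,diel_n_mult night multipliers for dive depth and
#'   dive counts; active in `diel_months` only.
#' @param diel_months months (integers) with a diel cycle.
#' @param sdlog_animal,sdlog_dive lognormal spread across animals / dives.
#' @param dur_intercept,dur_slope,dur_sd dive duration model (s, s/m, s).
#' @param n_dives_autumn,n_dives_winter daily dive counts (all dives).
#' @param tx_per_day transmitted (profiled) dives per day.
#' @param cast_rate CTD casts per animal per day.
#' @param argos_per_day Argos locations per day.
#' @param argos_outlier_frac fraction of gross position outliers.
#' @param argos_err_sd_km per-class isotropic error SDs (km).
#' @param lc_probs sampling probabilities of location classes 3,2,1,0,A,B.
#' @param wind_lag days between northerly wind forcing and the deep thermal
#'   response (the quantity the lag analysis recovers).
#' @param wind_event_rate northerly wind events per day (mid Oct-mid Apr).
#' @param wind_thresh windowed northerly speed (m/s) above which the deep
#'   layer warms.
#' @param aw_t_gain,aw_s_gain response of deep temperature (degC) and
#'   salinity (PSU) per m/s of windowed northerly wind above threshold.
#' @param terraces,terrace_edges_km,terrace_centres_km shelf geometry.
#' @param ou_tau_h,ou_sd_km movement model: OU relaxation time and
#'   stationary SD.
#' @param haulout_rate,haulout_min_h,haulout_max_h haul-out frequency (per
#'   day) and duration range (h).
#' @param coast_lon,lat_range,lon_range domain geometry (degrees).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_animals = 10,
                       start = "2010-09-01", end = "2011-05-09",
                       seed = 1,
                       autumn_depth_mean = 41, autumn_depth_sd = 24,
                       mld_autumn = 38, mld_peak = 108, mld_end = 70,
                       mld_peak_day = 165,
                       mld_box_offset = c(A = -5, B = 0, C = 5),
                       divergence_onset = "2010-12-27",
                       divergence_offset = 80,
                       diel_depth_mult = 1.15, diel_n_mult = 1.4,
                       diel_months = 9:11,
                       sdlog_animal = 0.45, sdlog_dive = 0.3,
                       dur_intercept = 60, dur_slope = 2.8, dur_sd = 35,
                       n_dives_autumn = 270, n_dives_winter = 120,
                       tx_per_day = 16, cast_rate = 2,
                       argos_per_day = 20, argos_outlier_frac = 0.02,
                       argos_err_sd_km = argos_error_sd_km,
                       lc_probs = c(0.15, 0.2, 0.25, 0.15, 0.1, 0.15),
                       wind_lag = 7, wind_event_rate = 1 / 12,
                       wind_thresh = 7.2, aw_t_gain = 1.35, aw_s_gain = 0.14,
                       terraces = c(35, 75, 120, 185),
                       terrace_edges_km = c(0, 1, 12, 14, 24, 26, 38, 40, 62, 70),
                       terrace_centres_km = c(6.5, 19, 32, 51),
                       ou_tau_h = 12, ou_sd_km = 2.5,
                       haulout_rate = 0.5, haulout_min_h = 2,
                       haulout_max_h = 8,
                       coast_lon = 12.6,
                       lat_range = c(77.8, 79.2),
                       lon_range = c(9.5, 13.0)) {
  cfg <- as.list(environment())
  cfg$start <- as.Date(start); cfg$end <- as.Date(end)
  cfg$divergence_onset <- as.Date(divergence_onset)
  if (cfg$end <= cfg$start) stop("sim_config: zero- or negative-duration simulation")
  stopifnot(cast_rate >= 0, tx_per_day >= 0, wind_event_rate >= 0,
            all(diff(terraces) > 0), n_animals >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# piecewise-linear terraced bathymetry, depth (m) vs offshore distance (km)
.bathy_profile <- function(cfg) {
  e <- cfg$terrace_edges_km; b <- cfg$terraces
  list(d = c(e[1], e[2], e[3], e[4], e[5], e[6], e[7], e[8], e[9], e[10], 400),
       z = c(5, b[1], b[1], b[2], b[2], b[3], b[3], b[4], b[4], 305, 305))
}

.bathy_at <- function(cfg, d_km) {
  p <- .bathy_profile(cfg)
  approx(p$d, p$z, xout = pmax(d_km, 0), rule = 2)$y
}

.km_per_deg_lat <- pi / 180 * 6371
.km_per_deg_lon <- function(lat) pi / 180 * 6371 * cos(lat * pi / 180)

# offshore distance (km west of the coast) of a longitude at given latitude
.offshore_km <- function(cfg, lon, lat) (cfg$coast_lon - lon) * .km_per_deg_lon(lat)
.lon_at_offshore <- function(cfg, d_km, lat) cfg$coast_lon - d_km / .km_per_deg_lon(lat)

#' True mixed-layer depth curve
#'
#' Flat through early autumn, cosine deepening to the winter maximum, then
#' cosine shoaling toward spring.
#'
#' @param cfg `sim_config`.
#' @param day day index from the simulation start (0-based; vectorised).
#' @param box optional region name for the per-box offset.
#' @return MLD in metres.
#' @export
mld_true <- function(cfg, day, box = NULL) {
  ndays <- as.numeric(cfg$end - cfg$start)
  ramp_start <- 60
  out <- ifelse(day <= ramp_start, cfg$mld_autumn,
         ifelse(day <= cfg$mld_peak_day,
                cfg$mld_autumn + (cfg$mld_peak - cfg$mld_autumn) *
                  (1 - cos(pi * (day - ramp_start) /
                             (cfg$mld_peak_day - ramp_start))) / 2,
                cfg$mld_peak + (cfg$mld_end - cfg$mld_peak) *
                  (1 - cos(pi * pmin(day - cfg$mld_peak_day,
                                     ndays - cfg$mld_peak_day) /
                             max(ndays - cfg$mld_peak_day, 1))) / 2))
  if (!is.null(box)) out <- out + unname(cfg$mld_box_offset[box])
  out
}

# seasonal surface temperature (deg C): ~5 in Sep, minimum ~ -1.8 in Feb/Mar
.surface_temp <- function(day) 1.6 + 3.4 * cos(2 * pi * (day - 350) / 365)

# per-day demand base: MLD before the divergence onset, MLD + offset after
.depth_base <- function(cfg, day) {
  onset <- as.numeric(cfg$divergence_onset - cfg$start)
  mld_true(cfg, day) + ifelse(day >= onset, cfg$divergence_offset, 0)
}

.month_of_day <- function(cfg, day) {
  as.integer(format(cfg$start + floor(day), "%m"))
}

# expected night-share-weighted diel depth multiplier in diel months
.diel_e <- function(cfg) {
  ns <- cfg$diel_n_mult * 12 / (cfg$diel_n_mult * 12 + 12)
  ns * cfg$diel_depth_mult + (1 - ns)
}

#' Generate a synthetic deployment
#'
#' Simulates every data stream the pipeline ingests, from one integer seed.
#' Identical seeds give identical outputs; each animal draws from its own
#' stream (derived from the seed and the animal index) so per-animal
#' re-simulation is stable.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sd_sim`: `argos`, `dives`, `summaries`, `casts`,
#'   `wind`, `haulouts`, `bathy` and `ice` rasters, and `truth` (true tracks,
#'   true MLD per region, true dive classes, expected daily mean dive depth,
#'   divergence onset, wind lag, daily windowed northerly wind, intrusion
#'   events, per-animal parameters).
#' @export
simulate_deployment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ndays <- as.numeric(cfg$end - cfg$start)
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  onset_day <- as.numeric(cfg$divergence_onset - cfg$start)

  ## ---- shared streams: wind, intrusion schedule, animal population ----
  set.seed(cfg$seed %% 2147483647L)
  wind <- .sim_wind(cfg, t0, ndays)
  dates <- cfg$start + 0:(ndays - 1)
  wL <- wind_covariates(wind, dates, cfg$wind_lag, "N")$value
  strength <- pmax(0, wL - cfg$wind_thresh)
  ev <- .sim_events_from_strength(strength, dates)
  h2_daily <- rep(NA_real_, ndays)
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      idx <- ev$start_idx[k]:ev$end_idx[k]
      h2_daily[idx] <- ev$h2[k]
    }
  }
  # per-animal depth multipliers: stratified lognormal quantiles
  i_all <- seq_len(cfg$n_animals)
  m_a <- qlnorm((i_all - 0.5) / cfg$n_animals, -cfg$sdlog_animal^2 / 2,
                cfg$sdlog_animal)
  home_lat <- runif(cfg$n_animals, 78.0, 78.85)
  sex <- rep_len(c("F", "M"), cfg$n_animals)
  age <- sample(c("adult", "juvenile"), cfg$n_animals, replace = TRUE)
  ids <- sprintf("S%02d", i_all)

  # normalisation so the autumn marginal mean equals the configured value
  aut_days <- which(.month_of_day(cfg, 0:(ndays - 1)) %in% 9:11) - 1
  scale <- cfg$autumn_depth_mean /
    (mean(m_a) * .diel_e(cfg) * mean(mld_true(cfg, aut_days)))
  f_a <- scale * m_a

  truth_field <- .make_truth_field(cfg, strength, h2_daily)

  ## ---- per-animal simulation ----
  argos <- dives <- summaries <- casts <- haulouts <- tracks <- list()
  class_truth <- list()
  for (i in i_all) {
    set.seed((cfg$seed + 77777L * i) %% 2147483647L)
    sim_i <- .sim_animal(cfg, ids[i], f_a[i], home_lat[i], sex[i], age[i],
                         t0, ndays, onset_day, truth_field)
    argos[[i]] <- sim_i$argos; dives[[i]] <- sim_i$dives
    summaries[[i]] <- sim_i$summaries; casts[[i]] <- sim_i$casts
    haulouts[[i]] <- sim_i$haulouts; tracks[[i]] <- sim_i$track
    class_truth[[i]] <- sim_i$class_truth
  }

  dives_all <- do.call(rbind, dives)
  truth_daily <- .expected_daily_depth(cfg, f_a, ndays)
  mld_boxes <- do.call(rbind, lapply(names(cfg$mld_box_offset), function(b) {
    data.frame(date = dates, box = b,
               mld = mld_true(cfg, 0:(ndays - 1), b))
  }))

  structure(list(
    cfg = cfg,
    argos = as_argos(do.call(rbind, argos)),
    dives = dives_all,
    summaries = do.call(rbind, summaries),
    casts = do.call(rbind, casts),
    wind = wind,
    haulouts = do.call(rbind, haulouts),
    bathy = .make_bathy_raster(cfg),
    ice = .make_ice_raster(cfg),
    animals = data.frame(id = ids, m = m_a, f = f_a, home_lat = home_lat,
                         sex = sex, age = age),
    truth = list(tracks = do.call(rbind, tracks),
                 mld = mld_boxes,
                 dive_class = do.call(rbind, class_truth),
                 daily_depth = truth_daily,
                 divergence_onset = cfg$divergence_onset,
                 wind_lag = cfg$wind_lag,
                 wind_daily = data.frame(date = dates, northerly = wL,
                                         strength = strength),
                 events = ev)
  ), class = "sd_sim")
}

#' @export
print.sd_sim <- function(x, ...) {
  cat(sprintf("<sd_sim> %d animals, %s..%s: %d argos, %d dives, %d summaries, %d cast levels\n",
              x$cfg$n_animals, x$cfg$start, x$cfg$end, nrow(x$argos),
              nrow(x$dives), nrow(x$summaries), nrow(x$casts)))
  invisible(x)
}

.sim_wind <- function(cfg, t0, ndays) {
  times <- t0 + seq(0, ndays * 86400 - 1, by = 21600)
  n <- length(times)
  u <- rnorm(n, 0, 3); v <- rnorm(n, 0, 3)
  # northerly events in the mid-Oct..mid-Apr window
  day <- as.numeric(difftime(times, t0, units = "days"))
  window <- day >= 45 & day <= 225
  ev_start <- c()
  d <- 45
  while (cfg$wind_event_rate > 0 && d < 225) {
    gap <- rexp(1, cfg$wind_event_rate)
    d <- d + gap
    if (d < 225) ev_start <- c(ev_start, d)
  }
  for (s in ev_start) {
    dur <- runif(1, 2, 5)
    idx <- which(day >= s & day < s + dur)
    v[idx] <- -(12 + runif(length(idx), 0, 6))
    u[idx] <- runif(length(idx), -3, 3)
  }
  data.frame(time = times, u = u, v = v, gap_after = FALSE)
}

.sim_events_from_strength <- function(strength, dates) {
  on <- strength > 0
  if (!any(on)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      start = as.Date(character(0)), h2 = numeric(0)))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             start = dates[starts[keep]],
             h2 = runif(length(keep), 100, 135))
}

# truth temperature/salinity field: two-layer with a deep intrusion layer
# whose warm/saline anomaly scales continuously with the windowed northerly
# wind above threshold
.make_truth_field <- function(cfg, strength, h2_daily) {
  function(z, day, box = "B") {
    di <- pmin(pmax(floor(day) + 1, 1), length(strength))
    h <- mld_true(cfg, day, box)
    ts <- .surface_temp(day)
    t_aw <- pmin(1.0 + cfg$aw_t_gain * strength[di], 4.8)
    s_aw <- pmin(34.7 + cfg$aw_s_gain * strength[di], 35.08)
    h2 <- ifelse(is.na(h2_daily[di]), 115, h2_daily[di])
    h2 <- pmax(h2, h + 8)
    l1 <- stats::plogis((z - h) / 0.5)
    l2 <- stats::plogis((z - h2) / 4)
    Tv <- ts + (1.0 - ts) * l1 + (t_aw - 1.0) * l2
    Sv <- 34.3 + (34.7 - 34.3) * l1 + (s_aw - 34.7) * l2
    list(T = Tv, S = Sv)
  }
}

# one animal: OU track over a daily-updated terrace centre, haul-outs, Argos
# observations, transmitted dives, 6-h summaries and CTD casts
.sim_animal <- function(cfg, id, f_i, home_lat, sex, age, t0, ndays,
                        onset_day, truth_field) {
  step_h <- 1 / 6
  nstep <- ndays * 144
  day_of <- floor((0:(nstep - 1)) * step_h / 24)

  # daily demand and terrace schedule
  days <- 0:(ndays - 1)
  demand_day <- f_i * .depth_base(cfg, days)
  b_target <- pmin(pmax(2.2 * demand_day, cfg$terraces[1]),
                   cfg$terraces[length(cfg$terraces)])
  ter_idx <- vapply(b_target, function(b) which.min(abs(cfg$terraces - b)),
                    integer(1))
  centre_d <- cfg$terrace_centres_km[ter_idx]

  # haul-out events
  ho_start <- c(); d <- 0
  while (cfg$haulout_rate > 0 && d < ndays) {
    d <- d + rexp(1, cfg$haulout_rate)
    if (d < ndays) ho_start <- c(ho_start, d)
  }
  ho_dur_h <- runif(length(ho_start), cfg$haulout_min_h, cfg$haulout_max_h)
  ho <- data.frame(id = id,
                   start = t0 + ho_start * 86400,
                   end = t0 + ho_start * 86400 + ho_dur_h * 3600)

  # OU track in (offshore km, alongshore km)
  a_decay <- exp(-step_h / cfg$ou_tau_h)
  sd_step <- cfg$ou_sd_km * sqrt(1 - a_decay^2)
  dpos <- numeric(nstep); apos <- numeric(nstep)
  dpos[1] <- centre_d[1]; apos[1] <- 0
  track_time <- t0 + (0:(nstep - 1)) * 600
  in_ho <- rep(FALSE, nstep)
  for (k in seq_len(nrow(ho))) {
    in_ho <- in_ho | (track_time >= ho$start[k] & track_time < ho$end[k])
  }
  eps_d <- rnorm(nstep, 0, sd_step); eps_a <- rnorm(nstep, 0, sd_step)
  for (s in 2:nstep) {
    if (in_ho[s]) {
      dpos[s] <- dpos[s - 1]; apos[s] <- apos[s - 1]
    } else {
      cd <- centre_d[day_of[s] + 1]
      dpos[s] <- cd + a_decay * (dpos[s - 1] - cd) + eps_d[s]
      apos[s] <- a_decay * apos[s - 1] + eps_a[s]
      dpos[s] <- max(dpos[s], 0.3)
    }
  }
  lat <- home_lat + apos / .km_per_deg_lat
  lon <- .lon_at_offshore(cfg, dpos, home_lat)
  track <- data.frame(id = id, time = track_time, lon = lon, lat = lat)

  pos_at <- function(tt) {
    h <- as.numeric(difftime(tt, t0, units = "secs")) / 600
    h <- pmin(pmax(h, 0), nstep - 1)
    i0 <- floor(h); w <- h - i0
    list(lon = lon[i0 + 1] * (1 - w) + lon[pmin(i0 + 2, nstep)] * w,
         lat = lat[i0 + 1] * (1 - w) + lat[pmin(i0 + 2, nstep)] * w,
         d = dpos[i0 + 1] * (1 - w) + dpos[pmin(i0 + 2, nstep)] * w)
  }

  ## Argos observations
  n_obs <- rpois(1, cfg$argos_per_day * ndays)
  ot <- t0 + sort(runif(n_obs, 0, ndays * 86400))
  p <- pos_at(ot)
  lc <- sample(ARGOS_CLASSES, n_obs, replace = TRUE, prob = cfg$lc_probs)
  sdk <- unname(cfg$argos_err_sd_km[lc])
  ex <- rnorm(n_obs, 0, sdk); ey <- rnorm(n_obs, 0, sdk)
  out_i <- runif(n_obs) < cfg$argos_outlier_frac
  if (any(out_i)) {
    r <- runif(sum(out_i), 15, 80); th <- runif(sum(out_i), 0, 2 * pi)
    ex[out_i] <- ex[out_i] + r * cos(th); ey[out_i] <- ey[out_i] + r * sin(th)
  }
  argos <- data.frame(
    id = id, time = ot,
    lon = p$lon + ex / .km_per_deg_lon(p$lat),
    lat = p$lat + ey / .km_per_deg_lat,
    lc = lc)

  ## transmitted dives with broken-stick profiles
  diel_on_day <- .month_of_day(cfg, days) %in% cfg$diel_months
  dive_rows <- vector("list", ndays)
  class_rows <- vector("list", ndays)
  for (dd in days) {
    n_tx <- rpois(1, cfg$tx_per_day)
    if (n_tx == 0) next
    hrs <- .sample_hours(n_tx, diel_on_day[dd + 1], cfg$diel_n_mult)
    st <- t0 + dd * 86400 + hrs * 3600
    pp <- pos_at(st)
    b_loc <- .bathy_at(cfg, pp$d)
    night <- hrs < 6 | hrs >= 18
    dielm <- ifelse(diel_on_day[dd + 1] & night, cfg$diel_depth_mult, 1)
    m_d <- rlnorm(n_tx, -cfg$sdlog_dive^2 / 2, cfg$sdlog_dive)
    demand <- f_i * .depth_base(cfg, dd + hrs / 24) * m_d * dielm
    capped <- demand > 0.9 * b_loc
    depth <- ifelse(capped, b_loc * runif(n_tx, 0.985, 1), demand)
    depth <- pmax(depth, 6.5)
    depth <- round(depth, 1)
    dur <- pmax(cfg$dur_intercept + cfg$dur_slope * depth +
                  rnorm(n_tx, 0, cfg$dur_sd), 30)
    prof <- .make_profiles(depth, dur, dd, onset_day)
    dive_rows[[dd + 1]] <- data.frame(
      id = id, start = st, duration_s = round(dur, 1),
      max_depth_m = depth,
      t1 = prof$t[, 1], t2 = prof$t[, 2], t3 = prof$t[, 3], t4 = prof$t[, 4],
      d1 = prof$d[, 1], d2 = prof$d[, 2], d3 = prof$d[, 3], d4 = prof$d[, 4])
    ratio <- depth / b_loc
    cls <- ifelse(b_loc < 50, "coastal",
                  ifelse(ratio > 0.95, "benthic", "pelagic"))
    class_rows[[dd + 1]] <- data.frame(
      id = id, start = st, lon = pp$lon, lat = pp$lat, bathy = b_loc,
      class = cls)
  }
  dives <- do.call(rbind, dive_rows)

  ## 6-h summaries
  sum_rows <- vector("list", ndays * 4)
  n_day_curve <- cfg$n_dives_autumn -
    (cfg$n_dives_autumn - cfg$n_dives_winter) *
    pmin(pmax((days - 60) / 90, 0), 1)
  for (dd in days) {
    diel <- diel_on_day[dd + 1]
    w <- if (diel) c(cfg$diel_n_mult, 1, 1, cfg$diel_n_mult) else rep(1, 4)
    share <- w / sum(w)
    b_day <- cfg$terraces[ter_idx[dd + 1]]
    for (pp in 1:4) {
      p_start <- t0 + dd * 86400 + (pp - 1) * 21600
      nd <- rpois(1, n_day_curve[dd + 1] * share[pp])
      dielm <- if (diel && pp %in% c(1, 4)) cfg$diel_depth_mult else 1
      dem <- f_i * .depth_base(cfg, dd) * dielm *
        rlnorm(max(nd, 1), -cfg$sdlog_dive^2 / 2, cfg$sdlog_dive)
      dep <- pmax(ifelse(dem > 0.9 * b_day, b_day * 0.9925, dem), 6.5)
      avg_depth <- mean(dep)
      avg_dur <- max(cfg$dur_intercept + cfg$dur_slope * avg_depth +
                       rnorm(1, 0, cfg$dur_sd / sqrt(max(nd, 1))), 30)
      ho_overlap <- .interval_overlap(p_start, p_start + 21600, ho)
      t_dive <- min(nd * avg_dur, 21600 - ho_overlap)
      sum_rows[[dd * 4 + pp]] <- data.frame(
        id = id, period_start = p_start, avg_depth_m = round(avg_depth, 1),
        avg_duration_s = round(avg_dur, 1), n_dives = nd,
        time_diving_s = round(t_dive),
        surface_time_s = round(max(21600 - ho_overlap - t_dive, 0)))
    }
  }
  summaries <- do.call(rbind, sum_rows)

  ## CTD casts: upcasts of a subset of (simulated) dives
  cast_rows <- list()
  cast_n <- 0
  for (dd in days) {
    nc <- rpois(1, cfg$cast_rate)
    if (nc == 0) next
    hrs <- runif(nc, 0, 24)
    st <- t0 + dd * 86400 + hrs * 3600
    pp <- pos_at(st)
    b_loc <- .bathy_at(cfg, pp$d)
    m_d <- rlnorm(nc, -cfg$sdlog_dive^2 / 2, cfg$sdlog_dive)
    demand <- f_i * .depth_base(cfg, dd + hrs / 24) * m_d
    cdep <- pmin(demand, b_loc * 0.95)
    for (j in seq_len(nc)) {
      if (cdep[j] < 12) next
      z <- seq(6, cdep[j], by = 5)
      ts <- truth_field(z, dd + hrs[j] / 24,
                        .box_of_lat(cfg, pp$lat[j]))
      cast_n <- cast_n + 1
      cast_rows[[length(cast_rows) + 1]] <- data.frame(
        cast_id = sprintf("%s_c%04d", id, cast_n), id = id,
        time = st[j], lon = pp$lon[j], lat = pp$lat[j],
        depth_m = z,
        temp_c = round(ts$T + rnorm(length(z), 0, 0.02), 3),
        sal_psu = round(ts$S + rnorm(length(z), 0, 0.005), 4))
    }
  }
  casts <- if (length(cast_rows)) do.call(rbind, cast_rows) else NULL

  list(argos = argos, dives = dives, summaries = summaries, casts = casts,
       haulouts = ho, track = track,
       class_truth = do.call(rbind, class_rows))
}

.box_of_lat <- function(cfg, lat) {
  ifelse(lat >= 78.9, "A", ifelse(lat >= 78.3, "B", "C"))
}

.sample_hours <- function(n, diel, n_mult) {
  w <- rep(1, 24)
  if (diel) w[c(1:6, 19:24)] <- n_mult
  hb <- sample(0:23, n, replace = TRUE, prob = w) + runif(n)
  sort(hb)
}

.interval_overlap <- function(a0, a1, intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(0)
  tot <- 0
  for (k in seq_len(nrow(intervals))) {
    o <- min(as.numeric(a1), as.numeric(intervals$end[k])) -
      max(as.numeric(a0), as.numeric(intervals$start[k]))
    if (o > 0) tot <- tot + o
  }
  tot
}

# broken-stick profiles: square-ish dives with a seasonally varying bottom
# fraction (effort lower in winter); V-shaped when transit consumes the dive
.make_profiles <- function(depth, dur, day, onset_day) {
  n <- length(depth)
  t_desc <- depth / 1.4; t_asc <- depth / 1.6
  span <- dur - t_desc - t_asc
  eff_mean <- if (day >= onset_day) 0.6 else 0.75
  eff <- rbeta(n, eff_mean * 12, (1 - eff_mean) * 12)
  tmat <- matrix(0, n, 4); dmat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    if (span[i] > 8) {
      b0 <- t_desc[i] + (1 - eff[i]) / 2 * span[i]
      b1 <- b0 + eff[i] * span[i]
      tt <- c(b0, b0 + (b1 - b0) / 3, b0 + 2 * (b1 - b0) / 3, b1)
      dd <- depth[i] * c(runif(1, 0.93, 0.99), 1,
                         runif(1, 0.95, 1), runif(1, 0.93, 0.99))
    } else {
      tt <- dur[i] * c(0.35, 0.48, 0.52, 0.65)
      dd <- depth[i] * c(0.8, 1, 0.97, 0.75)
    }
    tt <- pmin(pmax(tt, 1e-3), dur[i] - 1e-3)
    tt <- cumsum(pmax(diff(c(0, tt)), 1e-4))
    tt <- pmin(tt, dur[i] - 1e-4 * (4:1))
    tmat[i, ] <- round(tt, 2); dmat[i, ] <- round(pmin(dd, depth[i]), 2)
  }
  list(t = tmat, d = dmat)
}

.make_bathy_raster <- function(cfg) {
  dx <- 0.0225; dy <- 0.0045  # ~0.5 km x 0.5 km at 78.5 N
  lons <- seq(cfg$lon_range[1] + dx / 2, cfg$lon_range[2], by = dx)
  lats <- seq(cfg$lat_range[1] + dy / 2, cfg$lat_range[2], by = dy)
  m <- matrix(NA_real_, length(lats), length(lons))
  for (r in seq_along(lats)) {
    d <- .offshore_km(cfg, lons, lats[r])
    z <- .bathy_at(cfg, d)
    z[d < 0] <- NA  # land east of the coast
    m[r, ] <- z
  }
  raster_grid(m, cfg$lon_range[1], cfg$lat_range[1], dx, dy)
}

.make_ice_raster <- function(cfg) {
  dx <- 0.05; dy <- 0.01
  lons <- seq(cfg$lon_range[1] + dx / 2, cfg$lon_range[2], by = dx)
  lats <- seq(cfg$lat_range[1] + dy / 2, cfg$lat_range[2], by = dy)
  m <- outer(lats, lons, function(la, lo) pmin(pmax((la - 78.6) / 1.2, 0), 0.95))
  raster_grid(m, cfg$lon_range[1], cfg$lat_range[1], dx, dy)
}

# expected (noise-free) pooled daily mean transmitted-dive depth, by Gaussian
# quadrature over the dive multiplier and the diel mixture, including the
# benthic depth cap at the animal's terrace
.expected_daily_depth <- function(cfg, f_a, ndays) {
  qs <- qlnorm(seq(0.01, 0.99, length.out = 49), -cfg$sdlog_dive^2 / 2,
               cfg$sdlog_dive)
  days <- 0:(ndays - 1)
  base <- .depth_base(cfg, days)
  diel_on <- .month_of_day(cfg, days) %in% cfg$diel_months
  ns <- cfg$diel_n_mult * 12 / (cfg$diel_n_mult * 12 + 12)
  out <- numeric(ndays)
  for (di in seq_len(ndays)) {
    acc <- 0
    for (f_i in f_a) {
      dem0 <- f_i * base[di]
      b <- pmin(pmax(2.2 * dem0, cfg$terraces[1]),
                cfg$terraces[length(cfg$terraces)])
      b <- cfg$terraces[which.min(abs(cfg$terraces - b))]
      e_for <- function(mult) {
        dmd <- dem0 * qs * mult
        mean(ifelse(dmd > 0.9 * b, b * 0.9925, pmax(dmd, 6.5)))
      }
      acc <- acc + if (diel_on[di]) {
        ns * e_for(cfg$diel_depth_mult) + (1 - ns) * e_for(1)
      } else {
        e_for(1)
      }
    }
    out[di] <- acc / length(f_a)
  }
  data.frame(date = cfg$start + days, mean_depth = out)
}

#' Write a simulated deployment to disk
#'
#' Emits the same plain-text formats the readers in the package consume
#' (CSV tables, Esri ASCII grids) plus the ground truth as JSON-like CSVs.
#'
#' @param sim `sd_sim` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_argos(sim$argos, file.path(dir, "argos.csv"))
  write_dives(sim$dives, file.path(dir, "dives.csv"))
  write_summaries(sim$summaries, file.path(dir, "summaries.csv"))
  write_casts(sim$casts, file.path(dir, "casts.csv"))
  write_wind(sim$wind, file.path(dir, "wind.csv"))
  write_ascii_grid(sim$bathy, file.path(dir, "bathy.asc"))
  write_ascii_grid(sim$ice, file.path(dir, "ice.asc"))
  ho <- sim$haulouts
  ho$start <- .fmt_time(ho$start); ho$end <- .fmt_time(ho$end)
  write.csv(ho, file.path(dir, "haulouts.csv"), row.names = FALSE)
  invisible(dir)
}
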