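# Per-dive and per-day behavioural metrics: daily aggregation of 6-h
# summaries, bottom time from broken-stick profiles, foraging-effort
# residuals, bathymetry-relative dive types, diel bins and time-spent-in-area
# high-usage cells.

#' Aggregate 6-h dive summaries to daily series
#'
#' Days with a complete record of four 6-h summaries are aggregated: depth and
#' duration as means of the period averages, counts and times as sums, and the
#' dive/surface ratio as summed diving time over summed surface time.
#' Incomplete days are retained but flagged (`complete = FALSE`) and should be
#' excluded from model inputs.
#'
#' @param summaries data frame from [read_summaries()].
#' @return daily data frame: `id`, `date`, `depth`, `duration`, `n_dives`,
#'   `time_diving`, `surface_time`, `dive_surface_ratio`, `complete`.
#' @export
daily_series <- function(summaries) {
  s <- summaries
  s$date <- as.Date(s$period_start, tz = "UTC")
  key <- paste(s$id, s$date, format(s$period_start, "%H"))
  if (anyDuplicated(key)) stop("daily_series: duplicate 6-h period for a day")
  agg <- function(f, col) {
    a <- aggregate(s[[col]], list(id = s$id, date = s$date), f)
    a$x
  }
  base <- aggregate(s$avg_depth_m, list(id = s$id, date = s$date), length)
  out <- data.frame(id = base$id, date = base$date,
                    n_periods = base$x,
                    depth = agg(mean, "avg_depth_m"),
                    duration = agg(mean, "avg_duration_s"),
                    n_dives = agg(sum, "n_dives"),
                    time_diving = agg(sum, "time_diving_s"),
                    surface_time = agg(sum, "surface_time_s"))
  out$dive_surface_ratio <- ifelse(out$surface_time > 0,
                                   out$time_diving / out$surface_time, NA)
  out$complete <- out$n_periods == 4L
  out$n_periods <- NULL
  out <- out[order(out$id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Bottom time of a broken-stick dive profile
#'
#' The transmitted profile (four interior inflection points) is completed with
#' surface endpoints at the start and end of the dive and linearly
#' interpolated. Bottom time is the total time at depth strictly exceeding
#' `frac` (default 80\%) of the dive's maximum depth, with threshold crossings
#' computed exactly on each linear segment.
#'
#' @param duration dive duration, s.
#' @param max_depth maximum depth, m.
#' @param t_off numeric vector of profile time offsets (s, strictly increasing
#'   inside `(0, duration)`).
#' @param depth numeric vector of profile depths (m), same length.
#' @param frac threshold as a fraction of maximum depth.
#' @return bottom time in seconds.
#' @export
bottom_time <- function(duration, max_depth, t_off, depth, frac = 0.8) {
  stopifnot(length(t_off) == length(depth), duration > 0)
  tt <- c(0, t_off, duration)
  dd <- c(0, depth, 0)
  thr <- frac * max_depth
  tot <- 0
  for (i in seq_len(length(tt) - 1)) {
    t0 <- tt[i]; t1 <- tt[i + 1]; d0 <- dd[i]; d1 <- dd[i + 1]
    if (t1 <= t0) next
    if (d0 > thr && d1 > thr) {
      tot <- tot + (t1 - t0)
    } else if (d0 > thr || d1 > thr) {
      tc <- t0 + (thr - d0) / (d1 - d0) * (t1 - t0)
      tot <- tot + if (d0 > thr) tc - t0 else t1 - tc
    }
  }
  tot
}

#' Bottom times for a dive table
#'
#' Vectorised [bottom_time()] over a dive data frame from [read_dives()].
#'
#' @param dives dive data frame.
#' @param frac threshold fraction of maximum depth.
#' @return numeric vector of bottom times (s).
#' @export
bottom_time_df <- function(dives, frac = 0.8) {
  toff <- as.matrix(dives[paste0("t", 1:4)])
  dep <- as.matrix(dives[paste0("d", 1:4)])
  vapply(seq_len(nrow(dives)), function(i) {
    bottom_time(dives$duration_s[i], dives$max_depth_m[i],
                toff[i, ], dep[i, ], frac)
  }, numeric(1))
}

#' Foraging-effort residuals
#'
#' Per animal, fits an ordinary least squares regression of bottom time on
#' maximum depth and duration and returns standardized residuals (residual
#' divided by the residual standard deviation, so the per-animal residual
#' vector has mean 0 and SD 1). Positive residuals mark dives with a longer
#' bottom time than expected for their depth and duration (higher effort).
#'
#' @param dives dive data frame; a `bottom_s` column is used if present,
#'   otherwise computed via [bottom_time_df()].
#' @param min_dives animals with fewer dives are skipped with a warning.
#' @return data frame `id`, `start`, `bottom_s`, `resid_std`.
#' @export
effort_residuals <- function(dives, min_dives = 10) {
  if (!"bottom_s" %in% names(dives)) dives$bottom_s <- bottom_time_df(dives)
  parts <- lapply(split(dives, dives$id), function(sub) {
    if (nrow(sub) < min_dives) {
      warning(sprintf("effort_residuals: animal %s has <%d dives; skipped",
                      sub$id[1], min_dives))
      return(NULL)
    }
    X <- cbind(1, sub$max_depth_m, sub$duration_s)
    if (qr(X)$rank < 3) {
      stop(sprintf("effort_residuals: rank-deficient design for animal %s",
                   sub$id[1]))
    }
    fit <- lm(bottom_s ~ max_depth_m + duration_s, data = sub)
    r <- resid(fit)
    s <- sd(r)
    # a numerically perfect fit leaves residuals at machine noise; dividing
    # by their SD would amplify that noise into spurious effort signals
    data.frame(id = sub$id, start = sub$start, bottom_s = sub$bottom_s,
               resid_std = if (s > 1e-8) r / s else r)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Classify dives against bathymetry
#'
#' Dives over water shallower than 50 m are "coastal"; otherwise the ratio of
#' maximum dive depth to bathymetric depth classifies the dive as "benthic"
#' (ratio > 0.95) or "pelagic" (ratio <= 0.95; a ratio of exactly 0.95 is
#' assigned to pelagic). Missing bathymetry yields `NA` with a logged count.
#'
#' @param max_depth dive maximum depths, m.
#' @param bathy_depth bathymetric depths at the dive locations, m (positive).
#' @param coastal_max bathymetry below which dives are coastal, m.
#' @param benthic_ratio ratio above which non-coastal dives are benthic.
#' @return factor with levels coastal/benthic/pelagic (NA unclassified).
#' @export
classify_dive <- function(max_depth, bathy_depth, coastal_max = 50,
                          benthic_ratio = 0.95) {
  n_na <- sum(is.na(bathy_depth))
  if (n_na) message(sprintf("classify_dive: %d dive(s) unclassified (no bathymetry)",
                            n_na))
  ratio <- max_depth / bathy_depth
  out <- ifelse(bathy_depth < coastal_max, "coastal",
                ifelse(ratio > benthic_ratio, "benthic", "pelagic"))
  factor(out, levels = c("coastal", "benthic", "pelagic"))
}

#' Diel period of a timestamp
#'
#' Half-open hour bins in the configured timezone: night_am \[0, 6), day
#' \[6, 18), night_pm \[18, 24). For modelling, night is the union of the two
#' night bins (see `collapse`).
#'
#' @param t POSIXct vector.
#' @param tz timezone used for binning (default UTC, which at Svalbard is
#'   about one hour behind local solar time).
#' @param collapse if TRUE return two levels, night/day.
#' @return factor of diel bins.
#' @export
diel_bin <- function(t, tz = "UTC", collapse = FALSE) {
  hr <- as.integer(format(t, "%H", tz = tz))
  b <- ifelse(hr < 6, "night_am", ifelse(hr < 18, "day", "night_pm"))
  if (collapse) {
    factor(ifelse(b == "day", "day", "night"), levels = c("day", "night"))
  } else {
    factor(b, levels = c("night_am", "day", "night_pm"))
  }
}

#' Time-spent-in-area grid and high-usage cells
#'
#' Samples the fitted track at a fixed step, allocates elapsed time to square
#' grid cells by exact segment-in-cell length fractions (haul-out time is
#' excluded), and marks, per individual, cells whose time is at or above the
#' 75th percentile of that individual's positive-time cells as high usage.
#'
#' @param model `sd_track` object from [fit_track()].
#' @param cell_km cell size, km.
#' @param step_min sampling step along the track, minutes.
#' @param origin optional `c(lon, lat)` grid origin; defaults to the minimum
#'   observed coordinates across animals.
#' @param quantile_hi percentile defining high usage.
#' @return object of class `sd_tsa`: per-animal cell table (`id`, `ix`, `iy`,
#'   `tsa_s`, `high`), the grid origin, cell size and per-animal elapsed
#'   (non-haul-out) seconds.
#' @export
tsa_high_usage <- function(model, cell_km = 5, step_min = 10, origin = NULL,
                           quantile_hi = 0.75) {
  if (!length(model$fits)) stop("tsa_high_usage: empty track model")
  if (is.null(origin)) {
    lon0 <- min(vapply(model$fits, function(f) f$lon0 + min(f$x) /
                         (cos(f$lat0 * pi / 180) * pi / 180 * EARTH_RADIUS_KM),
                       numeric(1)))
    lat0 <- min(vapply(model$fits, function(f) f$lat0 + min(f$y) /
                         (pi / 180 * EARTH_RADIUS_KM), numeric(1)))
    origin <- c(lon0, lat0)
  }
  cells <- list(); elapsed <- numeric(0)
  for (f in model$fits) {
    tseq <- seq(f$span[1], f$span[2], by = step_min * 60)
    if (length(tseq) < 2) stop("tsa_high_usage: track too short")
    loc <- locate(model, f$id, tseq)
    xy <- .project_km(loc$lon, loc$lat, origin[1], origin[2])
    ts_s <- as.numeric(difftime(tseq, tseq[1], units = "secs"))
    skip <- rep(FALSE, length(tseq) - 1)
    if (!is.null(f$haulouts) && nrow(f$haulouts)) {
      for (k in seq_len(nrow(f$haulouts))) {
        skip <- skip | (tseq[-length(tseq)] >= f$haulouts$start[k] &
                          tseq[-1] <= f$haulouts$end[k])
      }
    }
    al <- .tsa_alloc(xy[, 1] / cell_km, xy[, 2] / cell_km, ts_s, skip)
    al$id <- f$id
    pos <- al$tsa_s[al$tsa_s > 0]
    thr <- quantile(pos, quantile_hi, type = 7)
    al$high <- al$tsa_s >= thr
    cells[[length(cells) + 1]] <- al
    elapsed[f$id] <- sum(diff(ts_s)[!skip])
  }
  out <- do.call(rbind, cells)
  structure(list(cells = out, origin = origin, cell_km = cell_km,
                 elapsed_s = elapsed),
            class = "sd_tsa")
}

#' Flag events falling in an individual's high-usage cells
#'
#' @param tsa `sd_tsa` object from [tsa_high_usage()].
#' @param events data frame with `id`, `lon`, `lat`.
#' @return logical vector, TRUE when the event's cell is high usage for that
#'   individual.
#' @export
in_high_usage <- function(tsa, events) {
  xy <- .project_km(events$lon, events$lat, tsa$origin[1], tsa$origin[2])
  ix <- floor(xy[, 1] / tsa$cell_km); iy <- floor(xy[, 2] / tsa$cell_km)
  key <- paste(events$id, ix, iy)
  hk <- with(tsa$cells[tsa$cells$high, ], paste(id, ix, iy))
  key %in% hk
}
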