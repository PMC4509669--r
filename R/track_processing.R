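# Track processing: speed-distance-angle filtering of raw Argos locations,
# a continuous-time correlated random walk state-space model with haul-out
# stopping, and geolocation of arbitrary timestamped events from the fitted
# model.

#' Default Argos measurement error SDs per location class (km)
#'
#' Isotropic Gaussian error magnitudes used for classes 3, 2, 1, 0, A, B.
#' These are configuration defaults in the usual magnitude regime for Argos
#' data, not asserted literature values.
#' @export
argos_error_sd_km <- c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                       "0" = 4, "A" = 8, "B" = 15)

#' Speed-distance-angle filter for Argos tracks
#'
#' Iteratively removes implausible locations per animal: first any location
#' whose implied swimming speed against both neighbours exceeds `vmax`
#' (worst violator per pass, by maximum implied speed), then "spikes" -- sharp
#' turns whose interior angle is below a rule's angle threshold while both
#' adjacent segment lengths exceed the rule's paired distance (smallest angle
#' first). The first location of a track is never removed. Great-circle
#' distances on a spherical Earth are used throughout.
#'
#' @param locs Argos data frame (see [read_argos()]).
#' @param vmax speed threshold, m/s.
#' @param spike_rules list of `c(angle_deg, dist_km)` pairs; a location is a
#'   spike if its angle is below `angle_deg` and both adjacent segments are
#'   longer than `dist_km` under any rule.
#' @return list with `locs` (kept rows) and `report` (data frame per animal:
#'   `n_input`, `n_removed_speed`, `n_removed_spike`, plus `removed`, a list
#'   column of removed input row indices).
#' @export
sda_filter <- function(locs, vmax = 2,
                       spike_rules = list(c(15, 2.5), c(25, 5))) {
  stopifnot(is.data.frame(locs))
  out <- vector("list", 0L)
  rep_rows <- vector("list", 0L)
  for (a in unique(locs$id)) {
    sub <- locs[locs$id == a, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3) {
      warning(sprintf("sda_filter: animal %s has <3 locations; passed through", a))
      out[[length(out) + 1]] <- sub
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(id = a, n_input = n, n_removed_speed = 0L,
                   n_removed_spike = 0L)
      rep_rows[[length(rep_rows)]]$removed <- list(integer(0))
      next
    }
    res <- .sda_core(sub$lon, sub$lat, as.numeric(sub$time), vmax,
                     vapply(spike_rules, `[`, numeric(1), 1),
                     vapply(spike_rules, `[`, numeric(1), 2))
    keep <- res$keep
    out[[length(out) + 1]] <- sub[keep, , drop = FALSE]
    rr <- data.frame(id = a, n_input = n, n_removed_speed = res$n_speed,
                     n_removed_spike = res$n_spike)
    rr$removed <- list(which(!keep))
    rep_rows[[length(rep_rows) + 1]] <- rr
  }
  locs_out <- do.call(rbind, out)
  rownames(locs_out) <- NULL
  report <- do.call(rbind, rep_rows)
  stopifnot(all(report$n_input ==
                  vapply(seq_len(nrow(report)),
                         function(i) sum(locs_out$id == report$id[i]) +
                           report$n_removed_speed[i] + report$n_removed_spike[i],
                         numeric(1))))
  list(locs = locs_out, report = report)
}

#' Detect haul-out intervals from a wet/dry sensor series
#'
#' A haul-out starts once the sensor has been continuously dry for more than
#' `min_dry_min` minutes (the interval is anchored at the first dry reading)
#' and ends at the first wet reading.
#'
#' @param wetdry data frame with `id`, `time`, `dry` (logical).
#' @param min_dry_min minimum continuous dry spell, minutes.
#' @return data frame with `id`, `start`, `end`.
#' @export
detect_haulouts <- function(wetdry, min_dry_min = 10) {
  res <- lapply(split(wetdry, wetdry$id), function(sub) {
    sub <- sub[order(sub$time), ]
    r <- rle(sub$dry)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    rows <- which(r$values)
    keep <- lapply(rows, function(k) {
      t0 <- sub$time[starts[k]]
      t1 <- if (ends[k] < nrow(sub)) sub$time[ends[k] + 1] else sub$time[ends[k]]
      if (as.numeric(difftime(t1, t0, units = "mins")) > min_dry_min) {
        data.frame(id = sub$id[1], start = t0, end = t1)
      }
    })
    do.call(rbind, keep)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.ctcrw_neg_loglik <- function(par, times, ox, oy, sds, frozen) {
  ll <- .ctcrw_kfs(times, ox, oy, sds, frozen, par[1], par[2], FALSE)$loglik
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a continuous-time correlated random walk track model
#'
#' Per animal, projects SDA-filtered locations onto a local tangent plane and
#' fits an integrated Ornstein-Uhlenbeck velocity model by maximum likelihood
#' (Kalman filter), with per-class Argos measurement SDs and process variance
#' frozen (movement stopped) inside haul-out intervals. Location estimates for
#' arbitrary times come from the RTS smoother via [locate()].
#'
#' @param locs filtered Argos data frame.
#' @param haulouts optional haul-out intervals (`id`, `start`, `end`).
#' @param err_sd_km named measurement SDs per location class (km).
#' @param fixed optional `c(beta, sigma)` to skip estimation (units 1/h and
#'   km/h^1.5).
#' @return object of class `sd_track`: per-animal fits with parameters,
#'   projection origin, data and time span.
#' @export
fit_track <- function(locs, haulouts = NULL, err_sd_km = argos_error_sd_km,
                      fixed = NULL) {
  fits <- lapply(split(locs, locs$id), function(sub) {
    sub <- sub[order(sub$time), ]
    if (nrow(sub) < 5) stop("fit_track: need >= 5 locations per animal")
    lon0 <- mean(sub$lon); lat0 <- mean(sub$lat)
    xy <- .project_km(sub$lon, sub$lat, lon0, lat0)
    t0 <- sub$time[1]
    th <- as.numeric(difftime(sub$time, t0, units = "hours"))
    sds <- unname(err_sd_km[as.character(sub$lc)])
    ho <- NULL
    if (!is.null(haulouts)) {
      ho <- haulouts[haulouts$id == sub$id[1], , drop = FALSE]
    }
    frozen <- .frozen_intervals(sub$time, ho)
    if (is.null(fixed)) {
      opt <- optim(c(log(1), log(2)), .ctcrw_neg_loglik,
                   times = th, ox = xy[, 1], oy = xy[, 2], sds = sds,
                   frozen = frozen, method = "L-BFGS-B",
                   lower = c(log(1e-3), log(1e-3)),
                   upper = c(log(50), log(50)))
      if (opt$convergence != 0 && opt$convergence != 52) {
        stop(sprintf("fit_track: optimiser did not converge (code %d, nll %.3f)",
                     opt$convergence, opt$value))
      }
      par <- opt$par; nll <- opt$value
    } else {
      par <- log(fixed); nll <- .ctcrw_neg_loglik(par, th, xy[, 1], xy[, 2],
                                                  sds, frozen)
    }
    list(id = sub$id[1], beta = exp(par[1]), sigma = exp(par[2]),
         loglik = -nll, lon0 = lon0, lat0 = lat0, t0 = t0, times_h = th,
         x = xy[, 1], y = xy[, 2], sds = sds, haulouts = ho,
         span = range(sub$time))
  })
  structure(list(fits = fits, err_sd_km = err_sd_km), class = "sd_track")
}

# frozen[i] = TRUE when the interval times[i]..times[i+1] lies inside a
# haul-out (returned with length n so the C++ side indexes i-1).
.frozen_intervals <- function(times, ho) {
  n <- length(times)
  fr <- rep(FALSE, n)
  if (is.null(ho) || nrow(ho) == 0) return(fr)
  for (k in seq_len(nrow(ho))) {
    inside <- times[-n] >= ho$start[k] & times[-1] <= ho$end[k]
    fr[which(inside)] <- TRUE
  }
  fr
}

#' @export
print.sd_track <- function(x, ...) {
  cat(sprintf("<sd_track> %d animal(s)\n", length(x$fits)))
  for (f in x$fits) {
    cat(sprintf("  %s: beta=%.3g /h, sigma=%.3g km/h^1.5, n=%d, %s..%s\n",
                f$id, f$beta, f$sigma, length(f$times_h),
                format(f$span[1]), format(f$span[2])))
  }
  invisible(x)
}

#' Locate timestamped events on a fitted track
#'
#' Runs the Kalman smoother over the union of observation and query times and
#' returns the smoothed position at each query. Queries inside a haul-out
#' interval return the interval's anchor location exactly. Times outside the
#' model's span plus `slack_h` hours raise an out-of-range error.
#'
#' @param model an `sd_track` object from [fit_track()].
#' @param id animal identifier (one animal per call).
#' @param t POSIXct vector of query times.
#' @param slack_h allowed extrapolation beyond the observed span, hours.
#' @return data frame with `id`, `time`, `lon`, `lat`, `se_km` (smoothed
#'   positional SE).
#' @export
locate <- function(model, id, t, slack_h = 6) {
  f <- NULL
  for (ff in model$fits) if (identical(ff$id, id)) f <- ff
  if (is.null(f)) stop("locate: unknown animal id: ", id)
  qh <- as.numeric(difftime(t, f$t0, units = "hours"))
  lo <- min(f$times_h) - slack_h; hi <- max(f$times_h) + slack_h
  if (any(qh < lo | qh > hi)) {
    stop("locate: query time outside model span + slack")
  }
  grid <- sort(unique(c(f$times_h, qh)))
  oi <- match(f$times_h, grid)
  ox <- rep(NA_real_, length(grid)); oy <- ox; sds <- rep(1, length(grid))
  ox[oi] <- f$x; oy[oi] <- f$y; sds[oi] <- f$sds
  grid_t <- f$t0 + grid * 3600
  frozen <- .frozen_intervals(grid_t, f$haulouts)
  sm <- .ctcrw_kfs(grid, ox, oy, sds, frozen, log(f$beta), log(f$sigma), TRUE)
  qi <- match(qh, grid)
  px <- sm$x[qi]; py <- sm$y[qi]; pv <- pmax(sm$pos_var[qi], 0)
  # snap queries inside a haul-out to the interval's anchor (smoothed state at
  # the haul-out start)
  if (!is.null(f$haulouts) && nrow(f$haulouts)) {
    for (k in seq_len(nrow(f$haulouts))) {
      inside <- t >= f$haulouts$start[k] & t <= f$haulouts$end[k]
      if (any(inside)) {
        sh <- as.numeric(difftime(f$haulouts$start[k], f$t0, units = "hours"))
        gi <- which.min(abs(grid - sh))
        px[inside] <- sm$x[gi]; py[inside] <- sm$y[gi]
        pv[inside] <- sm$pos_var[gi]
      }
    }
  }
  ll <- .unproject_km(px, py, f$lon0, f$lat0)
  data.frame(id = id, time = t, lon = ll[, 1], lat = ll[, 2],
             se_km = sqrt(pv))
}

#' Locate a table of events for several animals
#'
#' Convenience wrapper around [locate()] for a data frame with `id` and
#' `time` columns.
#'
#' @param model `sd_track` object.
#' @param events data frame with `id` and `time`.
#' @param slack_h see [locate()].
#' @return `events` with `lon`, `lat`, `se_km` columns appended (row order
#'   preserved).
#' @export
locate_events <- function(model, events, slack_h = 6) {
  events$.row <- seq_len(nrow(events))
  parts <- lapply(split(events, events$id), function(sub) {
    loc <- locate(model, sub$id[1], sub$time, slack_h = slack_h)
    sub$lon <- loc$lon; sub$lat <- loc$lat; sub$se_km <- loc$se_km
    sub
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$.row), ]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}
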