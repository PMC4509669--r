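# Linking oceanography to diving: the daily divergence between mixed-layer
# depth and dive depth with single change-point detection, and lagged wind
# covariates used as a proxy for wind-driven upwelling.

#' Daily MLD-minus-dive-depth divergence series
#'
#' Joins a daily mean dive-depth series (shelf dives only) to a daily
#' mixed-layer-depth series and emits `diff = mld - mean_dive_depth`. Negative
#' values mean the seals dive deeper than the mixed layer. A 3-day moving
#' weighted mean (triangular weights 1-2-1) is attached for presentation only
#' (`diff_smooth`); change-point analysis must use the raw series, since
#' smoothing inflates autocorrelation.
#'
#' @param daily_depth data frame with `date`, `depth` (daily mean dive depth,
#'   m, animal-pooled, shelf only).
#' @param daily_mld data frame with `date`, `mld` (m).
#' @return data frame `date`, `mld`, `mean_dive_depth`, `diff`,
#'   `diff_smooth`, `season_year`; days missing either term keep `NA` in
#'   `diff` (a gap, never zero).
#' @export
divergence_series <- function(daily_depth, daily_mld) {
  dates <- seq(min(c(daily_depth$date, daily_mld$date)),
               max(c(daily_depth$date, daily_mld$date)), by = "day")
  if (!length(intersect(daily_depth$date, daily_mld$date))) {
    stop("divergence_series: no overlapping dates")
  }
  out <- data.frame(date = dates)
  out$mld <- daily_mld$mld[match(dates, daily_mld$date)]
  out$mean_dive_depth <- daily_depth$depth[match(dates, daily_depth$date)]
  out$diff <- out$mld - out$mean_dive_depth
  w <- c(1, 2, 1)
  n <- nrow(out)
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1, i - 1):min(n, i + 1)
    wi <- w[j - i + 2]
    v <- out$diff[j]
    ok <- !is.na(v)
    if (any(ok)) sm[i] <- sum(wi[ok] * v[ok]) / sum(wi[ok])
  }
  out$diff_smooth <- sm
  m <- as.integer(format(out$date, "%m"))
  y <- as.integer(format(out$date, "%Y"))
  out$season_year <- ifelse(m >= 7, y, y - 1L)
  out
}

#' Single change point in the mean of a series
#'
#' At-most-one-change detection under a normal likelihood: for every
#' admissible split the log-likelihood-ratio statistic
#' `n * log(RSS0 / RSS1)` of a mean shift against a constant mean is
#' computed; the split with the largest statistic is the change-point
#' candidate, declared significant when the statistic exceeds the penalty
#' (default an MBIC-style `3 * log(n)`). The search is exhaustive over all
#' splits.
#'
#' @param x numeric series (NA values are dropped; positions are preserved
#'   through the `index` returned, which refers to `x` including NAs).
#' @param penalty numeric penalty, or `"mbic"` for `3 log(n)`, or `"none"` to
#'   always report the best split.
#' @param min_seg minimum segment length on either side.
#' @return list: `index` (last point of the first segment, on the original
#'   series), `stat`, `penalty`, `significant`, `pre_mean`, `post_mean`.
#' @export
change_point <- function(x, penalty = "mbic", min_seg = 2) {
  keep <- which(!is.na(x))
  y <- x[keep]
  n <- length(y)
  if (n < 20) stop("change_point: need >= 20 non-missing values")
  pen <- if (identical(penalty, "mbic")) 3 * log(n)
         else if (identical(penalty, "none")) -Inf
         else as.numeric(penalty)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  rss0 <- cs2[n] - cs[n]^2 / n
  ks <- min_seg:(n - min_seg)
  m1 <- cs[ks] / ks
  m2 <- (cs[n] - cs[ks]) / (n - ks)
  rss1 <- (cs2[ks] - cs[ks]^2 / ks) +
    ((cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks))
  stat <- n * log(pmax(rss0, 1e-300) / pmax(rss1, 1e-300))
  best <- which.max(stat)
  k <- ks[best]
  list(index = keep[k], stat = stat[best], penalty = pen,
       significant = stat[best] > pen,
       pre_mean = m1[best], post_mean = m2[best])
}

#' Change point of a divergence series
#'
#' Applies [change_point()] to the raw `diff` column and reports the change
#' date (first day of the post-change regime).
#'
#' @param ds divergence series from [divergence_series()].
#' @inheritParams change_point
#' @return list as [change_point()] plus `date`.
#' @export
change_point_series <- function(ds, penalty = "mbic", min_seg = 2) {
  cp <- change_point(ds$diff, penalty = penalty, min_seg = min_seg)
  after <- which(!is.na(ds$diff))
  after <- after[after > cp$index]
  cp$date <- ds$date[if (length(after)) after[1] else cp$index]
  cp
}

#' Lagged wind covariates (upwelling proxy)
#'
#' For each date `d`, averages the wind records in the window `[d - k, d)`
#' whose direction of origin falls inside the sector: `"N"` means within
#' +/- 45 degrees of true north; `"NE"` means the combined north-through-east
#' band (from-bearing in \[315, 135\] degrees). With the default
#' blowing-toward component convention, wind from the north has `v < 0`. The
#' covariate is the mean speed (or wind-stress magnitude
#' `rho_air * Cd * U^2`) of contributing records, 0 when none contribute.
#' Windows with data gaps exceeding half the window are flagged.
#'
#' @param wind data frame with `time`, `u`, `v` ([read_wind()]).
#' @param dates Date vector at which covariates are wanted.
#' @param k lag window length, days.
#' @param sector `"N"` or `"NE"`.
#' @param convention `"toward"` (u, v are blowing-toward components) or
#'   `"from"` (meteorological).
#' @param units `"speed"` (m/s) or `"stress"` (N m-2, rho_air = 1.25 kg m-3,
#'   Cd = 1.3e-3).
#' @return data frame `date`, `lag`, `sector`, `value`, `flagged`.
#' @export
wind_covariates <- function(wind, dates, k, sector = c("N", "NE"),
                            convention = c("toward", "from"),
                            units = c("speed", "stress")) {
  sector <- match.arg(sector)
  convention <- match.arg(convention)
  units <- match.arg(units)
  u <- wind$u; v <- wind$v
  if (convention == "toward") { fu <- -u; fv <- -v } else { fu <- u; fv <- v }
  dir_from <- (atan2(fu, fv) * 180 / pi) %% 360
  in_sector <- if (sector == "N") {
    dir_from >= 315 | dir_from <= 45
  } else {
    dir_from >= 315 | dir_from <= 135
  }
  spd <- sqrt(u^2 + v^2)
  val <- if (units == "speed") spd else 1.25 * 1.3e-3 * spd^2
  wt <- sort(as.numeric(wind$time))
  out <- data.frame(date = dates, lag = k, sector = sector,
                    value = NA_real_, flagged = FALSE)
  for (i in seq_along(dates)) {
    d1 <- as.numeric(as.POSIXct(as.character(dates[i]), tz = "UTC"))
    d0 <- d1 - k * 86400
    inw <- as.numeric(wind$time) >= d0 & as.numeric(wind$time) < d1
    # a record gap overlapping the window and longer than half the window
    # flags the covariate; so does a window the series does not cover
    half <- k * 86400 / 2
    gap_flag <- FALSE
    if (length(wt) > 1) {
      a <- wt[-length(wt)]; b <- wt[-1]
      gap_flag <- any((b - a) > half & b > d0 & a < d1)
    }
    uncovered <- !any(inw) || length(wt) == 0 ||
      min(wt) > d0 + half || max(wt) < d1 - half
    out$flagged[i] <- gap_flag || uncovered
    sel <- inw & in_sector
    out$value[i] <- if (any(sel)) mean(val[sel]) else 0
  }
  out
}

#' Lag grid of wind covariates
#'
#' Computes [wind_covariates()] for every lag in `lags` and both sectors,
#' returned wide: one column per sector-lag combination (`North_k`,
#' `NorthEast_k`).
#'
#' @inheritParams wind_covariates
#' @param lags integer vector of lags (days).
#' @return data frame with `date` and covariate columns.
#' @export
wind_covariate_grid <- function(wind, dates, lags = 1:7,
                                convention = "toward", units = "speed") {
  out <- data.frame(date = dates)
  for (k in lags) {
    out[[paste0("North_", k)]] <-
      wind_covariates(wind, dates, k, "N", convention, units)$value
    out[[paste0("NorthEast_", k)]] <-
      wind_covariates(wind, dates, k, "NE", convention, units)$value
  }
  out
}
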