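# Hydrography from seal-collected CTD casts: potential density, mixed-layer
# depth by the density-profile method, 3-D Gaussian-weighted assignment of
# temperature/salinity to dives, regional time series and water-mass labels.
#
# Density and potential temperature follow the UNESCO/EOS-80 polynomials
# (Fofonoff & Millard 1983). Pressure-depth conversion uses 1 dbar = 1 m,
# adequate at shelf depths; a latitude-aware conversion is available.

.sw_dens0 <- function(S, T) {
  # density of seawater at atmospheric pressure, kg m-3
  rw <- 999.842594 + T * (6.793952e-2 + T * (-9.095290e-3 +
        T * (1.001685e-4 + T * (-1.120083e-6 + T * 6.536332e-9))))
  b <- 8.24493e-1 + T * (-4.0899e-3 + T * (7.6438e-5 +
       T * (-8.2467e-7 + T * 5.3875e-9)))
  c <- -5.72466e-3 + T * (1.0227e-4 + T * -1.6546e-6)
  rw + S * b + S^1.5 * c + 4.8314e-4 * S^2
}

.sw_seck <- function(S, T, p_bar) {
  # secant bulk modulus, pressure in bar
  kw <- 19652.21 + T * (148.4206 + T * (-2.327105 +
        T * (1.360477e-2 + T * -5.155288e-5)))
  k0 <- kw + S * (54.6746 + T * (-0.603459 + T * (1.09987e-2 +
        T * -6.1670e-5))) +
    S^1.5 * (7.944e-2 + T * (1.6483e-2 + T * -5.3009e-4))
  aw <- 3.239908 + T * (1.43713e-3 + T * (1.16092e-4 + T * -5.77905e-7))
  a <- aw + S * (2.2838e-3 + T * (-1.0981e-5 + T * -1.6078e-6)) +
    1.91075e-4 * S^1.5
  bw <- 8.50935e-5 + T * (-6.12293e-6 + T * 5.2787e-8)
  b <- bw + S * (-9.9348e-7 + T * (2.0816e-8 + T * 9.1697e-10))
  k0 + a * p_bar + b * p_bar^2
}

#' In-situ seawater density (EOS-80)
#'
#' @param S practical salinity (PSU).
#' @param T temperature, deg C.
#' @param p pressure, dbar.
#' @return density, kg m-3.
#' @export
sw_dens <- function(S, T, p = 0) {
  pb <- p / 10
  .sw_dens0(S, T) / (1 - pb / .sw_seck(S, T, pb))
}

.sw_adtg <- function(S, T, p) {
  # adiabatic temperature gradient, deg C per dbar
  ds <- S - 35
  3.5803e-5 + T * (8.5258e-6 + T * (-6.836e-8 + T * 6.6228e-10)) +
    ds * (1.8932e-6 + T * -4.2393e-8) +
    p * (1.8741e-8 + T * (-6.7795e-10 + T * (8.733e-12 + T * -5.4481e-14))) +
    ds * p * (-1.1351e-10 + T * 2.7759e-12) +
    p^2 * (-4.6206e-13 + T * (1.8676e-14 + T * -2.1687e-16))
}

#' Potential temperature (EOS-80)
#'
#' Temperature a parcel would have if moved adiabatically to reference
#' pressure `pr`; 4th-order Runge-Kutta integration of the adiabatic lapse
#' rate.
#'
#' @inheritParams sw_dens
#' @param pr reference pressure, dbar.
#' @return potential temperature, deg C.
#' @export
sw_ptmp <- function(S, T, p, pr = 0) {
  del_p <- pr - p
  del_th <- del_p * .sw_adtg(S, T, p)
  th <- T + 0.5 * del_th
  q <- del_th
  del_th <- del_p * .sw_adtg(S, th, p + 0.5 * del_p)
  th <- th + (1 - 1 / sqrt(2)) * (del_th - q)
  q <- (2 - sqrt(2)) * del_th + (-2 + 3 / sqrt(2)) * q
  del_th <- del_p * .sw_adtg(S, th, p + 0.5 * del_p)
  th <- th + (1 + 1 / sqrt(2)) * (del_th - q)
  q <- (2 + sqrt(2)) * del_th + (-2 - 3 / sqrt(2)) * q
  del_th <- del_p * .sw_adtg(S, th, p + del_p)
  th + (del_th - 2 * q) / 6
}

#' Potential density anomaly sigma-theta
#'
#' Density anomaly of a parcel moved adiabatically to the surface:
#' `rho(S, theta(S,T,p,0), 0) - 1000` kg m-3.
#'
#' @inheritParams sw_dens
#' @return sigma-theta, kg m-3.
#' @export
potential_density <- function(S, T, p = 0) {
  if (any(S < 0 | S > 41, na.rm = TRUE)) stop("salinity out of range [0, 41]")
  if (any(T < -2.5 | T > 40, na.rm = TRUE)) stop("temperature out of range")
  if (any(p < 0 | p > 12000, na.rm = TRUE)) stop("pressure out of range")
  sw_dens(S, sw_ptmp(S, T, p, 0), 0) - 1000
}

#' Depth to pressure
#'
#' Default 1 m = 1 dbar; `latitude_aware = TRUE` uses the Saunders (1981)
#' approximation.
#'
#' @param depth_m depth, m.
#' @param lat latitude (only used when `latitude_aware`).
#' @param latitude_aware logical.
#' @return pressure, dbar.
#' @export
depth_to_pressure <- function(depth_m, lat = 78, latitude_aware = FALSE) {
  if (!latitude_aware) return(depth_m)
  x <- sin(lat * pi / 180)^2
  c1 <- 5.92e-3 + 5.25e-3 * x
  ((1 - c1) - sqrt((1 - c1)^2 - 8.84e-6 * depth_m)) / 4.42e-6
}

#' Mixed-layer depth of a cast (density-profile method)
#'
#' Computes sigma-theta at every level, interpolates a reference value at the
#' reference depth (6 m, the first data point of a dive, chosen to avoid
#' surface turbulence), and returns the shallowest depth at which sigma-theta
#' meets or exceeds the reference plus `dsigma`, located by linear
#' interpolation between the bracketing levels. If the threshold is never
#' exceeded the cast's deepest level is returned, flagged `bottom_limited`.
#'
#' @param cast data frame with `depth_m`, `temp_c`, `sal_psu` (one cast,
#'   depths strictly increasing).
#' @param dsigma density threshold, kg m-3 (default 0.03, a common
#'   oceanographic criterion).
#' @param ref_depth reference depth, m.
#' @return list with `mld`, `valid`, `bottom_limited`, `sigma_ref`.
#' @export
mixed_layer_depth <- function(cast, dsigma = 0.03, ref_depth = 6) {
  z <- cast$depth_m
  if (length(z) < 2 || max(z) <= ref_depth) {
    return(list(mld = NA_real_, valid = FALSE, bottom_limited = FALSE,
                sigma_ref = NA_real_))
  }
  sg <- potential_density(cast$sal_psu, cast$temp_c, depth_to_pressure(z))
  sig_ref <- if (min(z) >= ref_depth) {
    if (min(z) > ref_depth) sg[1] else sg[which.min(z)]
  } else {
    approx(z, sg, xout = ref_depth, rule = 2)$y
  }
  thr <- sig_ref + dsigma
  below <- z > ref_depth
  zi <- z[below]; si <- sg[below]
  hit <- which(si >= thr)
  if (!length(hit)) {
    return(list(mld = max(z), valid = TRUE, bottom_limited = TRUE,
                sigma_ref = sig_ref))
  }
  k <- hit[1]
  if (k == 1) {
    # bracket with the reference point itself
    z0 <- ref_depth; s0 <- sig_ref
  } else {
    z0 <- zi[k - 1]; s0 <- si[k - 1]
  }
  mld <- if (si[k] == s0) zi[k] else z0 + (thr - s0) / (si[k] - s0) * (zi[k] - z0)
  list(mld = max(mld, ref_depth), valid = TRUE, bottom_limited = FALSE,
       sigma_ref = sig_ref)
}

#' Mixed-layer depth for every cast in a long cast table
#'
#' @param casts long cast data frame (see [read_casts()]).
#' @inheritParams mixed_layer_depth
#' @return data frame: `cast_id`, `id`, `time`, `lon`, `lat`, `mld`, `valid`,
#'   `bottom_limited`.
#' @export
mld_by_cast <- function(casts, dsigma = 0.03, ref_depth = 6) {
  parts <- lapply(split(casts, casts$cast_id), function(sub) {
    sub <- sub[order(sub$depth_m), ]
    m <- mixed_layer_depth(sub, dsigma, ref_depth)
    data.frame(cast_id = sub$cast_id[1], id = sub$id[1], time = sub$time[1],
               lon = sub$lon[1], lat = sub$lat[1], mld = m$mld,
               valid = m$valid, bottom_limited = m$bottom_limited)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' 3-D Gaussian-weighted temperature/salinity interpolation
#'
#' Assigns temperature and salinity to target points (typically a dive at its
#' time, location and a depth of interest) as a weighted running average over
#' all cast levels of all animals. Each level's weight is the product of three
#' Gaussian kernels in time (SD 3 days), horizontal great-circle distance
#' (SD 25 km) and depth (SD 5 m, twice the sensor resolution). Targets whose
#' total unnormalised weight falls below `weight_floor` get a flagged
#' no-support result (`NA`).
#'
#' @param targets data frame with `time` (POSIXct), `lon`, `lat`, `depth_m`.
#' @param casts long cast table ([read_casts()]).
#' @param sd_t_days,sd_xy_km,sd_z_m kernel standard deviations.
#' @param trunc_sd time-window truncation in units of `sd_t_days` (Inf = use
#'   every level; finite values bound the level scan for speed at a relative
#'   weight error below `exp(-trunc_sd^2/2)`).
#' @param weight_floor minimum total weight for a supported estimate.
#' @return data frame `temp`, `sal`, `eff_weight`, `n_casts`, `ok`.
#' @export
interpolate_ts <- function(targets, casts, sd_t_days = 3, sd_xy_km = 25,
                           sd_z_m = 5, trunc_sd = Inf, weight_floor = 1e-6) {
  ord <- order(casts$time)
  cs <- casts[ord, ]
  ct <- as.numeric(cs$time) / 86400
  tt <- as.numeric(targets$time) / 86400
  m <- .gauss3_interp(tt, targets$lon, targets$lat, targets$depth_m,
                      ct, cs$lon, cs$lat, cs$depth_m, cs$temp_c, cs$sal_psu,
                      as.integer(factor(cs$cast_id)),
                      sd_t_days, sd_xy_km, sd_z_m, trunc_sd, weight_floor)
  out <- as.data.frame(m)
  out$ok <- !is.na(out$temp)
  out
}

#' Default analysis region boxes
#'
#' Three latitude bands on the shelf: box A in the north-west, box B in the
#' middle (west of the core haul-out area) and box C in the south. Bounds are
#' half-open: west and south edges inclusive.
#'
#' @return data frame `name`, `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
region_boxes <- function() {
  data.frame(name = c("A", "B", "C"),
             lon_min = 9, lon_max = 12.6,
             lat_min = c(78.9, 78.3, 77.5),
             lat_max = c(79.6, 78.9, 78.3))
}

#' Assign points to region boxes
#'
#' Half-open convention: a point on a box's west or south edge belongs to the
#' box; east/north edges do not.
#'
#' @param lon,lat point coordinates.
#' @param boxes data frame as from [region_boxes()] (must be pairwise
#'   disjoint).
#' @return character vector of box names (`NA` outside all boxes).
#' @export
assign_region <- function(lon, lat, boxes = region_boxes()) {
  out <- rep(NA_character_, length(lon))
  for (i in seq_len(nrow(boxes))) {
    inb <- lon >= boxes$lon_min[i] & lon < boxes$lon_max[i] &
      lat >= boxes$lat_min[i] & lat < boxes$lat_max[i]
    if (any(inb & !is.na(out))) stop("assign_region: boxes overlap")
    out[inb] <- boxes$name[i]
  }
  out
}

#' Regional daily series of a cast variable at fixed depth levels
#'
#' For each box, depth level and day: each cast contributes its profile value
#' linearly interpolated at the level depth (casts not spanning the level are
#' skipped), and the daily value is a Gaussian-weighted mean over casts within
#' the smoothing window. The 2-day window is read as a Gaussian of SD
#' `sd_days` = 1 day truncated at +/- `max_days` = 2 days. Days without
#' support are gaps (absent), not zeros.
#'
#' @param casts long cast table.
#' @param boxes region boxes.
#' @param var `"temp"` or `"sal"`.
#' @param depth_levels depths (m) at which to evaluate profiles.
#' @param sd_days Gaussian SD of the smoother, days.
#' @param max_days truncation half-width, days.
#' @return data frame `box`, `depth`, `date`, `value`, `n_casts`.
#' @export
region_series <- function(casts, boxes = region_boxes(), var = c("temp", "sal"),
                          depth_levels = c(6, 50, 100, 150),
                          sd_days = 1, max_days = 2) {
  var <- match.arg(var)
  col <- if (var == "temp") "temp_c" else "sal_psu"
  first <- !duplicated(casts$cast_id)
  meta <- casts[first, c("cast_id", "time", "lon", "lat")]
  meta$box <- assign_region(meta$lon, meta$lat, boxes)
  meta <- meta[!is.na(meta$box), ]
  if (!nrow(meta)) stop("region_series: no casts fall inside any box")
  # profile value at each level depth
  vals <- lapply(split(casts, casts$cast_id), function(sub) {
    sub <- sub[order(sub$depth_m), ]
    v <- rep(NA_real_, length(depth_levels))
    ok <- depth_levels >= min(sub$depth_m) & depth_levels <= max(sub$depth_m)
    if (any(ok)) v[ok] <- approx(sub$depth_m, sub[[col]],
                                 xout = depth_levels[ok])$y
    v
  })
  vmat <- do.call(rbind, vals[as.character(meta$cast_id)])
  day <- as.numeric(meta$time) / 86400
  out <- list()
  for (b in unique(meta$box)) {
    inb <- meta$box == b
    for (li in seq_along(depth_levels)) {
      v <- vmat[inb, li]; d <- day[inb]
      keep <- !is.na(v)
      v <- v[keep]; d <- d[keep]
      if (!length(v)) next
      days <- seq(floor(min(d)), ceiling(max(d)))
      for (dd in days) {
        w <- exp(-0.5 * ((d - dd) / sd_days)^2)
        w[abs(d - dd) > max_days] <- 0
        if (sum(w) <= 0) next
        out[[length(out) + 1]] <-
          data.frame(box = b, depth = depth_levels[li],
                     date = as.Date(dd, origin = "1970-01-01"),
                     value = sum(w * v) / sum(w), n_casts = sum(w > 0))
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$box, res$depth, res$date), ]
}

#' Water-mass label from temperature and salinity
#'
#' Descriptive classification into Atlantic Water (warm, saline), Arctic
#' Water (cold, fresher) or mixed/other. Thresholds follow the descriptive
#' ranges of the water masses on the West Spitsbergen Shelf and are
#' configuration, not a formal definition.
#'
#' @param T temperature, deg C.
#' @param S salinity, PSU.
#' @param aw_t,aw_s AW requires `T > aw_t` and `S > aw_s`.
#' @param arw_t,arw_s ArW requires `T < arw_t` and `S <= arw_s`.
#' @return factor with levels AW, ArW, mixed.
#' @export
water_mass_label <- function(T, S, aw_t = 3.0, aw_s = 34.9,
                             arw_t = 1.0, arw_s = 34.7) {
  out <- ifelse(T > aw_t & S > aw_s, "AW",
                ifelse(T < arw_t & S <= arw_s, "ArW", "mixed"))
  factor(out, levels = c("AW", "ArW", "mixed"))
}
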