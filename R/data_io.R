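# Readers/writers for the external table and grid formats used throughout the
# pipeline. Every other module consumes the data frames these functions emit.
# All timestamps are normalised to UTC at read time; files use comma-separated
# values, '.' decimals and ISO-8601 times (a ';' dialect is accepted via `sep`).

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B")

# Sea-ice concentration categories (fractional concentration `conc` in [0,1]):
# 1 open water (0-1/10), 2 very open drift ice (1/10-4/10), 3 open drift ice
# (4/10-7/10), 4 close drift ice (7/10-9/10), 5 very close drift ice
# (9/10-10/10), 6 land-fast ice (flagged separately, not derivable from
# concentration alone).

#' Categorise sea-ice concentration
#'
#' Maps fractional ice concentration to the six-category coding used for
#' ice covariates: open water through very close drift ice, with land-fast ice
#' as category 6 set from an explicit flag.
#'
#' @param conc numeric vector, ice concentration in \[0, 1\].
#' @param landfast logical vector (recycled), TRUE where ice is land-fast.
#' @return integer vector of categories 1-6.
#' @export
ice_category <- function(conc, landfast = FALSE) {
  stopifnot(all(is.na(conc) | (conc >= 0 & conc <= 1)))
  cat <- findInterval(conc, c(0, 0.1, 0.4, 0.7, 0.9), rightmost.closed = FALSE)
  cat[conc >= 0.9] <- 5L
  cat <- pmax(cat, 1L)
  landfast <- rep_len(landfast, length(conc))
  cat[landfast] <- 6L
  as.integer(cat)
}

.parse_time <- function(x, tz = "UTC") {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) out[bad] <- as.POSIXct(x[bad], tz = tz, format = "%Y-%m-%d")
  if (anyNA(out[!is.na(x)])) stop("unparseable timestamp(s), expected ISO-8601")
  attr(out, "tzone") <- "UTC"
  out
}

.fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
}

#' Read an Argos location table
#'
#' Reads a CSV of Argos satellite positions (columns `id`, `time`, `lon`,
#' `lat`, `lc`), validates location classes and coordinate ranges, drops exact
#' duplicates and sorts per animal by time.
#'
#' @param path CSV file path.
#' @param tz timezone of the input timestamps (normalised to UTC on read).
#' @param sep field separator (`","` or `";"`).
#' @return data frame with columns `id`, `time` (POSIXct UTC), `lon`, `lat`,
#'   `lc` (factor with levels 3,2,1,0,A,B). The number of duplicate rows
#'   dropped is reported via `message()`.
#' @export
read_argos <- function(path, tz = "UTC", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "time", "lon", "lat", "lc"), "argos")
  df$lc <- as.character(df$lc)
  bad <- !df$lc %in% ARGOS_CLASSES
  if (any(bad)) {
    stop(sprintf("argos: unknown location class value(s): %s",
                 paste(unique(df$lc[bad]), collapse = ", ")))
  }
  df$time <- .parse_time(df$time, tz)
  as_argos(df)
}

#' Validate and normalise an in-memory Argos table
#'
#' @param df data frame with `id`, `time`, `lon`, `lat`, `lc`.
#' @return sorted, deduplicated Argos data frame.
#' @export
as_argos <- function(df) {
  stopifnot(all(df$lat >= -90 & df$lat <= 90),
            all(df$lon >= -180 & df$lon <= 180))
  df$lc <- factor(as.character(df$lc), levels = ARGOS_CLASSES)
  if (anyNA(df$lc)) stop("argos: unknown location class")
  key <- paste(df$id, as.numeric(df$time), df$lon, df$lat)
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("argos: dropped %d exact duplicate row(s)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("id", "time", "lon", "lat", "lc")]
}

#' @rdname read_argos
#' @param df Argos data frame to write.
#' @export
write_argos <- function(df, path) {
  out <- df
  out$time <- .fmt_time(out$time)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-dive records
#'
#' CSV layout: `id`, `start`, `duration_s`, `max_depth_m`, inflection-point
#' offsets `t1..t4` (seconds into the dive) and depths `d1..d4` (m). The four
#' interior points describe the broken-stick profile; surface endpoints at the
#' start and end of the dive are implicit.
#'
#' @param path CSV file path.
#' @param tz,sep as in [read_argos()].
#' @return data frame of dive records sorted per animal by start time.
#' @export
read_dives <- function(path, tz = "UTC", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "start", "duration_s", "max_depth_m",
                      paste0("t", 1:4), paste0("d", 1:4)), "dives")
  df$start <- .parse_time(df$start, tz)
  stopifnot(all(df$duration_s >= 8), all(df$max_depth_m >= 6))
  toff <- as.matrix(df[paste0("t", 1:4)])
  dep <- as.matrix(df[paste0("d", 1:4)])
  if (any(toff <= 0 | toff >= df$duration_s)) {
    stop("dives: profile time offsets must lie strictly inside (0, duration)")
  }
  if (any(toff[, -1] <= toff[, -4])) {
    stop("dives: profile time offsets must be strictly increasing")
  }
  if (any(dep > df$max_depth_m + 1e-9)) {
    stop("dives: profile depths exceed max_depth")
  }
  df <- df[order(df$id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_dives
#' @param df dive data frame to write.
#' @export
write_dives <- function(df, path) {
  out <- df
  out$start <- .fmt_time(out$start)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read 6-h dive summaries
#'
#' CSV layout: `id`, `period_start` (00/06/12/18 h UTC), `avg_depth_m`,
#' `avg_duration_s`, `n_dives`, `time_diving_s`, `surface_time_s`.
#'
#' @inheritParams read_argos
#' @return data frame sorted per animal by period start.
#' @export
read_summaries <- function(path, tz = "UTC", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "period_start", "avg_depth_m", "avg_duration_s",
                      "n_dives", "time_diving_s", "surface_time_s"),
                "summaries")
  df$period_start <- .parse_time(df$period_start, tz)
  hr <- as.integer(format(df$period_start, "%H", tz = "UTC"))
  if (!all(hr %in% c(0L, 6L, 12L, 18L))) {
    stop("summaries: period_start must fall on 00/06/12/18 h UTC")
  }
  if (any(df$time_diving_s + df$surface_time_s > 21600 + 1e-6)) {
    stop("summaries: diving + surface time exceeds the 6-h period")
  }
  stopifnot(all(df$n_dives >= 0))
  df <- df[order(df$id, df$period_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_summaries
#' @param df summary data frame to write.
#' @export
write_summaries <- function(df, path) {
  out <- df
  out$period_start <- .fmt_time(out$period_start)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read CTD casts (long format)
#'
#' CSV layout: `cast_id`, `id`, `time`, `lon`, `lat`, `depth_m`, `temp_c`,
#' `sal_psu`; one row per sampled level, depths strictly increasing within a
#' cast.
#'
#' @inheritParams read_argos
#' @return long data frame of cast levels sorted by cast and depth.
#' @export
read_casts <- function(path, tz = "UTC", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .require_cols(df, c("cast_id", "id", "time", "lon", "lat", "depth_m",
                      "temp_c", "sal_psu"), "casts")
  df$time <- .parse_time(df$time, tz)
  stopifnot(all(df$temp_c >= -2.5 & df$temp_c <= 30),
            all(df$sal_psu >= 0 & df$sal_psu <= 41))
  df <- df[order(df$cast_id, df$depth_m), , drop = FALSE]
  if (any(unlist(tapply(df$depth_m, df$cast_id,
                        function(z) diff(z) <= 0)))) {
    stop("casts: depths must be strictly increasing within a cast")
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_casts
#' @param df cast data frame to write.
#' @export
write_casts <- function(df, path) {
  out <- df
  out$time <- .fmt_time(out$time)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wind time series
#'
#' CSV layout: `time`, `u`, `v` (m/s, eastward/northward components at a fixed
#' grid point). Cadence gaps are flagged in the `gap_after` column, not filled.
#'
#' @inheritParams read_argos
#' @return data frame with `time`, `u`, `v`, `gap_after` (logical: the
#'   interval to the next record exceeds 1.5x the modal cadence).
#' @export
read_wind <- function(path, tz = "UTC", sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  .require_cols(df, c("time", "u", "v"), "wind")
  df$time <- .parse_time(df$time, tz)
  df <- df[order(df$time), , drop = FALSE]
  dt <- diff(as.numeric(df$time))
  cadence <- if (length(dt)) as.numeric(names(sort(table(dt),
                                                   decreasing = TRUE))[1]) else NA
  df$gap_after <- c(dt > 1.5 * cadence, FALSE)
  rownames(df) <- NULL
  df
}

#' @rdname read_wind
#' @param df wind data frame to write.
#' @export
write_wind <- function(df, path) {
  out <- df[, c("time", "u", "v")]
  out$time <- .fmt_time(out$time)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Raster grids (axis-aligned, lon/lat). Stored in memory as a matrix with
# row 1 = southernmost row; on disk as plain-text Esri ASCII grid (.asc),
# which stores the northernmost row first.

#' Construct a raster grid
#'
#' An axis-aligned georeferenced grid in geographic coordinates. `values` is a
#' matrix with `nrow = ny` rows (row 1 = southernmost) and `ncol = nx`.
#'
#' @param values numeric matrix of cell values.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param dx,dy cell sizes (degrees); must be positive (an invertible
#'   transform), otherwise a format error is raised.
#' @param crs coordinate reference identifier (informational).
#' @param nodata sentinel value marking missing cells.
#' @return object of class `sd_raster`.
#' @export
raster_grid <- function(values, xll, yll, dx, dy = dx, crs = "EPSG:4326",
                        nodata = -9999) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0) {
    stop("raster: non-invertible transform (cell sizes must be positive)")
  }
  structure(list(values = values, xll = xll, yll = yll, dx = dx, dy = dy,
                 crs = crs, nodata = nodata),
            class = "sd_raster")
}

#' @export
print.sd_raster <- function(x, ...) {
  cat(sprintf("<sd_raster> %d x %d cells, origin (%.4f, %.4f), cell %.5g x %.5g, crs %s\n",
              nrow(x$values), ncol(x$values), x$xll, x$yll, x$dx, x$dy, x$crs))
  invisible(x)
}

#' Look up raster values at points
#'
#' Returns the containing cell's value for each point. Points outside the grid
#' yield a typed outside-domain result (`outside = TRUE`, value `NA`) rather
#' than an error; nodata cells yield `NA` with `outside = FALSE`.
#'
#' @param grid an [raster_grid()] object.
#' @param lon,lat point coordinates.
#' @return data frame with columns `value` and `outside`.
#' @export
raster_lookup <- function(grid, lon, lat) {
  nx <- ncol(grid$values); ny <- nrow(grid$values)
  ix <- floor((lon - grid$xll) / grid$dx) + 1
  iy <- floor((lat - grid$yll) / grid$dy) + 1
  # points exactly on the top/right edge belong to the last cell
  ix[lon == grid$xll + nx * grid$dx] <- nx
  iy[lat == grid$yll + ny * grid$dy] <- ny
  outside <- ix < 1 | ix > nx | iy < 1 | iy > ny
  val <- rep(NA_real_, length(lon))
  ok <- !outside & !is.na(ix) & !is.na(iy)
  val[ok] <- grid$values[cbind(iy[ok], ix[ok])]
  val[!is.na(val) & val == grid$nodata] <- NA_real_
  data.frame(value = val, outside = outside)
}

#' Read / write Esri ASCII grids
#'
#' Plain-text raster exchange format: a short header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` or `dx`/`dy`, `NODATA_value`) followed
#' by rows of values, northernmost row first.
#'
#' @param path file path.
#' @return [raster_grid()] object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) {
    stop("ascii grid: malformed header, need ", paste(need, collapse = ", "))
  }
  dx <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dy <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  if (is.null(dx) || is.null(dy)) stop("ascii grid: missing cell size")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ascii grid: value count does not match header dimensions")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]  # to south-first rows
  m[m == nodata] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, dx, dy, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param grid raster to write.
#' @export
write_ascii_grid <- function(grid, path) {
  ny <- nrow(grid$values); nx <- ncol(grid$values)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll))
  hdr <- if (grid$dx == grid$dy) {
    c(hdr, sprintf("cellsize %.10g", grid$dx))
  } else {
    c(hdr, sprintf("dx %.10g", grid$dx), sprintf("dy %.10g", grid$dy))
  }
  hdr <- c(hdr, sprintf("NODATA_value %.10g", grid$nodata))
  m <- grid$values[ny:1, , drop = FALSE]
  m[is.na(m)] <- grid$nodata
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
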