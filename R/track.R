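# GPS track handling: validation, step/turn series, ground-speed filtering and
# regular-grid resampling. A "track" is a tidy tibble of fixes with columns
# individual_id, time (POSIXct UTC), lat, lon; all verbs below are grouped by
# individual and return tibbles, so they chain with the pipe.

.as_track_time <- function(time) {
  if (inherits(time, "POSIXct")) return(time)
  if (is.numeric(time)) {
    return(as.POSIXct(time, origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(time, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  out
}

#' Validate a GPS fix table
#'
#' Checks that `fixes` has the columns `individual_id`, `time`, `lat`, `lon`,
#' that coordinates are within bounds, and that timestamps are strictly
#' increasing (no duplicates) within each individual.
#'
#' @param fixes A data frame of GPS fixes.
#' @return The input as a tibble, invisibly sorted by individual and time.
#' @export
validate_track <- function(fixes) {
  need <- c("individual_id", "time", "lat", "lon")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  fixes <- as_tibble(fixes)
  fixes$time <- .as_track_time(fixes$time)
  if (anyNA(fixes$time)) abort("unparseable timestamps")
  .check_lat_lon(fixes$lat, fixes$lon)
  fixes <- arrange(fixes, .data$individual_id, .data$time)
  dup <- fixes |>
    group_by(.data$individual_id) |>
    summarise(bad = anyDuplicated(.data$time) > 0, .groups = "drop")
  if (any(dup$bad)) {
    abort(paste0("duplicate timestamps for: ",
                 paste(dup$individual_id[dup$bad], collapse = ", ")))
  }
  fixes
}

.steps_one <- function(df) {
  n <- nrow(df)
  step_km <- speed_kmh <- dt_h <- rep(NA_real_, n)
  turn_rad <- rep(NA_real_, n)
  if (n >= 2) {
    i <- seq_len(n - 1)
    d <- haversine_km(df$lat[i], df$lon[i], df$lat[i + 1], df$lon[i + 1])
    dt <- as.numeric(difftime(df$time[i + 1], df$time[i], units = "hours"))
    if (any(dt <= 0)) abort("non-increasing timestamps in step computation")
    step_km[i] <- d
    dt_h[i] <- dt
    speed_kmh[i] <- d / dt
  }
  if (n >= 3) {
    j <- 2:(n - 1)
    b_in <- bearing_rad(df$lat[j - 1], df$lon[j - 1], df$lat[j], df$lon[j])
    b_out <- bearing_rad(df$lat[j], df$lon[j], df$lat[j + 1], df$lon[j + 1])
    tr <- wrap_angle(b_in - b_out) # positive = counterclockwise (left turn)
    # undefined where either adjacent step has zero length
    zero_in <- step_km[j - 1] == 0
    zero_out <- step_km[j] == 0
    tr[zero_in | zero_out] <- NA_real_
    turn_rad[j] <- tr
  }
  df$step_km <- step_km
  df$dt_h <- dt_h
  df$speed_kmh <- speed_kmh
  df$turn_rad <- turn_rad
  df
}

#' Step lengths, speeds and turning angles along a track
#'
#' For each fix, computes the great-circle step length to the next fix, the
#' elapsed time and implied ground speed, and (at interior fixes) the signed
#' turning angle between the incoming and outgoing step bearings, wrapped to
#' `(-pi, pi]` with positive = counterclockwise. Steps are `NA` at the last
#' fix of each individual (and each resampling segment, if a `segment` column
#' is present); turning angles are additionally `NA` at sequence endpoints and
#' wherever an adjacent step has zero length.
#'
#' @param fixes A validated fix table (see [validate_track()]).
#' @return The input tibble with columns `step_km`, `dt_h`, `speed_kmh`,
#'   `turn_rad` appended.
#' @export
track_steps <- function(fixes) {
  fixes <- validate_track(fixes)
  if (any(table(fixes$individual_id) < 2)) {
    abort("need at least 2 fixes per individual to compute steps")
  }
  keys <- intersect(c("individual_id", "segment"), names(fixes))
  fixes |>
    group_by(across(all_of(keys))) |>
    group_modify(~ .steps_one(.x)) |>
    ungroup()
}

.speed_filter_one <- function(df, vmax_kmh) {
  n <- nrow(df)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  t_h <- as.numeric(df$time) / 3600
  for (i in seq_len(n)[-1]) {
    d <- haversine_km(df$lat[last], df$lon[last], df$lat[i], df$lon[i])
    v <- d / (t_h[i] - t_h[last])
    if (v <= vmax_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep
}

#' Remove implausible ground-speed spikes
#'
#' Forward sweep per individual: the first fix is kept; each later fix is kept
#' if and only if the ground speed from the last *kept* fix does not exceed
#' `vmax_kmh`. The default 90 km/h is the conventional cutoff for flapping and
#' gliding seabirds. Filtering is idempotent, and every consecutive pair of
#' kept fixes has speed at or below the cutoff.
#'
#' @inheritParams track_steps
#' @param vmax_kmh Maximum plausible ground speed, km/h. Fixes implying a
#'   strictly greater speed are removed.
#' @param verbose Report the number of removed fixes.
#' @return Filtered fix tibble, with the removal count in attribute
#'   `n_removed`.
#' @export
filter_speed <- function(fixes, vmax_kmh = 90, verbose = FALSE) {
  fixes <- validate_track(fixes)
  kept <- fixes |>
    group_by(.data$individual_id) |>
    group_modify(~ .x[.speed_filter_one(.x, vmax_kmh), , drop = FALSE]) |>
    ungroup()
  n_removed <- nrow(fixes) - nrow(kept)
  if (verbose) inform(sprintf("filter_speed: removed %d of %d fixes", n_removed, nrow(fixes)))
  attr(kept, "n_removed") <- n_removed
  kept
}

.unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  adj <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
  lon + adj
}

.resample_one <- function(df, interval_s, max_gap_s) {
  t <- as.numeric(df$time)
  grid <- seq(t[1], t[length(t)], by = interval_s)
  idx <- findInterval(grid, t)
  idx[idx >= length(t)] <- length(t) - 1L
  gap <- t[idx + 1L] - t[idx]
  on_node <- grid %in% t
  ok <- on_node | gap <= max_gap_s
  # longitude interpolated on the unwrapped scale to survive the antimeridian
  lon_u <- .unwrap_lon(df$lon)
  w <- (grid - t[idx]) / gap
  lat <- df$lat[idx] + w * (df$lat[idx + 1L] - df$lat[idx])
  lon <- lon_u[idx] + w * (lon_u[idx + 1L] - lon_u[idx])
  exact <- match(grid, t)
  hit <- !is.na(exact)
  lat[hit] <- df$lat[exact[hit]]
  lon[hit] <- lon_u[exact[hit]]
  lon <- ((lon + 180) %% 360) - 180
  out <- tibble(
    time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    lat = lat, lon = lon
  )[ok, , drop = FALSE]
  # gaps split the track into segments: no steps or turns are formed across them
  out$segment <- cumsum(c(1L, diff(as.numeric(out$time)) > interval_s + 1e-6))
  out
}

#' Resample a track onto a regular time grid
#'
#' Per individual, places fixes at `t0, t0 + interval, t0 + 2 * interval, ...`
#' up to the last observed fix, with positions linearly interpolated between
#' the bracketing original fixes (latitude and longitude independently;
#' longitude is unwrapped so interpolation never crosses the antimeridian the
#' long way round). Grid times falling inside an observation gap longer than
#' `max_gap_min` are dropped rather than interpolated, splitting the output
#' into numbered `segment`s.
#'
#' @inheritParams track_steps
#' @param interval_min Target sampling interval in minutes.
#' @param max_gap_min Longest observation gap (minutes) across which positions
#'   may be interpolated; defaults to three sampling intervals.
#' @return Resampled fix tibble with a `segment` column.
#' @export
resample_track <- function(fixes, interval_min, max_gap_min = 3 * interval_min) {
  if (!is.numeric(interval_min) || interval_min <= 0) abort("interval_min must be > 0")
  fixes <- validate_track(fixes)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(~ {
      if (nrow(.x) < 2) abort("need at least 2 fixes to resample")
      .resample_one(.x, interval_min * 60, max_gap_min * 60)
    }) |>
    ungroup()
}

#' Read and write GPS fix tables
#'
#' The on-disk dialect has columns `individual_id,time_iso8601,lat,lon` with
#' ISO-8601 UTC timestamps. Malformed rows (unparseable time, out-of-bounds
#' coordinates) are skipped with a message reporting the count.
#'
#' @param path File path.
#' @return `read_track_csv()`: a validated fix tibble.
#' @export
read_track_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    time_iso8601 = readr::col_character(),
    lat = readr::col_double(),
    lon = readr::col_double()
  ))
  t1 <- as.POSIXct(strptime(raw$time_iso8601, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  t2 <- as.POSIXct(strptime(raw$time_iso8601, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  time <- dplyr::coalesce(t1, t2)
  ok <- !is.na(time) & is.finite(raw$lat) & is.finite(raw$lon) &
    abs(raw$lat) <= 90 & abs(raw$lon) <= 180
  if (any(!ok)) inform(sprintf("read_track_csv: skipped %d malformed rows", sum(!ok)))
  validate_track(tibble(
    individual_id = raw$individual_id[ok],
    time = time[ok], lat = raw$lat[ok], lon = raw$lon[ok]
  ))
}

#' @rdname read_track_csv
#' @param fixes A fix tibble.
#' @export
write_track_csv <- function(fixes, path) {
  fixes <- validate_track(fixes)
  out <- tibble(
    individual_id = fixes$individual_id,
    time_iso8601 = format(fixes$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = fixes$lat, lon = fixes$lon
  )
  readr::write_csv(out, path)
  invisible(path)
}
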