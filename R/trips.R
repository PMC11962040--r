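# Central-place foraging trip segmentation and per-trip / per-individual
# metrics. A trip is a maximal run of consecutive fixes strictly farther from
# the colony than a species-specific distance threshold, retained only when it
# lasts strictly longer than the species' duration threshold (gulls: 1 km and
# 1 h; shearwaters: 3 km and 6 h).

#' Species trip-definition rules
#'
#' @param species `"gull"` or `"shearwater"`.
#' @return A list with `min_colony_km` and `min_duration_h`.
#' @export
trip_rule <- function(species = c("gull", "shearwater")) {
  species <- match.arg(species)
  switch(species,
    gull = list(min_colony_km = 1, min_duration_h = 1),
    shearwater = list(min_colony_km = 3, min_duration_h = 6)
  )
}

#' Distance of every fix to the colony
#'
#' @inheritParams track_steps
#' @param colony Colony coordinates, a numeric vector `c(lat, lon)` (names
#'   `lat`/`lon` honoured if present).
#' @return The fix tibble with a `colony_km` column appended.
#' @export
colony_distance <- function(fixes, colony) {
  colony <- .as_colony(colony)
  fixes <- validate_track(fixes)
  fixes$colony_km <- haversine_km(fixes$lat, fixes$lon, colony[1], colony[2])
  fixes
}

.as_colony <- function(colony) {
  colony <- unlist(colony)
  if (length(colony) != 2 || !all(is.finite(colony))) {
    abort("colony must be two finite numbers (lat, lon)")
  }
  if (!is.null(names(colony)) && all(c("lat", "lon") %in% names(colony))) {
    colony <- colony[c("lat", "lon")]
  }
  unname(colony)
}

.segment_trips_one <- function(df, min_colony_km, min_duration_h, include_boundary) {
  away <- df$colony_km > min_colony_km
  seg <- if ("segment" %in% names(df)) df$segment else rep(1L, nrow(df))
  # data gaps end a run: we cannot certify the bird stayed away across a gap
  run_id <- cumsum(c(TRUE, diff(seg) != 0 | diff(away) != 0))
  trip <- rep(NA_integer_, nrow(df))
  k <- 0L
  for (r in split(seq_len(nrow(df)), run_id)) {
    if (!away[r[1]]) next
    dur_h <- as.numeric(difftime(df$time[r[length(r)]], df$time[r[1]], units = "hours"))
    if (dur_h > min_duration_h) {
      k <- k + 1L
      idx <- r
      if (include_boundary) {
        lo <- r[1] - 1L; hi <- r[length(r)] + 1L
        if (lo >= 1 && seg[lo] == seg[r[1]]) idx <- c(lo, idx)
        if (hi <= nrow(df) && seg[hi] == seg[r[length(r)]]) idx <- c(idx, hi)
      }
      trip[idx] <- k
    }
  }
  df$trip <- trip
  df
}

#' Segment a track into foraging trips
#'
#' Annotates each fix with a trip number. A trip is a maximal run of
#' consecutive fixes with colony distance strictly greater than
#' `min_colony_km` whose elapsed time (first to last fix of the run) is
#' strictly greater than `min_duration_h`. Runs are additionally broken at
#' resampling `segment` boundaries, i.e. across data gaps. By default the
#' colony-side crossing fixes are excluded from the trip;
#' `include_boundary = TRUE` adds them.
#'
#' @inheritParams colony_distance
#' @param min_colony_km,min_duration_h Trip thresholds; see [trip_rule()].
#' @param include_boundary Include the last fix before departure and the first
#'   after return in each trip.
#' @return The fix tibble with `colony_km` and an integer `trip` column
#'   (`NA` off-trip), trip numbers starting at 1 per individual.
#' @export
segment_trips <- function(fixes, colony, min_colony_km = 1, min_duration_h = 1,
                          include_boundary = FALSE) {
  if (min_colony_km <= 0 || min_duration_h <= 0) abort("trip thresholds must be > 0")
  fixes <- colony_distance(fixes, colony)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(~ .segment_trips_one(.x, min_colony_km, min_duration_h, include_boundary)) |>
    ungroup()
}

#' Per-trip foraging metrics
#'
#' For each trip: duration (first to last fix), total flight distance (sum of
#' step lengths between consecutive fixes inside the trip), maximum colony
#' distance, number of takeoffs (stationary-to-flight switches at the
#' `speed_threshold_kmh` ground-speed cutoff) and the takeoff frequency
#' (count divided by trip duration).
#'
#' @param fixes A fix tibble with `colony_km` and `trip` columns, as returned
#'   by [segment_trips()].
#' @param speed_threshold_kmh Flight/stationary ground-speed cutoff, km/h.
#' @return One row per (individual, trip) with columns `start_time`,
#'   `end_time`, `duration_h`, `total_flight_distance_km`,
#'   `max_colony_distance_km`, `n_takeoffs`, `takeoff_freq_per_h`.
#' @export
trip_metrics <- function(fixes, speed_threshold_kmh = 15) {
  if (!all(c("trip", "colony_km") %in% names(fixes))) {
    abort("fixes must carry `trip` and `colony_km`; run segment_trips() first")
  }
  on_trip <- filter(fixes, !is.na(.data$trip))
  if (nrow(on_trip) == 0) {
    return(tibble(
      individual_id = character(), trip = integer(),
      start_time = as.POSIXct(character(), tz = "UTC"),
      end_time = as.POSIXct(character(), tz = "UTC"),
      duration_h = double(), total_flight_distance_km = double(),
      max_colony_distance_km = double(), n_takeoffs = integer(),
      takeoff_freq_per_h = double()
    ))
  }
  on_trip |>
    group_by(.data$individual_id, .data$trip) |>
    group_modify(~ {
      dur <- as.numeric(difftime(max(.x$time), min(.x$time), units = "hours"))
      if (dur <= 0) abort("zero-duration trip; check segmentation thresholds")
      st <- .steps_one(.x)
      phases <- classify_flight(st$speed_kmh[!is.na(st$speed_kmh)],
                                threshold_kmh = speed_threshold_kmh)
      n_toff <- count_takeoffs(phases)
      tibble(
        start_time = min(.x$time), end_time = max(.x$time), duration_h = dur,
        total_flight_distance_km = sum(st$step_km, na.rm = TRUE),
        max_colony_distance_km = max(.x$colony_km),
        n_takeoffs = n_toff, takeoff_freq_per_h = n_toff / dur
      )
    }) |>
    ungroup()
}

#' Per-individual foraging metrics
#'
#' Aggregates trip metrics to one row per individual: trip counts, totals by
#' summation, the average maximum colony distance (sum of per-trip maxima over
#' the number of trips) and the average takeoff frequency as the *unweighted*
#' mean of per-trip frequencies (deliberately not total takeoffs over total
#' duration). Foraging duration and land use, when supplied, are joined in and
#' the percentage of foraging duration is computed against the logger-recorded
#' duration. Individuals with no qualifying trips are retained with zero
#' counts and missing (not zero) averages.
#'
#' @param trips A trip-metrics tibble from [trip_metrics()].
#' @param recorded A tibble `individual_id`, `recorded_duration_h` giving the
#'   logger-recorded duration per individual; defines the set of individuals
#'   reported.
#' @param foraging Optional tibble `individual_id`, `foraging_duration_h`
#'   from [foraging_phases()] summaries.
#' @param land Optional tibble `individual_id`, `pct_land` from
#'   [land_utilization()] (gulls only).
#' @return One row per individual with columns `n_trips`,
#'   `total_trip_duration_h`, `total_flight_distance_km`, `total_takeoffs`,
#'   `avg_max_distance_km`, `avg_takeoff_freq_per_h`, and when available
#'   `foraging_duration_h`, `pct_foraging`, `pct_land`.
#' @export
individual_metrics <- function(trips, recorded, foraging = NULL, land = NULL) {
  if (!all(c("individual_id", "recorded_duration_h") %in% names(recorded))) {
    abort("recorded must have individual_id and recorded_duration_h")
  }
  if (any(recorded$recorded_duration_h <= 0)) abort("recorded_duration_h must be > 0")
  per <- trips |>
    group_by(.data$individual_id) |>
    summarise(
      n_trips = n(),
      total_trip_duration_h = sum(.data$duration_h),
      total_flight_distance_km = sum(.data$total_flight_distance_km),
      total_takeoffs = sum(.data$n_takeoffs),
      avg_max_distance_km = sum(.data$max_colony_distance_km) / n(),
      avg_takeoff_freq_per_h = mean(.data$takeoff_freq_per_h),
      .groups = "drop"
    )
  out <- as_tibble(recorded) |>
    left_join(per, by = "individual_id") |>
    mutate(
      n_trips = coalesce(.data$n_trips, 0L),
      total_trip_duration_h = coalesce(.data$total_trip_duration_h, 0),
      total_flight_distance_km = coalesce(.data$total_flight_distance_km, 0),
      total_takeoffs = coalesce(.data$total_takeoffs, 0L)
    )
  if (!is.null(foraging)) {
    out <- left_join(out, as_tibble(foraging), by = "individual_id") |>
      mutate(pct_foraging = 100 * .data$foraging_duration_h / .data$recorded_duration_h)
  }
  if (!is.null(land)) {
    out <- left_join(out, as_tibble(land), by = "individual_id")
  }
  out
}
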