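# Flight-phase classification, takeoff counting and land-utilization
# percentages. Flight vs stationary is a simple ground-speed threshold
# (default 15 km/h); the boundary value itself counts as flight, a documented
# convention since equality is otherwise undefined.

#' Classify fixes as stationary or in flight
#'
#' @param speeds_kmh Ground speeds, km/h, finite and non-negative (`NA`
#'   allowed; propagated).
#' @param threshold_kmh Flight cutoff; speeds at or above it are `"flight"`,
#'   below it `"stationary"`.
#' @return Character vector of `"stationary"`/`"flight"`.
#' @export
classify_flight <- function(speeds_kmh, threshold_kmh = 15) {
  if (any(speeds_kmh < 0, na.rm = TRUE)) abort("negative ground speed")
  if (any(!is.finite(speeds_kmh) & !is.na(speeds_kmh))) abort("non-finite ground speed")
  ifelse(is.na(speeds_kmh), NA_character_,
         ifelse(speeds_kmh >= threshold_kmh, "flight", "stationary"))
}

#' Count takeoffs in a phase sequence
#'
#' A takeoff is a switch from `"stationary"` to `"flight"` between
#' consecutive points. A sequence that starts in flight contributes no
#' initial takeoff; `NA` phases break adjacency.
#'
#' @param phases Character vector of `"stationary"`/`"flight"`.
#' @return Integer count.
#' @export
count_takeoffs <- function(phases) {
  if (length(phases) == 0) abort("empty phase sequence")
  if (length(phases) == 1) return(0L)
  a <- phases[-length(phases)]
  b <- phases[-1]
  sum(a == "stationary" & b == "flight", na.rm = TRUE)
}

#' Read a land mask from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, a `Feature`, or a
#' `FeatureCollection` of them (WGS84 coordinates). The mask is stored as a
#' list of polygons, each a list of rings (outer ring first, holes after).
#'
#' @param path Path to a GeoJSON file.
#' @return An object of class `ox_land_mask`.
#' @export
read_land_mask <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- .collect_polygons(gj)
  if (length(polys) == 0) abort("no Polygon/MultiPolygon geometry found")
  structure(list(polygons = polys), class = "ox_land_mask")
}

.collect_polygons <- function(g) {
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  switch(g$type,
    FeatureCollection = unlist(lapply(g$features, .collect_polygons), recursive = FALSE),
    Feature = .collect_polygons(g$geometry),
    Polygon = list(lapply(g$coordinates, ring_mat)),
    MultiPolygon = lapply(g$coordinates, function(p) lapply(p, ring_mat)),
    abort(paste0("unsupported GeoJSON type: ", g$type))
  )
}

# Even-odd point-in-polygon over a set of rings (holes handled naturally);
# points exactly on a ring edge count as inside.
.pip_rings <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (ring in rings) {
    x <- ring[, "lon"]; y <- ring[, "lat"]
    n <- nrow(ring)
    if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
    for (k in seq_len(n - 1)) {
      x1 <- x[k]; y1 <- y[k]; x2 <- x[k + 1]; y2 <- y[k + 1]
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses & !is.na(crosses))
      cr <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
      scale <- max(abs(c(x1, y1, x2, y2, 1)))
      on_seg <- abs(cr) <= 1e-12 * scale &
        lon >= pmin(x1, x2) - 1e-12 & lon <= pmax(x1, x2) + 1e-12 &
        lat >= pmin(y1, y2) - 1e-12 & lat <= pmax(y1, y2) + 1e-12
      on_edge <- on_edge | on_seg
    }
  }
  inside | on_edge
}

#' Test points against a land mask
#'
#' @param lon,lat Point coordinates, decimal degrees.
#' @param mask An `ox_land_mask` from [read_land_mask()].
#' @return Logical vector: `TRUE` where a point lies inside (or on the
#'   boundary of) any mask polygon.
#' @export
point_on_land <- function(lon, lat, mask) {
  stopifnot(inherits(mask, "ox_land_mask"))
  out <- rep(FALSE, length(lon))
  for (poly in mask$polygons) out <- out | .pip_rings(lon, lat, poly)
  out
}

#' Land-utilization percentage during foraging trips
#'
#' On a 1-minute resampled, trip-annotated track, computes per individual
#' `100 * (trip fixes in flight phase over land) / (all trip fixes)`. The
#' numerator counts only flight-phase fixes by default; set
#' `numerator = "all"` to count every over-land trip fix instead (both
#' readings of the metric are plausible and the choice is exposed).
#'
#' @param fixes A 1-min resampled fix tibble annotated by [segment_trips()].
#' @param mask An `ox_land_mask`.
#' @param speed_threshold_kmh Flight cutoff for the numerator, km/h.
#' @param numerator `"flight"` (flight-phase fixes over land) or `"all"`
#'   (any trip fix over land).
#' @return A tibble `individual_id`, `pct_land` (in `[0, 100]`; `NA` for
#'   individuals with no trip fixes).
#' @export
land_utilization <- function(fixes, mask, speed_threshold_kmh = 15,
                             numerator = c("flight", "all")) {
  numerator <- match.arg(numerator)
  if (!"trip" %in% names(fixes)) abort("fixes must carry `trip`; run segment_trips() first")
  st <- track_steps(fixes)
  st$phase <- classify_flight(st$speed_kmh, threshold_kmh = speed_threshold_kmh)
  st$on_land <- point_on_land(st$lon, st$lat, mask)
  st |>
    filter(!is.na(.data$trip)) |>
    group_by(.data$individual_id) |>
    summarise(
      pct_land = if (n() == 0) NA_real_ else {
        num <- if (numerator == "flight") {
          sum(.data$on_land & !is.na(.data$phase) & .data$phase == "flight")
        } else {
          sum(.data$on_land)
        }
        100 * num / n()
      },
      .groups = "drop"
    )
}
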