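# Synthetic-data generator with known ground truth. Tracks are produced by a
# three-state switching movement model around a breeding colony: excursions
# (outbound transit, a foraging bout at a distant site, return transit)
# alternate with colony dwell, so trip counts, behavioural states and
# per-individual covariates are all known. Assay values are linearly driven
# by the behavioural covariates with Gaussian noise and interval censoring at
# the analyzer detection limits.

#' Default "true" movement model for simulation
#'
#' State-dependent step distributions at the GPS sampling interval, derived
#' from per-state ground speeds typical of the two species: resting drift
#' ~0.6 km/h, tortuous foraging ~9 km/h, directed flight ~30 km/h (safely
#' under the 90 km/h spike filter). The foraging state has the lowest
#' angular concentration (widest turns), flight the highest.
#'
#' @param interval_min GPS sampling interval, minutes.
#' @return An `ox_hmm_model` (K = 3, states ordered resting, foraging,
#'   flight).
#' @export
default_true_hmm <- function(interval_min = 1) {
  dt_h <- interval_min / 60
  speeds <- c(0.6, 9, 30) # km/h: resting, foraging, flight
  hmm_model(
    step_mean = speeds * dt_h,
    step_sd = speeds * dt_h * c(0.8, 0.5, 0.25),
    angle_mean = c(0, 0, 0),
    angle_kappa = c(0.7, 0.3, 15),
    tpm = matrix(c(0.95, 0.04, 0.01,
                   0.02, 0.96, 0.02,
                   0.02, 0.08, 0.90), 3, 3, byrow = TRUE),
    delta = c(0.6, 0.3, 0.1)
  )
}

#' Species defaults for the trip generator
#'
#' Colony coordinates (Kabushima for gulls, Awashima for shearwaters), GPS
#' interval, trip geometry and bout durations scaled to each species'
#' central-place foraging style.
#'
#' @param species `"gull"` or `"shearwater"`.
#' @return A list of generator settings.
#' @export
sim_species_defaults <- function(species = c("gull", "shearwater")) {
  species <- match.arg(species)
  if (species == "gull") {
    list(
      colony = c(lat = 40.533, lon = 141.558), interval_min = 1,
      trip_range_km = 25, forage_h = 2.5, dwell_h = 3,
      restlessness = 1, duration_days = 7
    )
  } else {
    list(
      colony = c(lat = 38.467, lon = 139.233), interval_min = 5,
      trip_range_km = 120, forage_h = 14, dwell_h = 10,
      restlessness = 1, duration_days = 7
    )
  }
}

.sim_track_one <- function(id, species, cfg, model, start_time) {
  n <- ceiling(cfg$duration_days * 24 * 60 / cfg$interval_min) + 1L
  dt_h <- cfg$interval_min / 60
  col_lat <- unname(cfg$colony[["lat"]]); col_lon <- unname(cfg$colony[["lon"]])
  lat <- lon <- numeric(n)
  state <- integer(n)
  trip_no <- integer(n)
  lat[1] <- col_lat; lon[1] <- col_lon
  state[1] <- 1L
  mode <- "dwell"
  dwell_left <- stats::rexp(1, 1 / cfg$dwell_h)
  forage_left <- 0
  heading <- runif(1, -pi, pi)
  site <- NULL
  trips_done <- 0L
  sr <- lapply(seq_len(3), function(k) .gamma_shape_rate(model$step_mean[k], model$step_sd[k]))
  draw_step <- function(k) rgamma(1, shape = sr[[k]]$shape, rate = sr[[k]]$rate)
  for (i in seq_len(n - 1)) {
    d_col <- haversine_km(lat[i], lon[i], col_lat, col_lon)
    if (mode == "dwell") {
      s <- 1L
      step <- draw_step(1L)
      heading <- if (d_col > 0.2) {
        bearing_rad(lat[i], lon[i], col_lat, col_lon)
      } else runif(1, -pi, pi)
      dwell_left <- dwell_left - dt_h
      if (dwell_left <= 0) {
        mode <- "out"
        ang <- runif(1, -pi, pi)
        dist <- max(cfg$trip_range_km * exp(rnorm(1, 0, 0.25)), 2)
        p <- .advance_position(col_lat, col_lon, dist, ang)
        site <- c(lat = p$lat, lon = p$lon)
      }
    } else if (mode == "out") {
      s <- 3L
      step <- draw_step(3L)
      heading <- bearing_rad(lat[i], lon[i], site["lat"], site["lon"]) +
        .rvm(1, 0, 25)
      if (haversine_km(lat[i], lon[i], site["lat"], site["lon"]) < 1.5) {
        mode <- "forage"
        forage_left <- stats::rexp(1, 1 / cfg$forage_h)
        s <- 2L
      }
    } else if (mode == "forage") {
      # Markov switching among the three states while at the foraging site;
      # individual restlessness scales the foraging-to-flight switching rate
      s_prev <- state[i]
      pr <- model$tpm[s_prev, ]
      if (s_prev == 2L) {
        p23 <- min(0.5, pr[3] * cfg$restlessness)
        pr <- c(pr[1], 1 - pr[1] - p23, p23)
      }
      s <- sample.int(3L, 1, prob = pr)
      step <- draw_step(s)
      turn <- .rvm(1, model$angle_mean[s], model$angle_kappa[s])
      heading <- wrap_angle(heading - turn)
      # weak tether keeps the bout near the site
      if (haversine_km(lat[i], lon[i], site["lat"], site["lon"]) > 6) {
        heading <- bearing_rad(lat[i], lon[i], site["lat"], site["lon"]) + .rvm(1, 0, 4)
      }
      forage_left <- forage_left - dt_h
      if (forage_left <= 0) mode <- "return"
    } else { # return
      s <- 3L
      step <- draw_step(3L)
      heading <- bearing_rad(lat[i], lon[i], col_lat, col_lon) +
        .rvm(1, 0, 25)
      if (d_col < 0.5) {
        mode <- "dwell"
        dwell_left <- stats::rexp(1, 1 / cfg$dwell_h)
        trips_done <- trips_done + 1L
        s <- 1L
      }
    }
    p <- .advance_position(lat[i], lon[i], step, heading)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
    state[i + 1] <- s
    trip_no[i + 1] <- if (mode %in% c("out", "forage", "return")) trips_done + 1L else 0L
  }
  state[1] <- state[2]
  tibble(
    individual_id = id,
    time = start_time + seq(0, by = cfg$interval_min * 60, length.out = n),
    lat = lat, lon = lon,
    true_state = state,
    true_trip = ifelse(trip_no == 0, NA_integer_, trip_no)
  )
}

#' Simulate colony-centric GPS tracks with known states
#'
#' Generates multi-trip trajectories for `n_individuals` central-place
#' foragers: behaviour switches among resting, foraging and flight with
#' gamma step lengths and von Mises turns, excursions are induced by an
#' outbound/return drift toward a randomly placed foraging site, and every
#' fix carries its true behavioural state and trip number. Optional dropout
#' deletes fixes at random to emulate logger outages. Per-individual
#' log-normal multipliers on trip range, foraging-bout length and colony
#' dwell give individuals genuinely different behavioural covariates.
#'
#' @param n_individuals Number of birds.
#' @param species `"gull"` or `"shearwater"` (sets colony, interval and trip
#'   geometry; see [sim_species_defaults()]).
#' @param seed RNG seed (required: simulations are reproducible by
#'   construction).
#' @param duration_days Deployment length in days.
#' @param dropout Probability that any non-endpoint fix is missing.
#' @param start_time Deployment start (POSIXct).
#' @param overrides Named list overriding [sim_species_defaults()] entries.
#' @return A list: `fixes` (with `true_state` and `true_trip` columns),
#'   `model` (the true `ox_hmm_model` at the sampling interval), `settings`,
#'   and `truth` (per-individual true trip counts).
#' @export
simulate_tracks <- function(n_individuals, species = "gull", seed,
                            duration_days = NULL, dropout = 0,
                            start_time = as.POSIXct("2021-05-10 00:00:00", tz = "UTC"),
                            overrides = list()) {
  set.seed(seed)
  cfg <- sim_species_defaults(species)
  cfg[names(overrides)] <- overrides
  if (!is.null(duration_days)) cfg$duration_days <- duration_days
  model <- default_true_hmm(cfg$interval_min)
  ids <- sprintf("%s%02d", if (species == "gull") "G" else "S", seq_len(n_individuals))
  fixes <- purrr::map_dfr(ids, function(id) {
    icfg <- cfg
    icfg$trip_range_km <- cfg$trip_range_km * exp(rnorm(1, 0, 0.5))
    icfg$forage_h <- cfg$forage_h * exp(rnorm(1, 0, 0.6))
    icfg$dwell_h <- cfg$dwell_h * exp(rnorm(1, 0, 0.7))
    icfg$restlessness <- exp(rnorm(1, 0, 0.6))
    .sim_track_one(id, species, icfg, model, start_time)
  })
  if (dropout > 0) {
    keep <- runif(nrow(fixes)) >= dropout
    # endpoints always retained so recorded duration is unchanged
    ends <- !duplicated(fixes$individual_id) |
      !duplicated(fixes$individual_id, fromLast = TRUE)
    fixes <- fixes[keep | ends, , drop = FALSE]
  }
  truth <- fixes |>
    group_by(.data$individual_id) |>
    summarise(true_n_trips = n_distinct(.data$true_trip, na.rm = TRUE), .groups = "drop")
  list(fixes = fixes, model = model, settings = cfg, species = species, truth = truth)
}

#' Simulate paired oxidative assay records
#'
#' Deploy-time d-ROMs and BAP levels are drawn from species-typical Gaussian
#' baselines; retrieve-time values add a linear effect of the individuals'
#' behavioural covariates plus Gaussian noise, so the generating coefficients
#' are known exactly. Values outside the analyzer detection ranges are
#' flagged per the censoring convention.
#'
#' @param metrics Per-individual behavioural metrics (from
#'   [individual_metrics()] run on the simulated tracks); covariate columns
#'   referenced by the effect vectors must be present.
#' @param seed RNG seed.
#' @param drom_effects,bap_effects Named numeric vectors of true effects on
#'   the change in d-ROMs (per U. CARR) and BAP (per uM/L); names are metric
#'   columns. Defaults: d-ROMs rises 0.06 U. CARR per km of flight distance;
#'   BAP rises 6 uM/L per foraging hour.
#' @param drom_intercept,bap_intercept True intercepts of the change models.
#' @param drom_sigma,bap_sigma Residual SDs of the changes.
#' @param baseline Species baseline list
#'   `list(drom = c(mean, sd), bap = c(mean, sd))`.
#' @param sex Optional named character vector of sexes per individual
#'   (`"F"`/`"M"`); defaults to alternating.
#' @return A list: `records` (long assay tibble with censor flags), `truth`
#'   (the generating coefficients) and `sex` table.
#' @export
simulate_assays <- function(metrics, seed,
                            drom_effects = c(total_flight_distance_km = 0.06),
                            bap_effects = c(foraging_duration_h = 35),
                            drom_intercept = -10, bap_intercept = 40,
                            drom_sigma = 30, bap_sigma = 300,
                            baseline = list(drom = c(130, 45), bap = c(1450, 320)),
                            sex = NULL) {
  set.seed(seed)
  n <- nrow(metrics)
  ids <- metrics$individual_id
  if (is.null(sex)) sex <- setNames(rep(c("F", "M"), length.out = n), ids)
  eff <- function(effects, intercept, sigma) {
    d <- rep(intercept, n)
    for (nm in names(effects)) {
      if (!nm %in% names(metrics)) abort(paste0("metric column not found: ", nm))
      d <- d + effects[[nm]] * metrics[[nm]]
    }
    d + rnorm(n, 0, sigma)
  }
  drom1 <- pmax(rnorm(n, baseline$drom[1], baseline$drom[2]), 1)
  bap1 <- pmax(rnorm(n, baseline$bap[1], baseline$bap[2]), 1)
  drom2 <- pmax(drom1 + eff(drom_effects, drom_intercept, drom_sigma), 1)
  bap2 <- pmax(bap1 + eff(bap_effects, bap_intercept, bap_sigma), 1)
  lim <- detection_limits()
  records <- bind_rows(
    tibble(individual_id = ids, timepoint = "deploy", drom_ucarr = drom1, bap_umol_l = bap1),
    tibble(individual_id = ids, timepoint = "retrieve", drom_ucarr = drom2, bap_umol_l = bap2)
  ) |>
    mutate(
      drom_censor = censor_flag(.data$drom_ucarr, lim$drom),
      bap_censor = censor_flag(.data$bap_umol_l, lim$bap),
      sex = unname(sex[.data$individual_id])
    ) |>
    arrange(.data$individual_id, .data$timepoint)
  list(records = records,
       truth = list(drom_effects = drom_effects, bap_effects = bap_effects,
                    drom_intercept = drom_intercept, bap_intercept = bap_intercept,
                    drom_sigma = drom_sigma, bap_sigma = bap_sigma),
       sex = tibble(individual_id = ids, sex = unname(sex[ids])))
}
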