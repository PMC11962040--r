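# Shared fixtures and independent oracles, all built in code.

# Build a fix tibble from time offsets (minutes) and coordinates.
make_fixes <- function(mins, lat, lon, id = "A",
                       t0 = as.POSIXct("2021-05-10 00:00:00", tz = "UTC")) {
  tibble::tibble(individual_id = id, time = t0 + mins * 60, lat = lat, lon = lon)
}

# Fixes placed at given distances (km) due north of a colony, at given
# time offsets in minutes.
make_radial_fixes <- function(mins, dist_km, id = "A",
                              colony = c(lat = 39, lon = 141)) {
  make_fixes(mins, lat = colony[["lat"]] + dist_km / 111.19493, lon = colony[["lon"]],
             id = id)
}

toy_colony <- c(lat = 39, lon = 141)

# ---- exhaustive HMM oracles (independent of the forward/Viterbi code) ----

# log emission densities computed from first principles
oracle_log_emissions <- function(model, steps, angles) {
  K <- model$K
  sapply(seq_len(K), function(k) {
    shape <- (model$step_mean[k] / model$step_sd[k])^2
    rate <- model$step_mean[k] / model$step_sd[k]^2
    ls <- dgamma(steps, shape = shape, rate = rate, log = TRUE)
    ls[is.na(steps)] <- 0
    kap <- model$angle_kappa[k]
    la <- kap * cos(angles - model$angle_mean[k]) - log(2 * pi * besselI(kap, 0))
    la[is.na(angles)] <- 0
    ls + la
  })
}

# sum over all K^T paths
oracle_loglik <- function(model, steps, angles) {
  K <- model$K
  Tn <- length(steps)
  logP <- oracle_log_emissions(model, steps, angles)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- log(model$delta)[paths[, 1]] + logP[cbind(1, paths[, 1])]
  if (Tn > 1) {
    for (t in 2:Tn) {
      lp <- lp + log(model$tpm)[cbind(paths[, t - 1], paths[, t])] +
        logP[cbind(t, paths[, t])]
    }
  }
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# argmax over all K^T paths
oracle_viterbi <- function(model, steps, angles) {
  K <- model$K
  Tn <- length(steps)
  logP <- oracle_log_emissions(model, steps, angles)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- log(model$delta)[paths[, 1]] + logP[cbind(1, paths[, 1])]
  if (Tn > 1) {
    for (t in 2:Tn) {
      lp <- lp + log(model$tpm)[cbind(paths[, t - 1], paths[, t])] +
        logP[cbind(t, paths[, t])]
    }
  }
  as.integer(paths[which.max(lp), ])
}

# a random valid 3-state model
random_hmm_model <- function() {
  K <- 3
  tpm <- matrix(rgamma(K * K, 1), K, K)
  tpm <- tpm / rowSums(tpm)
  delta <- rgamma(K, 1); delta <- delta / sum(delta)
  hmm_model(step_mean = sort(runif(K, 0.05, 6)),
            step_sd = runif(K, 0.05, 2),
            angle_mean = runif(K, -pi, pi),
            angle_kappa = runif(K, 0, 8),
            tpm = tpm, delta = delta)
}

# the well-separated reference model used in recovery checks
separated_model <- function() {
  hmm_model(step_mean = c(0.05, 1, 5), step_sd = c(0.04, 0.7, 1.5),
            angle_mean = c(0, 0, 0), angle_kappa = c(1, 0.5, 10),
            tpm = matrix(c(0.90, 0.05, 0.05,
                           0.10, 0.80, 0.10,
                           0.05, 0.15, 0.80), 3, 3, byrow = TRUE),
            delta = c(1, 1, 1) / 3)
}

# simulate observations respecting the likelihood's positive-step
# precondition (1 m floor, as applied by the fitting code)
sim_obs <- function(model, n) {
  obs <- simulate_hmm(model, n)
  obs$step_km <- pmax(obs$step_km, 1e-3)
  obs
}

sim_tracks_from_model <- function(model, n_tracks, len, seed) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_tracks), function(i) {
    s <- simulate_hmm(model, len)
    s$individual_id <- sprintf("t%02d", i)
    s
  }))
}

# unit square land polygon as a GeoJSON string
unit_square_geojson <- function(x0 = 0, y0 = 0, x1 = 1, y1 = 1) {
  sprintf('{"type":"Polygon","coordinates":[[[%f,%f],[%f,%f],[%f,%f],[%f,%f],[%f,%f]]]}',
          x0, y0, x1, y0, x1, y1, x0, y1, x0, y0)
}

write_mask <- function(geojson) {
  path <- withr::local_tempfile(fileext = ".geojson", .local_envir = parent.frame())
  writeLines(geojson, path)
  read_land_mask(path)
}
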