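# Three-state hidden Markov model for seabird movement: gamma-distributed step
# lengths and von Mises turning angles per state, fitted by Baum-Welch EM over
# multiple tracks sharing parameters, decoded globally by Viterbi. States are
# labelled resting / foraging / flight by ranking step-length means.

# ---- von Mises helpers -----------------------------------------------------

# log density; expon.scaled Bessel keeps large kappa finite
.dvm_log <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

# solve A1(kappa) = besselI(k,1)/besselI(k,0) = rbar for kappa
.vm_kappa <- function(rbar) {
  if (rbar < 1e-8) return(0)
  rbar <- min(rbar, 1 - 1e-8)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE) - rbar
  # A1 is increasing; bracket generously
  upper <- 2
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 4
  stats::uniroot(f, c(1e-10, upper), tol = 1e-10)$root
}

# von Mises sampler (Best & Fisher rejection); kappa = 0 falls back to uniform
.rvm <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(sign(u[3] - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

# weighted ML fit of a gamma distribution, returned as (mean, sd)
.gamma_wmle <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  s <- log(m) - sum(w * log(x))
  if (s < 1e-10) return(list(mean = m, sd = m / sqrt(1e6)))
  k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  g <- function(k) log(k) - digamma(k) - s
  lo <- k0 / 10; hi <- k0 * 10
  while (g(lo) < 0 && lo > 1e-10) lo <- lo / 10
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 10
  k <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(mean = m, sd = m / sqrt(k))
}

.gamma_shape_rate <- function(mean, sd) {
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

# ---- model object ----------------------------------------------------------

#' Construct a movement HMM
#'
#' Parameterizes a K-state hidden Markov model with gamma step-length
#' emissions, given as state means and standard deviations (km), and von
#' Mises turning-angle emissions (mean direction in radians, concentration
#' kappa).
#'
#' @param step_mean,step_sd Positive numeric vectors of length K, km.
#' @param angle_mean Mean turning angles in `(-pi, pi]`, length K.
#' @param angle_kappa Non-negative concentrations, length K.
#' @param tpm K x K row-stochastic transition probability matrix.
#' @param delta Initial state distribution (sums to 1); defaults to uniform.
#' @return An object of class `ox_hmm_model`.
#' @export
hmm_model <- function(step_mean, step_sd, angle_mean, angle_kappa, tpm,
                      delta = NULL) {
  K <- length(step_mean)
  if (length(step_sd) != K || length(angle_mean) != K || length(angle_kappa) != K) {
    abort("emission parameter vectors must share length K")
  }
  if (any(step_mean <= 0) || any(step_sd <= 0)) abort("gamma parameters must be > 0")
  if (any(angle_kappa < 0)) abort("kappa must be >= 0")
  tpm <- as.matrix(tpm)
  if (!all(dim(tpm) == K) || any(tpm < 0) ||
      any(abs(rowSums(tpm) - 1) > 1e-8)) {
    abort("tpm must be a K x K row-stochastic matrix")
  }
  if (is.null(delta)) delta <- rep(1 / K, K)
  if (length(delta) != K || any(delta < 0) || abs(sum(delta) - 1) > 1e-8) {
    abort("delta must be a length-K probability vector")
  }
  structure(list(K = K, step_mean = step_mean, step_sd = step_sd,
                 angle_mean = wrap_angle(angle_mean), angle_kappa = angle_kappa,
                 tpm = tpm, delta = delta),
            class = "ox_hmm_model")
}

# T x K matrix of log emission densities; NA angles contribute the step term
# only, NA steps contribute nothing (fully missing observation)
.hmm_log_emissions <- function(model, steps, angles) {
  K <- model$K
  Tn <- length(steps)
  out <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    sr <- .gamma_shape_rate(model$step_mean[k], model$step_sd[k])
    ls <- dgamma(steps, shape = sr$shape, rate = sr$rate, log = TRUE)
    ls[is.na(steps)] <- 0
    la <- .dvm_log(angles, model$angle_mean[k], model$angle_kappa[k])
    la[is.na(angles)] <- 0
    out[, k] <- ls + la
  }
  out
}

# scaled forward pass: returns log-likelihood plus normalized alphas and the
# per-step scaling constants (for the backward pass)
.hmm_forward <- function(model, logP) {
  Tn <- nrow(logP); K <- ncol(logP)
  mx <- apply(logP, 1, max)
  mx[!is.finite(mx)] <- 0
  P <- exp(logP - mx)
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  v <- model$delta * P[1, ]
  cvec[1] <- sum(v)
  if (cvec[1] <= 0) return(list(loglik = -Inf))
  alpha[1, ] <- v / cvec[1]
  for (t in seq_len(Tn)[-1]) {
    v <- (alpha[t - 1, ] %*% model$tpm)[1, ] * P[t, ]
    cvec[t] <- sum(v)
    if (cvec[t] <= 0) return(list(loglik = -Inf))
    alpha[t, ] <- v / cvec[t]
  }
  list(loglik = sum(log(cvec)) + sum(mx), alpha = alpha, cvec = cvec, P = P, mx = mx)
}

#' HMM log-likelihood of step/turn series
#'
#' Evaluates the log-likelihood of one or more step-length / turning-angle
#' series under a movement HMM by the scaled forward recursion. Missing
#' turning angles (sequence endpoints, post-gap points) contribute step-only
#' emission terms.
#'
#' @param model An `ox_hmm_model`.
#' @param data A data frame with columns `step_km` and `turn_rad`, and
#'   optionally `individual_id`/`segment` identifying independent series.
#' @return Total log-likelihood (sum over series).
#' @export
hmm_loglik <- function(model, data) {
  stopifnot(inherits(model, "ox_hmm_model"))
  tracks <- .split_tracks(data)
  sum(vapply(tracks, function(tr) {
    logP <- .hmm_log_emissions(model, tr$step_km, tr$turn_rad)
    .hmm_forward(model, logP)$loglik
  }, numeric(1)))
}

.split_tracks <- function(data) {
  data <- as_tibble(data)
  if (!all(c("step_km", "turn_rad") %in% names(data))) {
    abort("data needs columns step_km and turn_rad")
  }
  keys <- intersect(c("individual_id", "segment"), names(data))
  # rows with missing step length (trailing fixes) are dropped per series
  if (length(keys) == 0) {
    tracks <- list(data)
  } else {
    tracks <- data |> group_by(across(all_of(keys))) |> group_split()
  }
  tracks <- lapply(tracks, function(tr) tr[!is.na(tr$step_km), , drop = FALSE])
  tracks[vapply(tracks, nrow, integer(1)) > 0]
}

# ---- EM fitting ------------------------------------------------------------

.em_estep <- function(model, tracks) {
  K <- model$K
  ll <- 0
  g_list <- vector("list", length(tracks))
  xi_sum <- matrix(0, K, K)
  delta_acc <- rep(0, K)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    logP <- .hmm_log_emissions(model, tr$step_km, tr$turn_rad)
    fw <- .hmm_forward(model, logP)
    if (!is.finite(fw$loglik)) return(list(loglik = -Inf))
    Tn <- nrow(logP)
    beta <- matrix(0, Tn, K)
    beta[Tn, ] <- 1
    if (Tn > 1) {
      for (t in (Tn - 1):1) {
        beta[t, ] <- (model$tpm %*% (fw$P[t + 1, ] * beta[t + 1, ]))[, 1] / fw$cvec[t + 1]
      }
    }
    gam <- fw$alpha * beta
    gam <- gam / rowSums(gam)
    if (Tn > 1) {
      # sum_t alpha_t (x) (P_{t+1} * beta_{t+1} / c_{t+1}), elementwise * tpm
      W <- fw$P[-1, , drop = FALSE] * beta[-1, , drop = FALSE] / fw$cvec[-1]
      xi_sum <- xi_sum + crossprod(fw$alpha[-Tn, , drop = FALSE], W) * model$tpm
    }
    ll <- ll + fw$loglik
    g_list[[i]] <- gam
    delta_acc <- delta_acc + gam[1, ]
  }
  list(loglik = ll, gammas = g_list, xi_sum = xi_sum,
       delta = delta_acc / length(tracks))
}

.em_mstep <- function(tracks, es, K) {
  gam_all <- do.call(rbind, es$gammas)
  steps <- unlist(lapply(tracks, `[[`, "step_km"))
  angles <- unlist(lapply(tracks, `[[`, "turn_rad"))
  step_mean <- step_sd <- angle_mean <- angle_kappa <- numeric(K)
  for (k in seq_len(K)) {
    w <- gam_all[, k]
    gp <- .gamma_wmle(steps, w)
    step_mean[k] <- gp$mean; step_sd[k] <- gp$sd
    obs <- !is.na(angles)
    wa <- w[obs]; aa <- angles[obs]
    Cs <- sum(wa * cos(aa)); Ss <- sum(wa * sin(aa))
    angle_mean[k] <- atan2(Ss, Cs)
    rbar <- sqrt(Cs^2 + Ss^2) / sum(wa)
    angle_kappa[k] <- min(.vm_kappa(rbar), 1e4)
  }
  tpm <- es$xi_sum / rowSums(es$xi_sum)
  hmm_model(step_mean, step_sd, angle_mean, angle_kappa, tpm, es$delta / sum(es$delta))
}

.init_model <- function(tracks, K, jitter = FALSE) {
  steps <- unlist(lapply(tracks, `[[`, "step_km"))
  qs <- quantile(steps, probs = seq(0, 1, length.out = K + 1), names = FALSE)
  grp <- cut(steps, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < K) grp <- sample(seq_len(K), length(steps), replace = TRUE)
  step_mean <- tapply(steps, grp, mean)
  step_sd <- pmax(tapply(steps, grp, sd), 1e-4)
  step_sd[is.na(step_sd)] <- step_mean[is.na(step_sd)]
  if (jitter) {
    step_mean <- step_mean * exp(rnorm(K, 0, 0.3))
    step_sd <- step_sd * exp(rnorm(K, 0, 0.3))
  }
  tpm <- if (K == 1) matrix(1, 1, 1) else {
    m <- matrix(0.1 / (K - 1), K, K); diag(m) <- 0.9; m
  }
  hmm_model(as.numeric(step_mean), as.numeric(step_sd),
            rep(0, K), runif(K, 0.3, if (jitter) 3 else 1.2),
            tpm, rep(1 / K, K))
}

#' Fit a movement HMM by EM
#'
#' Baum-Welch estimation of a K-state HMM with gamma step-length and von
#' Mises turning-angle emissions, over one or more tracks contributing
#' independent forward passes that share parameters. The M-step uses exact
#' weighted maximum likelihood for both emission families, so the
#' log-likelihood trace is monotonically non-decreasing. Fitting restarts
#' from jittered tercile-moment initial values and keeps the best
#' log-likelihood; step lengths are floored at `step_floor_km` to keep the
#' gamma density finite at rest.
#'
#' @inheritParams hmm_loglik
#' @param K Number of states (default 3: resting, foraging, flight).
#' @param n_restarts Number of random restarts beyond the moment-based start.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Optional RNG seed for restarts.
#' @param step_floor_km Lower floor applied to step lengths (default 1 m).
#' @param min_obs Minimum number of observations required.
#' @param min_weight A state capturing less than this fraction of total
#'   posterior weight triggers a warning and a restart.
#' @return An object of class `ox_hmm`: the fitted `model`, `loglik`, the EM
#'   `trace`, `n_obs`, the training `data`, and `labels` mapping state index
#'   to behaviour (see [label_states()]).
#' @export
fit_hmm <- function(data, K = 3, n_restarts = 10, max_iter = 200, tol = 1e-6,
                    seed = NULL, step_floor_km = 0.001, min_obs = 50,
                    min_weight = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  tracks <- .split_tracks(data)
  tracks <- lapply(tracks, function(tr) {
    tr$step_km <- pmax(tr$step_km, step_floor_km)
    tr
  })
  n_obs <- sum(vapply(tracks, nrow, integer(1)))
  if (n_obs < min_obs) abort(sprintf("need at least %d observations, got %d", min_obs, n_obs))

  run_em <- function(model) {
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      es <- .em_estep(model, tracks)
      if (!is.finite(es$loglik)) return(NULL)
      trace <- c(trace, es$loglik)
      wfrac <- colSums(do.call(rbind, es$gammas)) / n_obs
      if (any(wfrac < min_weight)) {
        warn("HMM state collapsed below minimum weight; restarting")
        return(NULL)
      }
      model_new <- .em_mstep(tracks, es, K)
      if (it > 1 && abs(trace[it] - trace[it - 1]) <
            tol * (abs(trace[it - 1]) + 1e-12)) {
        model <- model_new
        break
      }
      model <- model_new
    }
    list(model = model, loglik = trace[length(trace)], trace = trace)
  }

  best <- NULL
  for (r in seq_len(1 + n_restarts)) {
    init <- .init_model(tracks, K, jitter = r > 1)
    res <- tryCatch(run_em(init), error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$loglik > best$loglik)) best <- res
  }
  if (is.null(best)) abort("all EM restarts failed or collapsed")

  # canonical state order: ascending mean step length
  ord <- order(best$model$step_mean)
  m <- best$model
  model <- hmm_model(m$step_mean[ord], m$step_sd[ord], m$angle_mean[ord],
                     m$angle_kappa[ord], m$tpm[ord, ord, drop = FALSE], m$delta[ord])
  fit <- structure(list(model = model, loglik = best$loglik, trace = best$trace,
                        n_obs = n_obs, K = K, data = as_tibble(data)),
                   class = "ox_hmm")
  fit$labels <- if (K == 3) label_states(model) else NULL
  fit
}

#' Label HMM states as resting / foraging / flight
#'
#' States are ranked by mean step length: smallest is resting, middle is
#' foraging, largest is flight. As a consistency check, the foraging state is
#' expected to have the lowest angular concentration (largest turning
#' angles); a warning is raised if the fitted kappas violate that pattern,
#' but labels still follow step length.
#'
#' @param model A 3-state `ox_hmm_model`.
#' @return Character vector of length 3 mapping raw state index to label.
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "ox_hmm_model"))
  if (model$K != 3) abort("state labelling is defined for K = 3")
  if (anyDuplicated(model$step_mean)) abort("tied state step-length means; labels undefined")
  ord <- order(model$step_mean)
  labels <- character(3)
  labels[ord] <- c("resting", "foraging", "flight")
  if (which.min(model$angle_kappa) != ord[2]) {
    warn("foraging state does not have the lowest angular concentration; labels follow step length")
  }
  labels
}

#' Viterbi decoding
#'
#' Computes the jointly most probable state path for each track under a
#' fitted model.
#'
#' @param model An `ox_hmm_model` (or an `ox_hmm` fit, whose model is used).
#' @inheritParams hmm_loglik
#' @return Integer vector of raw state indices, aligned with the rows of
#'   `data` (`NA` where the step length is missing).
#' @export
hmm_viterbi <- function(model, data) {
  if (inherits(model, "ox_hmm")) model <- model$model
  stopifnot(inherits(model, "ox_hmm_model"))
  data <- as_tibble(data)
  keys <- intersect(c("individual_id", "segment"), names(data))
  grp <- if (length(keys)) interaction(data[keys], drop = TRUE) else factor(rep(1, nrow(data)))
  out <- rep(NA_integer_, nrow(data))
  for (g in levels(grp)) {
    sel <- which(grp == g & !is.na(data$step_km))
    if (!length(sel)) next
    out[sel] <- .viterbi_one(model, data$step_km[sel], data$turn_rad[sel])
  }
  out
}

.viterbi_one <- function(model, steps, angles) {
  if (length(steps) == 0) abort("empty sequence")
  logP <- .hmm_log_emissions(model, steps, angles)
  Tn <- nrow(logP); K <- ncol(logP)
  ltpm <- log(model$tpm)
  v <- log(model$delta) + logP[1, ]
  back <- matrix(0L, Tn, K)
  for (t in seq_len(Tn)[-1]) {
    cand <- v + ltpm # K x K: previous state in rows
    back[t, ] <- apply(cand, 2, which.max)
    v <- apply(cand, 2, max) + logP[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(v)
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Decode behavioural states along a track
#'
#' Attaches decoded state indices and behaviour labels to a step series,
#' using global (Viterbi) or local (posterior-maximum) decoding.
#'
#' @param fit An `ox_hmm` fit.
#' @param data Step series to decode; defaults to the training data.
#' @param method `"viterbi"` (default) or `"local"`.
#' @return `data` with columns `state` (raw index) and `label` appended.
#' @export
decode_states <- function(fit, data = fit$data, method = c("viterbi", "local")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "ox_hmm"))
  data <- as_tibble(data)
  if (method == "viterbi") {
    data$state <- hmm_viterbi(fit$model, data)
  } else {
    data$state <- .local_decode(fit$model, data)
  }
  data$label <- if (!is.null(fit$labels)) fit$labels[data$state] else as.character(data$state)
  data
}

.local_decode <- function(model, data) {
  keys <- intersect(c("individual_id", "segment"), names(data))
  grp <- if (length(keys)) interaction(data[keys], drop = TRUE) else factor(rep(1, nrow(data)))
  out <- rep(NA_integer_, nrow(data))
  for (g in levels(grp)) {
    sel <- which(grp == g & !is.na(data$step_km))
    if (!length(sel)) next
    logP <- .hmm_log_emissions(model, data$step_km[sel], data$turn_rad[sel])
    fw <- .hmm_forward(model, logP)
    Tn <- nrow(logP); K <- ncol(logP)
    beta <- matrix(0, Tn, K); beta[Tn, ] <- 1
    if (Tn > 1) for (t in (Tn - 1):1) {
      beta[t, ] <- (model$tpm %*% (fw$P[t + 1, ] * beta[t + 1, ]))[, 1] / fw$cvec[t + 1]
    }
    out[sel] <- max.col(fw$alpha * beta)
  }
  out
}

#' Foraging phases and duration
#'
#' A foraging phase is a maximal run of consecutive fixes decoded as
#' `"foraging"` with at least `run_min` points; its duration is the time from
#' the first to the last point of the run. Runs never span resampling
#' segments.
#'
#' @param decoded A decoded step series from [decode_states()], with `time`
#'   and `label` columns.
#' @param run_min Minimum run length in points (default 2; a 1-point run has
#'   zero duration).
#' @return A tibble of phases: `individual_id`, `start_time`, `end_time`,
#'   `n_points`, `duration_h`.
#' @export
foraging_phases <- function(decoded, run_min = 2) {
  if (!all(c("time", "label") %in% names(decoded))) {
    abort("decoded data needs time and label columns")
  }
  keys <- intersect(c("individual_id", "segment"), names(decoded))
  decoded |>
    group_by(across(all_of(keys))) |>
    group_modify(~ {
      f <- !is.na(.x$label) & .x$label == "foraging"
      r <- rle(f)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values & r$lengths >= run_min
      tibble(
        start_time = .x$time[starts[keep]],
        end_time = .x$time[ends[keep]],
        n_points = r$lengths[keep]
      )
    }) |>
    ungroup() |>
    mutate(duration_h = as.numeric(difftime(.data$end_time, .data$start_time, units = "hours"))) |>
    select(any_of(c("individual_id", "segment")), everything())
}

#' Summarise foraging duration per individual
#'
#' @param phases A phase tibble from [foraging_phases()].
#' @param individual_ids Optional character vector of individuals to report;
#'   individuals without phases get zero duration.
#' @return A tibble `individual_id`, `foraging_duration_h`.
#' @export
foraging_duration <- function(phases, individual_ids = NULL) {
  out <- phases |>
    group_by(.data$individual_id) |>
    summarise(foraging_duration_h = sum(.data$duration_h), .groups = "drop")
  if (!is.null(individual_ids)) {
    out <- tibble(individual_id = individual_ids) |>
      left_join(out, by = "individual_id") |>
      mutate(foraging_duration_h = coalesce(.data$foraging_duration_h, 0))
  }
  out
}

#' Simulate a step/turn series from an HMM
#'
#' @param model An `ox_hmm_model`.
#' @param n Number of observations.
#' @param seed Optional RNG seed.
#' @return A tibble `state`, `step_km`, `turn_rad`.
#' @export
simulate_hmm <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "ox_hmm_model"))
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  states <- integer(n)
  states[1] <- sample.int(K, 1, prob = model$delta)
  for (t in seq_len(n)[-1]) {
    states[t] <- sample.int(K, 1, prob = model$tpm[states[t - 1], ])
  }
  steps <- turns <- numeric(n)
  for (k in seq_len(K)) {
    idx <- which(states == k)
    if (!length(idx)) next
    sr <- .gamma_shape_rate(model$step_mean[k], model$step_sd[k])
    steps[idx] <- rgamma(length(idx), shape = sr$shape, rate = sr$rate)
    turns[idx] <- .rvm(length(idx), model$angle_mean[k], model$angle_kappa[k])
  }
  tibble(state = states, step_km = steps, turn_rad = turns)
}

# ---- broom-style methods ---------------------------------------------------

#' @method tidy ox_hmm
#' @export
tidy.ox_hmm <- function(x, ...) {
  m <- x$model
  tibble(
    state = seq_len(m$K),
    label = if (!is.null(x$labels)) x$labels else as.character(seq_len(m$K)),
    step_mean_km = m$step_mean, step_sd_km = m$step_sd,
    angle_mean_rad = m$angle_mean, angle_kappa = m$angle_kappa
  )
}

#' @method glance ox_hmm
#' @export
glance.ox_hmm <- function(x, ...) {
  m <- x$model
  # free parameters: 4 per state emissions + K(K-1) transitions + K-1 initial
  p <- 4 * m$K + m$K * (m$K - 1) + (m$K - 1)
  tibble(K = m$K, n_obs = x$n_obs, logLik = x$loglik,
         AIC = -2 * x$loglik + 2 * p, n_iter = length(x$trace))
}

#' @method print ox_hmm
#' @export
print.ox_hmm <- function(x, ...) {
  cat(sprintf("Movement HMM: %d states, %d observations, logLik %.2f\n",
              x$model$K, x$n_obs, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' Plot fitted HMM state-dependent distributions
#'
#' Shows the fitted gamma step-length densities per state over a histogram of
#' the training steps.
#'
#' @param object An `ox_hmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ox_hmm
#' @export
autoplot.ox_hmm <- function(object, ...) {
  m <- object$model
  steps <- object$data$step_km[!is.na(object$data$step_km)]
  grid <- seq(1e-4, quantile(steps, 0.99), length.out = 300)
  dens <- purrr::map_dfr(seq_len(m$K), function(k) {
    sr <- .gamma_shape_rate(m$step_mean[k], m$step_sd[k])
    tibble(state = if (!is.null(object$labels)) object$labels[k] else as.character(k),
           step_km = grid,
           density = dgamma(grid, shape = sr$shape, rate = sr$rate))
  })
  ggplot() +
    geom_histogram(data = tibble(step_km = steps),
                   aes(x = .data$step_km, y = after_stat(density)),
                   bins = 60, fill = "grey85", colour = "grey70") +
    geom_line(data = dens,
              aes(x = .data$step_km, y = .data$density, colour = .data$state),
              linewidth = 0.8) +
    labs(x = "step length (km)", y = "density", colour = "state") +
    theme_minimal()
}
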