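test_that("changes are retrieve minus deploy and unpaired birds stay missing", {
  rec <- tibble::tribble(
    ~individual_id, ~timepoint, ~drom_ucarr, ~bap_umol_l,
    "A", "deploy", 100, 1500,
    "A", "retrieve", 90, 1400,
    "B", "deploy", 120, 2000,
    "B", "retrieve", 120, 2000,
    "C", "deploy", 80, 1700
  )
  ch <- compute_changes(rec)
  expect_equal(ch$delta_drom[ch$individual_id == "A"], -10)
  expect_equal(ch$delta_bap[ch$individual_id == "A"], -100)
  expect_equal(ch$delta_drom[ch$individual_id == "B"], 0)
  expect_true(is.na(ch$delta_drom[ch$individual_id == "C"]))
  dup <- dplyr::bind_rows(rec, tibble::tibble(individual_id = "A", timepoint = "deploy",
                                              drom_ucarr = 1, bap_umol_l = 1))
  expect_error(compute_changes(dup), "duplicate")
})

test_that("Carratelli unit conversion is exact", {
  expect_identical(ucarr_to_mg_h2o2_dl(1), 0.08)
  expect_identical(ucarr_to_mg_h2o2_dl(0), 0)
  expect_equal(ucarr_to_mg_h2o2_dl(131.52), 10.5216)
  expect_error(ucarr_to_mg_h2o2_dl(-1), "non-negative")
})

test_that("censor flags follow the detection-limit convention", {
  lim <- detection_limits()
  expect_equal(lim$drom[["lower"]], 40)
  expect_equal(lim$drom[["upper"]], 1000)
  expect_equal(lim$bap[["lower"]], 500)
  expect_equal(lim$bap[["upper"]], 6000)
  expect_equal(censor_flag(c(39, 40, 41, 999, 1000, 1200), lim$drom),
               c("below_lower", "below_lower", "in_range", "in_range",
                 "above_upper", "above_upper"))
})

test_that("uncensored Tobit equals OLS and intercept-only gives the mean", {
  set.seed(3)
  n <- 120
  d <- tibble::tibble(x = rnorm(n), y = 2 + 3 * rnorm(n) + rnorm(n))
  d$y <- 200 + 5 * d$x + rnorm(n, 0, 3) # all safely inside (40, 1000)
  fit <- tobit_fit(d, y ~ x, limits = c(40, 1000))
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(sum(resid(ols)^2) / n), tolerance = 1e-6)
  expect_equal(fit$n_censored_low + fit$n_censored_high, 0)

  i0 <- tobit_fit(d, y ~ 1, limits = c(40, 1000))
  expect_equal(unname(i0$coefficients), mean(d$y), tolerance = 1e-8)

  # unbounded limits reproduce the linear fit on censor-prone data too
  d$y2 <- 45 + 5 * d$x + rnorm(n, 0, 10)
  f_inf <- tobit_fit(d, y2 ~ x, limits = c(-Inf, Inf))
  expect_equal(unname(f_inf$coefficients), unname(coef(lm(y2 ~ x, d))),
               tolerance = 1e-6)
})

test_that("Tobit recovers truth under censoring and matches survreg", {
  skip_if_not_installed("survival")
  set.seed(17)
  n <- 500
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n) # ~20% below L for L chosen at the 20% quantile
  L <- unname(quantile(y, 0.2))
  d <- tibble::tibble(x = x, y = pmax(y, L))
  fit <- tobit_fit(d, y ~ x, limits = c(L, Inf))
  expect_gt(fit$n_censored_low / n, 0.15)
  # truth within 3 standard errors
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 2) / fit$se[["(Intercept)"]], 3)
  expect_lt(abs(fit$coefficients[["x"]] - 3) / fit$se[["x"]], 3)
  # independent censored-regression oracle
  sv <- survival::survreg(
    survival::Surv(d$y, d$y > L, type = "left") ~ x,
    data = d, dist = "gaussian",
    control = survival::survreg.control(rel.tolerance = 1e-12, iter.max = 200)
  )
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
})

test_that("the Tobit optimum is a local maximum of the censored likelihood", {
  set.seed(29)
  n <- 300
  x <- rnorm(n)
  y <- pmin(pmax(1 + 2 * x + rnorm(n), -2), 4)
  d <- tibble::tibble(x = x, y = y)
  fit <- tobit_fit(d, y ~ x, limits = c(-2, 4))
  ll_at <- function(beta, sigma) {
    mu <- beta[1] + beta[2] * x
    unc <- y > -2 & y < 4
    sum(dnorm(y[unc], mu[unc], sigma, log = TRUE)) +
      sum(pnorm((-2 - mu[y <= -2]) / sigma, log.p = TRUE)) +
      sum(pnorm((mu[y >= 4] - 4) / sigma, log.p = TRUE))
  }
  best <- ll_at(fit$coefficients, fit$sigma)
  expect_equal(best, fit$logLik, tolerance = 1e-8)
  for (k in 1:200) {
    pert <- ll_at(fit$coefficients + rnorm(2, 0, 0.05),
                  fit$sigma * exp(rnorm(1, 0, 0.05)))
    expect_gt(best, pert)
  }
  # one-sided full censoring is rejected
  d2 <- tibble::tibble(x = x, y = rep(-2, n))
  expect_error(tobit_fit(d2, y ~ x, limits = c(-2, 4)), "censored")
})

test_that("linear fit matches group means and the normal equations", {
  d <- tibble::tibble(g = factor(rep(c("a", "b"), each = 6)),
                      y = rep(c(10, 14), each = 6))
  fit <- linear_fit(d, y ~ g)
  expect_equal(unname(coef(fit)), c(10, 4))

  set.seed(19)
  d2 <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  d2$y <- 1 + 2 * d2$x1 - d2$x2 + rnorm(20)
  fit2 <- linear_fit(d2, y ~ x1 + x2)
  X <- cbind(1, d2$x1, d2$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(unname(coef(fit2)), drop(beta), tolerance = 1e-10)

  d2$x3 <- d2$x1 # exact duplicate
  expect_error(linear_fit(d2, y ~ x1 + x2 + x3), "rank")
})

test_that("VIF pruning drops the highest-VIF column until all are below 3", {
  set.seed(23)
  n <- 200
  # orthogonalized columns: nothing dropped
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  ortho <- tibble::tibble(a = X[, 1], b = X[, 2], c = X[, 3])
  res <- vif_prune(ortho)
  expect_equal(res$retained, c("a", "b", "c"))
  expect_true(all(res$history$vif < 1.1))
  expect_equal(res$dropped, character(0))

  # duplicated column: infinite VIF, the later copy goes first
  dup <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  dup$a2 <- dup$a
  res2 <- vif_prune(dup)
  expect_equal(res2$dropped[1], "a2")
  expect_false("a2" %in% res2$retained)

  # three correlated columns vs a hand-run of the iterative rule
  z <- rnorm(n)
  d3 <- tibble::tibble(p = z + rnorm(n, 0, 0.4),
                       q = z + rnorm(n, 0, 0.4),
                       r = z + rnorm(n, 0, 0.4))
  res3 <- vif_prune(d3)
  hand_vif <- function(df) {
    vapply(names(df), function(j) {
      others <- setdiff(names(df), j)
      dd <- cbind(.resp = df[[j]], df[others])
      r2 <- summary(lm(stats::reformulate(others, ".resp"), data = dd))$r.squared
      1 / (1 - r2)
    }, numeric(1))
  }
  cur <- d3; hand_dropped <- character(0)
  repeat {
    if (ncol(cur) < 2) break
    v <- hand_vif(cur)
    if (max(v) < 3) break
    # ties (e.g. the exactly symmetric two-column case) drop the later column
    worst <- names(v)[max(which(v >= max(v) - 1e-8))]
    hand_dropped <- c(hand_dropped, worst)
    cur <- cur[setdiff(names(cur), worst)]
  }
  expect_equal(res3$dropped, hand_dropped)
  expect_equal(res3$retained, names(cur))
  # invariant: final round VIFs all below threshold (when >= 2 remain)
  last <- res3$history[res3$history$round == max(res3$history$round), ]
  if (length(res3$retained) >= 2) expect_true(all(last$vif < 3))
})

test_that("VIF pruning agrees with the car implementation on the first round", {
  skip_if_not_installed("car")
  set.seed(31)
  n <- 150
  z <- rnorm(n)
  d <- tibble::tibble(a = z + rnorm(n), b = z + rnorm(n), c = rnorm(n))
  d$y <- rnorm(n)
  ours <- vif_prune(d[c("a", "b", "c")], threshold = 1e9)$history
  theirs <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(setNames(ours$vif, ours$term), theirs, tolerance = 1e-8)
})

test_that("Bayesian regression tracks OLS and calls strong signals", {
  set.seed(37)
  n <- 200
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 1 + 5 * d$x + rnorm(n, 0, 0.5)
  fit <- bayes_lm(d, y ~ x, seed = 41)
  s <- tidy(fit)
  xrow <- s[s$term == "x", ]
  expect_equal(xrow$sign_call, "positive")
  expect_gt(xrow$conf.low, 0)
  # flat-prior posterior mean is within Monte Carlo error of OLS
  ols <- coef(lm(y ~ x, d))
  expect_equal(unname(xrow$estimate), unname(ols[["x"]]), tolerance = 0.01)
  expect_true(all(s$rhat < 1.05))
  # negative signal called negative
  d$y2 <- 1 - 4 * d$x + rnorm(n, 0, 0.5)
  s2 <- tidy(bayes_lm(d, y2 ~ x, seed = 42))
  expect_equal(s2$sign_call[s2$term == "x"], "negative")
})

test_that("credible-interval widths shrink roughly as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    set.seed(seed)
    d <- tibble::tibble(x = rnorm(n))
    d$y <- 2 + 0.5 * d$x + rnorm(n)
    s <- tidy(bayes_lm(d, y ~ x, seed = seed + 1, n_draws = 1500))
    s$conf.high[s$term == "x"] - s$conf.low[s$term == "x"]
  }
  w50 <- width_at(50, 51); w200 <- width_at(200, 52); w800 <- width_at(800, 53)
  expect_gt(w50, w200)
  expect_gt(w200, w800)
  expect_equal(w50 / w800, sqrt(800 / 50), tolerance = 0.35)
})

test_that("the sign rule matches the CI definition exactly", {
  expect_equal(sign_call(c(0.01, -1, -2), c(0.12, 1, -0.2)),
               c("positive", "none", "negative"))
  expect_equal(sign_call(0, 1), "none") # bound touching zero is no call
  expect_error(sign_call(1, 0), "order")
  # hand-built draw sets straddling / excluding zero through the full path
  draws_pos <- rnorm(4000, 5, 0.5)
  q <- quantile(draws_pos, c(0.025, 0.975))
  expect_equal(sign_call(q[1], q[2]), "positive")
})
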