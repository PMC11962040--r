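# Tobit (interval-censored Gaussian) regression by maximum likelihood, for
# assay values restricted to the analyzer's detection range. Observations at
# or beyond a limit contribute a censored tail probability; with no censoring
# the ML solution coincides with ordinary least squares.

.tobit_negll <- function(theta, y, X, cens, limits) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  ll <- 0
  unc <- cens == "in_range"
  if (any(unc)) ll <- ll + sum(dnorm(y[unc], mu[unc], sigma, log = TRUE))
  lo <- cens == "below_lower"
  if (any(lo)) ll <- ll + sum(pnorm((limits[1] - mu[lo]) / sigma, log.p = TRUE))
  hi <- cens == "above_upper"
  if (any(hi)) ll <- ll + sum(pnorm((mu[hi] - limits[2]) / sigma, log.p = TRUE))
  -ll
}

.tobit_grad <- function(theta, y, X, cens, limits) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  gbeta <- numeric(p); gls <- 0
  unc <- cens == "in_range"
  if (any(unc)) {
    r <- (y[unc] - mu[unc]) / sigma
    gbeta <- gbeta + drop(crossprod(X[unc, , drop = FALSE], r / sigma))
    gls <- gls + sum(r^2 - 1)
  }
  lo <- cens == "below_lower"
  if (any(lo)) {
    z <- (limits[1] - mu[lo]) / sigma
    lam <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE)) # Mills ratio
    gbeta <- gbeta - drop(crossprod(X[lo, , drop = FALSE], lam / sigma))
    gls <- gls - sum(lam * z)
  }
  hi <- cens == "above_upper"
  if (any(hi)) {
    z <- (mu[hi] - limits[2]) / sigma
    lam <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    gbeta <- gbeta + drop(crossprod(X[hi, , drop = FALSE], lam / sigma))
    gls <- gls - sum(lam * z)
  }
  -c(gbeta, gls)
}

#' Tobit regression with detection limits
#'
#' Fits a Gaussian linear model where response values at or below the lower
#' detection limit (or at or above the upper limit) are treated as
#' interval-censored. Maximizes the censored Gaussian likelihood by BFGS on
#' `(beta, log sigma)` from an OLS start; standard errors come from the
#' observed information. With no censored observations the estimates equal
#' OLS (with the ML, n-denominator residual standard deviation).
#'
#' @param data A data frame containing the model variables.
#' @param formula A model formula, e.g. `drom ~ species`.
#' @param limits Detection limits `c(lower, upper)`; use `-Inf`/`Inf` for an
#'   uncensored side. See [detection_limits()].
#' @return An object of class `ox_tobit` with elements `coefficients`,
#'   `sigma`, `se`, `vcov`, `logLik`, `n`, `n_censored_low`,
#'   `n_censored_high`.
#' @export
tobit_fit <- function(data, formula, limits) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n <= p) abort("need more observations than parameters")
  if (limits[1] >= limits[2]) abort("limits must be ordered (lower < upper)")
  cens <- dplyr::case_when(
    y <= limits[1] ~ "below_lower",
    y >= limits[2] ~ "above_upper",
    TRUE ~ "in_range"
  )
  if (all(cens == "below_lower") || all(cens == "above_upper")) {
    abort("all observations censored on one side; model not identifiable")
  }
  ols <- stats::lm.fit(X, y)
  s0 <- sqrt(sum(ols$residuals^2) / n)
  theta0 <- c(ols$coefficients, log(max(s0, 1e-6)))
  opt <- optim(theta0, .tobit_negll, gr = .tobit_grad, y = y, X = X,
               cens = cens, limits = limits, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14), hessian = FALSE)
  # polish with tight Nelder-Mead-free second BFGS pass and numeric hessian
  opt <- optim(opt$par, .tobit_negll, gr = .tobit_grad, y = y, X = X,
               cens = cens, limits = limits, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14), hessian = TRUE)
  theta <- unname(opt$par)
  sigma <- exp(theta[p + 1])
  if (sigma < 1e-8) abort("sigma collapsed towards zero; fit not usable")
  # delta method back from log-sigma parameterization
  H <- opt$hessian
  Vt <- tryCatch(solve(H), error = function(e) abort("singular information matrix"))
  J <- diag(p + 1); J[p + 1, p + 1] <- sigma
  V <- J %*% Vt %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta, sigma = sigma,
    se = setNames(se[seq_len(p)], colnames(X)), sigma_se = se[p + 1],
    vcov = V[seq_len(p), seq_len(p), drop = FALSE],
    logLik = -opt$value, n = n,
    n_censored_low = sum(cens == "below_lower"),
    n_censored_high = sum(cens == "above_upper"),
    limits = limits, formula = formula, converged = opt$convergence == 0
  ), class = "ox_tobit")
}

#' @method tidy ox_tobit
#' @export
tidy.ox_tobit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @method glance ox_tobit
#' @export
glance.ox_tobit <- function(x, ...) {
  tibble(sigma = x$sigma, logLik = x$logLik, n = x$n,
         n_censored_low = x$n_censored_low, n_censored_high = x$n_censored_high,
         converged = x$converged)
}

#' @method print ox_tobit
#' @export
print.ox_tobit <- function(x, ...) {
  cat(sprintf("Tobit regression (limits %s to %s): n = %d, %d left-, %d right-censored\n",
              format(x$limits[1]), format(x$limits[2]), x$n,
              x$n_censored_low, x$n_censored_high))
  print(tidy(x))
  invisible(x)
}

#' Ordinary least squares with tidy output
#'
#' Thin wrapper over [stats::lm()] used for species contrasts in oxidative
#' change; rejects rank-deficient designs.
#'
#' @inheritParams tobit_fit
#' @return The fitted `lm` object.
#' @export
linear_fit <- function(data, formula) {
  fit <- lm(formula, data = data)
  X <- stats::model.matrix(formula, stats::model.frame(formula, data))
  if (fit$rank < ncol(X)) abort("rank-deficient design matrix")
  fit
}
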