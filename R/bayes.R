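# Bayesian Gaussian linear regression by a conjugate Gibbs sampler, with the
# 95% equal-tailed credible-interval sign rule: a coefficient whose CI lies
# entirely above zero is called positive, entirely below zero negative,
# otherwise no call. Priors are weakly informative: flat on the
# coefficients, inverse-gamma(0.001, 0.001) on the error variance, so the
# posterior mean tracks OLS.

.split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(d) {
    n <- length(d)
    list(d[seq_len(n %/% 2)], d[(n %/% 2 + 1):n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian Gaussian regression with CI sign calls
#'
#' Samples the posterior of a Gaussian linear model by conjugate Gibbs
#' (coefficients given variance: multivariate normal around OLS; variance
#' given coefficients: inverse gamma). Runs several chains and checks
#' split-R-hat convergence; draws are pooled across chains after warmup.
#' Each coefficient gets a 95% equal-tailed credible interval and a sign
#' call: `"positive"` if the interval excludes zero from above,
#' `"negative"` if from below, `"none"` otherwise.
#'
#' @inheritParams tobit_fit
#' @param n_draws Post-warmup draws per chain.
#' @param warmup Warmup draws discarded per chain.
#' @param chains Number of chains.
#' @param seed Optional RNG seed.
#' @param prior Inverse-gamma prior on the error variance,
#'   `list(a0 = , b0 = )`.
#' @param ci_level Credible-interval mass (default 0.95).
#' @param rhat_max Largest acceptable split-R-hat; exceeding it is an error.
#' @return An object of class `ox_bayes` with pooled `draws` (matrix,
#'   coefficients plus `sigma`), a `summary` tibble (`term`, `estimate`,
#'   `conf.low`, `conf.high`, `rhat`, `sign_call`) and fit metadata.
#' @export
bayes_lm <- function(data, formula, n_draws = 2000, warmup = 500, chains = 4,
                     seed = NULL, prior = list(a0 = 0.001, b0 = 0.001),
                     ci_level = 0.95, rhat_max = 1.05) {
  if (!is.null(seed)) set.seed(seed)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n <= p) abort("need more observations than parameters")
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) abort("singular design matrix"))
  beta_hat <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  # chol factor of (X'X)^-1 for correlated normal draws
  A <- backsolve(R, diag(p))
  draw_chain <- function() {
    total <- warmup + n_draws
    bdraws <- matrix(0, total, p)
    sdraws <- numeric(total)
    sigma2 <- var(y - drop(X %*% beta_hat)) + 1e-12
    for (i in seq_len(total)) {
      beta <- beta_hat + sqrt(sigma2) * drop(A %*% rnorm(p))
      rss <- sum((y - drop(X %*% beta))^2)
      sigma2 <- 1 / rgamma(1, shape = prior$a0 + n / 2, rate = prior$b0 + rss / 2)
      bdraws[i, ] <- beta
      sdraws[i] <- sqrt(sigma2)
    }
    list(beta = bdraws[(warmup + 1):total, , drop = FALSE],
         sigma = sdraws[(warmup + 1):total])
  }
  chain_list <- lapply(seq_len(chains), function(i) draw_chain())
  draws <- do.call(rbind, lapply(chain_list, `[[`, "beta"))
  colnames(draws) <- colnames(X)
  sigma_draws <- unlist(lapply(chain_list, `[[`, "sigma"))
  alpha <- (1 - ci_level) / 2
  rhat <- vapply(seq_len(p), function(j) {
    .split_rhat(lapply(chain_list, function(ch) ch$beta[, j]))
  }, numeric(1))
  if (any(rhat > rhat_max)) {
    abort(sprintf("chains failed to converge (max split-R-hat %.3f)", max(rhat)))
  }
  lo <- apply(draws, 2, quantile, probs = alpha)
  hi <- apply(draws, 2, quantile, probs = 1 - alpha)
  summ <- tibble(
    term = colnames(X),
    estimate = colMeans(draws),
    conf.low = unname(lo),
    conf.high = unname(hi),
    rhat = rhat,
    sign_call = sign_call(lo, hi)
  )
  structure(list(draws = cbind(draws, sigma = sigma_draws), summary = summ,
                 formula = formula, n = n, chains = chains,
                 n_draws = n_draws, ci_level = ci_level),
            class = "ox_bayes")
}

#' Credible-interval sign rule
#'
#' @param lower,upper CI bounds (vectors).
#' @return `"positive"` where `lower > 0`, `"negative"` where `upper < 0`,
#'   else `"none"`.
#' @export
sign_call <- function(lower, upper) {
  if (any(lower > upper, na.rm = TRUE)) abort("CI bounds out of order")
  dplyr::case_when(
    is.na(lower) | is.na(upper) ~ NA_character_,
    lower > 0 ~ "positive",
    upper < 0 ~ "negative",
    TRUE ~ "none"
  )
}

#' @method tidy ox_bayes
#' @export
tidy.ox_bayes <- function(x, ...) x$summary

#' @method glance ox_bayes
#' @export
glance.ox_bayes <- function(x, ...) {
  tibble(n = x$n, chains = x$chains, n_draws = x$n_draws,
         sigma = mean(x$draws[, "sigma"]), ci_level = x$ci_level)
}

#' @method print ox_bayes
#' @export
print.ox_bayes <- function(x, ...) {
  cat(sprintf("Bayesian Gaussian regression: n = %d, %d chains x %d draws\n",
              x$n, x$chains, x$n_draws))
  print(x$summary)
  invisible(x)
}

#' Plot posterior coefficient intervals
#'
#' Point estimates with credible intervals per term, coloured by sign call.
#'
#' @param object An `ox_bayes` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ox_bayes
#' @export
autoplot.ox_bayes <- function(object, ...) {
  s <- filter(object$summary, .data$term != "(Intercept)")
  ggplot(s, aes(x = .data$estimate, y = .data$term, colour = .data$sign_call)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    scale_colour_manual(values = c(positive = "#2166ac", negative = "#b2182b",
                                   none = "grey40")) +
    labs(x = "posterior estimate (95% CI)", y = NULL, colour = "sign call") +
    theme_minimal()
}
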