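# Iterative variance-inflation-factor pruning of collinear predictors: drop
# the single highest-VIF column until all VIFs fall below the threshold
# (default 3).

.vif_values <- function(X) {
  p <- ncol(X)
  Xs <- scale(X)
  # zero-variance columns are perfectly "predicted" by the intercept
  vapply(seq_len(p), function(j) {
    if (!is.finite(sd(X[, j])) || sd(X[, j]) == 0) return(Inf)
    others <- Xs[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), Xs[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((Xs[, j] - mean(Xs[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Prune predictors by variance inflation factor
#'
#' Computes VIFs (`1 / (1 - R^2)` of each predictor regressed on all the
#' others, columns standardized for conditioning) and repeatedly removes the
#' single highest-VIF predictor while any VIF is at or above `threshold`.
#' Ties are broken deterministically by dropping the later column in input
#' order; perfectly collinear columns have infinite VIF and go first.
#'
#' @param data A data frame of numeric predictor columns (>= 2).
#' @param threshold Retain only predictors with VIF strictly below this value
#'   (default 3).
#' @return A list with `retained` (character vector of kept column names),
#'   `dropped` (in removal order) and `history`, a tibble of per-round VIF
#'   values (`round`, `term`, `vif`, `dropped`).
#' @export
vif_prune <- function(data, threshold = 3) {
  X <- as.matrix(as_tibble(data))
  if (!is.numeric(X)) abort("all predictor columns must be numeric")
  if (ncol(X) < 2) abort("need at least 2 predictor columns")
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- cols
  history <- list()
  dropped <- character(0)
  round <- 0L
  repeat {
    round <- round + 1L
    v <- .vif_values(X)
    # tie-break (within numerical noise): drop the later column in input order
    worst <- which(v >= max(v) * (1 - 1e-8))
    worst <- worst[length(worst)]
    drop_now <- max(v) >= threshold && ncol(X) > 1
    history[[round]] <- tibble(
      round = round, term = colnames(X), vif = v,
      dropped = drop_now & seq_along(v) == worst
    )
    if (!drop_now) break
    dropped <- c(dropped, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
    if (ncol(X) < 2) break
  }
  list(retained = colnames(X), dropped = dropped,
       history = bind_rows(history))
}
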