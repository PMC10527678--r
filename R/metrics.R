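# Evaluation metrics shared across the sensor and ensemble layers.

.check_pair <- function(est, obs) {
  if (length(est) != length(obs))
    stop("'est' and 'obs' must share length", call. = FALSE)
  if (length(est) == 0L)
    stop("empty input", call. = FALSE)
}

#' Mean absolute error
#' @param est model estimates.
#' @param obs observations.
#' @return A single non-negative number.
#' @export
mae <- function(est, obs) {
  .check_pair(est, obs)
  mean(abs(est - obs))
}

#' Residual sum of squares
#' @inheritParams mae
#' @export
rss <- function(est, obs) {
  .check_pair(est, obs)
  sum((est - obs)^2)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS`; may be negative for fits worse than the mean
#' predictor. Undefined (error) when the observations are constant.
#'
#' @inheritParams mae
#' @export
r_squared <- function(est, obs) {
  .check_pair(est, obs)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0)
    stop("R^2 undefined: observations are constant (TSS = 0)", call. = FALSE)
  1 - rss(est, obs) / tss
}

#' Root mean square error from a residual sum of squares
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @export
rmse_from_rss <- function(rss, n) {
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  sqrt(rss / n)
}

#' Range-normalized mean absolute error
#'
#' `nMAE = MAE / (max(obs) - min(obs))`: scale-free, so errors are
#' comparable across solutes and sites.
#'
#' @param mae mean absolute error (same units as the observations).
#' @param obs the observation series defining the range.
#' @export
nmae <- function(mae, obs) {
  if (length(obs) == 0L) stop("empty observations", call. = FALSE)
  rng <- max(obs) - min(obs)
  if (rng <= 0)
    stop("nMAE undefined: observations are constant", call. = FALSE)
  mae / rng
}

#' Modified mean-square training loss
#'
#' The sensor's training loss inflates the weight of sub-unit errors by
#' offsetting each absolute error by one before squaring:
#' `mean((|est - obs| + 1)^2)` (the default, `type = "squared"`), which
#' equals 1 for perfect predictions. The alternative reading
#' `sum(|est - obs| + 1) / (2n)` is available as `type = "scaled_mae"`.
#'
#' @inheritParams mae
#' @param type which variant to evaluate.
#' @return A single number (>= 1 for `"squared"`).
#' @examples
#' mmse_loss(c(1, 2), c(1, 2))  # 1
#' mmse_loss(0, 1)              # (1 + 1)^2 = 4
#' @export
mmse_loss <- function(est, obs, type = c("squared", "scaled_mae")) {
  .check_pair(est, obs)
  type <- match.arg(type)
  e <- abs(est - obs)
  switch(type,
         squared = mean((e + 1)^2),
         scaled_mae = sum(e + 1) / (2 * length(e)))
}
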