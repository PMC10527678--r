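# Latent physiological states derived from off-gas measurements.
#
# The culture's oxygen demand is modelled as a strain-specific balance
#   OUR = alpha * dX/dt + beta * (X - X_cX),
# where the maintenance term beta only engages once the cumulative
# biomass-time integral (sum of X * dt) exceeds the threshold k_cX.
# Inverting the balance yields the latent biomass trajectory; the specific
# growth rate and the cell-age statistics are derived from it.

#' Strain-specific parameters of the oxygen-to-biomass balance
#'
#' Bundles the nuisance parameters that link the oxygen uptake rate to the
#' biomass trajectory of a given *E. coli* strain: the oxygen-per-growth
#' yield `alpha`, the maintenance coefficient `beta`, the cumulative
#' biomass-time threshold `k_cX` at which maintenance respiration engages,
#' and the reference biomass level `X_cX` that offsets the maintenance term.
#' Calibration of these values from cultivation data is outside the scope of
#' this package; they are accepted as inputs.
#'
#' @param alpha oxygen-to-growth yield factor (g O2 per g biomass); a single
#'   value or one value per sampling instant. Must be positive.
#' @param beta maintenance coefficient (g O2 per g biomass per hour); scalar
#'   or per-instant. Must be non-negative.
#' @param k_cX cumulative biomass-time threshold (g h/L) after which the
#'   maintenance term participates. The default 0 engages it from the start;
#'   `Inf` disables it.
#' @param X_cX reference biomass level (g/L) appearing in the maintenance
#'   branch. The default 0 disables the offset.
#' @return An object of class `strain_params`.
#' @examples
#' strain_params(alpha = 1, beta = 0.03)
#' @export
strain_params <- function(alpha, beta = 0, k_cX = 0, X_cX = 0) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be positive and finite everywhere", call. = FALSE)
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta < 0))
    stop("'beta' must be non-negative and finite", call. = FALSE)
  if (!is.numeric(k_cX) || length(k_cX) != 1L || is.na(k_cX) || k_cX < 0)
    stop("'k_cX' must be a single non-negative value", call. = FALSE)
  if (!is.numeric(X_cX) || length(X_cX) != 1L || !is.finite(X_cX))
    stop("'X_cX' must be a single finite value", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 k_cX = as.numeric(k_cX), X_cX = as.numeric(X_cX)),
            class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat("Strain parameters (oxygen balance OUR = alpha dX/dt + beta (X - X_cX))\n")
  cat(sprintf("  alpha: %s g O2 / g X\n", paste(signif(unique(x$alpha), 4), collapse = ", ")))
  cat(sprintf("  beta:  %s g O2 / g X / h\n", paste(signif(unique(x$beta), 4), collapse = ", ")))
  cat(sprintf("  k_cX:  %g g h/L    X_cX: %g g/L\n", x$k_cX, x$X_cX))
  invisible(x)
}

#' One fed-batch cultivation's measured time series
#'
#' Container for the online measurements of a single cultivation run:
#' sampling times (hours since inoculation), off-gas oxygen uptake and
#' carbon dioxide production rates, broth weight and feed profiles, plus the
#' scalar metadata (inoculation biomass, initial glucose, induction time).
#'
#' @param times sampling instants in hours since inoculation; strictly
#'   increasing, non-negative.
#' @param our oxygen uptake rate per instant (g/L/h); non-negative.
#' @param cpr carbon dioxide production rate per instant (g/L/h); optional.
#' @param broth_kg broth weight per instant (kg); optional, non-negative.
#' @param feed_glucose glucose feed rate per instant (g/h); optional.
#' @param feed_isoleucine optional second feed rate profile (g/h).
#' @param x0 inoculation biomass concentration (g/L); positive.
#' @param s0 initial glucose concentration (g/L); optional.
#' @param induction_time induction (IPTG) time in hours, or `NA` if the run
#'   was not induced.
#' @param experiment_id character label identifying the run.
#' @return An object of class `cultivation_record`.
#' @examples
#' cultivation_record(times = 0:5, our = rep(1, 6), x0 = 0.5,
#'                    experiment_id = "demo")
#' @export
cultivation_record <- function(times, our, cpr = NULL, broth_kg = NULL,
                               feed_glucose = NULL, feed_isoleucine = NULL,
                               x0, s0 = NA_real_, induction_time = NA_real_,
                               experiment_id = "run") {
  times <- as.numeric(times)
  our <- as.numeric(our)
  n <- length(times)
  if (n < 1L) stop("'times' must contain at least one instant", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative (hours since inoculation)",
         call. = FALSE)
  if (n > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (length(our) != n || any(!is.finite(our)))
    stop("'our' must be finite and share length with 'times'", call. = FALSE)
  if (any(our < 0)) stop("'our' must be non-negative", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("'x0' must be a single positive value", call. = FALSE)
  chk <- function(v, nm, nonneg = FALSE) {
    if (is.null(v)) return(NULL)
    v <- as.numeric(v)
    if (length(v) != n)
      stop(sprintf("'%s' must share length with 'times'", nm), call. = FALSE)
    if (nonneg && any(v < 0, na.rm = TRUE))
      stop(sprintf("'%s' must be non-negative", nm), call. = FALSE)
    v
  }
  structure(list(
    experiment_id = as.character(experiment_id),
    times = times, our = our,
    cpr = chk(cpr, "cpr"),
    broth_kg = chk(broth_kg, "broth_kg", nonneg = TRUE),
    feed_glucose = chk(feed_glucose, "feed_glucose"),
    feed_isoleucine = chk(feed_isoleucine, "feed_isoleucine"),
    x0 = as.numeric(x0), s0 = as.numeric(s0),
    induction_time = as.numeric(induction_time)
  ), class = "cultivation_record")
}

#' @export
print.cultivation_record <- function(x, ...) {
  cat(sprintf("Cultivation record '%s': %d instants, %.2f-%.2f h\n",
              x$experiment_id, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  x0 = %.3g g/L, s0 = %.3g g/L, induction at %s h\n",
              x$x0, x$s0, ifelse(is.na(x$induction_time), "-", format(x$induction_time))))
  series <- c("our", "cpr", "broth_kg", "feed_glucose", "feed_isoleucine")
  have <- series[!vapply(x[series], is.null, logical(1))]
  cat("  series:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cultivation_record <- function(x, ...) {
  d <- data.frame(time_h = x$times, our = x$our)
  for (nm in c("cpr", "broth_kg", "feed_glucose", "feed_isoleucine"))
    if (!is.null(x[[nm]])) d[[nm]] <- x[[nm]]
  d
}

# Recycle a scalar or per-instant parameter vector to length n.
.per_instant <- function(v, n, nm) {
  if (length(v) == 1L) return(rep(v, n))
  if (length(v) != n)
    stop(sprintf("'%s' must be a scalar or one value per instant", nm),
         call. = FALSE)
  v
}

#' Latent biomass concentration from the oxygen uptake rate
#'
#' Inverts the strain oxygen balance `OUR = alpha dX/dt + beta (X - X_cX)`
#' to recover the biomass trajectory from measured OUR. While the cumulative
#' biomass-time integral up to the previous instant stays at or below
#' `k_cX`, the maintenance-free form applies and the biomass is the
#' cumulative sum `x0 + sum(OUR dt / alpha)`; afterwards the maintenance
#' term engages and the update uses the integrating-factor discretization
#' `x_i = x_{i-1} exp(-(beta/alpha) dt) + (OUR_i + beta X_cX)/alpha * dt`.
#' Both regimes are one formula with a per-step effective `beta` (zero
#' before the threshold crossing), so the trajectory is continuous at the
#' switch and with `beta = 0` the two branches coincide exactly.
#'
#' Times are hours since inoculation; the inoculum `x0` is the biomass at
#' time zero, and the first interval is `times[1] - 0`.
#'
#' @param record a [cultivation_record()].
#' @param params a [strain_params()].
#' @return Numeric vector: biomass concentration (g/L) at `record$times`.
#' @examples
#' rec <- cultivation_record(times = 1:5, our = rep(1, 5), x0 = 1)
#' latent_biomass(rec, strain_params(alpha = 1))  # 2 3 4 5 6
#' @export
latent_biomass <- function(record, params) {
  stopifnot(inherits(record, "cultivation_record"),
            inherits(params, "strain_params"))
  times <- record$times
  n <- length(times)
  if (n > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  alpha <- .per_instant(params$alpha, n, "alpha")
  beta <- .per_instant(params$beta, n, "beta")
  if (any(alpha <= 0)) stop("'alpha' must be positive everywhere", call. = FALSE)
  dt <- diff(c(0, times))
  x <- numeric(n)
  xprev <- record$x0
  cum_xt <- 0  # cumulative biomass-time through instant i-1
  for (i in seq_len(n)) {
    b_eff <- if (cum_xt > params$k_cX) beta[i] else 0
    decay <- exp(-(b_eff / alpha[i]) * dt[i])
    x[i] <- xprev * decay +
      (record$our[i] + b_eff * params$X_cX) / alpha[i] * dt[i]
    cum_xt <- cum_xt + x[i] * dt[i]
    xprev <- x[i]
  }
  x
}

#' Specific growth rate from a biomass trajectory
#'
#' Computes `mu = (dX/dt) / X` with second-order central finite differences
#' on the (possibly non-uniform) time grid; one-sided differences are used
#' at the two ends. A length-1 trajectory has no derivative and returns 0.
#'
#' @param biomass biomass trajectory (g/L); strictly positive.
#' @param times sampling instants (h); strictly increasing.
#' @return Numeric vector of specific growth rates (1/h).
#' @examples
#' t <- seq(0, 5, by = 0.1)
#' specific_growth_rate(exp(0.2 * t), t)  # ~0.2 throughout
#' @export
specific_growth_rate <- function(biomass, times) {
  n <- length(biomass)
  if (length(times) != n)
    stop("'biomass' and 'times' must share length", call. = FALSE)
  if (any(biomass <= 0))
    stop("'biomass' must be strictly positive", call. = FALSE)
  if (n == 1L) return(0)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  dxdt <- numeric(n)
  dxdt[1] <- (biomass[2] - biomass[1]) / (times[2] - times[1])
  dxdt[n] <- (biomass[n] - biomass[n - 1]) / (times[n] - times[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    h1 <- times[i] - times[i - 1]
    h2 <- times[i + 1] - times[i]
    dxdt[i] <- -h2 / (h1 * (h1 + h2)) * biomass[i - 1] +
      (h2 - h1) / (h1 * h2) * biomass[i] +
      h1 / (h2 * (h1 + h2)) * biomass[i + 1]
  }
  dxdt / biomass
}

# Shared cohort bookkeeping for the age statistics: the whole initial
# population is one cohort born at the first instant, so the increment at
# the first point is the full starting biomass and sum(dX) telescopes to X.
.age_sums <- function(biomass, times) {
  n <- length(biomass)
  if (length(times) != n)
    stop("'biomass' and 'times' must share length", call. = FALSE)
  if (any(biomass <= 0))
    stop("'biomass' must be strictly positive", call. = FALSE)
  if (n > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  dX <- c(biomass[1], diff(biomass))
  # sum_j (t_i - t_j) dX_j  =  t_i * X_i - cumsum(t_j dX_j)
  times * biomass - cumsum(times * dX)
}

#' Average age of the biomass population
#'
#' The biomass-weighted mean age of the cohorts present at each instant:
#' `Age_i = sum_j (t_i - t_j) dX_j / X_i`, where `dX_j` is the biomass laid
#' down at instant `j` and the inoculum counts as a cohort born at the first
#' instant. Negative increments (biomass decline) enter the sum as-is.
#'
#' @inheritParams specific_growth_rate
#' @return Numeric vector of average ages (h); the first element is 0.
#' @examples
#' average_age(c(2, 2, 2), c(0, 2, 4))  # single cohort ages linearly: 0 2 4
#' @export
average_age <- function(biomass, times) {
  .age_sums(biomass, times) / biomass
}

#' Cumulative cell age of the biomass population
#'
#' The biomass-scaled integral of cohort ages,
#' `cAge_i = sum_j (t_i - t_j) dX_j` (g h/L). It satisfies the identity
#' `cAge = Age * X` with [average_age()] at every instant.
#'
#' @inheritParams specific_growth_rate
#' @return Numeric vector of cumulative ages (g h/L).
#' @examples
#' cumulative_age(c(2, 2), c(0, 3))  # inoculum cohort of 2 g/L aged 3 h -> 6
#' @export
cumulative_age <- function(biomass, times) {
  .age_sums(biomass, times)
}

#' Derive all latent physiological states of a cultivation
#'
#' Bundles the latent biomass, specific growth rate, average and cumulative
#' cell age, plus the cumulative biomass-time integral, into one table.
#'
#' @inheritParams latent_biomass
#' @return A `latent_states` data frame with columns `time_h`, `biomass`,
#'   `mu`, `age`, `cage`, `cum_biomass_time`.
#' @examples
#' rec <- cultivation_record(times = 1:5, our = rep(1, 5), x0 = 1)
#' derive_latent_states(rec, strain_params(alpha = 1))
#' @export
derive_latent_states <- function(record, params) {
  x <- latent_biomass(record, params)
  if (any(x <= 0))
    stop("derived biomass is non-positive; check OUR and strain parameters",
         call. = FALSE)
  times <- record$times
  dt <- diff(c(0, times))
  out <- data.frame(
    time_h = times,
    biomass = x,
    mu = specific_growth_rate(x, times),
    age = average_age(x, times),
    cage = cumulative_age(x, times),
    cum_biomass_time = cumsum(x * dt)
  )
  class(out) <- c("latent_states", "data.frame")
  attr(out, "experiment_id") <- record$experiment_id
  out
}

#' @export
print.latent_states <- function(x, ...) {
  cat(sprintf("Latent states for '%s' (%d instants)\n",
              attr(x, "experiment_id"), nrow(x)))
  NextMethod()
}
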