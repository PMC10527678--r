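# Mechanistic synthetic fed-batch cultivations: Monod growth on glucose with
# overflow-metabolism acetate, exponential feeding, optional secondary
# solutes, and off-gas signals generated from the same oxygen balance the
# physiology module inverts.

#' Build and validate a simulation configuration
#'
#' Either supply a named list (e.g. read from a scenario YAML file) or start
#' from a shipped site scenario via [site_scenario()]. Individual fields can
#' be overridden through `...` using the same nested structure.
#'
#' @param config named list with fields `duration_h`, `sampling_interval_h`,
#'   `feed_start_h`, `initial`, `feed`, `kinetics`, `oxygen`, `solutes`,
#'   `noise`, `assay`, `seed`, ... (see the shipped scenario files under
#'   `inst/extdata/scenarios/` for the full schema and units).
#' @param ... top-level fields to override, e.g. `seed = 7`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(config, ...) {
  over <- list(...)
  config <- utils::modifyList(config, over)
  need <- c("duration_h", "sampling_interval_h", "feed_start_h", "initial",
            "feed", "kinetics", "oxygen", "noise", "assay", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("missing configuration fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (config$duration_h <= config$feed_start_h || config$feed_start_h < 0)
    stop("'duration_h' must exceed 'feed_start_h' (>= 0)", call. = FALSE)
  if (config$sampling_interval_h <= 0)
    stop("'sampling_interval_h' must be positive", call. = FALSE)
  rates <- unlist(config$kinetics)
  if (any(rates < 0)) stop("kinetic rates and yields must be >= 0", call. = FALSE)
  if (is.null(config$solutes)) config$solutes <- list()
  config$seed <- as.integer(config$seed)
  class(config) <- "simulation_config"
  config
}

#' Shipped site scenarios
#'
#' Loads one of the two bundled cultivation regimes: site 1 is a short
#' (20 h) high-density fed-batch with glucose-only exponential feeding
#' starting at 5-7 h and dense sampling; site 2 is a long (66 h) pilot-scale
#' run with feed start at 21 h, an isoleucine co-feed, several tracked
#' solutes and sparse offline assays.
#'
#' @param site 1 or 2.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @examples
#' cfg <- site_scenario(1, seed = 42)
#' @export
site_scenario <- function(site, ...) {
  if (!site %in% c(1, 2)) stop("unknown site: ", site, call. = FALSE)
  path <- system.file("extdata", "scenarios",
                      sprintf("site%d.yaml", as.integer(site)),
                      package = "softsensr")
  if (!nzchar(path)) stop("scenario file not found", call. = FALSE)
  simulation_config(yaml::read_yaml(path), ...)
}

# Glucose feed rate profile [g/h] at time t.
.feed_rate <- function(t, cfg) {
  ifelse(t < cfg$feed_start_h, 0,
         cfg$feed$glucose_rate_start_g_h *
           exp(cfg$feed$glucose_exp_rate_h * (t - cfg$feed_start_h)))
}

# Off-gas emission: OUR on the sampling grid from the true biomass
# trajectory via the same discrete oxygen balance (including the k_cX
# switch semantics) that latent_biomass() inverts, so the noiseless
# round trip is exact. The first instant (dt = 0) carries the continuous
# balance value instead.
.our_from_biomass <- function(x, times, ox, mu0) {
  n <- length(x)
  dt <- diff(c(0, times))
  our <- numeric(n)
  cum_xt <- 0
  for (i in seq_len(n)) {
    b_eff <- if (cum_xt > ox$k_cX) ox$beta else 0
    if (dt[i] > 0) {
      decay <- exp(-(b_eff / ox$alpha) * dt[i])
      xprev <- if (i == 1L) x[1] else x[i - 1]
      our[i] <- ox$alpha * (x[i] - xprev * decay) / dt[i] - b_eff * ox$X_cX
    } else {
      our[i] <- ox$alpha * mu0 * x[i] + b_eff * (x[i] - ox$X_cX)
    }
    cum_xt <- cum_xt + x[i] * dt[i]
  }
  our
}

#' Simulate one fed-batch cultivation
#'
#' Integrates a fed-batch ODE system -- Monod growth on glucose, overflow
#' metabolism (acetate produced while the specific glucose uptake exceeds
#' the oxidative capacity `qs_crit`, re-consumed once uptake is limiting),
#' exponential feeding with volume increase, and optional first-order
#' production/consumption laws for further solutes. Off-gas OUR is emitted
#' from the strain oxygen balance `OUR = alpha dX/dt + beta (X - X_cX)`
#' (maintenance engaging past the `k_cX` biomass-time threshold), CPR from
#' OUR through a drifting respiratory quotient. Observation noise
#' (multiplicative Gaussian) is applied per the configured noise model; the
#' same seed reproduces the output bit for bit.
#'
#' @param config a [simulation_config()].
#' @return A `simulated_cultivation` list with elements `record` (a noisy
#'   [cultivation_record()]), `truth` (noise-free state trajectories,
#'   including `our_true`, `cpr_true` and glucose-balance bookkeeping) and
#'   `assays` (sparse noisy offline concentration samples, one column per
#'   solute).
#' @examples
#' sim <- simulate_cultivation(site_scenario(1, duration_h = 8, seed = 1))
#' head(sim$assays)
#' @export
simulate_cultivation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  kin <- cfg$kinetics
  ox <- cfg$oxygen
  qs_max <- kin$mu_max / kin$Y_XS
  solutes <- cfg$solutes
  sol_names <- names(solutes)
  ind_t <- if (is.null(cfg$induction_time_h)) Inf else cfg$induction_time_h

  rates <- function(t, y, parms) {
    V <- y[["V"]]
    X <- max(y[["mX"]], 0) / V
    S <- max(y[["mS"]], 0) / V
    A <- max(y[["mA"]], 0) / V
    qs <- qs_max * S / (kin$K_S + S)
    qs_ox <- min(qs, kin$qs_crit)
    qs_of <- qs - qs_ox
    qac <- kin$qac_max * A / (kin$K_A + A) * max(0, 1 - qs / kin$qs_crit)
    mu <- kin$Y_XS * qs_ox + kin$Y_XA * qac
    Fg <- .feed_rate(t, cfg)
    Fv <- Fg / cfg$feed$glucose_feed_conc_g_l
    d <- c(V = Fv,
           mX = mu * X * V,
           mS = Fg - qs * X * V,
           mA = (kin$Y_AS * qs_of - qac) * X * V,
           cum_fed = Fg,
           cum_cons = qs * X * V)
    if (length(sol_names)) {
      ind <- as.numeric(t >= ind_t)
      for (nm in sol_names) {
        p <- solutes[[nm]]
        C <- max(y[[nm]], 0) / V
        dC <- (p$k_mu * mu + p$k_ind * ind) * X * V - p$k_cons * C * X * V
        if (nm == "isoleucine" && t >= cfg$feed_start_h)
          dC <- dC + cfg$feed$isoleucine_rate_g_h
        d[nm] <- dC
      }
    }
    list(d)
  }

  y0 <- c(V = cfg$initial$volume_l,
          mX = cfg$initial$x0_g_l * cfg$initial$volume_l,
          mS = cfg$initial$s0_g_l * cfg$initial$volume_l,
          mA = 0, cum_fed = 0, cum_cons = 0)
  if (length(sol_names)) y0[sol_names] <- 0
  times <- seq(0, cfg$duration_h, by = cfg$sampling_interval_h)
  sol <- try(deSolve::lsoda(y0, times, rates, parms = NULL,
                            rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times))
    stop("fed-batch ODE integration failed: ",
         if (inherits(sol, "try-error")) conditionMessage(attr(sol, "condition"))
         else "integrator stopped early", call. = FALSE)
  sol <- as.data.frame(sol)

  V <- sol$V
  X <- pmax(sol$mX, 0) / V
  S <- pmax(sol$mS, 0) / V
  A <- pmax(sol$mA, 0) / V
  qs <- qs_max * S / (kin$K_S + S)
  mu0 <- kin$Y_XS * min(qs[1], kin$qs_crit)
  our_true <- .our_from_biomass(X, times, ox, mu0)
  if (any(our_true < -1e-9))
    stop("simulation produced negative OUR; parameterization inconsistent ",
         "with the oxygen balance (dilution exceeds growth)", call. = FALSE)
  our_true <- pmax(our_true, 0)
  rq_t <- ox$rq * (1 + ox$rq_drift * times / cfg$duration_h)
  cpr_true <- our_true * rq_t * (44 / 32)
  feed_glc <- .feed_rate(times, cfg)
  broth_true <- V * cfg$broth_density_kg_l

  truth <- data.frame(time_h = times, biomass = X, glucose = S, acetate = A,
                      volume_l = V, mu = specific_growth_rate(pmax(X, 1e-12), times),
                      our_true = our_true, cpr_true = cpr_true,
                      feed_glucose = feed_glc,
                      cum_fed_glucose = sol$cum_fed,
                      cum_consumed_glucose = sol$cum_cons)
  for (nm in sol_names) truth[[nm]] <- pmax(sol[[nm]], 0) / V

  set.seed(cfg$seed)
  nz <- cfg$noise
  rel_noise <- function(v, sd) pmax(v * (1 + rnorm(length(v), 0, sd)), 0)
  our_obs <- rel_noise(our_true, nz$our_rel_sd)
  cpr_obs <- rel_noise(cpr_true, nz$cpr_rel_sd)
  broth_obs <- rel_noise(broth_true, nz$broth_rel_sd)

  feed_ile <- if (cfg$feed$isoleucine_rate_g_h > 0)
    ifelse(times < cfg$feed_start_h, 0, cfg$feed$isoleucine_rate_g_h) else NULL
  record <- cultivation_record(
    times = times, our = our_obs, cpr = cpr_obs, broth_kg = broth_obs,
    feed_glucose = feed_glc, feed_isoleucine = feed_ile,
    x0 = cfg$initial$x0_g_l, s0 = cfg$initial$s0_g_l,
    induction_time = if (is.finite(ind_t)) ind_t else NA_real_,
    experiment_id = if (is.null(cfg$experiment_id)) sprintf("site%d_seed%d", cfg$site, cfg$seed)
                    else cfg$experiment_id)

  # Offline assays: ground truth subsampled at the assay schedule + noise.
  idx <- unique(round(seq(
    which.min(abs(times - cfg$assay$first_sample_h)), length(times),
    length.out = cfg$assay$n_samples)))
  assays <- data.frame(time_h = times[idx], grid_index = idx)
  for (nm in c("acetate", sol_names)) {
    v <- truth[[nm]][idx]
    assays[[nm]] <- pmax(v * (1 + rnorm(length(v), 0, nz$assay_rel_sd)) +
                           rnorm(length(v), 0, nz$assay_abs_sd_g_l), 0)
  }

  structure(list(record = record, truth = truth, assays = assays,
                 config = cfg), class = "simulated_cultivation")
}

#' @export
print.simulated_cultivation <- function(x, ...) {
  cat(sprintf("Simulated cultivation '%s': %.0f h, %d instants, %d assays\n",
              x$record$experiment_id, max(x$record$times),
              length(x$record$times), nrow(x$assays)))
  cat(sprintf("  final biomass %.1f g/L, acetate peak %.2f g/L\n",
              tail(x$truth$biomass, 1), max(x$truth$acetate)))
  invisible(x)
}

#' Generate a campaign of simulated cultivations
#'
#' Runs differ by seeded run-to-run perturbations of the kinetic parameters
#' (multiplicative log-normal jitter on `mu_max`, `qs_crit`, `Y_XS`, the
#' feed magnitude and the inoculum) and, for site 1, a feed start drawn
#' within the scenario's 5-7 h window. Deterministic given `base_seed`.
#'
#' @param n_runs number of cultivations (>= 1).
#' @param site 1 or 2, selecting the shipped scenario.
#' @param base_seed integer seed controlling all draws.
#' @param perturb relative scale of the run-to-run parameter jitter
#'   (default 0.05; 0 makes all runs identical up to observation noise).
#' @param scenario optional `simulation_config` to use instead of the
#'   shipped site scenario.
#' @return A list of `simulated_cultivation` objects.
#' @export
generate_campaign <- function(n_runs, site = 1, base_seed = 1,
                              perturb = 0.02, scenario = NULL) {
  if (n_runs < 1) stop("'n_runs' must be >= 1", call. = FALSE)
  base <- if (is.null(scenario)) site_scenario(site) else scenario
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  jit <- function(v) v * exp(rnorm(1, 0, perturb))
  fs_rng <- base$feed_start_range_h
  # draw every per-run configuration first, so the campaign-level RNG stream
  # is not interleaved with the per-run observation-noise streams
  cfgs <- lapply(seq_len(n_runs), function(i) {
    cfg <- base
    cfg$seed <- seeds[i]
    cfg$experiment_id <- sprintf("site%d_run%02d", base$site, i)
    if (perturb > 0) {
      cfg$kinetics$mu_max <- jit(cfg$kinetics$mu_max)
      cfg$kinetics$qs_crit <- jit(cfg$kinetics$qs_crit)
      cfg$kinetics$Y_XS <- jit(cfg$kinetics$Y_XS)
      cfg$feed$glucose_rate_start_g_h <- jit(cfg$feed$glucose_rate_start_g_h)
      cfg$initial$x0_g_l <- jit(cfg$initial$x0_g_l)
      if (!is.null(fs_rng) && fs_rng[2] > fs_rng[1])
        cfg$feed_start_h <- runif(1, fs_rng[1], fs_rng[2])
    }
    cfg
  })
  lapply(cfgs, simulate_cultivation)
}
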