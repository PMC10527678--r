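# Independent oracles and small fixture builders shared across tests.

# Fine-grid RK4 integrator for the continuous oxygen balance
#   alpha dX/dt + beta X = OUR(t)   (maintenance always on, X_cX = 0),
# used as the reference the discrete latent-biomass inversion must approach.
rk4_biomass <- function(our_fun, times, x0, alpha, beta, refine = 100) {
  f <- function(t, x) (our_fun(t) - beta * x) / alpha
  x <- numeric(length(times))
  cur <- x0
  prev_t <- 0
  for (i in seq_along(times)) {
    tt <- seq(prev_t, times[i], length.out = refine + 1)
    for (k in seq_len(refine)) {
      h <- tt[k + 1] - tt[k]
      if (h == 0) next
      k1 <- f(tt[k], cur)
      k2 <- f(tt[k] + h / 2, cur + h / 2 * k1)
      k3 <- f(tt[k] + h / 2, cur + h / 2 * k2)
      k4 <- f(tt[k] + h, cur + h * k3)
      cur <- cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x[i] <- cur
    prev_t <- times[i]
  }
  x
}

# Random smooth positive OUR profile (sum of exponential + sines).
random_smooth_our <- function() {
  a <- runif(1, 0.5, 2); b <- runif(1, 0.05, 0.3)
  c1 <- runif(1, 0, 0.5); w1 <- runif(1, 0.3, 1.5); ph <- runif(1, 0, 2 * pi)
  function(t) a * exp(b * t) * (1 + c1 * sin(w1 * t + ph)) + 0.2
}

# O(n^2) brute-force cohort sums behind the age statistics.
brute_age_sums <- function(biomass, times) {
  dX <- c(biomass[1], diff(biomass))
  sapply(seq_along(times), function(i)
    sum((times[i] - times[seq_len(i)]) * dX[seq_len(i)]))
}

# Brute-force subset dominance: drop eval i iff a proper subset with
# strictly lower mae exists.
brute_dominance <- function(groups, maes) {
  n <- length(groups)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && length(groups[[j]]) < length(groups[[i]]) &&
        all(groups[[j]] %in% groups[[i]]) && maes[j] < maes[i])
      keep[i] <- FALSE
  }
  keep
}

# Small windowed dataset on a deterministic signal, two experiments.
toy_windows <- function(n = 200, steps = 5, fun = function(x) 0.5 * x + 1,
                        seed = 2) {
  set.seed(seed)
  x <- matrix(runif(n, 0, 10), ncol = 1, dimnames = list(NULL, "f"))
  make_windows(x, fun(x[, 1]), window_steps = steps,
               experiment = rep(c("a", "b"), each = n / 2))
}

# Config for quick sanity fits (small net, no dropout), overridable.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(window_steps = 5, lstm_units = 8, dense_units = 5,
         dropout_rate = 0, max_epochs = 400, patience = 30),
    list(...))
  do.call(sensor_config, args)
}
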