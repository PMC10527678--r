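test_that("maintenance-free latent biomass is a cumulative OUR sum", {
  rec <- cultivation_record(times = 1:5, our = rep(1, 5), x0 = 1)
  expect_equal(latent_biomass(rec, strain_params(alpha = 1)), 2:6)

  # beta = 0 makes the threshold irrelevant: k_cX = 0 and k_cX = Inf agree
  set.seed(7)
  tms <- cumsum(runif(30, 0.05, 0.5))
  rec2 <- cultivation_record(times = tms, our = runif(30, 0.5, 3), x0 = 0.4)
  p0 <- strain_params(alpha = 1.3, beta = 0, k_cX = 0)
  pInf <- strain_params(alpha = 1.3, beta = 0, k_cX = Inf)
  expect_identical(latent_biomass(rec2, p0), latent_biomass(rec2, pInf))

  # and equals x0 + cumsum(OUR dt / alpha) exactly
  dt <- diff(c(0, tms))
  expect_equal(latent_biomass(rec2, p0), 0.4 + cumsum(rec2$our * dt / 1.3))
})

test_that("latent biomass converges to the continuous oxygen balance", {
  set.seed(42)
  for (rep in 1:20) {
    f <- random_smooth_our()
    alpha <- runif(1, 0.8, 1.5)
    beta <- runif(1, 0.01, 0.08)
    x0 <- runif(1, 0.3, 1)
    err <- sapply(c(0.05, 0.025), function(dt) {
      tms <- seq(dt, 10, by = dt)
      rec <- cultivation_record(times = tms, our = f(tms), x0 = x0)
      xd <- latent_biomass(rec, strain_params(alpha, beta, k_cX = 0))
      xr <- rk4_biomass(f, tms, x0, alpha, beta, refine = 50)
      max(abs(xd - xr) / xr)
    })
    expect_lt(err[1], 0.02)          # already close at dt = 0.05 h
    expect_lt(err[2], err[1] / 1.9)  # halving dt at least ~halves the error
  }
})

test_that("the trajectory is continuous at the maintenance switch", {
  tms <- seq(0.1, 10, by = 0.1)
  rec <- cultivation_record(times = tms, our = 1 + 0.3 * tms, x0 = 0.5)
  x <- latent_biomass(rec, strain_params(1, beta = 0.3, k_cX = 5))
  # no jump anywhere: steps bounded by the local OUR increment scale
  expect_true(all(abs(diff(x)) <= max(rec$our) * 0.1 / 1 + 1e-9))
  # the maintenance branch slows accumulation relative to beta = 0
  x_free <- latent_biomass(rec, strain_params(1, beta = 0, k_cX = 5))
  expect_true(all(x <= x_free + 1e-12))
  expect_lt(tail(x, 1), tail(x_free, 1))
})

test_that("invalid records and parameters are rejected", {
  expect_error(cultivation_record(times = c(1, 1, 2), our = rep(1, 3), x0 = 1),
               "strictly increasing")
  expect_error(cultivation_record(times = 1:3, our = c(1, -1, 1), x0 = 1),
               "non-negative")
  expect_error(cultivation_record(times = 1:3, our = rep(1, 3), x0 = 0),
               "positive")
  expect_error(strain_params(alpha = 0), "alpha")
  expect_error(strain_params(alpha = c(1, -2)), "alpha")
  expect_error(strain_params(alpha = 1, beta = -0.1), "beta")
})

test_that("specific growth rate matches closed forms", {
  # constant biomass
  expect_equal(specific_growth_rate(rep(5, 10), 1:10), rep(0, 10))
  # exponential: mu = 0.2 within 1e-3 interiorly
  tms <- seq(0, 5, by = 0.1)
  mu <- specific_growth_rate(exp(0.2 * tms), tms)
  expect_lt(max(abs(mu[2:(length(mu) - 1)] - 0.2)), 1e-3)
  # linear growth: mu(t) = 1/(1+t); central differences are exact here
  tms2 <- seq(0, 4, by = 0.5)
  mu2 <- specific_growth_rate(1 + tms2, tms2)
  expect_equal(mu2[tms2 == 1], 0.5, tolerance = 1e-10)
  # scale invariance
  x <- exp(0.3 * tms) + sin(tms) + 2
  expect_equal(specific_growth_rate(x, tms),
               specific_growth_rate(7.3 * x, tms))
  # domain and degenerate cases
  expect_error(specific_growth_rate(c(1, 0, 1), 1:3), "positive")
  expect_identical(specific_growth_rate(3, 1), 0)
})

test_that("age statistics follow the cohort sums", {
  # single inoculum cohort ages linearly
  expect_equal(average_age(rep(2, 5), 0:4), 0:4)
  # two equal cohorts born at t = 0 and t = 2, queried at t = 4
  b <- c(1, 1, 2, 2, 2)
  expect_equal(average_age(b, 0:4)[5], 3)
  # single cohort of 2 g/L at 3 h: cAge = 6 g h/L
  expect_equal(cumulative_age(c(2, 2), c(0, 3)), c(0, 6))
  # brute-force O(n^2) oracle on exponential and random trajectories
  set.seed(11)
  for (rep in 1:5) {
    tms <- sort(runif(50, 0, 20))
    x <- cumsum(abs(rnorm(50, 0.5, 0.3))) + 0.2
    expect_equal(cumulative_age(x, tms), brute_age_sums(x, tms))
    expect_equal(average_age(x, tms), brute_age_sums(x, tms) / x)
  }
  expect_error(average_age(c(1, -1), 0:1), "positive")
})

test_that("cAge equals Age times biomass for arbitrary trajectories", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    tms <- sort(runif(n, 0, 30))
    # allow declines: increments may be negative as printed
    x <- abs(cumsum(rnorm(n, 0.3, 0.6))) + 0.5
    cage <- cumulative_age(x, tms)
    age <- average_age(x, tms)
    expect_equal(cage, age * x, tolerance = 1e-9)
  }
})

test_that("derive_latent_states bundles consistent trajectories", {
  rec <- cultivation_record(times = 1:5, our = rep(2, 5), x0 = 1,
                            experiment_id = "toy")
  ls <- derive_latent_states(rec, strain_params(alpha = 2))
  expect_s3_class(ls, "latent_states")
  expect_equal(ls$biomass, 2:6)
  expect_equal(ls$cage, ls$age * ls$biomass, tolerance = 1e-9)
  expect_equal(ls$cum_biomass_time, cumsum(ls$biomass * diff(c(0, 1:5))))
  expect_true(all(ls$age >= 0) && all(ls$age <= ls$time_h))
  # non-decreasing biomass whenever OUR >= beta * X * alpha
  tms <- seq(0.2, 15, by = 0.2)
  rec2 <- cultivation_record(times = tms, our = 2 + 0.5 * tms, x0 = 0.5)
  ls2 <- derive_latent_states(rec2, strain_params(1, beta = 0.02, k_cX = 1))
  expect_true(all(rec2$our >= 0.02 * ls2$biomass * 1))
  expect_true(all(diff(ls2$biomass) >= -1e-12))
  # degenerate length-1 record: biomass = x0 (+ first increment), mu/age 0
  rec3 <- cultivation_record(times = 0, our = 1, x0 = 0.7)
  ls3 <- derive_latent_states(rec3, strain_params(1))
  expect_equal(ls3$biomass, 0.7)
  expect_equal(ls3$mu, 0)
  expect_equal(ls3$age, 0)
})
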