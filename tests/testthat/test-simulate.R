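test_that("site scenarios carry the documented regimes", {
  s1 <- site_scenario(1)
  expect_equal(s1$duration_h, 20)
  expect_true(s1$feed_start_h >= 5 && s1$feed_start_h <= 7)
  expect_equal(s1$feed$isoleucine_rate_g_h, 0)
  s2 <- site_scenario(2)
  expect_equal(s2$duration_h, 66)
  expect_equal(s2$feed_start_h, 21)
  expect_gt(s2$feed$isoleucine_rate_g_h, 0)
  expect_true(all(c("lactate", "glutamate", "glutamine", "isoleucine") %in%
                    names(s2$solutes)))
  expect_error(site_scenario(3), "unknown site")
})

test_that("seeding contract: identical seeds give identical records", {
  cfg <- site_scenario(1, duration_h = 8, seed = 9)
  a <- simulate_cultivation(cfg)
  b <- simulate_cultivation(cfg)
  expect_identical(a$record, b$record)
  expect_identical(a$assays, b$assays)
  # different seeds: only the noise draws differ
  c <- simulate_cultivation(site_scenario(1, duration_h = 8, seed = 10))
  expect_identical(a$truth, c$truth)
  expect_identical(a$record$feed_glucose, c$record$feed_glucose)
  expect_false(identical(a$record$our, c$record$our))
})

test_that("overflow metabolism: acetate rises on excess glucose, then declines", {
  # batch only (no feed within the horizon): biomass plateaus after
  # glucose exhaustion and acetate is re-consumed
  cfg <- site_scenario(1, duration_h = 16, seed = 2)
  cfg$feed_start_h <- 15.9
  cfg$feed$glucose_rate_start_g_h <- 0
  sim <- simulate_cultivation(cfg)
  tr <- sim$truth
  expect_true(all(tr$biomass >= 0) && all(tr$glucose >= -1e-9) &&
                all(tr$acetate >= 0))
  ipk <- which.max(tr$acetate)
  expect_gt(tr$acetate[ipk], 0.5)
  expect_true(ipk > 5 && ipk < nrow(tr))          # interior peak
  expect_lt(tail(tr$acetate, 1), tr$acetate[ipk] / 2)  # re-consumed
  # biomass plateaus once glucose is gone
  late <- tr$biomass[tr$time_h > tr$time_h[ipk] + 2]
  expect_lt(diff(range(late)) / mean(late), 0.15)
  # acetate accumulates only while uptake exceeds the oxidative capacity
  qs_max <- cfg$kinetics$mu_max / cfg$kinetics$Y_XS
  qs <- qs_max * tr$glucose / (cfg$kinetics$K_S + tr$glucose)
  rising <- diff(tr$acetate) > 1e-6
  expect_true(all(qs[which(rising)] > cfg$kinetics$qs_crit))
})

test_that("glucose mass balance closes to integrator tolerance", {
  for (site in 1:2) {
    sim <- simulate_cultivation(site_scenario(site, seed = 5))
    tr <- tail(sim$truth, 1)
    cfg <- sim$config
    fed_plus_initial <- cfg$initial$s0_g_l * cfg$initial$volume_l +
      tr$cum_fed_glucose
    residual <- tr$glucose * tr$volume_l
    expect_equal(tr$cum_consumed_glucose, fed_plus_initial - residual,
                 tolerance = 1e-6)
  }
})

test_that("noiseless off-gas inverts exactly back to the true biomass", {
  for (site in 1:2) {
    sim <- simulate_cultivation(site_scenario(site, seed = 3))
    ox <- sim$config$oxygen
    rec <- sim$record
    rec$our <- sim$truth$our_true
    x <- latent_biomass(rec, strain_params(ox$alpha, ox$beta,
                                           k_cX = ox$k_cX, X_cX = ox$X_cX))
    expect_equal(x, sim$truth$biomass, tolerance = 1e-12)
  }
})

test_that("campaigns are reproducible and runs differ by seeded jitter", {
  camp <- generate_campaign(4, site = 1, base_seed = 21)
  camp2 <- generate_campaign(4, site = 1, base_seed = 21)
  expect_identical(lapply(camp, `[[`, "record"),
                   lapply(camp2, `[[`, "record"))
  ids <- vapply(camp, function(s) s$record$experiment_id, "")
  expect_equal(length(unique(ids)), 4)
  # runs genuinely differ (kinetic jitter, feed start window)
  finals <- vapply(camp, function(s) tail(s$truth$biomass, 1), 0)
  expect_gt(diff(range(finals)), 0)
  # perturbation scale 0: identical up to observation noise
  camp0 <- generate_campaign(3, site = 1, base_seed = 8, perturb = 0)
  expect_identical(camp0[[1]]$truth, camp0[[2]]$truth)
  expect_false(identical(camp0[[1]]$record$our, camp0[[2]]$record$our))
  # site 2 horizon
  c2 <- generate_campaign(2, site = 2, base_seed = 1)
  expect_true(all(vapply(c2, function(s) max(s$record$times), 0) == 66))
  expect_false(any(vapply(c2, function(s) is.null(s$record$feed_isoleucine),
                          TRUE)))
})

test_that("assay tables subsample the truth at the configured schedule", {
  sim <- simulate_cultivation(site_scenario(1, seed = 12))
  expect_equal(nrow(sim$assays), sim$config$assay$n_samples)
  expect_true(all(c("acetate", "grid_index") %in% names(sim$assays)))
  expect_equal(sim$assays$time_h,
               sim$truth$time_h[sim$assays$grid_index])
  expect_true(all(sim$assays$acetate >= 0))
})
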