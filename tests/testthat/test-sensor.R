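test_that("architecture parameter count and shapes match the layer stack", {
  expect_equal(sensor_parameter_count(8, 23, 10),
               4 * 23 * (8 + 23 + 1) + (23 * 10 + 10) + (10 + 1))
  s <- build_sensor(sensor_config(seed = 1), n_features = 8)
  expect_equal(dim(s$params$Wx), c(8, 4 * 23))
  expect_equal(dim(s$params$Wh), c(23, 4 * 23))
  expect_equal(dim(s$params$W1), c(23, 10))
  expect_equal(dim(s$params$W2), c(10, 1))
  got <- sum(vapply(s$params, length, 0L))
  expect_equal(got, sensor_parameter_count(8))
  # unit forget-gate bias, non-negative output layer at init
  expect_true(all(s$params$b[24:46] == 1))
  expect_true(all(s$params$W2 >= 0) && s$params$b2 >= 0)
})

test_that("identical seeds give identical initial weights and training", {
  a <- build_sensor(sensor_config(seed = 42), n_features = 3)
  b <- build_sensor(sensor_config(seed = 42), n_features = 3)
  expect_identical(a$params, b$params)
  c <- build_sensor(sensor_config(seed = 43), n_features = 3)
  expect_false(identical(a$params, c$params))
  ds <- toy_windows()
  cfg <- quick_config(max_epochs = 15, seed = 99)
  f1 <- lstm_sensor(ds, cfg)
  f2 <- lstm_sensor(ds, cfg)
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
  expect_identical(f1$history, f2$history)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(1)
  cfg <- sensor_config(window_steps = 4, lstm_units = 5, dense_units = 3,
                       seed = 11)
  s <- build_sensor(cfg, n_features = 2)
  # keep every preactivation away from the ReLU kinks, where the
  # subgradient and the finite difference legitimately disagree
  s$params <- lapply(s$params, function(p)
    p + runif(length(p), 0.02, 0.1) * sign(runif(length(p)) - 0.4))
  X <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  y <- runif(6)
  eps <- 1e-6
  for (lt in 1:2) {
    g <- softsensr:::cpp_lstm_grad(s$params, X, y, lt)
    for (nm in names(s$params)) {
      gn <- as.numeric(g[[nm]])
      for (i in seq_along(s$params[[nm]])) {
        pp <- s$params
        pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- softsensr:::cpp_lstm_grad(pp, X, y, lt)$loss
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        lm <- softsensr:::cpp_lstm_grad(pp, X, y, lt)$loss
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - gn[i]) / max(1e-4, abs(fd), abs(gn[i])), 1e-4)
      }
    }
  }
})

test_that("predictions are non-negative, length-matched and unit-consistent", {
  set.seed(8)
  ds <- toy_windows(n = 60, seed = 8)
  s <- build_sensor(quick_config(seed = 3), n_features = 1)
  s$features <- "f"
  est <- predict(s, ds)
  expect_length(est, dim(ds$x)[1])
  expect_true(all(est >= 0))
  # adversarial inputs (huge negatives) still yield non-negative output
  ds2 <- ds; ds2$x[] <- -1e3
  expect_true(all(predict(s, ds2) >= 0))
  # all-zero weights: constant non-negative output
  s0 <- s; s0$params <- lapply(s0$params, function(p) p * 0)
  expect_equal(unique(predict(s0, ds)), 0)
  # feature-set mismatch is a contract error
  dsm <- ds; dsm$features <- "other"
  expect_error(predict(s, dsm), "mismatch")
})

test_that("a noiseless linear target is fitted to near zero error", {
  ds <- toy_windows()
  fit <- lstm_sensor(ds, quick_config(seed = 7))
  val <- softsensr:::windows_subset(ds, which(ds$provenance$experiment == "b"))
  expect_lt(mae(predict(fit, val), val$y), 0.05)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  # with dropout jittering the optimizer, early stopping fires well
  # before the epoch cap
  fit_dp <- lstm_sensor(ds, quick_config(dropout_rate = 0.2, patience = 15,
                                         seed = 7))
  expect_lt(fit_dp$stopped_epoch, 400)
  # validation loss at accepted checkpoints decreases monotonically
  vl <- fit$history$val_loss
  accepted <- vl[vl <= cummin(vl)]
  expect_true(all(diff(accepted) <= 0))
  # round trip through the target scaler preserves estimates
  sc <- fit$tscaler
  est <- predict(fit, val)
  expect_equal(drop(invert_scaler(sc, apply_scaler(sc, est))), est,
               tolerance = 1e-10)
})

test_that("shuffled targets are not learned better than the train mean", {
  base <- toy_windows(n = 120, seed = 3)
  idx_a <- which(base$provenance$experiment == "a")
  idx_b <- which(base$provenance$experiment == "b")
  val <- softsensr:::windows_subset(base, idx_b)
  ratios <- vapply(1:5, function(sd) {
    set.seed(sd)
    ds <- base
    ds$y[idx_a] <- sample(ds$y[idx_a])  # break the input-target link
    fit <- lstm_sensor(ds, quick_config(max_epochs = 120, seed = sd))
    baseline <- mae(rep(mean(ds$y[idx_a]), length(idx_b)), val$y)
    mae(predict(fit, val), val$y) / baseline
  }, 0)
  expect_gte(median(ratios), 0.8)
})

test_that("the experiment-level split never leaks windows", {
  prov <- data.frame(experiment = rep(c("a", "b", "c", "d", "e"),
                                      times = c(10, 8, 12, 9, 11)))
  sp <- softsensr:::.split_by_experiment(prov, 0.8)
  tr_exp <- unique(prov$experiment[sp$train])
  va_exp <- unique(prov$experiment[sp$val])
  expect_length(intersect(tr_exp, va_exp), 0)
  expect_setequal(c(sp$train, sp$val), seq_len(nrow(prov)))
  expect_error(softsensr:::.split_by_experiment(
    data.frame(experiment = rep("a", 5)), 0.8), "two experiments")
})

test_that("non-finite loss aborts training naming the epoch", {
  set.seed(2)
  s <- build_sensor(sensor_config(window_steps = 3, lstm_units = 4,
                                  dense_units = 3, seed = 2), n_features = 2)
  X <- array(rnorm(8 * 2 * 3), c(8, 2, 3))
  y <- c(NaN, runif(7))
  opts <- list(learning_rate = 1e-3, max_epochs = 5, batch_size = 8,
               dropout_rate = 0, patience = 5, loss_type = 1L, seed = 1L)
  expect_error(softsensr:::cpp_lstm_train(s$params, X, y, X[0, , ,
                                          drop = FALSE], numeric(0), opts),
               "diverged.*epoch")
})

test_that("off-gas and latent states carry a learnable acetate signal", {
  # noiseless simulated runs: a sensor on (OUR, CPR, biomass, mu) beats the
  # train-mean predictor at least fivefold (median over 5 seeds)
  scen <- site_scenario(1)
  for (nm in c("our_rel_sd", "cpr_rel_sd", "broth_rel_sd", "assay_rel_sd"))
    scen$noise[[nm]] <- 0
  scen$noise$assay_abs_sd_g_l <- 0
  camp <- generate_campaign(8, site = 1, base_seed = 31, scenario = scen)
  strain <- strain_params(1.0, 0.03, k_cX = 5)
  ds <- softsensr:::.campaign_windows(camp[1:6], "acetate", strain, 23, "edge")
  dsv <- softsensr:::.campaign_windows(camp[7:8], "acetate", strain, 23, "edge")
  g <- c("our", "cpr", "biomass", "mu")
  tr <- softsensr:::.windows_features(ds, g)
  va <- softsensr:::.windows_features(dsv, g)
  baseline <- mae(rep(mean(tr$y), length(va$y)), va$y)
  ratios <- vapply(1:5, function(sd) {
    fit <- lstm_sensor(tr, sensor_config(max_epochs = 60, patience = 60,
                                         seed = sd))
    baseline / mae(predict(fit, va), va$y)
  }, 0)
  expect_gte(median(ratios), 5)
})
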