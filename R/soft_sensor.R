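# The end-to-end soft-sensor fit: derive latent states, enumerate input
# groups, screen-train one sensor per group, filter by MAE and by subset
# dominance, retrain the survivors over several trials, rank them, select
# the entropy-maximizing committee and evaluate it on held-out runs.

# The full registry of candidate input variables.
FEATURE_POOL <- c("time", "our", "cpr", "broth_kg", "feed_glucose",
                  "feed_isoleucine", "s0", "induction_time",
                  "biomass", "mu", "age", "cage")

# Assemble the per-instant feature table of one run (measured + latent).
.feature_table <- function(record, strain) {
  ls <- derive_latent_states(record, strain)
  n <- length(record$times)
  zero_if_null <- function(v) if (is.null(v)) rep(0, n) else v
  cbind(time = record$times,
        our = record$our,
        cpr = zero_if_null(record$cpr),
        broth_kg = zero_if_null(record$broth_kg),
        feed_glucose = zero_if_null(record$feed_glucose),
        feed_isoleucine = zero_if_null(record$feed_isoleucine),
        s0 = rep(ifelse(is.na(record$s0), 0, record$s0), n),
        induction_time = rep(ifelse(is.na(record$induction_time), 0,
                                    record$induction_time), n),
        biomass = ls$biomass, mu = ls$mu, age = ls$age, cage = ls$cage)
}

# Normalize a run input: either a simulated_cultivation or a
# list(record = <cultivation_record>, assays = <data.frame>).
.as_run <- function(x) {
  if (inherits(x, "simulated_cultivation")) list(record = x$record,
                                                 assays = x$assays)
  else if (is.list(x) && inherits(x$record, "cultivation_record") &&
           is.data.frame(x$assays)) x[c("record", "assays")]
  else stop("runs must be simulated cultivations or list(record, assays)",
            call. = FALSE)
}

# Windows over a list of runs at the assayed instants, carrying all pool
# features; groups later subset the feature dimension.
.campaign_windows <- function(runs, target, strain, window_steps, pad) {
  feats <- NULL; targ <- NULL; at <- NULL; expid <- NULL; tms <- NULL
  offset <- 0L
  for (r in runs) {
    ft <- .feature_table(r$record, strain)
    n <- nrow(ft)
    if (!target %in% names(r$assays))
      stop("assay table lacks target solute '", target, "'", call. = FALSE)
    if (is.null(r$assays$grid_index))  # external data: snap to nearest instant
      r$assays$grid_index <- vapply(r$assays$time_h, function(t)
        which.min(abs(r$record$times - t)), integer(1))
    tv <- rep(NA_real_, n)
    tv[r$assays$grid_index] <- r$assays[[target]]
    feats <- rbind(feats, ft)
    targ <- c(targ, tv)
    at <- c(at, offset + r$assays$grid_index)
    expid <- c(expid, rep(r$record$experiment_id, n))
    tms <- c(tms, r$record$times)
    offset <- offset + n
  }
  targ[is.na(targ)] <- 0  # placeholders at non-assayed instants (never used)
  make_windows(feats, targ, window_steps = window_steps, at = at,
               experiment = expid, times = tms, pad = pad)
}

# Select a feature subset of a windowed dataset.
.windows_features <- function(ds, vars) {
  sel <- match(vars, ds$features)
  if (anyNA(sel)) stop("unknown feature(s): ",
                       paste(vars[is.na(sel)], collapse = ", "), call. = FALSE)
  ds$x <- ds$x[, , sel, drop = FALSE]
  ds$features <- vars
  ds
}

#' Fit the full soft-sensor ensemble for one solute
#'
#' Runs the whole estimation pipeline on a set of training cultivations:
#' latent physiological states are derived from each run's OUR; input
#' groups of sizes `sizes` are enumerated from `pool`; one screening sensor
#' is trained per group and groups with screening MAE above `mae_threshold`
#' or dominated by a better-scoring subset are discarded; survivors are
#' retrained `trials` times (best trial kept) and ranked by MAE; nested
#' committees of growing size are scored by Shannon entropy and the
#' entropy-maximizing committee, with RMSE-derived weights, becomes the
#' estimator. Model MAE/RMSE for ranking and weighting are computed on the
#' experiment-level hold-out split of the training runs; the returned
#' validation metrics come from `val_runs`, which the fit never sees.
#'
#' @param train_runs list of training cultivations (simulated cultivations
#'   or `list(record, assays)` pairs).
#' @param val_runs list of held-out cultivations for final evaluation.
#' @param target solute name present in the assay tables (default
#'   `"acetate"`).
#' @param strain a [strain_params()] for the latent-state derivation.
#' @param pool candidate input variables (subset of the feature registry).
#' @param sizes input-group sizes to enumerate.
#' @param config a [sensor_config()].
#' @param trials retraining trials per surviving group (best kept).
#' @param screen_config optional cheaper [sensor_config()] used for the
#'   screening pass only (the coarse ranking tolerates fewer epochs);
#'   `NULL` screens with `config`.
#' @param mae_threshold screening MAE cutoff in g/L.
#' @param max_committee largest committee size considered.
#' @param prob_source `"occurrence"` or `"explanation"` probabilities for
#'   the entropy criterion.
#' @param seed integer seed governing all randomized steps.
#' @param verbose print progress.
#' @return A `soft_sensor` object with the evaluation tables, the fitted
#'   member sensors, the selected committee and the validation metrics.
#' @export
soft_sensor <- function(train_runs, val_runs, target = "acetate",
                        strain, pool = FEATURE_POOL, sizes = 3:5,
                        config = sensor_config(), trials = 3,
                        screen_config = NULL,
                        mae_threshold = 0.5, max_committee = 14,
                        prob_source = c("occurrence", "explanation"),
                        seed = 1, verbose = FALSE) {
  prob_source <- match.arg(prob_source)
  stopifnot(inherits(strain, "strain_params"))
  if (!all(pool %in% FEATURE_POOL))
    stop("unknown pool variable(s): ",
         paste(setdiff(pool, FEATURE_POOL), collapse = ", "), call. = FALSE)
  train_runs <- lapply(train_runs, .as_run)
  val_runs <- lapply(val_runs, .as_run)
  set.seed(as.integer(seed))

  say <- function(...) if (verbose) cat(sprintf(...))
  ds_all <- .campaign_windows(train_runs, target, strain,
                              config$window_steps, config$pad)
  ds_val <- .campaign_windows(val_runs, target, strain,
                              config$window_steps, config$pad)

  # experiment-level split: weight updates vs early stopping + ranking
  exps <- unique(ds_all$provenance$experiment)
  n_tr <- max(1L, min(length(exps) - 1L,
                      round(config$train_fraction * length(exps))))
  tr_exp <- sample(exps, n_tr)
  idx_tr <- which(ds_all$provenance$experiment %in% tr_exp)
  idx_ev <- which(!ds_all$provenance$experiment %in% tr_exp)
  ds_tr <- windows_subset(ds_all, idx_tr)
  ds_ev <- windows_subset(ds_all, idx_ev)

  groups <- enumerate_input_groups(pool, min(sizes), max(sizes))
  say("screening %d input groups\n", length(groups))
  train_one <- function(g, sd, base_cfg = config) {
    cfg <- base_cfg; cfg$seed <- sd
    sub_tr <- .windows_features(ds_tr, g)
    sub_ev <- .windows_features(ds_ev, g)
    s <- lstm_sensor(sub_tr, cfg, val = sub_ev)
    est <- predict(s, sub_ev)
    list(sensor = s, mae = mae(est, sub_ev$y))
  }
  if (is.null(screen_config)) screen_config <- config
  seeds_screen <- sample.int(.Machine$integer.max - 1L, length(groups))
  screen_mae <- numeric(length(groups))
  for (i in seq_along(groups)) {
    screen_mae[i] <- train_one(groups[[i]], seeds_screen[i], screen_config)$mae
    if (i %% 25 == 0) say("  %d/%d groups screened\n", i, length(groups))
  }
  evals_screen <- model_evaluation(groups, mae = screen_mae, n_trials = 1L)

  kept <- filter_by_mae(evals_screen, mae_threshold)
  say("%d groups at or below %.2f g/L MAE\n", nrow(kept), mae_threshold)
  kept <- subset_dominance_filter(kept)
  say("%d groups after subset-dominance filtering\n", nrow(kept))
  if (nrow(kept) == 0L)
    stop("no input group survived filtering; relax 'mae_threshold'",
         call. = FALSE)

  say("retraining %d groups x %d trials\n", nrow(kept), trials)
  seeds_re <- matrix(sample.int(.Machine$integer.max - 1L,
                                nrow(kept) * trials), nrow(kept), trials)
  members <- vector("list", nrow(kept))
  fin_mae <- fin_rss <- fin_r2 <- fin_rmse <- numeric(nrow(kept))
  trial_mae <- vector("list", nrow(kept))
  obs_ev <- .windows_features(ds_ev, kept$group[[1]])$y
  for (i in seq_len(nrow(kept))) {
    fits <- lapply(seq_len(trials), function(k)
      train_one(kept$group[[i]], seeds_re[i, k]))
    maes <- vapply(fits, `[[`, numeric(1), "mae")
    best <- which.min(maes)
    members[[i]] <- fits[[best]]$sensor
    sub_ev <- .windows_features(ds_ev, kept$group[[i]])
    est <- predict(members[[i]], sub_ev)
    fin_mae[i] <- maes[best]
    fin_rss[i] <- rss(est, sub_ev$y)
    fin_r2[i] <- r_squared(est, sub_ev$y)
    fin_rmse[i] <- rmse_from_rss(fin_rss[i], length(est))
    trial_mae[[i]] <- maes
  }
  evals <- model_evaluation(kept$group, mae = fin_mae, rss = fin_rss,
                            r2 = fin_r2, rmse = fin_rmse,
                            n_trials = trials, trial_mae = trial_mae)
  ord <- order(evals$mae)
  evals <- evals[ord, , drop = FALSE]
  members <- members[ord]

  explain_cb <- NULL
  if (prob_source == "explanation") {
    explain_cb <- function(member_idx) {
      dss <- lapply(member_idx, function(i)
        .windows_features(ds_ev, evals$group[[i]]))
      explanation_probabilities(members[member_idx], dss)
    }
  }
  committee <- select_committee(evals, max_size = max_committee,
                                prob_source = prob_source,
                                explain_probs = explain_cb)

  # held-out validation: per-member predictions, committee estimate, and
  # the MAE-vs-size curve over the nested committees
  max_k <- min(max_committee, nrow(evals))
  pred_val <- vapply(seq_len(max_k), function(i)
    predict(members[[i]], .windows_features(ds_val, evals$group[[i]])),
    numeric(length(ds_val$y)))
  pred_val <- matrix(pred_val, ncol = max_k)
  mae_by_size <- vapply(seq_len(max_k), function(k) {
    w <- if (k == 1L) 1 else ensemble_weights(evals$rmse[seq_len(k)])
    mae(committee_predict(pred_val[, seq_len(k), drop = FALSE], w), ds_val$y)
  }, numeric(1))
  est_comm <- committee_predict(pred_val[, committee$members, drop = FALSE],
                                committee$weights)
  validation <- list(
    observations = ds_val$y,
    estimates = est_comm,
    provenance = ds_val$provenance,
    member_mae = vapply(seq_len(max_k), function(i)
      mae(pred_val[, i], ds_val$y), numeric(1)),
    mae = mae(est_comm, ds_val$y),
    r2 = r_squared(est_comm, ds_val$y),
    nmae = nmae(mae(est_comm, ds_val$y), ds_val$y),
    mae_by_size = data.frame(size = seq_len(max_k), mae = mae_by_size),
    best_single_mae = mae_by_size[1],  # the top-ranked model on its own
    train_mean_baseline_mae = mae(rep(mean(ds_tr$y), length(ds_val$y)),
                                  ds_val$y)
  )

  structure(list(target = target, strain = strain, pool = pool,
                 sizes = sizes, config = config, seed = seed,
                 evals_screen = evals_screen, evals = evals,
                 members = members, committee = committee,
                 validation = validation,
                 train_experiments = tr_exp,
                 eval_experiments = setdiff(exps, tr_exp)),
            class = "soft_sensor")
}

#' @export
print.soft_sensor <- function(x, ...) {
  cat(sprintf("Soft sensor for %s: %d groups screened, %d retrained, committee of %d\n",
              x$target, nrow(x$evals_screen), nrow(x$evals),
              x$committee$size))
  cat(sprintf("  committee entropy %.3f bits (%s probabilities)\n",
              x$committee$entropy, x$committee$prob_source))
  cat(sprintf("  validation: MAE %.4f g/L, R2 %.3f, nMAE %.3f (best single model %.4f g/L)\n",
              x$validation$mae, x$validation$r2, x$validation$nmae,
              x$validation$best_single_mae))
  invisible(x)
}

#' @export
summary.soft_sensor <- function(object, ...) {
  cat("Ranked surviving input groups:\n")
  print(data.frame(group = object$evals$group_id,
                   mae = signif(object$evals$mae, 4),
                   rmse = signif(object$evals$rmse, 4),
                   r2 = signif(object$evals$r2, 3)), row.names = FALSE)
  cat("\n")
  print(object$committee)
  cat("\nValidation MAE by committee size:\n")
  print(object$validation$mae_by_size, row.names = FALSE)
  invisible(object)
}

#' @export
weights.soft_sensor <- function(object, ...) object$committee$weights

#' Predict solute concentrations for new cultivations
#'
#' Derives the latent states of each new run, cuts windows, runs every
#' committee member and returns the weighted committee estimate.
#'
#' @param object a fitted `soft_sensor`.
#' @param newdata list of cultivations (simulated cultivations, or
#'   `list(record, assays)`; assays are only needed with `at = "assays"`).
#' @param at `"assays"` estimates at the assayed instants; `"all"` at every
#'   sampling instant.
#' @param ... unused.
#' @return Data frame with experiment, time and the committee estimate.
#' @export
predict.soft_sensor <- function(object, newdata, at = c("assays", "all"),
                                ...) {
  at <- match.arg(at)
  if (inherits(newdata, "simulated_cultivation") ||
      (is.list(newdata) && inherits(newdata$record, "cultivation_record")))
    newdata <- list(newdata)
  runs <- lapply(newdata, function(r) {
    r <- if (at == "assays") .as_run(r)
         else list(record = (if (inherits(r, "simulated_cultivation")) r$record
                             else r$record),
                   assays = NULL)
    if (at == "all") {
      n <- length(r$record$times)
      r$assays <- data.frame(time_h = r$record$times, grid_index = seq_len(n))
      r$assays[[object$target]] <- 0
    }
    r
  })
  ds <- .campaign_windows(runs, object$target, object$strain,
                          object$config$window_steps, object$config$pad)
  pred <- vapply(committee_members(object), function(i)
    predict(object$members[[i]],
            .windows_features(ds, object$evals$group[[i]])),
    numeric(length(ds$y)))
  est <- committee_predict(matrix(pred, ncol = object$committee$size),
                           object$committee$weights)
  data.frame(experiment = ds$provenance$experiment,
             time_h = ds$provenance$end_time, estimate = est)
}

# indices of the committee members within the ranked evaluation table
committee_members <- function(object) object$committee$members

#' @export
plot.soft_sensor <- function(x, which = c("entropy", "mae"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    old <- par(mfrow = c(1, length(which)))
    on.exit(par(old))
  }
  if ("entropy" %in% which) plot(x$committee)
  if ("mae" %in% which) {
    plot(x$validation$mae_by_size$size, x$validation$mae_by_size$mae,
         type = "b", xlab = "committee size", ylab = "validation MAE [g/L]",
         main = "MAE vs committee size")
    abline(v = x$committee$size, lty = 2)
  }
  invisible(x)
}
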