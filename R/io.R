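# CSV / YAML interfaces: cultivation records travel as a CSV time-series
# table plus a YAML metadata sidecar; latent states, assay tables and
# evaluation tables are plain CSV; committee manifests are YAML.

#' Write / read a cultivation record as CSV + YAML sidecar
#'
#' The CSV holds the per-instant series (`time_h`, `our`, `cpr`,
#' `broth_kg`, `feed_glucose`, `feed_isoleucine`); the sidecar
#' (`<path>.yaml`) holds the scalar metadata: experiment id, `x0`, `s0`,
#' induction time and the declared units.
#'
#' @param record a [cultivation_record()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_cultivation_record` returns `path` invisibly;
#'   `read_cultivation_record` returns a [cultivation_record()].
#' @export
write_cultivation_record <- function(record, path) {
  write.csv(as.data.frame(record), path, row.names = FALSE)
  meta <- list(experiment_id = record$experiment_id, x0_g_l = record$x0,
               s0_g_l = record$s0,
               induction_time_h = record$induction_time,
               units = list(time = "h", our = "g/L/h", cpr = "g/L/h",
                            broth = "kg", feed = "g/h"))
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_cultivation_record
#' @export
read_cultivation_record <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_h", "our") %in% names(d)))
    stop("record CSV must contain columns 'time_h' and 'our' (file: ",
         path, ")", call. = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  cultivation_record(
    times = d$time_h, our = d$our, cpr = d$cpr, broth_kg = d$broth_kg,
    feed_glucose = d$feed_glucose, feed_isoleucine = d$feed_isoleucine,
    x0 = meta$x0_g_l, s0 = if (is.null(meta$s0_g_l)) NA_real_ else meta$s0_g_l,
    induction_time = if (is.null(meta$induction_time_h)) NA_real_
                     else meta$induction_time_h,
    experiment_id = meta$experiment_id)
}

#' Write latent states or an evaluation table as CSV
#' @param x a `latent_states` data frame or [model_evaluation()] table.
#' @param path output CSV path.
#' @export
write_states_csv <- function(x, path) {
  if (inherits(x, "model_evaluation")) {
    d <- data.frame(group_id = x$group_id,
                    variables = vapply(x$group, paste, character(1),
                                       collapse = ";"),
                    mae = x$mae, rss = x$rss, r2 = x$r2, rmse = x$rmse,
                    n_trials = x$n_trials)
  } else d <- as.data.frame(x)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a committee manifest as YAML
#' @param committee a `sensor_committee`.
#' @param path output YAML path.
#' @param extra optional named list merged into the manifest (seeds,
#'   versions, timings).
#' @export
write_committee_manifest <- function(committee, path, extra = list()) {
  manifest <- c(list(
    size = committee$size,
    members = as.list(committee$member_ids),
    weights = as.numeric(committee$weights),
    entropy_bits = committee$entropy,
    prob_source = committee$prob_source,
    occurrence_probs = as.list(committee$occurrence_probs)
  ), extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
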