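# Sliding-window dataset preparation and min-max feature scaling for the
# recurrent sensor. Windows never span two experiments; each window's target
# is the solute value at the window's final instant, and windows are built
# only at instants where the target was actually assayed.

#' Fit a per-feature min-max scaler
#'
#' Affine map of each feature to `[0, 1]`, fitted on the supplied (training)
#' data only. A constant feature is mapped by `x - min` with scale 1 (a
#' warning is logged). Values outside the fitting range scale beyond
#' `[0, 1]`; no clipping is applied.
#'
#' @param x numeric matrix (rows = instants, columns = features) or vector.
#' @return A `minmax_scaler` with `min` and `range` per feature.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning("constant feature(s) ",
            paste(colnames(x)[rng == 0], collapse = ", "),
            ": scaling by 1, shifting by min", call. = FALSE)
    rng[rng == 0] <- 1
  }
  structure(list(min = mins, range = rng), class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$min, "-"), 2, scaler$range, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$range, "*"), 2, scaler$min, "+")
}

#' Build sliding windows over one or more experiments
#'
#' Cuts fixed-length input sequences ending at selected instants. The first
#' `window_steps - 1` instants of an experiment have incomplete history; in
#' the default `pad = "edge"` mode the first instant is replicated backwards
#' to fill the window, while `pad = "strict"` drops those instants.
#'
#' @param features numeric matrix (instants x features) with column names.
#' @param target numeric target series aligned with `features` (values only
#'   needed at `at`).
#' @param window_steps window length in instants (default 23).
#' @param at integer indices of the instants at which windows are built
#'   (default: every instant). Use the assayed instants so targets are
#'   measurements, never interpolations.
#' @param experiment single experiment id, or one id per instant; windows
#'   never span two experiments.
#' @param times optional instant times recorded as window provenance.
#' @param pad `"edge"` (replicate the first instant) or `"strict"` (drop
#'   windows with incomplete history).
#' @return A `windowed_dataset`: array `x` of dim (windows, steps,
#'   features), vector `y`, and a `provenance` data frame (experiment id,
#'   end index, end time).
#' @export
make_windows <- function(features, target, window_steps = 23, at = NULL,
                         experiment = "run", times = NULL,
                         pad = c("edge", "strict")) {
  pad <- match.arg(pad)
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n)
    stop("'features' and 'target' must be aligned on the same grid",
         call. = FALSE)
  if (n < 1L) stop("need at least one instant", call. = FALSE)
  if (window_steps < 1L) stop("'window_steps' must be >= 1", call. = FALSE)
  if (is.null(at)) at <- seq_len(n)
  if (any(at < 1L | at > n)) stop("'at' indices out of range", call. = FALSE)
  if (length(experiment) == 1L) experiment <- rep(experiment, n)
  if (length(experiment) != n)
    stop("'experiment' must be a single id or one per instant", call. = FALSE)
  if (is.null(times)) times <- seq_len(n)

  exps <- unique(experiment)
  xs <- list(); ys <- list(); prov <- list()
  for (ex in exps) {
    rows <- which(experiment == ex)
    sel <- at[experiment[at] == ex]
    if (pad == "strict") sel <- sel[match(sel, rows) >= window_steps]
    if (!length(sel)) next
    xa <- array(NA_real_, c(length(sel), window_steps, ncol(features)))
    for (k in seq_along(sel)) {
      i <- sel[k]
      idx <- (i - window_steps + 1L):i
      idx[idx < rows[1]] <- rows[1]  # edge padding within the experiment
      xa[k, , ] <- features[idx, , drop = FALSE]
    }
    xs[[ex]] <- xa
    ys[[ex]] <- target[sel]
    prov[[ex]] <- data.frame(experiment = ex, end_index = sel,
                             end_time = times[sel],
                             stringsAsFactors = FALSE)
  }
  if (!length(xs))
    stop("no windows could be built (strict mode dropped everything?)",
         call. = FALSE)
  x <- do.call(abind_first, xs)
  structure(list(x = x, y = unlist(ys, use.names = FALSE),
                 provenance = do.call(rbind, c(prov, make.row.names = FALSE)),
                 features = colnames(features),
                 window_steps = window_steps),
            class = "windowed_dataset")
}

# rbind for 3-d arrays along the first margin
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 0)),
                           d[2], d[3]))
  at <- 1L
  for (p in parts) {
    np <- dim(p)[1]
    out[at:(at + np - 1L), , ] <- p
    at <- at + np
  }
  out
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed dataset: %d windows x %d steps x %d features (%s)\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              paste(x$features, collapse = ", ")))
  cat(sprintf("  experiments: %s\n",
              paste(unique(x$provenance$experiment), collapse = ", ")))
  invisible(x)
}

# Subset a windowed dataset by window index.
windows_subset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , , drop = FALSE], y = ds$y[idx],
                 provenance = ds$provenance[idx, , drop = FALSE],
                 features = ds$features, window_steps = ds$window_steps),
            class = "windowed_dataset")
}

# Scale a windowed dataset's features (and optionally target) in place.
windows_scale <- function(ds, fscaler, tscaler = NULL) {
  for (f in seq_len(dim(ds$x)[3]))
    ds$x[, , f] <- (ds$x[, , f] - fscaler$min[f]) / fscaler$range[f]
  if (!is.null(tscaler)) ds$y <- drop(apply_scaler(tscaler, ds$y))
  ds
}
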