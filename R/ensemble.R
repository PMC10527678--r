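# Input-group enumeration, model filtering, RMSE-weighted committees and
# Shannon-entropy committee-size selection.

#' Enumerate candidate input groups
#'
#' All subsets of the variable pool with sizes in `[min_size, max_size]`,
#' in deterministic order (by size, then lexicographic position within the
#' pool).
#'
#' @param pool character vector of candidate variable names (no duplicates).
#' @param min_size,max_size inclusive bounds on the group size. `max_size`
#'   is capped at the pool size.
#' @return A list of character vectors, each one input group.
#' @examples
#' length(enumerate_input_groups(letters[1:5], 3, 5))  # choose(5,3)+...= 16
#' @export
enumerate_input_groups <- function(pool, min_size = 3, max_size = 11) {
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("'pool' contains duplicates", call. = FALSE)
  if (max_size < min_size) stop("'max_size' < 'min_size'", call. = FALSE)
  if (length(pool) < min_size)
    stop("pool smaller than 'min_size'", call. = FALSE)
  max_size <- min(max_size, length(pool))
  out <- list()
  for (k in min_size:max_size) {
    m <- combn(pool, k, simplify = FALSE)
    out <- c(out, m)
  }
  out
}

#' Evaluation table for a set of trained models
#'
#' Assembles per-group metrics into the table the filtering and committee
#' steps consume. `group` is a list column of character vectors.
#'
#' @param groups list of input groups (character vectors).
#' @param mae,rss,r2,rmse numeric metric vectors, one value per group.
#' @param n_trials number of training trials behind each row.
#' @param trial_mae optional list of per-trial MAE vectors.
#' @return A `model_evaluation` data frame.
#' @export
model_evaluation <- function(groups, mae, rss = NA_real_, r2 = NA_real_,
                             rmse = NA_real_, n_trials = 1L,
                             trial_mae = NULL) {
  n <- length(groups)
  d <- data.frame(
    group_id = vapply(groups, paste, character(1), collapse = "+"),
    mae = rep_len(mae, n), rss = rep_len(rss, n), r2 = rep_len(r2, n),
    rmse = rep_len(rmse, n), n_trials = rep_len(as.integer(n_trials), n),
    stringsAsFactors = FALSE
  )
  d$group <- I(groups)
  if (!is.null(trial_mae)) d$trial_mae <- I(trial_mae)
  class(d) <- c("model_evaluation", "data.frame")
  d
}

#' Drop input groups whose error exceeds a threshold
#'
#' Groups with a mean absolute error strictly greater than `threshold` are
#' excluded; a group exactly at the threshold is kept.
#'
#' @param evals a [model_evaluation()] table.
#' @param threshold MAE cutoff in g/L (default 0.5).
#' @return The surviving rows, original order preserved.
#' @export
filter_by_mae <- function(evals, threshold = 0.5) {
  if (nrow(evals) == 0L) stop("'evals' is empty", call. = FALSE)
  keep <- evals$mae <= threshold
  if (!any(keep))
    warning("no input group at or below the MAE threshold", call. = FALSE)
  evals[keep, , drop = FALSE]
}

#' Drop groups dominated by a better-scoring subset
#'
#' A group is dropped when some other group is a proper subset of it and
#' has a strictly lower MAE: the extra variables bought no accuracy. Ties in
#' MAE keep both groups. The result is ordered by MAE ascending.
#'
#' @param evals a [model_evaluation()] table carrying `group` and `mae`.
#' @return The surviving rows, sorted by MAE.
#' @export
subset_dominance_filter <- function(evals) {
  n <- nrow(evals)
  if (n == 0L) return(evals)
  groups <- evals$group
  drop <- logical(n)
  for (i in seq_len(n)) {
    gi <- groups[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      gj <- groups[[j]]
      if (length(gj) < length(gi) && all(gj %in% gi) &&
          evals$mae[j] < evals$mae[i]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  out <- evals[!drop, , drop = FALSE]
  out[order(out$mae), , drop = FALSE]
}

#' RMSE-derived ensemble weights
#'
#' Members with lower RMSE receive larger weights:
#' `w_i = (sum_j RMSE_j - RMSE_i) / (sum_j RMSE_j * (n - 1))`.
#' The weights sum to one by construction. A single member receives weight
#' 1 by convention.
#'
#' @param rmses positive RMSE values, one per committee member.
#' @return Numeric weight vector summing to 1.
#' @examples
#' ensemble_weights(c(1, 3))  # 0.75 0.25
#' @export
ensemble_weights <- function(rmses) {
  n <- length(rmses)
  if (n == 0L) stop("no committee members", call. = FALSE)
  if (any(!is.finite(rmses)) || any(rmses <= 0))
    stop("all RMSE values must be positive and finite", call. = FALSE)
  if (n == 1L) return(1)
  s <- sum(rmses)
  (s - rmses) / (s * (n - 1))
}

#' Weighted-average committee prediction
#'
#' Pointwise weighted sum of member predictions. Weights are used as-is
#' (they are already normalized by [ensemble_weights()]).
#'
#' @param predictions numeric matrix, one column per member, one row per
#'   evaluation point (a plain vector is treated as a single member).
#' @param weights weight vector matching the member count.
#' @return Numeric vector of committee estimates.
#' @export
committee_predict <- function(predictions, weights) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) != length(weights))
    stop("number of prediction columns must match number of weights",
         call. = FALSE)
  drop(predictions %*% weights)
}

#' Occurrence probability of each variable within a committee
#'
#' For each variable in the union of the members' input groups, the number
#' of members whose group contains it divided by the number of members.
#' The values are per-variable presence frequencies and are deliberately
#' not renormalized into a distribution across variables.
#'
#' @param groups list of the members' input groups (character vectors).
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @examples
#' occurrence_probabilities(list(c("A", "B"), c("A", "C")))
#' @export
occurrence_probabilities <- function(groups) {
  if (length(groups) == 0L) stop("no committee members", call. = FALSE)
  vars <- sort(unique(unlist(groups)))
  counts <- vapply(vars, function(v)
    sum(vapply(groups, function(g) v %in% g, logical(1))), numeric(1))
  counts / length(groups)
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum p log2 p` in bits, with the convention `0 log2 0 = 0`. The
#' input need not be a normalized distribution (committee occurrence
#' frequencies are applied literally).
#'
#' @param probs probabilities in `[0, 1]`.
#' @return Entropy in bits (non-negative for probabilities <= 1).
#' @examples
#' shannon_entropy(rep(1/8, 8))  # 3 bits
#' @export
shannon_entropy <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  p <- probs[probs > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' Select the committee size maximizing Shannon entropy
#'
#' Builds nested committees of sizes `1..max_size` from an MAE-ranked
#' evaluation table (size k = the k best models), computes each committee's
#' entropy from its members' input-variable probabilities, and returns the
#' committee with maximum entropy; ties are broken toward the smallest
#' committee.
#'
#' @param ranked_evals a [model_evaluation()] table sorted by MAE ascending
#'   with valid `rmse` values.
#' @param max_size largest committee considered (default 14, capped at the
#'   number of available models).
#' @param prob_source how per-variable probabilities are computed:
#'   `"occurrence"` counts group membership; `"explanation"` requires
#'   `explain_probs`, a function `(members_index) -> named probabilities`
#'   (e.g. wrapping [explanation_probabilities()]).
#' @param explain_probs optional probability callback for
#'   `prob_source = "explanation"`.
#' @return A `sensor_committee` object: member indices into `ranked_evals`,
#'   Eq.-style RMSE weights, the probabilities, entropy, and the per-size
#'   entropy table.
#' @export
select_committee <- function(ranked_evals, max_size = 14,
                             prob_source = c("occurrence", "explanation"),
                             explain_probs = NULL) {
  prob_source <- match.arg(prob_source)
  n <- nrow(ranked_evals)
  if (n == 0L) stop("empty model ranking", call. = FALSE)
  if (is.unsorted(ranked_evals$mae))
    stop("'ranked_evals' must be sorted by MAE ascending", call. = FALSE)
  max_size <- min(max_size, n)
  sizes <- seq_len(max_size)
  probs_for <- function(k) {
    if (prob_source == "occurrence")
      occurrence_probabilities(ranked_evals$group[seq_len(k)])
    else {
      if (is.null(explain_probs))
        stop("'explain_probs' callback required for explanation probabilities",
             call. = FALSE)
      explain_probs(seq_len(k))
    }
  }
  plist <- lapply(sizes, probs_for)
  hs <- vapply(plist, shannon_entropy, numeric(1))
  best <- which.max(hs)  # which.max returns the first (smallest) maximizer
  k <- sizes[best]
  weights <- if (k == 1L) 1 else ensemble_weights(ranked_evals$rmse[seq_len(k)])
  structure(list(
    size = k,
    members = seq_len(k),
    member_ids = ranked_evals$group_id[seq_len(k)],
    groups = ranked_evals$group[seq_len(k)],
    weights = weights,
    occurrence_probs = plist[[best]],
    entropy = hs[best],
    prob_source = prob_source,
    entropy_by_size = data.frame(size = sizes, entropy = hs)
  ), class = "sensor_committee")
}

#' @export
print.sensor_committee <- function(x, ...) {
  cat(sprintf("Sensor committee: %d member(s), entropy %.3f bits (%s probabilities)\n",
              x$size, x$entropy, x$prob_source))
  cat("  members (MAE rank order):\n")
  for (i in seq_len(x$size))
    cat(sprintf("    %2d. %-40s w = %.4f\n", i, x$member_ids[i], x$weights[i]))
  invisible(x)
}

#' @export
weights.sensor_committee <- function(object, ...) object$weights

#' @export
plot.sensor_committee <- function(x, ...) {
  plot(x$entropy_by_size$size, x$entropy_by_size$entropy, type = "b",
       xlab = "committee size", ylab = "entropy [bits]",
       main = "Entropy vs committee size", ...)
  abline(v = x$size, lty = 2)
  invisible(x)
}
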