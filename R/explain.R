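# Perturbation-based local surrogate explanations: for each data point a
# local ridge-regression surrogate is fitted to the sensor's response around
# the point's window; the top-ranked window features are collected and
# mapped back to their source variables, yielding per-variable importance
# probabilities usable in place of occurrence counts for the entropy
# criterion.

#' Explanation-derived variable probabilities for a committee
#'
#' For every selected data point and every committee member, perturbs the
#' point's input window (Gaussian perturbations in the member's scaled
#' feature space), fits a proximity-weighted local linear surrogate to the
#' member's predictions, and ranks the windowed features by the magnitude
#' of their surrogate coefficients. The `top_k` features of each point are
#' collected; a window feature counts toward its source variable regardless
#' of its time lag. The per-variable counts divided by the total number of
#' collected features give `p(x)` (summing to 1 across variables).
#'
#' @param members list of fitted [lstm_sensor] objects.
#' @param datasets list of windowed datasets (original units), one per
#'   member, aligned with `members`; a single dataset is recycled.
#' @param top_k number of top-ranked window features collected per data
#'   point (default 20).
#' @param n_perturb perturbation samples per data point.
#' @param n_points maximum number of data points explained per member
#'   (evenly spaced subset; `NULL` = all).
#' @param perturb_sd standard deviation of the perturbations in scaled
#'   feature space.
#' @param kernel_width proximity kernel width (in scaled distance units).
#' @param ridge ridge penalty of the local surrogate.
#' @return Named numeric vector of per-variable probabilities.
#' @export
explanation_probabilities <- function(members, datasets, top_k = 20,
                                      n_perturb = 80, n_points = 25,
                                      perturb_sd = 0.3, kernel_width = 0.75,
                                      ridge = 1e-3) {
  if (!length(members)) stop("no committee members", call. = FALSE)
  if (inherits(datasets, "windowed_dataset"))
    datasets <- rep(list(datasets), length(members))
  counts <- numeric(0)
  total <- 0
  for (m in seq_along(members)) {
    sensor <- members[[m]]
    ds <- datasets[[m]]
    scl <- windows_scale(ds, sensor$fscaler)
    n <- dim(scl$x)[1]; Tn <- dim(scl$x)[2]; Fn <- dim(scl$x)[3]
    var_of <- rep(ds$features, each = Tn)  # column-major (T, F) flatten
    k <- min(top_k, Tn * Fn)
    pts <- if (is.null(n_points) || n_points >= n) seq_len(n)
           else unique(round(seq(1, n, length.out = n_points)))
    for (p in pts) {
      w0 <- as.vector(scl$x[p, , ])
      Z <- matrix(rnorm(n_perturb * length(w0), 0, perturb_sd),
                  n_perturb, length(w0))
      Zx <- sweep(Z, 2, w0, "+")
      cube <- array(t(Zx), c(Tn, Fn, n_perturb))        # (T, F) per sample
      cube <- aperm(cube, c(3, 2, 1))                   # (n, F, T)
      pred <- as.numeric(cpp_lstm_predict(sensor$params, cube))
      wts <- exp(-rowSums(Z^2) / (length(w0) * kernel_width^2))
      A <- crossprod(Z * wts, Z) + diag(ridge, ncol(Z))
      coefs <- solve(A, crossprod(Z * wts, pred - mean(pred)))
      top <- order(abs(coefs), decreasing = TRUE)[seq_len(k)]
      tv <- table(var_of[top])
      counts[names(tv)] <- ifelse(is.na(counts[names(tv)]), 0,
                                  counts[names(tv)]) + as.numeric(tv)
      total <- total + k
    }
  }
  counts[is.na(counts)] <- 0
  counts / total
}
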