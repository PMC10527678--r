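# The recurrent soft sensor: configuration, architecture construction,
# training and prediction. The layer stack is fixed:
#   LSTM(units, ReLU) -> dropout -> dense(dense_units, ReLU) -> dropout
#   -> dense(1) with non-negative kernel and bias.

#' Sensor configuration
#'
#' Hyperparameters of the recurrent soft sensor. The defaults are the
#' reference configuration: 23-step windows, an LSTM layer of 23 units with
#' ReLU activation, two dropout layers at rate 0.2, a 10-unit ReLU dense
#' layer, a single non-negative output unit, Adam at learning rate 0.001,
#' batch size 16, at most 1000 epochs with early stopping on the validation
#' loss (patience 50, best weights restored), and an 80/20 train/validation
#' split applied at the experiment level.
#'
#' @param window_steps input sequence length (instants).
#' @param lstm_units LSTM layer width.
#' @param dense_units width of the intermediate dense layer.
#' @param dropout_rate dropout rate of both dropout layers, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param train_fraction fraction of experiments used for weight updates
#'   when the sensor splits its own early-stopping hold-out.
#' @param loss `"mmse"`: mean((|error| + 1)^2), the modified mean-square
#'   loss emphasizing sub-unit errors; `"scaled_mae"`: sum(|error| + 1)/(2n).
#' @param pad window left-edge handling, see [make_windows()].
#' @param seed integer seed for weight initialization, shuffling and
#'   dropout; `NULL` leaves the RNG state alone.
#' @return A `sensor_config` list.
#' @export
sensor_config <- function(window_steps = 23, lstm_units = 23,
                          dense_units = 10, dropout_rate = 0.2,
                          learning_rate = 0.001, max_epochs = 1000,
                          batch_size = 16, patience = 50,
                          train_fraction = 0.8,
                          loss = c("mmse", "scaled_mae"),
                          pad = c("edge", "strict"), seed = NULL) {
  loss <- match.arg(loss)
  pad <- match.arg(pad)
  if (window_steps < 1) stop("'window_steps' must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)", call. = FALSE)
  structure(list(window_steps = window_steps, lstm_units = lstm_units,
                 dense_units = dense_units, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 batch_size = batch_size, patience = patience,
                 train_fraction = train_fraction, loss = loss, pad = pad,
                 seed = seed), class = "sensor_config")
}

#' Trainable parameter count of the sensor architecture
#'
#' `4 H (F + H + 1)` for the LSTM (four gates over input, recurrent and
#' bias terms) plus the two dense layers.
#'
#' @param n_features number of input variables F.
#' @param lstm_units LSTM width H.
#' @param dense_units dense layer width D.
#' @export
sensor_parameter_count <- function(n_features, lstm_units = 23,
                                   dense_units = 10) {
  4 * lstm_units * (n_features + lstm_units + 1) +
    (lstm_units * dense_units + dense_units) + (dense_units + 1)
}

.glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

#' Build an untrained sensor
#'
#' Initializes the fixed layer stack for a given number of input features:
#' Glorot-uniform kernels, zero biases with a unit forget-gate bias, and a
#' non-negative output layer. Two builds under the same seed produce
#' identical initial weights.
#'
#' @param config a [sensor_config()].
#' @param n_features number of input variables.
#' @param features optional character vector of feature names (the sensor's
#'   input group).
#' @return An `lstm_sensor` object (untrained: empty history).
#' @export
build_sensor <- function(config = sensor_config(), n_features,
                         features = NULL) {
  stopifnot(inherits(config, "sensor_config"))
  if (!is.null(features)) n_features <- length(features)
  H <- config$lstm_units
  D <- config$dense_units
  if (!is.null(config$seed)) set.seed(config$seed)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # unit forget-gate bias
  params <- list(
    Wx = .glorot(n_features, 4 * H),
    Wh = .glorot(H, 4 * H),
    b = b,
    W1 = .glorot(H, D),
    b1 = rep(0, D),
    W2 = abs(.glorot(D, 1)),
    b2 = 0
  )
  structure(list(params = params, config = config,
                 features = features, n_features = n_features,
                 fscaler = NULL, tscaler = NULL,
                 history = NULL, best_epoch = NA_integer_,
                 stopped_epoch = NA_integer_, val_loss = NA_real_),
            class = "lstm_sensor")
}

# Split window indices into train / early-stopping sets by experiment.
.split_by_experiment <- function(prov, train_fraction) {
  exps <- unique(prov$experiment)
  if (length(exps) < 2L)
    stop("need at least two experiments to split by experiment; ",
         "pass an explicit 'val' dataset instead", call. = FALSE)
  n_tr <- max(1L, min(length(exps) - 1L, round(train_fraction * length(exps))))
  tr_exp <- exps[seq_len(n_tr)]
  list(train = which(prov$experiment %in% tr_exp),
       val = which(!prov$experiment %in% tr_exp))
}

#' Fit a recurrent soft sensor
#'
#' Trains the LSTM stack on a windowed dataset. Min-max scalers for the
#' features and the target are fitted on the training split only; training
#' minimizes the configured loss with Adam, stopping early on the
#' validation loss and restoring the best weights. When `val` is not
#' supplied, the dataset's experiments are split `train_fraction` /
#' `1 - train_fraction` (never mixing windows of one experiment across the
#' split, so no temporal context leaks through overlapping windows).
#'
#' @param dataset a [make_windows()] dataset in original units.
#' @param config a [sensor_config()].
#' @param val optional windowed dataset used for early stopping.
#' @return A fitted `lstm_sensor` with training history, scalers and the
#'   validation loss at the restored epoch.
#' @seealso [predict.lstm_sensor()]
#' @export
lstm_sensor <- function(dataset, config = sensor_config(), val = NULL) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (is.null(val)) {
    sp <- .split_by_experiment(dataset$provenance, config$train_fraction)
    val <- windows_subset(dataset, sp$val)
    dataset <- windows_subset(dataset, sp$train)
  }
  sensor <- build_sensor(config, n_features = dim(dataset$x)[3],
                         features = dataset$features)
  cpp_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  d <- dim(dataset$x)
  flat <- matrix(dataset$x, d[1] * d[2], d[3])
  fscaler <- fit_scaler(flat)
  names(fscaler$min) <- names(fscaler$range) <- dataset$features
  tscaler <- fit_scaler(dataset$y)
  tr <- windows_scale(dataset, fscaler, tscaler)
  va <- windows_scale(val, fscaler, tscaler)

  opts <- list(learning_rate = config$learning_rate,
               max_epochs = config$max_epochs,
               batch_size = config$batch_size,
               dropout_rate = config$dropout_rate,
               patience = config$patience,
               loss_type = if (config$loss == "mmse") 1L else 2L,
               seed = cpp_seed)
  fit <- cpp_lstm_train(sensor$params, aperm(tr$x, c(1, 3, 2)), tr$y,
                        aperm(va$x, c(1, 3, 2)), va$y, opts)
  sensor$params <- fit[c("Wx", "Wh", "b", "W1", "b1", "W2", "b2")]
  sensor$history <- data.frame(epoch = seq_along(fit$train_loss),
                               train_loss = fit$train_loss,
                               val_loss = fit$val_loss)
  sensor$best_epoch <- fit$best_epoch
  sensor$stopped_epoch <- fit$stopped_epoch
  sensor$val_loss <- fit$best_val_loss
  sensor$fscaler <- fscaler
  sensor$tscaler <- tscaler
  sensor
}

#' Predict solute concentrations with a fitted sensor
#'
#' Scales the new windows with the sensor's own scalers, runs the network,
#' and returns estimates in original units, clipped at zero (the output
#' layer is non-negative in scaled space; the clip guards the inverse
#' scaling).
#'
#' @param object an `lstm_sensor`.
#' @param newdata a windowed dataset in original units whose features match
#'   the sensor's input group.
#' @param ... unused.
#' @return Numeric vector of non-negative estimates (g/L), one per window.
#' @export
predict.lstm_sensor <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "windowed_dataset"))
  if (!is.null(object$features) &&
      !identical(newdata$features, object$features))
    stop("feature set mismatch: sensor was trained on (",
         paste(object$features, collapse = ", "), ")", call. = FALSE)
  if (dim(newdata$x)[3] != object$n_features)
    stop("feature count mismatch", call. = FALSE)
  x <- if (is.null(object$fscaler)) newdata$x
       else windows_scale(newdata, object$fscaler)$x
  est <- cpp_lstm_predict(object$params, aperm(x, c(1, 3, 2)))
  if (!is.null(object$tscaler))
    est <- drop(invert_scaler(object$tscaler, est))
  pmax(as.numeric(est), 0)
}

#' @export
print.lstm_sensor <- function(x, ...) {
  cat(sprintf("LSTM soft sensor: %d features -> LSTM(%d, ReLU) -> dense(%d, ReLU) -> 1 (non-negative)\n",
              x$n_features, x$config$lstm_units, x$config$dense_units))
  if (!is.null(x$features))
    cat("  input group:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  %d trainable parameters\n",
              sensor_parameter_count(x$n_features, x$config$lstm_units,
                                     x$config$dense_units)))
  if (is.null(x$history)) {
    cat("  untrained\n")
  } else {
    cat(sprintf("  trained %d epochs (best %d restored), validation loss %.4f\n",
                x$stopped_epoch, x$best_epoch, x$val_loss))
  }
  invisible(x)
}

#' @export
plot.lstm_sensor <- function(x, ...) {
  if (is.null(x$history)) stop("sensor is untrained", call. = FALSE)
  matplot(x$history$epoch, cbind(x$history$train_loss, x$history$val_loss),
          type = "l", lty = 1:2, col = c("black", "firebrick"),
          xlab = "epoch", ylab = "loss", main = "Training history", ...)
  legend("topright", c("training", "validation"), lty = 1:2,
         col = c("black", "firebrick"), bty = "n")
  abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' @export
residuals.lstm_sensor <- function(object, newdata, ...) {
  predict(object, newdata) - newdata$y
}
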