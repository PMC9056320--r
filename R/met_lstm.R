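#' Fit a gated recurrent regressor for vimentin percent change
#'
#' Trains a single-layer gated memory cell (input, forget and output gates,
#' tanh candidate, linear readout of the final hidden state) to map an
#' ordered sequence of per-window spectral peak features to a cell's
#' vimentin percent change. Optimization is full-batch Adam on the
#' mean-squared error, with gradients obtained by backpropagation through
#' time; labels are standardized internally and the parameters achieving the
#' best validation loss across epochs are returned. The whole fit is
#' deterministic under `seed`.
#'
#' @param x List of feature sequences: [extract_features()] objects or
#'   numeric matrices with one row per window and a common number of columns.
#' @param y Numeric vector of vimentin percent-change labels, one per
#'   sequence; at least two distinct values.
#' @param hidden_size Number of memory-cell units (default 16).
#' @param epochs Training epochs (default 500).
#' @param learning_rate Adam step size (default 1e-2).
#' @param validation_split Fraction of sequences held out for epoch selection
#'   (default 0.2); must be in (0, 1).
#' @param seed Integer seed controlling initialization and the split.
#' @param verbose Print loss every 50 epochs.
#' @return An object of class `met_lstm` with components `params` (best
#'   parameters, flat), `shape`, `history` (per-epoch train/validation loss),
#'   `best_epoch`, `y_center`/`y_scale`, `fitted.values`, `residuals` and the
#'   matched `call`.
#' @seealso [predict.met_lstm()], [r_squared()], [write_checkpoint()]
#' @examples
#' set.seed(1)
#' x <- replicate(60, matrix(rnorm(10), 5, 2), simplify = FALSE)
#' y <- vapply(x, function(m) mean(m[, 1]), numeric(1))
#' fit <- met_lstm(x, y, hidden_size = 4, epochs = 120, seed = 1)
#' r_squared(fitted(fit), y)
#' @export
met_lstm <- function(x, y, hidden_size = 16L, epochs = 500L,
                     learning_rate = 1e-2, validation_split = 0.2,
                     seed = 1L, verbose = FALSE) {
  x <- normalize_sequences(x)
  n <- length(x)
  if (n < 2L) stop_data("need at least 2 training sequences")
  if (length(y) != n) stop_usage("x and y lengths differ")
  if (!all(is.finite(y))) stop_data("labels must be finite")
  if (stats::sd(y) == 0) stop_data("degenerate target: all labels identical")
  check_number(hidden_size, "hidden_size", lower = 1)
  check_number(validation_split, "validation_split", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (validation_split >= 1) stop_usage("validation_split must be in (0, 1)")
  d <- ncol(x[[1]])
  h <- as.integer(hidden_size)
  shape <- lstm_shape(d, h)

  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  seeds <- derive_seeds(seed, 2L)
  idx <- with_seed(seeds[1], sample.int(n))
  n_val <- floor(n * validation_split)
  val_idx <- if (n_val >= 1L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) < 2L) stop_data("too few sequences left for training")

  gr_tr <- lstm_group_sequences(x[tr_idx])
  ys_tr <- lapply(gr_tr$index, function(i) ys[tr_idx][i])
  gr_val <- if (length(val_idx)) lstm_group_sequences(x[val_idx]) else NULL
  ys_val <- if (length(val_idx)) lapply(gr_val$index, function(i) ys[val_idx][i])

  theta <- lstm_init(d, h, seed = seeds[2])
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  for (ep in seq_len(epochs)) {
    lg <- lstm_loss_grad(theta, gr_tr$groups, ys_tr, shape)
    if (!is.finite(lg$loss)) {
      stop_numerical("training diverged at epoch ", ep,
                     " (non-finite loss); lower the learning rate")
    }
    m <- beta1 * m + (1 - beta1) * lg$grad
    v <- beta2 * v + (1 - beta2) * lg$grad^2
    mhat <- m / (1 - beta1^ep)
    vhat <- v / (1 - beta2^ep)
    theta <- theta - learning_rate * mhat / (sqrt(vhat) + eps)
    val_loss <- if (length(val_idx)) {
      lstm_loss_grad(theta, gr_val$groups, ys_val, shape, want_grad = FALSE)$loss
    } else {
      lstm_loss_grad(theta, gr_tr$groups, ys_tr, shape, want_grad = FALSE)$loss
    }
    history$train_loss[ep] <- lg$loss
    history$val_loss[ep] <- val_loss
    if (is.finite(val_loss) && val_loss < best$loss) {
      best <- list(loss = val_loss, theta = theta, epoch = ep)
    }
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("epoch %4d  train %.5f  val %.5f", ep, lg$loss, val_loss))
    }
  }

  par <- lstm_unflatten(best$theta, shape)
  fitted_vals <- lstm_predict_list(x, par, shape) * y_scale + y_center
  structure(
    list(params = best$theta, shape = shape,
         hidden_size = h, input_size = d,
         y_center = y_center, y_scale = y_scale,
         history = history, best_epoch = best$epoch,
         hyper = list(epochs = epochs, learning_rate = learning_rate,
                      validation_split = validation_split, seed = seed),
         n_train = length(tr_idx), n_val = length(val_idx),
         fitted.values = fitted_vals, residuals = y - fitted_vals,
         y = y, call = match.call()),
    class = "met_lstm"
  )
}

# Accept feature_sequence objects, matrices, or a bare matrix; return a list
# of plain numeric matrices with a common column count.
normalize_sequences <- function(x) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !length(x)) stop_usage("x must be a non-empty list of sequences")
  x <- lapply(x, function(s) {
    m <- unclass(s)
    if (!is.matrix(m) || !is.numeric(m)) stop_usage("each sequence must be a numeric matrix")
    if (!nrow(m)) stop_usage("each sequence needs at least one window")
    attributes(m) <- list(dim = dim(m))
    m
  })
  d <- unique(vapply(x, ncol, integer(1)))
  if (length(d) != 1L) stop_usage("all sequences must have the same feature width")
  x
}

#' Predict vimentin percent change for new feature sequences
#'
#' @param object A fitted [met_lstm()] model.
#' @param newdata List of feature sequences (or a single matrix). When
#'   omitted, returns the fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted percent changes.
#' @export
predict.met_lstm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- normalize_sequences(newdata)
  if (ncol(x[[1]]) != object$input_size) {
    stop_usage("newdata feature width (", ncol(x[[1]]),
               ") does not match the model (", object$input_size, ")")
  }
  par <- lstm_unflatten(object$params, object$shape)
  lstm_predict_list(x, par, object$shape) * object$y_scale + object$y_center
}

#' @export
coef.met_lstm <- function(object, ...) {
  par <- lstm_unflatten(object$params, object$shape)
  h <- object$shape$h
  gates <- c("input", "forget", "output", "candidate")
  colnames(par$W) <- paste0(rep(gates, each = h), rep(seq_len(h), 4))
  names(par$b) <- colnames(par$W)
  names(par$w_out) <- paste0("readout", seq_len(h))
  c(structure(as.numeric(par$W),
              names = as.vector(outer(seq_len(nrow(par$W)), colnames(par$W),
                                      function(i, g) paste0("W_", g, "_", i)))),
    structure(par$b, names = paste0("b_", names(par$b))),
    structure(par$w_out, names = names(par$w_out)),
    readout_bias = par$b_out)
}

#' @export
fitted.met_lstm <- function(object, ...) object$fitted.values

#' @export
residuals.met_lstm <- function(object, ...) object$residuals

#' @export
print.met_lstm <- function(x, ...) {
  cat("Gated recurrent vimentin regressor (met_lstm)\n")
  cat(sprintf("  %d memory units, %d input features, %d parameters\n",
              x$hidden_size, x$input_size, x$shape$n_total))
  cat(sprintf("  trained on %d sequences (%d held for validation), best epoch %d\n",
              x$n_train, x$n_val, x$best_epoch))
  cat(sprintf("  training r-squared: %.3f\n", r_squared(x$fitted.values, x$y)))
  invisible(x)
}

#' @export
summary.met_lstm <- function(object, ...) {
  out <- list(
    model = object,
    train_r2 = r_squared(object$fitted.values, object$y),
    final_train_loss = utils::tail(object$history$train_loss, 1),
    best_val_loss = object$history$val_loss[object$best_epoch],
    residual_sd = stats::sd(object$residuals)
  )
  class(out) <- "summary.met_lstm"
  out
}

#' @export
print.summary.met_lstm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  best validation MSE (standardized): %.5f\n", x$best_val_loss))
  cat(sprintf("  residual SD: %.3f %%\n", x$residual_sd))
  invisible(x)
}

#' Plot training history or prediction agreement
#'
#' @param x A fitted [met_lstm()] model.
#' @param which `"loss"` for the loss trajectory, `"fit"` for fitted vs
#'   observed labels.
#' @param ... Passed to the underlying plot call.
#' @export
plot.met_lstm <- function(x, which = c("loss", "fit"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    plot(x$history$epoch, x$history$train_loss, type = "l",
         xlab = "epoch", ylab = "MSE (standardized labels)",
         main = "Training history", ...)
    lines(x$history$epoch, x$history$val_loss, lty = 2)
    abline(v = x$best_epoch, lty = 3, col = "grey50")
    legend("topright", c("train", "validation"), lty = c(1, 2), bty = "n")
  } else {
    plot(x$y, x$fitted.values, xlab = "measured vimentin change (%)",
         ylab = "predicted (%)", main = "Fitted vs measured", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Squared Pearson correlation between predictions and measurements
#'
#' The accuracy metric for the vimentin regression: the square of the
#' Pearson correlation of predicted against true values. Invariant to affine
#' rescaling of either argument.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3), each
#'   with nonzero variance.
#' @return r-squared in [0, 1].
#' @examples
#' r_squared(2 * (1:10) + 7, 1:10) # 1: affine invariance
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop_usage("length mismatch")
  if (length(predicted) < 3L) stop_usage("need at least 3 pairs")
  if (!all(is.finite(predicted)) || !all(is.finite(observed))) {
    stop_data("non-finite values in r_squared input")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop_data("undefined correlation: zero variance")
  }
  stats::cor(predicted, observed)^2
}

#' Save / load a model checkpoint
#'
#' Checkpoints are flat JSON documents holding all weights, the label
#' scaling, hyperparameters and seed - portable plain text, no binary
#' serialization. `read_checkpoint()` restores a model whose predictions are
#' identical to the saved one's.
#'
#' @param object A fitted [met_lstm()] model.
#' @param path File path for the JSON checkpoint.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a `met_lstm` object.
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "met_lstm"))
  doc <- list(
    format = "metsig_lstm_checkpoint",
    version = as.character(utils::packageVersion("metsig")),
    input_size = object$input_size, hidden_size = object$hidden_size,
    y_center = object$y_center, y_scale = object$y_scale,
    params = object$params, best_epoch = object$best_epoch,
    hyper = object$hyper
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("checkpoint not found: ", path),
                        class = c("metsig_io_error", "metsig_error")))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "metsig_lstm_checkpoint")) {
    stop_data("not a metsig checkpoint: ", path)
  }
  shape <- lstm_shape(doc$input_size, doc$hidden_size)
  structure(
    list(params = as.numeric(doc$params), shape = shape,
         hidden_size = doc$hidden_size, input_size = doc$input_size,
         y_center = doc$y_center, y_scale = doc$y_scale,
         history = NULL, best_epoch = doc$best_epoch, hyper = doc$hyper,
         n_train = NA_integer_, n_val = NA_integer_,
         fitted.values = NULL, residuals = NULL, y = NULL,
         call = quote(read_checkpoint())),
    class = "met_lstm"
  )
}
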