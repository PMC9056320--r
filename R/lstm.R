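# Internal machinery for the gated recurrent (LSTM-style) sequence regressor.
#
# One memory cell layer with input/forget/output gates and a tanh candidate,
# followed by a linear readout of the final hidden state:
#   i_t = sigm(W_i [h_{t-1}, x_t] + b_i)      f_t = sigm(W_f [.] + b_f)
#   g_t = tanh(W_c [.] + b_c)                 o_t = sigm(W_o [.] + b_o)
#   c_t = f_t * c_{t-1} + i_t * g_t           h_t = o_t * tanh(c_t)
#   yhat = w_y . h_T + b_y
# Gradients are derived analytically (backpropagation through time) and
# verified against central finite differences in the test suite.
#
# Parameters are stored flat; `W` is a (h+d) x 4h matrix whose column blocks
# are [input | forget | output | candidate].

lstm_shape <- function(d, h) {
  list(d = d, h = h,
       n_W = (h + d) * 4L * h, n_b = 4L * h,
       n_total = (h + d) * 4L * h + 4L * h + h + 1L)
}

lstm_unflatten <- function(theta, shape) {
  d <- shape$d; h <- shape$h
  i <- 0L
  W <- matrix(theta[i + seq_len(shape$n_W)], h + d, 4L * h); i <- i + shape$n_W
  b <- theta[i + seq_len(shape$n_b)]; i <- i + shape$n_b
  w_out <- theta[i + seq_len(h)]; i <- i + h
  b_out <- theta[i + 1L]
  list(W = W, b = b, w_out = w_out, b_out = b_out)
}

lstm_flatten <- function(par) {
  c(as.numeric(par$W), par$b, par$w_out, par$b_out)
}

# Small uniform init; forget-gate biases start at +1 so early training keeps
# cell memory open (standard practice).
lstm_init <- function(d, h, seed = NULL) {
  shape <- lstm_shape(d, h)
  with_seed(seed, {
    s <- 1 / sqrt(h + d)
    W <- matrix(runif(shape$n_W, -s, s), h + d, 4L * h)
    b <- numeric(4L * h)
    b[h + seq_len(h)] <- 1
    w_out <- runif(h, -s, s)
    lstm_flatten(list(W = W, b = b, w_out = w_out, b_out = 0))
  })
}

logistic <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch X [n, T, d]. Returns predictions and, if
# `keep_cache`, everything the backward pass needs.
lstm_forward <- function(X, par, shape, keep_cache = FALSE) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; h <- shape$h
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  bmat <- matrix(par$b, n, 4L * h, byrow = TRUE)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], nrow = n)
    Z <- cbind(H, xt)
    G <- Z %*% par$W + bmat
    ig <- logistic(G[, seq_len(h), drop = FALSE])
    fg <- logistic(G[, h + seq_len(h), drop = FALSE])
    og <- logistic(G[, 2L * h + seq_len(h), drop = FALSE])
    gg <- tanh(G[, 3L * h + seq_len(h), drop = FALSE])
    C_prev <- C
    C <- fg * C_prev + ig * gg
    tC <- tanh(C)
    H <- og * tC
    if (keep_cache) {
      cache[[t]] <- list(Z = Z, i = ig, f = fg, o = og, g = gg,
                         C_prev = C_prev, tC = tC)
    }
  }
  yhat <- drop(H %*% par$w_out) + par$b_out
  list(yhat = yhat, H_T = H, cache = cache)
}

# Backward pass: gradient of sum_j dyhat_j * yhat_j wrt all parameters.
lstm_backward <- function(X, par, shape, fwd, dyhat) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; h <- shape$h
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  db <- numeric(4L * h)
  dw_out <- drop(crossprod(fwd$H_T, dyhat))
  db_out <- sum(dyhat)
  dH <- tcrossprod(dyhat, par$w_out) # n x h
  dC <- matrix(0, n, h)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dC <- dC + dH * cc$o * (1 - cc$tC^2)
    do_ <- dH * cc$tC
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$C_prev
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + crossprod(cc$Z, dG)
    db <- db + colSums(dG)
    dZ <- tcrossprod(dG, par$W)
    dH <- dZ[, seq_len(h), drop = FALSE]
    dC <- dC * cc$f
  }
  lstm_flatten(list(W = dW, b = db, w_out = dw_out, b_out = db_out))
}

# Mean-squared-error loss and gradient over ragged data grouped by sequence
# length: `groups` is a list of arrays [n_g, T_g, d], `ys` the matching list
# of (standardized) label vectors. n_total normalizes the mean.
lstm_loss_grad <- function(theta, groups, ys, shape, want_grad = TRUE) {
  par <- lstm_unflatten(theta, shape)
  n_total <- sum(vapply(ys, length, integer(1)))
  loss <- 0
  grad <- if (want_grad) numeric(length(theta)) else NULL
  for (g in seq_along(groups)) {
    fwd <- lstm_forward(groups[[g]], par, shape, keep_cache = want_grad)
    res <- fwd$yhat - ys[[g]]
    loss <- loss + sum(res^2)
    if (want_grad) {
      grad <- grad + lstm_backward(groups[[g]], par, shape, fwd, 2 * res / n_total)
    }
  }
  list(loss = loss / n_total, grad = grad)
}

# Group a list of T_i x d matrices by sequence length into 3-d arrays.
lstm_group_sequences <- function(x) {
  lens <- vapply(x, nrow, integer(1))
  d <- ncol(x[[1]])
  groups <- list(); index <- list()
  for (Tn in sort(unique(lens))) {
    idx <- which(lens == Tn)
    arr <- array(0, dim = c(length(idx), Tn, d))
    for (j in seq_along(idx)) arr[j, , ] <- x[[idx[j]]]
    groups[[length(groups) + 1L]] <- arr
    index[[length(index) + 1L]] <- idx
  }
  list(groups = groups, index = index)
}

# Predict (standardized scale) for a list of sequences, preserving order.
lstm_predict_list <- function(x, par, shape) {
  gr <- lstm_group_sequences(x)
  out <- numeric(length(x))
  for (g in seq_along(gr$groups)) {
    out[gr$index[[g]]] <- lstm_forward(gr$groups[[g]], par, shape)$yhat
  }
  out
}
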