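test_that("zero weights collapse the recurrence to the readout bias", {
  shape <- metsig:::lstm_shape(d = 3, h = 4)
  par <- metsig:::lstm_unflatten(numeric(shape$n_total), shape)
  par$b_out <- 1.7
  for (Tn in c(1, 4, 9)) {
    X <- array(rnorm(2 * Tn * 3), c(2, Tn, 3))
    expect_equal(metsig:::lstm_forward(X, par, shape)$yhat, c(1.7, 1.7))
  }
})

test_that("the forward pass is deterministic and matches a scalar-loop oracle", {
  set.seed(4)
  shape <- metsig:::lstm_shape(d = 2, h = 3)
  theta <- metsig:::lstm_init(2, 3, seed = 10)
  par <- metsig:::lstm_unflatten(theta, shape)
  X <- array(rnorm(1 * 4 * 2), c(1, 4, 2))
  y1 <- metsig:::lstm_forward(X, par, shape)$yhat
  expect_identical(y1, metsig:::lstm_forward(X, par, shape)$yhat)

  # independent plain-loop reimplementation of the gating equations
  sigm <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, 3); cc <- rep(0, 3)
  for (t in 1:4) {
    z <- c(h, X[1, t, ])
    G <- drop(z %*% par$W) + par$b
    i <- sigm(G[1:3]); f <- sigm(G[4:6]); o <- sigm(G[7:9]); g <- tanh(G[10:12])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  expect_equal(unname(y1), sum(h * par$w_out) + par$b_out, tolerance = 1e-12)
})

test_that("with an open forget gate, predictions converge in sequence length", {
  # constant input drives the hidden state to a fixed point; the prediction
  # for a long repeated-window sequence approaches it
  shape <- metsig:::lstm_shape(d = 2, h = 4)
  theta <- metsig:::lstm_init(2, 4, seed = 2)
  par <- metsig:::lstm_unflatten(theta, shape)
  par$b[5:8] <- 6 # forget gate ~ 1
  x0 <- c(0.3, -0.6)
  pred_len <- function(Tn) {
    X <- array(rep(x0, each = Tn), c(1, Tn, 2))
    metsig:::lstm_forward(X, par, shape)$yhat
  }
  # fixed-point oracle: iterate the one-step map independently
  sigm <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, 4); cc <- rep(0, 4)
  for (t in 1:200) {
    G <- drop(c(h, x0) %*% par$W) + par$b
    cc <- sigm(G[5:8]) * cc + sigm(G[1:4]) * tanh(G[13:16])
    h <- sigm(G[9:12]) * tanh(cc)
  }
  limit <- sum(h * par$w_out) + par$b_out
  expect_equal(pred_len(200), limit, tolerance = 1e-8)
  expect_lt(abs(pred_len(100) - pred_len(200)), abs(pred_len(5) - pred_len(200)))
})

test_that("analytic gradients match central finite differences", {
  set.seed(6)
  shape <- metsig:::lstm_shape(d = 2, h = 3)
  theta <- metsig:::lstm_init(2, 3, seed = 8)
  groups <- list(array(rnorm(2 * 3 * 2), c(2, 3, 2)),
                 array(rnorm(1 * 5 * 2), c(1, 5, 2)))
  ys <- list(rnorm(2), rnorm(1))
  ana <- metsig:::lstm_loss_grad(theta, groups, ys, shape)$grad
  eps <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (metsig:::lstm_loss_grad(tp, groups, ys, shape, want_grad = FALSE)$loss -
     metsig:::lstm_loss_grad(tm, groups, ys, shape, want_grad = FALSE)$loss) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-6)), 1e-5)
})

test_that("training recovers a noiseless linear relation", {
  coh <- make_linear_cohort(200, seed = 13)
  train <- 1:160
  fit <- met_lstm(coh$x[train], coh$y[train], hidden_size = 16,
                  epochs = 300, seed = 1)
  pred <- predict(fit, coh$x[-train])
  expect_gte(r_squared(pred, coh$y[-train]), 0.95)
  # ordinary least squares on the same (time-averaged) features is the oracle
  feat <- t(vapply(coh$x, function(m) colMeans(m), numeric(3)))
  ols <- lm(y ~ ., data = data.frame(y = coh$y, feat)[train, ])
  ols_pred <- predict(ols, data.frame(feat)[-train, ])
  expect_gte(r_squared(ols_pred, coh$y[-train]), 0.99)
  expect_gte(r_squared(pred, ols_pred), 0.9)
})

test_that("permuted labels cannot be learned", {
  r2s <- vapply(1:20, function(s) {
    coh <- make_linear_cohort(100, Tn = 3, seed = 100 + s)
    set.seed(s)
    y_perm <- sample(coh$y)
    fit <- met_lstm(coh$x[1:70], y_perm[1:70], hidden_size = 8, epochs = 100,
                    seed = s)
    r_squared(predict(fit, coh$x[71:100]), y_perm[71:100])
  }, numeric(1))
  expect_lte(mean(r2s), 0.15)
})

test_that("training is bit-identical under the same seed and rejects bad input", {
  coh <- make_linear_cohort(30, seed = 3)
  f1 <- met_lstm(coh$x, coh$y, hidden_size = 4, epochs = 30, seed = 7)
  f2 <- met_lstm(coh$x, coh$y, hidden_size = 4, epochs = 30, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_error(met_lstm(coh$x, rep(1, 30)), "degenerate")
  expect_error(met_lstm(coh$x[1], coh$y[1]), "at least 2")
  expect_error(met_lstm(coh$x, coh$y[1:5]), "lengths differ")
  # running minimum of the training loss never increases
  expect_true(all(diff(cummin(f1$history$train_loss)) <= 0))
})

test_that("r-squared has the Pearson edge-case behavior", {
  y <- rnorm(50)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(2 * y + 7, y), 1) # affine invariance
  # orthogonalized predictions carry no information
  set.seed(17)
  true <- rnorm(1000)
  p <- rnorm(1000)
  p_orth <- residuals(lm(p ~ true))
  expect_lte(r_squared(p_orth, true), 0.01)
  expect_error(r_squared(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("checkpoints restore a model with identical predictions", {
  coh <- make_linear_cohort(30, seed = 5)
  fit <- met_lstm(coh$x, coh$y, hidden_size = 4, epochs = 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(predict(back, coh$x), predict(fit, coh$x), tolerance = 1e-12)
})
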