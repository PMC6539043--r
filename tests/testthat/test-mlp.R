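test_that("network initialisation is seeded, sized, and bounded", {
  net <- init_network(4, 8, seed = 3)
  expect_identical(net, init_network(4, 8, seed = 3))
  expect_length(flavqsar:::mlp_pack(net), 4 * 8 + 8 + 8 + 1)  # 49 parameters
  expect_identical(dim(net$w_ih), c(8L, 4L))
  expect_length(net$b_1, 8)
  expect_true(all(abs(net$w_ih) <= 0.5))
  expect_true(all(abs(net$w_ho) <= 0.5))
  expect_identical(net$b_1, rep(0, 8))
  expect_identical(net$b_2, 0)
  expect_error(init_network(4, 0, seed = 1), "n_hidden")
})

test_that("forward pass matches hand evaluation and a scalar-loop oracle", {
  # 1 hidden neuron, identity scaling: y = 1 + 2 tanh(0.5)
  net <- init_network(4, 1, seed = 1)
  net$w_ih[1, ] <- c(1, 0, 0, 0)
  net$w_ho <- 2
  net$b_2 <- 1
  x <- matrix(c(0.5, 9, -3, 2), 1)
  expect_equal(mlp_forward(net, x), 1 + 2 * tanh(0.5))

  # zero weights: constant b_2
  net0 <- init_network(3, 4, seed = 2)
  net0$w_ih[] <- 0; net0$w_ho[] <- 0; net0$b_2 <- 0.7
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(mlp_forward(net0, X), rep(0.7, 5))

  # tanh range bound on the network scale
  netb <- random_network(3, 6, seed = 4, scaled = FALSE)
  bound <- abs(netb$b_2) + sum(abs(netb$w_ho))
  expect_true(all(abs(mlp_forward(netb, 100 * X)) <= bound))

  # scalar-loop oracle on random scaled networks
  for (s in 1:10) {
    m <- sample(1:6, 1); h <- sample(1:10, 1)
    net <- random_network(m, h, seed = 200 + s)
    Xr <- matrix(runif(4 * m, -1.5, 2.5), 4, m)
    expect_equal(mlp_forward(net, Xr), mlp_forward_loop(net, Xr),
                 tolerance = 1e-12)
  }
  expect_error(mlp_forward(net0, X[, 1:2]), "columns")
})

test_that("LM training terminates immediately at a zero-gradient start", {
  net <- random_network(2, 3, seed = 5, scaled = FALSE)
  X <- matrix(rnorm(20), 10, 2)
  y <- mlp_forward(net, X)
  net$scaling <- list(x = list(lo = c(-3, -3), hi = c(3, 3)),
                      y = list(lo = min(y) - 1, hi = max(y) + 1))
  ys <- mlp_forward(net, X) # regenerate targets under the stored scaling
  fit <- train_lm(net, X, ys)
  expect_identical(fit$epochs, 0L)
  expect_identical(fit$stopped_by, "gradient")
  expect_lt(rmse(ys, mlp_forward(fit$model, X)), 1e-10)
})

test_that("LM fits y = x^2 on 41 points with 8 hidden neurons", {
  X <- matrix(seq(-1, 1, length.out = 41), ncol = 1)
  y <- X[, 1]^2
  ok <- vapply(1:5, function(s) {
    net <- init_network(1, 8, seed = s)
    fit <- train_lm(net, X, y, config = lm_config(max_epochs = 400))
    mean((mlp_forward(fit$model, X) - y)^2) < 1e-3
  }, TRUE)
  expect_true(all(ok))
})

test_that("training error decreases monotonically over accepted epochs", {
  set.seed(9)
  X <- matrix(rnorm(60, 2, 1), 20, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  net <- init_network(3, 4, seed = 10)
  fit <- train_lm(net, X, y, config = lm_config(max_epochs = 50))
  expect_true(all(diff(fit$trace$train_mse) < 0))
})

test_that("early stopping halts on a rising stop-set error", {
  set.seed(11)
  X <- matrix(rnorm(80, 0, 1), 40, 2)
  y <- tanh(X[, 1]) - X[, 2]^2 + rnorm(40, 0, 0.05)
  net <- init_network(2, 8, seed = 12)
  fit <- train_lm(net, X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                  config = lm_config(max_epochs = 500, patience = 3))
  expect_true(fit$stopped_by %in%
                c("early_stop", "lambda_max", "gradient", "max_epochs"))
  expect_true(all(!is.na(fit$trace$stop_mse)))
  expect_gte(fit$best_epoch, 1)
})
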