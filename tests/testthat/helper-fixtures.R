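# shared fixtures and independent oracles

# a tiny two-compound descriptor-only table written to a temp CSV
write_toy_csv <- function(path, drop_col = NULL, activity = FALSE) {
  df <- data.frame(name = c("a", "b"),
                   ete1 = c(80.1, 90.2), pa1 = c(33.5, 40.1),
                   bde1 = c(74.8, 91.5), he = c(-15.3, -9.9))
  if (activity) df$ln_orac <- c(1.5, -0.5)
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  write.csv(df, path, row.names = FALSE)
  path
}

# scalar-loop forward pass, independent of the package's matrix code
mlp_forward_loop <- function(model, X) {
  sapply(seq_len(nrow(X)), function(k) {
    x <- X[k, ]
    if (!is.null(model$scaling)) {
      x <- 2 * (x - model$scaling$x$lo) /
        (model$scaling$x$hi - model$scaling$x$lo) - 1
    }
    acc <- model$b_2
    for (i in seq_len(model$n_hidden)) {
      a <- model$b_1[i]
      for (j in seq_len(model$n_inputs)) a <- a + model$w_ih[i, j] * x[j]
      acc <- acc + model$w_ho[i] * tanh(a)
    }
    if (!is.null(model$scaling)) {
      acc <- (acc + 1) / 2 * (model$scaling$y$hi - model$scaling$y$lo) +
        model$scaling$y$lo
    }
    acc
  })
}

# finite differences of the network output w.r.t. each raw input
# (five-point central stencil, step 1e-4, so the oracle's own truncation
# error stays far below the 1e-6 comparison threshold)
pad_fd <- function(model, X, eps = 1e-4) {
  D <- matrix(0, nrow(X), ncol(X))
  shift <- function(j, k) { Xs <- X; Xs[, j] <- Xs[, j] + k * eps; Xs }
  for (j in seq_len(ncol(X))) {
    D[, j] <- (mlp_forward(model, shift(j, -2)) -
                 8 * mlp_forward(model, shift(j, -1)) +
                 8 * mlp_forward(model, shift(j, 1)) -
                 mlp_forward(model, shift(j, 2))) / (12 * eps)
  }
  D
}

# random small network with random min-max scaling
random_network <- function(n_inputs, n_hidden, seed, scaled = TRUE) {
  net <- init_network(n_inputs, n_hidden, seed)
  set.seed(seed + 1)
  net$b_1 <- runif(n_hidden, -0.3, 0.3)
  net$b_2 <- runif(1, -0.3, 0.3)
  if (scaled) {
    lo <- runif(n_inputs, -2, 0); hi <- lo + runif(n_inputs, 0.5, 3)
    ylo <- runif(1, -2, 0)
    net$scaling <- list(x = list(lo = lo, hi = hi),
                        y = list(lo = ylo, hi = ylo + runif(1, 0.5, 3)))
  }
  net
}

# cached full-protocol fit at the default master seed (shared by the
# acceptance tests; computed once per test run)
.fixture_env <- new.env(parent = emptyenv())

protocol_fit <- function() {
  if (is.null(.fixture_env$ann)) {
    .fixture_env$ann <- qsar_ann(load_bundled_dataset(), n_hidden = 8,
                                 n_cycles = 1000, seed = 1)
  }
  .fixture_env$ann
}

# independent mirror map and orbit key for scaffold oracles
mirror_oracle <- c("3" = "3", "5" = "5", "6" = "6", "7" = "7", "8" = "8",
                   "2'" = "6'", "3'" = "5'", "4'" = "4'", "5'" = "3'",
                   "6'" = "2'")

orbit_key <- function(sites) {
  a <- paste(sort(sites), collapse = "|")
  b <- paste(sort(unname(mirror_oracle[sites])), collapse = "|")
  min(a, b)
}
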