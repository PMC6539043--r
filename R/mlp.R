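#' Initialise a single-hidden-layer perceptron
#'
#' Architecture: `n_inputs` inputs, `n_hidden` tanh hidden neurons, one
#' linear output.  Weights are drawn uniformly in \[-0.5, 0.5\] from the
#' seeded generator; biases start at zero.  Input and output scaling default
#' to the identity and are set by [train_lm()] or the resampling protocol.
#'
#' @param n_inputs number of input variables.
#' @param n_hidden number of hidden neurons (>= 1).
#' @param seed integer seed for the weight draw.
#' @return object of class `mlp_model`: `w_ih` (`n_hidden` x `n_inputs`),
#'   `b_1`, `w_ho`, `b_2`, and `scaling` (`list(x =, y =)` min-max
#'   parameters or `NULL` for identity).
#' @export
init_network <- function(n_inputs, n_hidden, seed) {
  if (n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  if (n_inputs < 1L) stop("n_inputs must be >= 1", call. = FALSE)
  set.seed(seed)
  structure(list(
    w_ih = matrix(runif(n_hidden * n_inputs, -0.5, 0.5), n_hidden, n_inputs),
    b_1 = rep(0, n_hidden),
    w_ho = runif(n_hidden, -0.5, 0.5),
    b_2 = 0,
    n_inputs = as.integer(n_inputs),
    n_hidden = as.integer(n_hidden),
    scaling = NULL
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP: %d-%d-1 (tanh hidden, linear output), %d parameters%s\n",
              x$n_inputs, x$n_hidden, n_params(x),
              if (is.null(x$scaling)) ", identity scaling" else ""))
  invisible(x)
}

n_params <- function(model) {
  model$n_inputs * model$n_hidden + 2L * model$n_hidden + 1L
}

# flatten / restore the trainable parameters (column-major w_ih, b_1, w_ho, b_2)
mlp_pack <- function(model) {
  c(as.vector(model$w_ih), model$b_1, model$w_ho, model$b_2)
}

mlp_unpack <- function(model, theta) {
  m <- model$n_inputs; h <- model$n_hidden
  model$w_ih <- matrix(theta[seq_len(h * m)], h, m)
  model$b_1 <- theta[h * m + seq_len(h)]
  model$w_ho <- theta[h * m + h + seq_len(h)]
  model$b_2 <- theta[h * m + 2L * h + 1L]
  model
}

# forward pass on the network (already-scaled) scale
mlp_forward_scaled <- function(model, Xs) {
  H <- tanh(sweep(Xs %*% t(model$w_ih), 2, model$b_1, "+"))
  drop(H %*% model$w_ho + model$b_2)
}

#' Forward pass of an MLP
#'
#' Applies the stored input scaling, the tanh hidden layer, the linear
#' output, and the inverse output scaling.  With no stored scaling the raw
#' inputs are fed to the network directly.
#'
#' @param model an `mlp_model`.
#' @param X K x M matrix in the training column order.
#' @return numeric vector of K predictions.
#' @export
mlp_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs) {
    stop("X has ", ncol(X), " columns; network expects ", model$n_inputs,
         call. = FALSE)
  }
  if (!is.null(model$scaling)) {
    Xs <- minmax_apply(X, model$scaling$x)
    ys <- mlp_forward_scaled(model, Xs)
    drop(minmax_invert(matrix(ys), model$scaling$y))
  } else {
    mlp_forward_scaled(model, X)
  }
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  mlp_forward(object, extract_x(newdata))
}

# Jacobian of the scaled-scale residuals w.r.t. the packed parameters
mlp_jacobian <- function(model, Xs) {
  h <- model$n_hidden; m <- model$n_inputs
  A <- sweep(Xs %*% t(model$w_ih), 2, model$b_1, "+")
  H <- tanh(A)
  D <- (1 - H^2) * matrix(model$w_ho, nrow(Xs), h, byrow = TRUE)
  JW <- matrix(0, nrow(Xs), m * h)
  for (k in seq_len(m)) JW[, (k - 1L) * h + seq_len(h)] <- D * Xs[, k]
  cbind(JW, D, H, 1)
}

#' Levenberg-Marquardt training configuration
#'
#' @param lambda0 initial damping.
#' @param factor multiplicative damping update (divide on an accepted step,
#'   multiply on a rejected one).
#' @param max_epochs epoch budget.
#' @param grad_tol stop when the largest gradient component falls below this.
#' @param patience stop after this many consecutive increases of the
#'   stop-set error.
#' @param lambda_max training stalls (local minimum) when the damping exceeds
#'   this.
#' @return list of class `lm_config`.
#' @export
lm_config <- function(lambda0 = 1e-3, factor = 10, max_epochs = 1000,
                      grad_tol = 1e-7, patience = 6, lambda_max = 1e10) {
  structure(list(lambda0 = lambda0, factor = factor,
                 max_epochs = as.integer(max_epochs), grad_tol = grad_tol,
                 patience = as.integer(patience), lambda_max = lambda_max),
            class = "lm_config")
}

#' Train an MLP by Levenberg-Marquardt with early stopping
#'
#' Damped Gauss-Newton minimisation of the sum of squared errors over all
#' weights and biases.  A step is accepted only if it decreases the training
#' error (damping / `factor` on acceptance, x `factor` on rejection).
#' Training ends at the epoch budget, at the gradient tolerance, when the
#' damping exceeds `lambda_max` (a local minimum), or when the stop-set
#' error has increased on `patience` consecutive evaluations.  The returned
#' network carries the weights at termination; the epoch with the lowest
#' stop-set error is recorded in the trace.
#'
#' Min-max scaling of inputs and targets to \[-1, 1\] is fitted on the
#' training set (unless the model already stores scaling parameters, which
#' are then reused).
#'
#' @param model an initialised `mlp_model`.
#' @param X_train,y_train training data (raw scale).
#' @param X_stop,y_stop stop set monitored for early stopping (raw scale);
#'   `NULL` disables early stopping.
#' @param config an [lm_config()].
#' @return list with `model` (trained) and `trace` (data.frame per epoch:
#'   training MSE, stop-set MSE, damping) plus `stopped_by`, `best_epoch`.
#' @export
train_lm <- function(model, X_train, y_train, X_stop = NULL, y_stop = NULL,
                     config = lm_config()) {
  stopifnot(inherits(model, "mlp_model"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0L) stop("training set is empty", call. = FALSE)
  if (is.null(model$scaling)) {
    model$scaling <- list(x = minmax_fit(X_train),
                          y = minmax_fit(matrix(y_train)))
  }
  Xs <- minmax_apply(X_train, model$scaling$x)
  ys <- drop(minmax_apply(matrix(y_train), model$scaling$y))
  has_stop <- !is.null(X_stop) && nrow(as.matrix(X_stop)) > 0L
  if (has_stop) {
    Ss <- minmax_apply(as.matrix(X_stop), model$scaling$x)
    ss <- drop(minmax_apply(matrix(y_stop), model$scaling$y))
  }
  np <- n_params(model)
  theta <- mlp_pack(model)
  lambda <- config$lambda0
  r <- mlp_forward_scaled(model, Xs) - ys
  sse <- sum(r^2)
  if (!is.finite(sse)) stop("non-finite loss at initialisation", call. = FALSE)
  es_prev <- Inf; best_stop <- Inf; best_epoch <- 0L; fails <- 0L
  stopped_by <- "max_epochs"
  trace <- vector("list", config$max_epochs)
  ep <- 0L
  while (ep < config$max_epochs) {
    ep <- ep + 1L
    J <- mlp_jacobian(model, Xs)
    g <- crossprod(J, r)
    if (max(abs(g)) < config$grad_tol) {
      stopped_by <- "gradient"; ep <- ep - 1L; break
    }
    JtJ <- crossprod(J)
    accepted <- FALSE
    repeat {
      step <- tryCatch(solve(JtJ + lambda * diag(np), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- mlp_unpack(model, theta + drop(step))
        rn <- mlp_forward_scaled(cand, Xs) - ys
        ssen <- sum(rn^2)
        if (!is.finite(ssen)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        }
        if (ssen < sse) {
          model <- cand; theta <- theta + drop(step)
          r <- rn; sse <- ssen
          lambda <- lambda / config$factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$factor
      if (lambda > config$lambda_max) break
    }
    if (!accepted) { stopped_by <- "lambda_max"; ep <- ep - 1L; break }
    es <- if (has_stop) mean((mlp_forward_scaled(model, Ss) - ss)^2) else NA_real_
    trace[[ep]] <- c(epoch = ep, train_mse = sse / length(ys),
                     stop_mse = es, lambda = lambda)
    if (has_stop) {
      if (es < best_stop) { best_stop <- es; best_epoch <- ep }
      if (es > es_prev) {
        fails <- fails + 1L
        if (fails >= config$patience) { stopped_by <- "early_stop"; break }
      } else {
        fails <- 0L
      }
      es_prev <- es
    }
  }
  trace <- as.data.frame(do.call(rbind, trace[seq_len(ep)][!vapply(
    trace[seq_len(ep)], is.null, TRUE)]))
  list(model = model, trace = trace, stopped_by = stopped_by,
       best_epoch = best_epoch, epochs = ep)
}
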