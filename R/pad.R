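#' PaD derivative matrix of an MLP
#'
#' Exact analytic partial derivatives of the network output with respect to
#' each input, evaluated at every sample.  For a tanh hidden layer and a
#' linear output the network-scale derivative is
#' `sum_i w_ho[i] * (1 - tanh(a_i)^2) * w_ih[i, j]`; the min-max scaling
#' Jacobians of inputs and output are folded in so the returned derivatives
#' are in raw units (ln(ORAC) per kcal/mol), which makes derivative-versus-
#' descriptor scatter plots directly interpretable.
#'
#' @param model a trained `mlp_model`.
#' @param X K x M matrix of raw descriptor values.
#' @return object of class `pad_result`: `derivatives` (K x M), `x` (the
#'   evaluation points), and empty SSD fields to be filled by
#'   [ssd_contributions()].
#' @export
pad_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs) {
    stop("X has ", ncol(X), " columns; network expects ", model$n_inputs,
         call. = FALSE)
  }
  if (!is.null(model$scaling)) {
    Xs <- minmax_apply(X, model$scaling$x)
    jac_x <- 2 / (model$scaling$x$hi - model$scaling$x$lo)
    jac_y <- (model$scaling$y$hi - model$scaling$y$lo) / 2
  } else {
    Xs <- X
    jac_x <- rep(1, ncol(X))
    jac_y <- 1
  }
  A <- sweep(Xs %*% t(model$w_ih), 2, model$b_1, "+")
  D <- (1 - tanh(A)^2) * matrix(model$w_ho, nrow(X), model$n_hidden,
                                byrow = TRUE)
  dscaled <- D %*% model$w_ih          # d y_scaled / d x_scaled
  derivs <- sweep(dscaled * jac_y, 2, jac_x, "*")
  colnames(derivs) <- colnames(X)
  structure(list(derivatives = derivs, x = X, ssd = NULL,
                 ssd_normalized = NULL, ranking = NULL),
            class = "pad_result")
}

#' Sum-of-squared-derivatives contributions
#'
#' Fills the SSD fields of a [pad_matrix()] result: `ssd[j]` is the sum of
#' squared derivatives of input `j` over all samples; `ssd_normalized`
#' divides by the total so contributions sum to one; `ranking` orders the
#' inputs by decreasing normalised SSD.  An all-zero derivative matrix is
#' flagged and the normalised vector reported absent.
#'
#' @param result a `pad_result`.
#' @return the `pad_result` with `ssd`, `ssd_normalized` and `ranking`
#'   filled (plus `degenerate = TRUE` when all derivatives are zero).
#' @export
ssd_contributions <- function(result) {
  stopifnot(inherits(result, "pad_result"))
  ssd <- colSums(result$derivatives^2)
  result$ssd <- ssd
  if (sum(ssd) == 0) {
    result$ssd_normalized <- NULL
    result$ranking <- NULL
    result$degenerate <- TRUE
  } else {
    result$ssd_normalized <- ssd / sum(ssd)
    result$ranking <- order(result$ssd_normalized, decreasing = TRUE)
    result$degenerate <- FALSE
  }
  result
}

#' @export
print.pad_result <- function(x, ...) {
  cat(sprintf("PaD result: %d samples x %d inputs\n",
              nrow(x$derivatives), ncol(x$derivatives)))
  if (!is.null(x$ssd_normalized)) {
    cat("normalised SSD:\n")
    print(round(x$ssd_normalized, 4))
  }
  invisible(x)
}

#' Aggregate PaD results over protocol cycles
#'
#' Element-wise mean and standard deviation of the normalised SSD over a
#' list of [ssd_contributions()] results (each cycle carries equal weight,
#' so the mean vector still sums to one), a consensus ranking by mean, and
#' the pooled (descriptor value, derivative) pairs for scatter plots.
#'
#' @param results list of `pad_result`s with SSD fields filled.
#' @return list of class `pad_aggregate`: `mean_ssd`, `sd_ssd`, `ranking`,
#'   `input_names`, `scatter` (long data.frame: input, value, derivative).
#' @export
aggregate_pad <- function(results) {
  if (length(results) < 1L) stop("need at least one result", call. = FALSE)
  m <- ncol(results[[1]]$derivatives)
  if (any(vapply(results, function(r) ncol(r$derivatives), 0L) != m)) {
    stop("inconsistent number of inputs across results", call. = FALSE)
  }
  keep <- !vapply(results, function(r) isTRUE(r$degenerate), TRUE)
  results <- results[keep]
  S <- vapply(results, `[[`, numeric(m), "ssd_normalized")
  S <- matrix(S, nrow = m)
  nm <- colnames(results[[1]]$derivatives) %||% paste0("x", seq_len(m))
  scatter <- do.call(rbind, lapply(results, function(r) {
    data.frame(input = rep(nm, each = nrow(r$derivatives)),
               value = as.vector(r$x),
               derivative = as.vector(r$derivatives))
  }))
  structure(list(
    mean_ssd = setNames(rowMeans(S), nm),
    sd_ssd = setNames(apply(S, 1, function(v)
      if (length(v) > 1L) sd(v) else NA_real_), nm),
    ranking = order(rowMeans(S), decreasing = TRUE),
    input_names = nm,
    n_results = length(results),
    scatter = scatter
  ), class = "pad_aggregate")
}

#' @export
print.pad_aggregate <- function(x, ...) {
  cat(sprintf("PaD aggregate over %d cycles\n", x$n_results))
  tab <- data.frame(mean_ssd = round(x$mean_ssd, 4),
                    sd_ssd = round(x$sd_ssd, 4))
  print(tab[x$ranking, ])
  invisible(x)
}

#' PaD interpretation of a fitted ANN protocol
#'
#' Computes the PaD derivative matrix and SSD contributions for every cycle
#' of a [qsar_ann()] fit (evaluated at all compounds of `data`, by default
#' the training data) and aggregates them.
#'
#' @param fit a `qsar_ann` object.
#' @param data evaluation compound set or descriptor matrix.
#' @return a [aggregate_pad()] result.
#' @export
interpret_ann <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "qsar_ann"))
  X <- extract_x(if (is.null(data)) fit$data else data)
  results <- lapply(fit$cycles, function(cc) {
    ssd_contributions(pad_matrix(cc$model, X))
  })
  aggregate_pad(results)
}
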