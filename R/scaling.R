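#' Autoscaling (z-score standardisation)
#'
#' Centres each column to zero mean and scales to unit variance (sd with the
#' n-1 divisor).  When `params` is supplied the stored training means and
#' standard deviations are applied unchanged, which is how validation and
#' test data must be scaled.
#'
#' @param X numeric matrix or vector.
#' @param params optional scaling parameters from a previous call.
#' @return list with `x` (scaled matrix) and `params`
#'   (`list(mean =, sd =)`).
#' @export
autoscale <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (is.null(params)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    zero <- which(sdv <= 0 | !is.finite(sdv))
    if (length(zero) > 0L) {
      nm <- colnames(X)[zero] %||% as.character(zero)
      stop("zero-variance column(s): ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
    params <- list(mean = mu, sd = sdv)
  }
  list(x = sweep(sweep(X, 2, params$mean), 2, params$sd, "/"),
       params = params)
}

#' Undo autoscaling
#'
#' @param Xs scaled matrix.
#' @param params scaling parameters from [autoscale()].
#' @return matrix on the original scale.
#' @export
unscale <- function(Xs, params) {
  sweep(sweep(as.matrix(Xs), 2, params$sd, "*"), 2, params$mean, "+")
}

# min-max scaling to [-1, 1], used by the neural-network model (suits the
# saturation range of the tanh hidden layer)
minmax_fit <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (any(hi <= lo)) {
    stop("zero-range column(s): ",
         paste(colnames(X)[hi <= lo] %||% which(hi <= lo), collapse = ", "),
         call. = FALSE)
  }
  list(lo = lo, hi = hi)
}

minmax_apply <- function(X, p) {
  sweep(sweep(as.matrix(X), 2, p$lo), 2, (p$hi - p$lo) / 2, "/") - 1
}

minmax_invert <- function(Xs, p) {
  sweep(sweep((as.matrix(Xs) + 1) / 2, 2, p$hi - p$lo, "*"), 2, p$lo, "+")
}
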