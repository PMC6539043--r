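#' Root mean square error
#'
#' `sqrt(mean((pred - obs)^2))`, the error measure used for RMSEE (training),
#' RMSEP (external prediction) and RMSECV (cross-validation).
#'
#' @param y_obs,y_pred numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    stop("y_obs and y_pred must have equal length", call. = FALSE)
  }
  sqrt(mean((y_pred - y_obs)^2))
}

#' SIMPLS partial least squares on scaled data
#'
#' De Jong's SIMPLS algorithm for a univariate response: latent variables are
#' extracted by deflating the descriptor-response cross-product vector
#' against an orthonormal basis of loading directions, so successive score
#' vectors are mutually orthogonal.  At full rank the coefficients equal the
#' ordinary least squares solution.  Inputs must already be autoscaled
#' (see [autoscale()]); [qsar_pls()] is the user-facing wrapper that handles
#' scaling.
#'
#' @param Xs scaled N x M descriptor matrix.
#' @param ys scaled response vector.
#' @param n_lv number of latent variables, at most `min(N - 1, M)`.
#' @return list with `coefficients` (M-vector on the scaled scale),
#'   `x_weights`, `x_loadings`, `y_loadings`, `scores` and `n_lv`.
#' @export
fit_simpls <- function(Xs, ys, n_lv) {
  Xs <- as.matrix(Xs)
  ys <- as.numeric(ys)
  n <- nrow(Xs); m <- ncol(Xs)
  if (n_lv < 1L || n_lv > min(n - 1L, m)) {
    stop("n_lv must be between 1 and min(N - 1, M)", call. = FALSE)
  }
  S <- crossprod(Xs, ys)
  R <- matrix(0, m, n_lv); P <- matrix(0, m, n_lv)
  Q <- numeric(n_lv); V <- matrix(0, m, n_lv)
  Tm <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    r <- S                       # univariate y: dominant direction is S itself
    t <- drop(Xs %*% r)
    nt <- sqrt(sum(t * t))
    if (nt < 1e-10) {
      stop("rank deficiency: achieved rank ", a - 1L,
           " before requested ", n_lv, " latent variables", call. = FALSE)
    }
    t <- t / nt; r <- r / nt
    p <- crossprod(Xs, t)
    q <- drop(crossprod(ys, t))
    v <- p
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    v <- v / sqrt(sum(v * v))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p; Q[a] <- q; V[, a] <- v; Tm[, a] <- t
  }
  rownames(R) <- rownames(P) <- colnames(Xs)
  list(coefficients = drop(R %*% Q), x_weights = R, x_loadings = P,
       y_loadings = Q, scores = Tm, n_lv = n_lv)
}

# fit scaling + SIMPLS on raw training data; predict raw new data
simpls_fit_raw <- function(X, y, n_lv) {
  sx <- autoscale(X)
  muy <- mean(y); sdy <- sd(y)
  if (sdy <= 0) stop("zero-variance response", call. = FALSE)
  core <- fit_simpls(sx$x, (y - muy) / sdy, n_lv)
  list(core = core,
       scaling = list(x = sx$params, y = list(mean = muy, sd = sdy)))
}

simpls_predict_raw <- function(fit, X) {
  Xs <- autoscale(X, fit$scaling$x)$x
  fit$scaling$y$mean +
    fit$scaling$y$sd * drop(Xs %*% fit$core$coefficients)
}

#' Leave-one-out cross-validation curve for PLS
#'
#' For each candidate number of latent variables, every row is held out in
#' turn, the scaling and the SIMPLS model are refitted on the remaining rows
#' (no information leaks from the held-out row), and the row is predicted.
#' RMSECV is the root mean square of the held-out residuals; the selected
#' model size attains the minimum.
#'
#' @param X raw descriptor matrix.
#' @param y raw response vector.
#' @param lv_range candidate numbers of latent variables.
#' @return list of class `cv_curve`: `lv`, `rmsecv`, `selected_lv`,
#'   `min_rmsecv`, and `residuals` (held-out residual matrix, one column per
#'   candidate).
#' @export
loocv_rmsecv <- function(X, y, lv_range = 1:4) {
  X <- as.matrix(X)
  n <- nrow(X)
  res <- matrix(NA_real_, n, length(lv_range),
                dimnames = list(rownames(X), paste0("lv", lv_range)))
  for (j in seq_along(lv_range)) {
    for (i in seq_len(n)) {
      fit <- simpls_fit_raw(X[-i, , drop = FALSE], y[-i], lv_range[j])
      res[i, j] <- simpls_predict_raw(fit, X[i, , drop = FALSE]) - y[i]
    }
  }
  rmsecv <- sqrt(colMeans(res^2))
  structure(list(lv = lv_range, rmsecv = unname(rmsecv),
                 selected_lv = lv_range[which.min(rmsecv)],
                 min_rmsecv = unname(min(rmsecv)), residuals = res),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("LOOCV curve (RMSECV by latent variables):\n")
  print(setNames(round(x$rmsecv, 4), paste0("LV", x$lv)))
  cat(sprintf("selected: %d LV (RMSECV = %.3f)\n", x$selected_lv,
              x$min_rmsecv))
  invisible(x)
}

#' Cross-validated ANOVA significance ratio
#'
#' Compares the cross-validated residuals of a model against those of the
#' mean-only null model: `F` is the ratio of the mean squared null residuals
#' to the mean squared model residuals, referred to the upper tail of the F
#' distribution with the stated degrees of freedom (by default the number of
#' residuals on each side).
#'
#' @param cv_residuals cross-validated residuals of the model.
#' @param null_residuals cross-validated residuals of the mean-only null
#'   model.
#' @param df_model,df_null degrees of freedom for the denominator and
#'   numerator mean squares.
#' @return list of class `cv_anova`: `F`, `p`, `df`, and `degenerate`
#'   (`TRUE` when the model residuals are all zero, in which case `p = 0`).
#' @export
cv_anova <- function(cv_residuals, null_residuals,
                     df_model = length(cv_residuals),
                     df_null = length(null_residuals)) {
  ms_model <- sum(cv_residuals^2) / df_model
  ms_null <- sum(null_residuals^2) / df_null
  if (ms_model == 0) {
    return(structure(list(F = Inf, p = 0, df = c(df_null, df_model),
                          degenerate = TRUE), class = "cv_anova"))
  }
  f <- ms_null / ms_model
  structure(list(F = f, p = pf(f, df_null, df_model, lower.tail = FALSE),
                 df = c(df_null, df_model), degenerate = FALSE),
            class = "cv_anova")
}

#' @export
print.cv_anova <- function(x, ...) {
  cat(sprintf("CV-ANOVA: F(%d, %d) = %.3f, p = %.3g%s\n", x$df[1], x$df[2],
              x$F, x$p, if (x$degenerate) " (degenerate: zero residuals)" else ""))
  invisible(x)
}

#' Jackknife confidence half-widths for PLS coefficients
#'
#' Leave-one-out jackknife standard errors of the standardised SIMPLS
#' coefficients, multiplied by the two-sided t critical value at `N - 1`
#' degrees of freedom.
#'
#' @param X raw descriptor matrix (N >= 3 rows).
#' @param y raw response.
#' @param n_lv number of latent variables.
#' @param level confidence level.
#' @return named vector of half-widths, one per descriptor.
#' @export
coefficient_intervals <- function(X, y, n_lv, level = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  full <- simpls_fit_raw(X, y, n_lv)$core$coefficients
  B <- t(vapply(seq_len(n), function(i) {
    simpls_fit_raw(X[-i, , drop = FALSE], y[-i], n_lv)$core$coefficients
  }, numeric(ncol(X))))
  bbar <- colMeans(B)
  se <- sqrt((n - 1) / n * colSums(sweep(B, 2, bbar)^2))
  hw <- qt(1 - (1 - level) / 2, df = n - 1) * se
  setNames(hw, colnames(X) %||% names(full))
}
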