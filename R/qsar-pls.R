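#' Fit a PLS QSAR model for ln(ORAC)
#'
#' Fits a SIMPLS partial least squares model of log ORAC on the four
#' descriptors of a compound set.  Descriptors and response are autoscaled
#' before fitting, so the reported coefficients are standardised; predictions
#' are returned on the raw ln(ORAC) scale.  When `n_lv` is `NULL` the number
#' of latent variables is selected by leave-one-out cross-validation over
#' `1:lv_max` (minimum RMSECV).
#'
#' @param data a compound set (see [load_bundled_dataset()]) with an
#'   `ln_orac` column, or a list `list(X =, y =)`.
#' @param n_lv number of latent variables; `NULL` to select by LOOCV.
#' @param lv_max largest model size considered during selection (at most the
#'   number of descriptors).
#' @return object of class `qsar_pls` with components `coefficients`
#'   (standardised), `intercept` (0 by construction on the standardised
#'   scale), `scaling`, `n_lv`, `cv` (the [loocv_rmsecv()] curve, when
#'   selection was run), `rmsee`, `fitted`, `residuals`, `anova`
#'   ([cv_anova()] of the selected model against the mean-only null) and
#'   `data` (the training set).
#' @examples
#' flav <- load_bundled_dataset()
#' split <- kennard_stone(descriptor_matrix(flav), 25)
#' fit <- qsar_pls(flav[split$train_idx, ])
#' fit
#' predict(fit, flav[split$val_idx, ])
#' @export
qsar_pls <- function(data, n_lv = NULL, lv_max = 4) {
  d <- extract_xy(data)
  X <- d$X; y <- d$y
  cv <- NULL
  if (is.null(n_lv)) {
    cv <- loocv_rmsecv(X, y, seq_len(min(lv_max, ncol(X), nrow(X) - 1L)))
    n_lv <- cv$selected_lv
  }
  fit <- simpls_fit_raw(X, y, n_lv)
  yhat <- simpls_predict_raw(fit, X)
  # LOOCV residuals of the selected model and the mean-only null
  if (is.null(cv)) {
    cvres <- loocv_rmsecv(X, y, n_lv)$residuals[, 1]
  } else {
    cvres <- cv$residuals[, match(n_lv, cv$lv)]
  }
  n <- nrow(X)
  null_res <- vapply(seq_len(n), function(i) mean(y[-i]) - y[i], 0)
  structure(list(
    coefficients = fit$core$coefficients,
    intercept = 0,
    x_weights = fit$core$x_weights,
    x_loadings = fit$core$x_loadings,
    y_loadings = fit$core$y_loadings,
    scaling = fit$scaling,
    n_lv = n_lv,
    cv = cv,
    rmsee = rmse(y, yhat),
    fitted = yhat,
    residuals = y - yhat,
    anova = cv_anova(cvres, null_res),
    data = data
  ), class = "qsar_pls")
}

# accept a compound_set (with ln_orac) or list(X =, y =)
extract_xy <- function(data) {
  if (inherits(data, "compound_set") || is.data.frame(data)) {
    if (is.null(data$ln_orac) || anyNA(data$ln_orac)) {
      stop("data must contain a complete ln_orac column", call. = FALSE)
    }
    list(X = descriptor_matrix(data), y = data$ln_orac,
         names = data$name)
  } else if (is.list(data) && !is.null(data$X) && !is.null(data$y)) {
    list(X = as.matrix(data$X), y = as.numeric(data$y),
         names = rownames(data$X))
  } else {
    stop("data must be a compound set or a list(X =, y =)", call. = FALSE)
  }
}

extract_x <- function(newdata) {
  if (inherits(newdata, "compound_set") || is.data.frame(newdata)) {
    descriptor_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
}

#' Predict ln(ORAC) from a fitted PLS model
#'
#' Applies the training scaling, the standardised linear model, and the
#' inverse response scaling.
#'
#' @param object a `qsar_pls` fit.
#' @param newdata compound set or descriptor matrix in the canonical column
#'   order; defaults to the training data.
#' @param ... unused.
#' @return numeric vector of predicted ln(ORAC).
#' @export
predict.qsar_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- extract_x(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$coefficients), call. = FALSE)
  }
  Xs <- autoscale(X, object$scaling$x)$x
  drop(object$scaling$y$mean +
         object$scaling$y$sd *
           (object$intercept + Xs %*% object$coefficients))
}

#' Coefficients of a PLS QSAR model
#'
#' @param object a `qsar_pls` fit.
#' @param raw if `TRUE`, convert the standardised coefficients to raw
#'   ln(ORAC)-per-kcal/mol units (with the matching intercept as attribute).
#' @param ... unused.
#' @export
coef.qsar_pls <- function(object, raw = FALSE, ...) {
  b <- object$coefficients
  if (!raw) return(b)
  sx <- object$scaling$x; sy <- object$scaling$y
  braw <- b * sy$sd / sx$sd
  structure(braw, intercept = sy$mean - sum(braw * sx$mean))
}

#' @export
fitted.qsar_pls <- function(object, ...) object$fitted

#' @export
residuals.qsar_pls <- function(object, ...) object$residuals

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("PLS QSAR model (SIMPLS, %d latent variable%s)\n", x$n_lv,
              if (x$n_lv > 1) "s" else ""))
  cat("Standardised coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("RMSEE = %.3f", x$rmsee))
  if (!is.null(x$cv)) cat(sprintf(", RMSECV = %.3f", x$cv$min_rmsecv))
  cat("\n")
  invisible(x)
}

#' @export
summary.qsar_pls <- function(object, level = 0.95, ...) {
  d <- extract_xy(object$data)
  hw <- coefficient_intervals(d$X, d$y, object$n_lv, level = level)
  out <- list(fit = object,
              table = data.frame(coefficient = object$coefficients,
                                 half_width = hw),
              level = level)
  class(out) <- "summary.qsar_pls"
  out
}

#' @export
print.summary.qsar_pls <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Jackknife %d%% confidence half-widths:\n",
              round(100 * x$level)))
  print(round(x$table, 4))
  print(x$fit$anova)
  invisible(x)
}

#' Observed-versus-predicted plot
#'
#' @param x a `qsar_pls` fit.
#' @param newdata optional external set, over-plotted with filled points.
#' @param ... passed to [plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot.qsar_pls <- function(x, newdata = NULL, ...) {
  d <- extract_xy(x$data)
  obs <- d$y; pred <- x$fitted
  xlim <- range(obs, pred)
  graphics::plot(obs, pred, xlab = "observed ln(ORAC)",
                 ylab = "predicted ln(ORAC)", xlim = xlim, ylim = xlim, ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(newdata)) {
    d2 <- extract_xy(newdata)
    graphics::points(d2$y, predict(x, newdata), pch = 19)
  }
  invisible(list(observed = obs, predicted = pred))
}
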