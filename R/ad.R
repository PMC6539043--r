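#' Leverage values
#'
#' Diagonal of the hat matrix `X2 (X1' X1)^-1 X2'` where `X1` is the
#' training descriptor matrix and `X2` the query matrix, both autoscaled by
#' the training parameters.  When the query equals the training set the
#' leverages sum to the number of descriptors (hat-matrix trace identity).
#'
#' @param X_train N x K training matrix (full column rank after scaling).
#' @param X_query Q x K query matrix; defaults to the training set.
#' @return numeric vector of Q leverages.
#' @export
leverages <- function(X_train, X_query = X_train) {
  sc <- autoscale(as.matrix(X_train))
  Xs1 <- sc$x
  Xs2 <- autoscale(as.matrix(X_query), sc$params)$x
  XtX <- crossprod(Xs1)
  inv <- tryCatch(solve(XtX), error = function(e) {
    stop("training cross-product matrix is singular (rank-deficient X)",
         call. = FALSE)
  })
  unname(rowSums((Xs2 %*% inv) * Xs2))
}

#' Critical leverage threshold
#'
#' The conventional warning limit `h* = 3 (K + 1) / N`, with `K` the number
#' of descriptors and `N` the number of training observations.
#'
#' @param K number of descriptors (>= 0).
#' @param N training-set size (> 0).
#' @return scalar threshold.
#' @examples
#' critical_leverage(4, 25) # 0.600
#' critical_leverage(4, 26) # 0.577
#' @export
critical_leverage <- function(K, N) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (K < 0) stop("K must be non-negative", call. = FALSE)
  3 * (K + 1) / N
}

#' Standardised residuals
#'
#' Residuals centred on their mean and divided by their standard deviation.
#' A zero-spread residual vector is returned as all zeros with a
#' `degenerate` attribute instead of failing.
#'
#' @param y_obs,y_pred observed and predicted values.
#' @return numeric vector with attribute `degenerate`.
#' @export
standardized_residuals <- function(y_obs, y_pred) {
  r <- y_obs - y_pred
  s <- sd(r)
  if (!is.finite(s) || s == 0) {
    return(structure(rep(0, length(r)), degenerate = TRUE))
  }
  structure((r - mean(r)) / s, degenerate = FALSE)
}

#' Williams-plot applicability-domain report
#'
#' Combines leverages against the training set, the critical leverage
#' `h* = 3(K + 1)/N`, and standardised residuals into per-compound domain
#' flags: `high_leverage` when `h > h*`, `residual_outlier` when
#' `|r| > residual_limit` (three standard deviations by default), `both`,
#' or `in_domain`.
#'
#' @param X_train training descriptor matrix.
#' @param X_query query descriptor matrix.
#' @param y_obs,y_pred observed and predicted activities for the query rows
#'   (optional; without them only leverage flags are set).
#' @param std_resid pre-computed standardised residuals, overriding
#'   `y_obs`/`y_pred` (used by protocol averaging).
#' @param h pre-computed leverages, overriding `X_query`.
#' @param residual_limit warning limit on `|r|`.
#' @param names compound names for the report rows.
#' @return data.frame of class `ad_report` with columns `name`, `leverage`,
#'   `std_residual`, `flag`; attributes `h_star`, `K`, `N`.
#' @export
williams_report <- function(X_train, X_query = X_train, y_obs = NULL,
                            y_pred = NULL, std_resid = NULL, h = NULL,
                            residual_limit = 3, names = NULL) {
  X_train <- as.matrix(X_train)
  if (is.null(h)) h <- leverages(X_train, X_query)
  K <- ncol(X_train)
  N <- nrow(X_train)
  h_star <- critical_leverage(K, N)
  if (is.null(std_resid)) {
    std_resid <- if (!is.null(y_obs) && !is.null(y_pred)) {
      standardized_residuals(y_obs, y_pred)
    } else {
      rep(NA_real_, length(h))
    }
  }
  if (length(std_resid) != length(h)) {
    stop("residuals and leverages have different lengths", call. = FALSE)
  }
  high_h <- h > h_star
  out_r <- !is.na(std_resid) & abs(std_resid) > residual_limit
  flag <- ifelse(high_h & out_r, "both",
                 ifelse(high_h, "high_leverage",
                        ifelse(out_r, "residual_outlier", "in_domain")))
  rep_names <- names %||% rownames(as.matrix(X_query)) %||%
    as.character(seq_along(h))
  structure(data.frame(name = rep_names, leverage = h,
                       std_residual = as.numeric(std_resid), flag = flag,
                       stringsAsFactors = FALSE),
            h_star = h_star, K = K, N = N,
            class = c("ad_report", "data.frame"))
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("Applicability domain (K = %d, N = %d, h* = %.3f):\n",
              attr(x, "K"), attr(x, "N"), attr(x, "h_star")))
  flagged <- x$flag != "in_domain"
  if (any(flagged)) {
    print.data.frame(x[flagged, ], row.names = FALSE)
    cat(sprintf("%d of %d compounds outside the domain\n", sum(flagged),
                nrow(x)))
  } else {
    cat(sprintf("all %d compounds inside the domain\n", nrow(x)))
  }
  invisible(x)
}

#' Applicability domain of a fitted QSAR model
#'
#' For a [qsar_pls()] fit, leverages of the query compounds against the PLS
#' training set and standardised residuals of the PLS predictions.  For a
#' [qsar_ann()] fit, the per-cycle leverages (against each cycle's training
#' subset) and per-cycle standardised residuals (over all compounds) are
#' averaged over cycles before flagging, so the report reflects the whole
#' resampling protocol; `N` in the critical leverage is the per-cycle
#' training-set size.
#'
#' @param fit a `qsar_pls` or `qsar_ann` object.
#' @param newdata query compounds (PLS only); defaults to the training data.
#' @param ... passed to [williams_report()].
#' @return an `ad_report`.
#' @export
ad_summary <- function(fit, newdata = NULL, ...) UseMethod("ad_summary")

#' @rdname ad_summary
#' @export
ad_summary.qsar_pls <- function(fit, newdata = NULL, ...) {
  d <- extract_xy(fit$data)
  if (is.null(newdata)) {
    williams_report(d$X, d$X, d$y, predict(fit), names = d$names, ...)
  } else {
    dq <- extract_xy(newdata)
    williams_report(d$X, dq$X, dq$y, predict(fit, newdata),
                    names = dq$names, ...)
  }
}

#' @rdname ad_summary
#' @export
ad_summary.qsar_ann <- function(fit, newdata = NULL, ...) {
  if (!is.null(newdata)) {
    stop("the ANN protocol report is defined on its own data set",
         call. = FALSE)
  }
  d <- extract_xy(fit$data)
  n <- nrow(d$X)
  lev <- vapply(fit$cycles, function(cc) {
    leverages(d$X[cc$split$train_idx, , drop = FALSE], d$X)
  }, numeric(n))
  sr <- vapply(fit$cycles, function(cc) {
    as.numeric(standardized_residuals(d$y, cc$pred))
  }, numeric(n))
  # K+1 and N follow the per-cycle training matrices
  williams_report(d$X[fit$cycles[[1]]$split$train_idx, , drop = FALSE],
                  h = rowMeans(lev), std_resid = rowMeans(sr),
                  names = d$names, ...)
}
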