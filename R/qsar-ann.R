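#' Fit the repeated-resampling ANN QSAR model
#'
#' The neural-network QSAR protocol: in each cycle the data set is randomly
#' re-partitioned into disjoint training / test / validation sets (default
#' 26/5/5), a fresh network is initialised, and Levenberg-Marquardt training
#' runs with the test set as the early-stopping monitor; the validation set
#' is never seen during training.  Per cycle the protocol records the
#' training RMSEE, the test and validation RMSEPs, and every compound's
#' prediction; across cycles it aggregates means and standard deviations of
#' the errors and of each compound's prediction (over all cycles and over
#' out-of-train cycles only).  Cycles whose training diverges are dropped
#' and counted.
#'
#' Because the three sets are re-drawn every cycle, each compound moves in
#' and out of training; the per-compound averages therefore mix in-train and
#' out-of-train predictions (roughly in proportion 26:10), and the RMSE of
#' those averaged predictions is much smaller than any single cycle's
#' out-of-train error.  Both views are reported; see the package vignette
#' for why they differ by a factor of several.
#'
#' @param data compound set with `ln_orac`.
#' @param n_hidden hidden-layer size.
#' @param n_cycles number of resampling cycles.
#' @param sizes `c(n_train, n_test, n_val)`, summing to `nrow(data)`.
#' @param seed master seed; per-cycle seeds are spawned from it.
#' @param config [lm_config()] used for every cycle.
#' @return object of class `qsar_ann`; see Details.  Components include
#'   `cycles` (list with each cycle's trained model, split and errors),
#'   `errors` (per-cycle RMSEE/RMSEP matrix), `summary` (mean and sd of each
#'   error over completed cycles; sd is `NA` when `n_cycles = 1`),
#'   `predictions` (per-compound mean and sd over all cycles and over
#'   out-of-train cycles), `ensemble_rmse` (RMSE of cycle-averaged
#'   predictions, by membership), and `n_diverged`.
#' @examples
#' flav <- load_bundled_dataset()
#' fit <- qsar_ann(flav, n_cycles = 25, seed = 1)
#' fit
#' @export
qsar_ann <- function(data, n_hidden = 8, n_cycles = 1000,
                     sizes = c(26, 5, 5), seed = 1, config = lm_config()) {
  d <- extract_xy(data)
  X <- d$X; y <- d$y
  n <- nrow(X)
  if (sum(sizes) != n) stop("sizes must sum to nrow(data)", call. = FALSE)
  set.seed(seed)
  cycle_seeds <- sample.int(.Machine$integer.max - 1L, n_cycles)
  cycles <- vector("list", n_cycles)
  diverged <- 0L
  for (cy in seq_len(n_cycles)) {
    cycles[[cy]] <- tryCatch(
      run_ann_cycle(X, y, sizes, n_hidden, cycle_seeds[cy], config),
      error = function(e) e
    )
    if (inherits(cycles[[cy]], "error")) diverged <- diverged + 1L
  }
  ok <- !vapply(cycles, inherits, TRUE, what = "error")
  if (!any(ok)) stop("all cycles diverged", call. = FALSE)
  cycles <- cycles[ok]
  errors <- t(vapply(cycles, `[[`, numeric(3), "errors"))
  colnames(errors) <- c("rmsee", "rmsep_test", "rmsep_val")
  P <- vapply(cycles, `[[`, numeric(n), "pred")        # n x cycles
  in_train <- vapply(cycles, function(cc) seq_len(n) %in% cc$split$train_idx,
                     logical(n))
  mean_sd <- function(v) c(mean = mean(v),
                           sd = if (length(v) > 1L) sd(v) else NA_real_)
  pred_stats <- function(mask) {
    t(vapply(seq_len(n), function(i) {
      v <- P[i, mask[i, ], drop = TRUE]
      if (length(v) == 0L) c(mean = NA_real_, sd = NA_real_) else mean_sd(v)
    }, numeric(2)))
  }
  all_mask <- matrix(TRUE, n, ncol(P))
  stats_all <- pred_stats(all_mask)
  stats_out <- pred_stats(!in_train)
  predictions <- data.frame(
    name = d$names %||% as.character(seq_len(n)),
    observed = y,
    mean = stats_all[, "mean"], sd = stats_all[, "sd"],
    mean_out_of_train = stats_out[, "mean"], sd_out_of_train = stats_out[, "sd"]
  )
  membership_rmse <- function(mask) {
    m <- pred_stats(mask)[, "mean"]
    keep <- !is.na(m)
    rmse(y[keep], m[keep])
  }
  test_mask <- vapply(cycles, function(cc) seq_len(n) %in% cc$split$test_idx,
                      logical(n))
  val_mask <- vapply(cycles, function(cc) seq_len(n) %in% cc$split$val_idx,
                     logical(n))
  structure(list(
    n_hidden = n_hidden, n_cycles = n_cycles, sizes = sizes, seed = seed,
    config = config, cycles = cycles, errors = errors,
    summary = apply(errors, 2, mean_sd),
    predictions = predictions,
    ensemble_rmse = c(all = membership_rmse(all_mask),
                      train = membership_rmse(in_train),
                      test = membership_rmse(test_mask),
                      val = membership_rmse(val_mask),
                      out_of_train = membership_rmse(!in_train)),
    n_diverged = diverged,
    data = data
  ), class = "qsar_ann")
}

run_ann_cycle <- function(X, y, sizes, n_hidden, seed, config) {
  split <- random_three_way_split(nrow(X), sizes, seed = seed)
  net <- init_network(ncol(X), n_hidden, seed = seed + 1L)
  fit <- train_lm(net, X[split$train_idx, , drop = FALSE], y[split$train_idx],
                  X[split$test_idx, , drop = FALSE], y[split$test_idx],
                  config = config)
  pred <- mlp_forward(fit$model, X)
  err <- c(rmse(y[split$train_idx], pred[split$train_idx]),
           if (length(split$test_idx) > 0)
             rmse(y[split$test_idx], pred[split$test_idx]) else NA_real_,
           if (length(split$val_idx) > 0)
             rmse(y[split$val_idx], pred[split$val_idx]) else NA_real_)
  list(model = fit$model, split = split, errors = err, pred = pred,
       epochs = fit$epochs, stopped_by = fit$stopped_by)
}

#' @export
print.qsar_ann <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ANN QSAR model: %d-%d-1 perceptron, %d resampling cycles (%d/%d/%d splits)\n",
              x$cycles[[1]]$model$n_inputs, x$n_hidden, nrow(x$errors),
              x$sizes[1], x$sizes[2], x$sizes[3]))
  fmt <- function(j) sprintf("%.3f +- %.3f", s["mean", j], s["sd", j])
  cat("  per-cycle RMSEE:            ", fmt("rmsee"), "\n")
  cat("  per-cycle RMSEP (test):     ", fmt("rmsep_test"), "\n")
  cat("  per-cycle RMSEP (validation):", fmt("rmsep_val"), "\n")
  cat(sprintf("  cycle-averaged prediction RMSE (all compounds): %.3f\n",
              x$ensemble_rmse["all"]))
  if (x$n_diverged > 0)
    cat(sprintf("  %d cycle(s) diverged and were dropped\n", x$n_diverged))
  invisible(x)
}

#' @export
summary.qsar_ann <- function(object, ...) {
  structure(list(fit = object), class = "summary.qsar_ann")
}

#' @export
print.summary.qsar_ann <- function(x, ...) {
  print(x$fit)
  cat("\nPer-compound predictions (mean over cycles):\n")
  tab <- round(x$fit$predictions[, -1], 3)
  rownames(tab) <- x$fit$predictions$name
  print(tab)
  invisible(x)
}

#' Ensemble prediction from the resampling protocol
#'
#' Each cycle's network predicts `newdata`; the mean (and sd) over cycles is
#' returned — the model's consensus prediction for new compounds.
#'
#' @param object a `qsar_ann` fit.
#' @param newdata compound set or descriptor matrix; defaults to the
#'   training data.
#' @param ... unused.
#' @return data.frame with `mean` and `sd` of the predicted ln(ORAC).
#' @export
predict.qsar_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$predictions[, c("mean", "sd")])
  }
  X <- extract_x(newdata)
  P <- vapply(object$cycles, function(cc) mlp_forward(cc$model, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  data.frame(mean = rowMeans(P), sd = apply(P, 1, sd))
}

#' @export
plot.qsar_ann <- function(x, ...) {
  p <- x$predictions
  lim <- range(p$observed, p$mean)
  graphics::plot(p$observed, p$mean, xlim = lim, ylim = lim,
                 xlab = "observed ln(ORAC)",
                 ylab = "predicted ln(ORAC) (cycle mean)", ...)
  graphics::arrows(p$observed, p$mean - p$sd, p$observed, p$mean + p$sd,
                   angle = 90, code = 3, length = 0.02)
  graphics::abline(0, 1, lty = 2)
  invisible(p)
}

#' Architecture grid search for the ANN protocol
#'
#' Runs a reduced resampling protocol for every combination of hidden-layer
#' size and training ratio and returns the cell with the lowest mean
#' validation RMSEP.  The remaining samples are split evenly between test
#' and validation sets.
#'
#' @param data compound set.
#' @param hidden_range candidate hidden-layer sizes.
#' @param train_ratio_range candidate training fractions (0-1).
#' @param cycles_per_cell resampling cycles per grid cell.
#' @param seed master seed.
#' @param config [lm_config()].
#' @return list with `best` (`n_hidden`, `train_ratio`) and `table`
#'   (one row per cell: mean errors).
#' @export
grid_search_architecture <- function(data, hidden_range = 2:12,
                                     train_ratio_range = seq(0.6, 0.75, 0.05),
                                     cycles_per_cell = 20, seed = 1,
                                     config = lm_config()) {
  if (length(hidden_range) == 0L || length(train_ratio_range) == 0L) {
    stop("grid ranges must be nonempty", call. = FALSE)
  }
  d <- extract_xy(data)
  n <- nrow(d$X)
  grid <- expand.grid(n_hidden = hidden_range, train_ratio = train_ratio_range)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n_train <- round(grid$train_ratio[i] * n)
    n_test <- ceiling((n - n_train) / 2)
    sizes <- c(n_train, n_test, n - n_train - n_test)
    fit <- qsar_ann(data, n_hidden = grid$n_hidden[i],
                    n_cycles = cycles_per_cell, sizes = sizes,
                    seed = seed + i, config = config)
    data.frame(n_hidden = grid$n_hidden[i], train_ratio = grid$train_ratio[i],
               rmsee = fit$summary["mean", "rmsee"],
               rmsep_test = fit$summary["mean", "rmsep_test"],
               rmsep_val = fit$summary["mean", "rmsep_val"])
  })
  table <- do.call(rbind, rows)
  best <- table[which.min(table$rmsep_val), , drop = FALSE]
  list(best = list(n_hidden = best$n_hidden, train_ratio = best$train_ratio),
       table = table)
}

#' Five-fold cross-validation of the ANN
#'
#' Repeated k-fold cross-validation: per fold the network trains on the
#' other folds (with a small internal stop split carved out of them for
#' early stopping) and predicts the held-out fold, so every compound is
#' predicted exactly once per repetition.  The per-repetition RMSECV is the
#' RMSE over all held-out predictions.  On small data sets this is a much
#' harsher test than the resampling protocol because each training set loses
#' a full fold of compounds.
#'
#' @param data compound set.
#' @param k number of folds.
#' @param cycles number of repetitions (fresh fold assignment and weights).
#' @param n_hidden hidden-layer size.
#' @param n_stop size of the internal stop split.
#' @param seed master seed.
#' @param config [lm_config()].
#' @return list with `rmsecv` (per repetition), `mean`, `sd`, and
#'   `predictions` (held-out predictions, compounds x repetitions).
#' @export
kfold_cv_ann <- function(data, k = 5, cycles = 20, n_hidden = 8, n_stop = 5,
                         seed = 1, config = lm_config()) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  d <- extract_xy(data)
  X <- d$X; y <- d$y; n <- nrow(X)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cycles)
  P <- matrix(NA_real_, n, cycles)
  for (rp in seq_len(cycles)) {
    folds <- kfold_indices(n, k, seed = rep_seeds[rp])
    for (f in seq_len(k)) {
      tr <- folds[[f]]$train_idx
      ho <- folds[[f]]$val_idx
      set.seed(rep_seeds[rp] + f)
      st <- sample(tr, min(n_stop, max(1L, length(tr) %/% 5L)))
      tr2 <- setdiff(tr, st)
      net <- init_network(ncol(X), n_hidden, seed = rep_seeds[rp] + k + f)
      fit <- train_lm(net, X[tr2, , drop = FALSE], y[tr2],
                      X[st, , drop = FALSE], y[st], config = config)
      P[ho, rp] <- mlp_forward(fit$model, X[ho, , drop = FALSE])
    }
  }
  rmsecv <- apply(P, 2, function(p) rmse(y, p))
  list(rmsecv = rmsecv, mean = mean(rmsecv),
       sd = if (cycles > 1) sd(rmsecv) else NA_real_, predictions = P)
}
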