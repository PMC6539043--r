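#' Specification for synthetic descriptor/activity data
#'
#' Describes a generator whose descriptors mimic the bundled table (same
#' four columns, means and standard deviations matched to it by default) and
#' whose activity follows a known ground-truth function plus Gaussian noise:
#' `y = intercept + sum(beta * x) + gamma * tanh(delta * z_pa)`, where
#' `z_pa` is the standardised proton-affinity column.  The bounded tanh term
#' reproduces the saturating, non-linear descriptor-activity trends that
#' motivate the neural-network model; set `gamma = 0` for purely linear
#' truth.
#'
#' @param n sample count.
#' @param means,sds descriptor means and standard deviations (kcal/mol);
#'   defaults are the bundled table's column statistics.
#' @param beta linear coefficients on the raw descriptor scale.
#' @param intercept intercept of the truth function.
#' @param gamma amplitude of the tanh non-linearity (ln ORAC units).
#' @param delta steepness of the tanh non-linearity.
#' @param noise_sd standard deviation of the additive activity noise.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 100,
                           means = NULL, sds = NULL,
                           beta = NULL, intercept = 0,
                           gamma = 1, delta = 2,
                           noise_sd = 0.1, seed = 1) {
  if (is.null(means) || is.null(sds) || is.null(beta)) {
    flav <- load_bundled_dataset()
    X <- descriptor_matrix(flav)
    if (is.null(means)) means <- colMeans(X)
    if (is.null(sds)) sds <- apply(X, 2, sd)
    if (is.null(beta)) {
      # negative dependence on each descriptor, scaled to its spread,
      # mirroring the bundled QSAR's coefficient signs
      sdy <- sd(flav$ln_orac)
      beta <- setNames(-0.35 * sdy / sds, DESCRIPTORS)
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(sds <= 0)) stop("descriptor sds must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), means = means, sds = sds, beta = beta,
                 intercept = intercept, gamma = gamma, delta = delta,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic compound set with known truth
#'
#' Draws descriptors from independent normals with the spec's moments,
#' computes the ground-truth activity, adds Gaussian noise, and returns both
#' the compound set (provenance `"synthetic"`) and the truth function.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (compound set including `ln_orac`), `truth`
#'   (function mapping a descriptor matrix to noiseless activity), and
#'   `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n
  X <- vapply(seq_along(DESCRIPTORS), function(j) {
    rnorm(n, spec$means[j], spec$sds[j])
  }, numeric(n))
  colnames(X) <- DESCRIPTORS
  truth <- function(X) {
    X <- as.matrix(X)
    z_pa <- (X[, "pa1"] - spec$means["pa1"]) / spec$sds["pa1"]
    spec$intercept + drop(X %*% spec$beta) +
      spec$gamma * tanh(spec$delta * z_pa)
  }
  y <- truth(X) + rnorm(n, 0, spec$noise_sd)
  df <- data.frame(name = sprintf("synth_%03d", seq_len(n)), X,
                   ln_orac = y, check.names = FALSE)
  list(data = as_compound_set(df, provenance = "synthetic"),
       truth = truth, spec = spec)
}

#' Parameter-recovery report for synthetic data
#'
#' Checks how well the fitted models recover a known generator: for the
#' linear part, whether each true standardised coefficient lies inside the
#' PLS jackknife confidence interval; for predictive accuracy, the RMSEP of
#' the PLS model (and optionally of the ANN protocol) on freshly generated
#' noiseless test data, to be compared against the generator's `noise_sd`.
#'
#' @param gen a [generate_dataset()] result.
#' @param pls_fit a [qsar_pls()] fit on `gen$data`.
#' @param ann_fit optional [qsar_ann()] fit on `gen$data`.
#' @param n_test size of the fresh test sample.
#' @param level confidence level for the coefficient check.
#' @return list with `true_standardized` (true coefficients on the fitted
#'   model's standardised scale, linear part), `covered` (logical per
#'   coefficient), `pls_rmsep`, and `ann_rmsep` (`NA` without `ann_fit`).
#' @export
parameter_recovery_report <- function(gen, pls_fit, ann_fit = NULL,
                                      n_test = 500, level = 0.95) {
  spec <- gen$spec
  d <- extract_xy(gen$data)
  # truth on the standardised scale of the fitted model (linear term only)
  sx <- pls_fit$scaling$x; sy <- pls_fit$scaling$y
  true_std <- spec$beta * sx$sd / sy$sd
  hw <- coefficient_intervals(d$X, d$y, pls_fit$n_lv, level = level)
  covered <- abs(pls_fit$coefficients - true_std) <= hw
  # fresh noiseless test data
  test_spec <- spec
  test_spec$n <- as.integer(n_test)
  test_spec$noise_sd <- 0
  test_spec$seed <- spec$seed + 1L
  test <- generate_dataset(test_spec)
  Xt <- descriptor_matrix(test$data)
  yt <- test$truth(Xt)
  pls_rmsep <- rmse(yt, predict(pls_fit, Xt))
  ann_rmsep <- if (!is.null(ann_fit)) {
    rmse(yt, predict(ann_fit, Xt)$mean)
  } else NA_real_
  list(true_standardized = true_std, covered = covered,
       half_widths = hw, pls_rmsep = pls_rmsep, ann_rmsep = ann_rmsep,
       noise_sd = spec$noise_sd)
}
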