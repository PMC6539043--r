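test_that("the resampling protocol is reproducible and well-formed", {
  flav <- load_bundled_dataset()
  fit1 <- qsar_ann(flav, n_cycles = 8, seed = 21)
  fit2 <- qsar_ann(flav, n_cycles = 8, seed = 21)
  expect_equal(fit1$errors, fit2$errors)
  expect_equal(fit1$predictions, fit2$predictions)
  fit3 <- qsar_ann(flav, n_cycles = 8, seed = 22)
  expect_false(identical(fit1$errors, fit3$errors))

  # per-cycle splits partition the data
  for (cc in fit1$cycles) {
    expect_setequal(c(cc$split$train_idx, cc$split$test_idx,
                      cc$split$val_idx), 1:36)
  }
  # summary statistics recompute from the per-cycle records
  expect_equal(fit1$summary["mean", "rmsee"], mean(fit1$errors[, "rmsee"]))
  expect_equal(fit1$summary["sd", "rmsep_val"], sd(fit1$errors[, "rmsep_val"]))
  expect_true(all(fit1$predictions$sd >= 0, na.rm = TRUE))
  expect_error(qsar_ann(flav, n_cycles = 2, sizes = c(20, 5, 5), seed = 1),
               "sum")
})

test_that("a single cycle reports absent (not zero) standard deviations", {
  fit <- qsar_ann(load_bundled_dataset(), n_cycles = 1, seed = 5)
  expect_true(all(is.na(fit$summary["sd", ])))
  expect_true(all(is.na(fit$predictions$sd)))
})

test_that("noiseless linear data is learned to near machine noise", {
  g <- generate_dataset(synthetic_spec(n = 36, gamma = 0, noise_sd = 0,
                                       seed = 42))
  fit <- qsar_ann(g$data, n_cycles = 15, seed = 7)
  expect_true(all(fit$summary["mean", ] < 0.05))
})

test_that("ensemble prediction on new data averages the cycle networks", {
  g <- generate_dataset(synthetic_spec(n = 36, noise_sd = 0.05, seed = 2))
  fit <- qsar_ann(g$data, n_cycles = 5, seed = 3)
  Xnew <- descriptor_matrix(g$data)[1:4, ]
  pr <- predict(fit, Xnew)
  manual <- rowMeans(vapply(fit$cycles,
                            function(cc) mlp_forward(cc$model, Xnew),
                            numeric(4)))
  expect_equal(pr$mean, manual)
})

test_that("architecture grid search covers the grid and returns its best cell", {
  flav <- load_bundled_dataset()
  gs <- grid_search_architecture(flav, hidden_range = c(4, 8),
                                 train_ratio_range = 26 / 36,
                                 cycles_per_cell = 4, seed = 13)
  expect_identical(nrow(gs$table), 2L)
  expect_true(gs$best$n_hidden %in% c(4, 8))
  expect_equal(gs$best$n_hidden,
               gs$table$n_hidden[which.min(gs$table$rmsep_val)])

  single <- grid_search_architecture(flav, hidden_range = 6,
                                     train_ratio_range = 26 / 36,
                                     cycles_per_cell = 3, seed = 14)
  expect_identical(nrow(single$table), 1L)
  expect_identical(single$best$n_hidden, 6)
  expect_error(grid_search_architecture(flav, integer(0)), "nonempty")
})

test_that("k-fold CV predicts each compound exactly once per repetition", {
  flav <- load_bundled_dataset()
  kf <- kfold_cv_ann(flav, k = 5, cycles = 3, seed = 17)
  expect_identical(dim(kf$predictions), c(36L, 3L))
  expect_true(all(!is.na(kf$predictions)))
  expect_length(kf$rmsecv, 3)
  expect_equal(kf$mean, mean(kf$rmsecv))
  expect_error(kfold_cv_ann(flav, k = 1), "k")
})

test_that("k-fold CV error approaches the noise floor on easy data", {
  g <- generate_dataset(synthetic_spec(n = 120, noise_sd = 0.1, seed = 31))
  kf <- kfold_cv_ann(g$data, k = 5, cycles = 2, seed = 32)
  expect_lt(kf$mean, 0.3)
})
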