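new_split_result <- function(train_idx, test_idx, val_idx, method,
                             seed = NA_integer_, n = NA_integer_) {
  idx <- c(train_idx, test_idx, val_idx)
  if (anyDuplicated(idx)) stop("split indices are not disjoint", call. = FALSE)
  if (!is.na(n) && length(idx) > 0 && (min(idx) < 1L || max(idx) > n)) {
    stop("split indices out of range", call. = FALSE)
  }
  structure(list(train_idx = as.integer(train_idx),
                 test_idx = as.integer(test_idx),
                 val_idx = as.integer(val_idx),
                 method = method, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("%s split: %d train / %d test / %d validation\n", x$method,
              length(x$train_idx), length(x$test_idx), length(x$val_idx)))
  invisible(x)
}

#' Kennard-Stone training-set selection
#'
#' Deterministic max-min-distance selection of a space-covering training
#' subset.  Distances are Euclidean on the autoscaled (zero mean, unit
#' variance) descriptor matrix, so no descriptor dominates by virtue of its
#' kcal/mol scale.  The seed pair is the two rows at maximum distance; each
#' following pick maximises its minimum distance to the already selected
#' rows.  Ties are broken by lowest row index, making the selection fully
#' reproducible.  Unselected rows form the validation set.
#'
#' @param X numeric descriptor matrix (rows = compounds), no missing values.
#' @param n_select number of training rows, between 2 and `nrow(X)`.
#' @return a `split_result` with `train_idx` in selection order and
#'   `val_idx` the remaining rows.
#' @examples
#' flav <- load_bundled_dataset()
#' kennard_stone(descriptor_matrix(flav), 25)
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  if (n_select < 2L || n_select > n) {
    stop("n_select must be between 2 and nrow(X)", call. = FALSE)
  }
  Xs <- autoscale(X)$x
  D <- as.matrix(dist(Xs))
  # seed pair: maximum pairwise distance, lexicographically first on ties
  pairs <- which(D == max(D), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sel <- as.integer(pairs[1, ])
  rest <- setdiff(seq_len(n), sel)
  while (length(sel) < n_select) {
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    pick <- rest[which.max(mind)]  # which.max returns first (lowest index) tie
    sel <- c(sel, pick)
    rest <- setdiff(rest, pick)
  }
  new_split_result(sel, integer(0), sort(rest),
                   method = "kennard_stone", n = n)
}

#' Random three-way split
#'
#' Partitions `1:n` into disjoint training, test and validation sets of the
#' requested sizes by a seeded uniform permutation.
#'
#' @param n number of samples.
#' @param sizes integer vector `c(n_train, n_test, n_val)`; must sum to `n`.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return a `split_result`.
#' @export
random_three_way_split <- function(n, sizes = c(26, 5, 5), seed) {
  if (length(sizes) != 3L || sum(sizes) != n) {
    stop("sizes must have length 3 and sum to n", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  new_split_result(perm[seq_len(sizes[1])],
                   perm[sizes[1] + seq_len(sizes[2])],
                   perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                   method = "random_three_way", seed = seed, n = n)
}

#' k-fold cross-validation indices
#'
#' Each index is held out exactly once; fold sizes differ by at most one.
#' With `k = n` this is leave-one-out.
#'
#' @param n number of samples.
#' @param k number of folds, between 2 and `n`.
#' @param seed integer seed for the fold assignment.
#' @return list of `k` `split_result`s; the held-out fold is `val_idx`.
#' @export
kfold_indices <- function(n, k, seed) {
  if (k < 2L || k > n) stop("k must be between 2 and n", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    new_split_result(which(fold != f), integer(0), which(fold == f),
                     method = "kfold", seed = seed, n = n)
  })
}
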