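test_that("pattern enumeration matches the brute-force orbit count", {
  pats <- enumerate_patterns(3)
  expect_length(pats, 115)

  # oracle: all 175 non-empty subsets of size <= 3, grouped by mirror orbit
  sites <- flavone_sites()
  all_subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(sites, k, simplify = FALSE)
  }), recursive = FALSE)
  expect_length(all_subsets, 175)
  expect_length(unique(vapply(all_subsets, orbit_key, "")), 115)

  # every enumerated pattern is a distinct canonical representative
  keys <- vapply(pats, orbit_key, "")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(vapply(pats, function(p) {
    identical(p, canonical_pattern(p))
  }, TRUE)))

  expect_length(enumerate_patterns(1), 8)
  expect_length(enumerate_patterns(0), 0)
  expect_error(enumerate_patterns(11), "between")

  # stable deterministic order
  expect_identical(pats, enumerate_patterns(3))
})

test_that("canonical form folds the B-ring mirror symmetry", {
  expect_identical(canonical_pattern("6"), "6")
  expect_identical(canonical_pattern("2'"), canonical_pattern("6'"))
  expect_identical(canonical_pattern(c("3'", "5'")), c("3'", "5'"))
  # idempotent
  p <- canonical_pattern(c("6'", "7"))
  expect_identical(canonical_pattern(p), p)
  expect_error(canonical_pattern("9"), "unknown site")
})

test_that("SMILES emission gives the right formulas", {
  expect_identical(pattern_formula(character(0)), "C15H10O2")
  expect_identical(pattern_formula(c("7", "8")), "C15H10O4")
  expect_true(all(vapply(enumerate_patterns(3), function(p) {
    length(p) <= 3 && pattern_formula(p) == sprintf("C15H10O%d", 2 + length(p))
  }, TRUE)))

  # hydroxyl count in the SMILES string equals the substitution count
  smi <- pattern_to_smiles(c("3", "7", "4'"))
  expect_identical(lengths(regmatches(smi, gregexpr("(O)", smi, fixed = TRUE))),
                   3L)
  # balanced ring-bond digits and one carbonyl
  expect_identical(substr(smi, 1, 4), "O=C1")
  expect_error(pattern_to_smiles("R4"), "unknown site")

  designs <- designed_compounds(3)
  expect_identical(nrow(designs), 115L)
  expect_false(anyDuplicated(designs$smiles) > 0)
})

test_that("substituent frequency table counts sites by activity group", {
  pats <- list(c("6", "7"), c("6", "7", "3'"), c("5"), c("6"))
  preds <- c(8, 6, 1, 3)  # two high (> 5), one low (< 2), one in between
  tab <- substituent_frequency_table(pats, preds)
  expect_identical(attr(tab, "n_high"), 2L)
  expect_identical(attr(tab, "n_low"), 1L)
  expect_identical(tab["6", "high"], 2L)   # in every high compound
  expect_identical(tab["7", "high"], 2L)
  expect_identical(tab["5", "low"], 1L)
  expect_identical(tab["6", "low"], 0L)
  # counting identity: totals equal the summed pattern sizes per group
  expect_identical(sum(tab[, "high"]), 5L)
  expect_identical(sum(tab[, "low"]), 1L)
  expect_true(all(tab[, "high"] <= attr(tab, "n_high")))

  # all predictions below the low threshold: empty high group
  tab0 <- substituent_frequency_table(pats, rep(0.5, 4))
  expect_identical(attr(tab0, "n_high"), 0L)
  expect_true(all(tab0[, "high"] == 0L))

  # log-scale input is exponentiated before thresholding
  tabl <- substituent_frequency_table(pats, log(preds), scale = "ln_orac")
  expect_identical(tabl, tab)

  expect_error(substituent_frequency_table(pats, preds[1:2]), "one prediction")
  expect_error(substituent_frequency_table(pats, preds, high_threshold = 1,
                                           low_threshold = 2), "threshold")
})
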