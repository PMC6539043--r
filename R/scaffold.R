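#' Flavone substitution sites
#'
#' The ten aromatic C-H positions of the flavone (2-phenyl-4H-chromen-4-one)
#' template available for hydroxylation: position 3 on the pyranone C ring,
#' 5-8 on the fused A ring, and 2'-6' on the pendant B-ring phenyl.  The B
#' ring rotates freely, so patterns related by its mirror symmetry
#' (2' <-> 6', 3' <-> 5') describe the same molecule.
#'
#' @format character vector of site labels, in canonical order.
#' @export
flavone_sites <- function() c("3", "5", "6", "7", "8",
                              "2'", "3'", "4'", "5'", "6'")

MIRROR <- c("3" = "3", "5" = "5", "6" = "6", "7" = "7", "8" = "8",
            "2'" = "6'", "3'" = "5'", "4'" = "4'", "5'" = "3'", "6'" = "2'")

site_index <- function(sites) match(sites, flavone_sites())

#' Canonical form of a substitution pattern
#'
#' Returns the lexicographically smaller (by site order) of the pattern and
#' its B-ring mirror image; idempotent.  The result is sorted in canonical
#' site order.
#'
#' @param sites character vector of site labels (1 to 10 of
#'   [flavone_sites()]).
#' @return character vector, the canonical representative.
#' @examples
#' canonical_pattern(c("6'")) # "2'"
#' canonical_pattern(c("3'", "5'")) # unchanged: mirror-invariant
#' @export
canonical_pattern <- function(sites) {
  idx <- site_index(sites)
  if (anyNA(idx)) {
    stop("unknown site label(s): ",
         paste(sites[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicated sites", call. = FALSE)
  a <- sort(idx)
  b <- sort(site_index(MIRROR[sites]))
  pick <- a
  for (i in seq_along(a)) {
    if (a[i] < b[i]) break
    if (a[i] > b[i]) { pick <- b; break }
  }
  flavone_sites()[pick]
}

#' Enumerate hydroxylation patterns of flavone
#'
#' All distinct ways of placing 1 to `max_substitutions` hydroxyl groups on
#' the ten aromatic sites, de-duplicated under the B-ring mirror symmetry
#' and returned as canonical representatives in a stable lexicographic
#' order.  With the default of three substitutions this yields 115 distinct
#' structures (175 raw subsets collapsing into 115 mirror orbits).
#'
#' @param max_substitutions largest number of hydroxyls (0 to 10).
#' @return list of character vectors (patterns).
#' @examples
#' length(enumerate_patterns(3)) # 115
#' @export
enumerate_patterns <- function(max_substitutions = 3) {
  if (max_substitutions < 0 || max_substitutions > 10) {
    stop("max_substitutions must be between 0 and 10", call. = FALSE)
  }
  sites <- flavone_sites()
  out <- list()
  seen <- character(0)
  for (k in seq_len(max_substitutions)) {
    if (k > length(sites)) break
    combos <- utils::combn(sites, k, simplify = FALSE)
    for (cc in combos) {
      can <- canonical_pattern(cc)
      key <- paste(can, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- can
      }
    }
  }
  # stable order: by size, then lexicographic in site indices
  ord <- order(vapply(out, length, 0L),
               vapply(out, function(p) {
                 paste(sprintf("%02d", site_index(p)), collapse = "")
               }, ""))
  out[ord]
}

# SMILES template of 2-phenyl-4H-chromen-4-one with substituent slots.
# Core ring atoms: C4(=O), C3, C2, O1, C8a, C8, C7, C6, C5, C4a;
# B ring: C1', C2', C3', C4', C5', C6'.
pattern_to_smiles_one <- function(pattern) {
  s <- function(site) if (site %in% pattern) "(O)" else ""
  tail6 <- if ("6'" %in% pattern) "O" else ""
  paste0("O=C1C", s("3"), "=C(Oc2c", s("8"), "c", s("7"), "c", s("6"),
         "c", s("5"), "c21)c1c", s("2'"), "c", s("3'"), "c", s("4'"),
         "c", s("5'"), "c1", tail6)
}

#' SMILES of a hydroxylated flavone
#'
#' Writes the SMILES of the flavone template with hydroxyl groups at the
#' given sites.  The molecular formula is C15H10O(2+k) for k substitutions.
#'
#' @param pattern character vector of site labels (may be empty for plain
#'   flavone).
#' @return single SMILES string.
#' @examples
#' pattern_to_smiles(c("7", "8")) # 7,8-dihydroxyflavone
#' @export
pattern_to_smiles <- function(pattern) {
  if (length(pattern) > 0L) {
    idx <- site_index(pattern)
    if (anyNA(idx)) {
      stop("unknown site label(s): ",
           paste(pattern[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  }
  pattern_to_smiles_one(pattern)
}

#' Molecular formula of a hydroxylated flavone
#'
#' By substitution arithmetic on the C15H10O2 template: each hydroxyl
#' replaces an aromatic H with OH, leaving C and H counts unchanged and
#' adding one oxygen.
#'
#' @param pattern character vector of site labels.
#' @return formula string, e.g. `"C15H10O4"`.
#' @export
pattern_formula <- function(pattern) {
  sprintf("C15H10O%d", 2L + length(pattern))
}

#' Designed-compound table
#'
#' Enumerates all hydroxylation patterns up to `max_substitutions` and
#' tabulates label, canonical sites, number of hydroxyls, SMILES and
#' molecular formula.  Predicted activities can be merged in afterwards
#' (descriptors for the designs must be supplied by the user; the package
#' does not compute quantum-chemical descriptors).
#'
#' @param max_substitutions largest number of hydroxyls.
#' @return data.frame, one row per design.
#' @export
designed_compounds <- function(max_substitutions = 3) {
  patterns <- enumerate_patterns(max_substitutions)
  data.frame(
    label = vapply(patterns, function(p) paste(p, collapse = ","), ""),
    n_oh = vapply(patterns, length, 0L),
    smiles = vapply(patterns, pattern_to_smiles, ""),
    formula = vapply(patterns, pattern_formula, ""),
    stringsAsFactors = FALSE
  )
}

#' Substituent frequency table of designed compounds
#'
#' Partitions designs into a high-activity group (predicted ORAC above
#' `high_threshold`) and a low-activity group (below `low_threshold`) and
#' counts how often each site carries a hydroxyl in each group — the basis
#' for identifying favourable substitution positions.
#'
#' @param patterns list of site-label vectors.
#' @param predictions one predicted activity per pattern.
#' @param high_threshold,low_threshold group limits on the ORAC scale.
#' @param scale `"orac"` if `predictions` are ORAC values, `"ln_orac"` if
#'   they are log-scale (they are then exponentiated before thresholding).
#' @return matrix with one row per site and columns `high` and `low`;
#'   attributes `n_high`, `n_low`.
#' @export
substituent_frequency_table <- function(patterns, predictions,
                                        high_threshold = 5,
                                        low_threshold = 2,
                                        scale = c("orac", "ln_orac")) {
  scale <- match.arg(scale)
  if (length(patterns) != length(predictions)) {
    stop("one prediction per pattern required", call. = FALSE)
  }
  if (low_threshold > high_threshold) {
    stop("low_threshold must not exceed high_threshold", call. = FALSE)
  }
  if (scale == "ln_orac") predictions <- from_log_activity(predictions)
  sites <- flavone_sites()
  count_group <- function(keep) {
    tab <- table(factor(unlist(patterns[keep]), levels = sites))
    as.integer(tab)
  }
  high <- predictions > high_threshold
  low <- predictions < low_threshold
  out <- cbind(high = count_group(high), low = count_group(low))
  rownames(out) <- sites
  structure(out, n_high = sum(high), n_low = sum(low))
}
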