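#' Compound sets
#'
#' A compound set is a `data.frame` (class `compound_set`) with one row per
#' compound and the columns `name`, the four descriptors `ete1`, `pa1`,
#' `bde1`, `he` (kcal/mol), and optionally `n_oh`, `ln_orac` (natural log of
#' ORAC in mM Trolox equivalents) and `ln_orac_sd`.  A `provenance` attribute
#' records where it came from (`"bundled"`, `"user"` or `"synthetic"`).
#'
#' @param x data.frame with at least `name` and the four descriptor columns.
#' @param provenance origin tag.
#' @return `x` validated, with class `compound_set`.
#' @export
as_compound_set <- function(x, provenance = "user") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("name", DESCRIPTORS), names(x))
  if (length(missing_cols) > 0L) {
    stop("compound set is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in DESCRIPTORS) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x[[col]]))))
    if (length(bad) > 0L) {
      stop("non-numeric or missing descriptor value in column '", col,
           "', row(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
    x[[col]] <- as.numeric(x[[col]])
  }
  if (anyDuplicated(x$name)) {
    stop("compound names must be unique; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$ln_orac_sd) && any(x$ln_orac_sd < 0, na.rm = TRUE)) {
    stop("ln_orac_sd must be non-negative", call. = FALSE)
  }
  class(x) <- unique(c("compound_set", class(x)))
  attr(x, "provenance") <- provenance
  x
}

#' Bundled flavonoid ORAC data set
#'
#' The 36 flavonoids with measured ln(ORAC) (mM Trolox equivalents, natural
#' log scale) and the four quantum-mechanical descriptors of the first
#' oxidation step: electron transfer enthalpy `ete1`, proton affinity `pa1`,
#' minimum O-H bond dissociation enthalpy `bde1`, and hydration energy `he`
#' (all kcal/mol).
#'
#' @return A [as_compound_set()] data.frame with 36 rows and provenance
#'   `"bundled"`.
#' @examples
#' flav <- load_bundled_dataset()
#' head(flav)
#' @export
load_bundled_dataset <- function() {
  path <- system.file("extdata", "flavonoid_orac_table.csv",
                      package = "flavqsar")
  if (!nzchar(path)) stop("bundled data file not found; corrupt installation")
  cs <- read_compounds_csv(path)
  if (nrow(cs) != 36L) {
    stop("bundled data corrupt: expected 36 rows, found ", nrow(cs))
  }
  if (any(!is.finite(descriptor_matrix(cs)))) {
    stop("bundled data corrupt: missing descriptor values")
  }
  if (any(cs$he > 0) || any(cs$n_oh < 1)) {
    stop("bundled data corrupt: he must be <= 0 and n_oh >= 1; first bad row ",
         which(cs$he > 0 | cs$n_oh < 1)[1])
  }
  attr(cs, "provenance") <- "bundled"
  cs
}

#' Descriptor matrix of a compound set
#'
#' Returns the numeric descriptor matrix in the canonical column order
#' (`ete1`, `pa1`, `bde1`, `he`) with compound names as row names.
#'
#' @param cs a compound set.
#' @return numeric matrix, one row per compound.
#' @export
descriptor_matrix <- function(cs) {
  X <- as.matrix(as.data.frame(cs)[, DESCRIPTORS])
  rownames(X) <- cs$name
  X
}

#' Read and write compound CSV tables
#'
#' The CSV format is RFC-4180 with a header row containing `name`, the four
#' descriptor columns `ete1`, `pa1`, `bde1`, `he`, and optionally `n_oh`,
#' `ln_orac`, `ln_orac_sd`.  Writing then reading reproduces all numeric
#' fields to full precision.
#'
#' @param path file path.
#' @param provenance origin tag attached to the returned set.
#' @return `read_compounds_csv` returns a compound set;
#'   `write_compounds_csv` invisibly returns `path`.
#' @export
read_compounds_csv <- function(path, provenance = "user") {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_compound_set(df, provenance = provenance)
}

#' @param cs compound set to write.
#' @rdname read_compounds_csv
#' @export
write_compounds_csv <- function(cs, path) {
  stopifnot(inherits(cs, "compound_set"))
  write.csv(as.data.frame(cs), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Activity transforms
#'
#' ORAC values (mM Trolox equivalents) are modelled on the natural log scale
#' to reduce skewness.  `to_log_activity` and `from_log_activity` are mutual
#' inverses.
#'
#' @param orac ORAC values, strictly positive.
#' @param ln_orac log-scale activities.
#' @return transformed numeric vector.
#' @examples
#' from_log_activity(-1.581) # 0.206, the smallest ORAC in the bundled set
#' @export
to_log_activity <- function(orac) {
  if (any(orac <= 0, na.rm = TRUE)) {
    stop("ORAC values must be strictly positive", call. = FALSE)
  }
  log(orac)
}

#' @rdname to_log_activity
#' @export
from_log_activity <- function(ln_orac) exp(ln_orac)

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("Compound set: %d compounds (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
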