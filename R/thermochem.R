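SPECIES_ROLES <- c("roh", "ro_radical", "ro_anion", "roh_radical_cation",
                   "po_radical", "poh", "poh_radical_cation", "po_anion")

#' Proton, electron and hydrogen-atom enthalpy constants
#'
#' Reference enthalpies (kcal/mol) used to assemble the mechanism
#' descriptors.  Gas phase: H(H+) = 1.481 and H(e-) = 0.752 (translational
#' enthalpy conventions); aqueous phase (relative permittivity 78.4, solvated
#' by attachment to one water molecule): H(H+) = -250.574 and
#' H(e-) = -17.816.  The hydrogen-atom enthalpy in water, -307.208, is fixed
#' by the identity `PA + ETE - BDE = H(H+) + H(e-) - H(H.)` together with
#' the constant value 38.818 kcal/mol that this combination takes across the
#' bundled descriptor table; the gas-phase value -312.274 is the electronic
#' (-0.5 hartree) plus thermal (5/2 RT) enthalpy of the hydrogen atom.
#'
#' @param phase `"gas"` or `"water"`.
#' @return list of class `thermo_constants` with `phase`, `H_proton`,
#'   `H_electron`, `H_hydrogen_atom`, `relative_permittivity`.
#' @export
thermo_constants <- function(phase = c("gas", "water")) {
  phase <- match.arg(phase)
  out <- if (phase == "gas") {
    list(phase = "gas", H_proton = 1.481, H_electron = 0.752,
         H_hydrogen_atom = -312.274, relative_permittivity = 1)
  } else {
    list(phase = "water", H_proton = -250.574, H_electron = -17.816,
         H_hydrogen_atom = -250.574 - 17.816 - 38.818,
         relative_permittivity = 78.4)
  }
  structure(out, class = "thermo_constants")
}

#' Species enthalpy sets
#'
#' Per-compound standard enthalpies (H298, kcal/mol) of the species involved
#' in the antioxidant mechanisms, by phase.  Roles for the flavonoid (ROH)
#' side: `roh`, `ro_radical`, `ro_anion`, `roh_radical_cation`; for the
#' peroxyl (PO.) side: `po_radical`, `poh`, `poh_radical_cation`,
#' `po_anion`.  Each phase is a named numeric vector over (a subset of)
#' these roles.
#'
#' @param compound compound label.
#' @param gas,water named numeric vectors of H298 by role.
#' @return list of class `species_enthalpy_set`.
#' @export
species_enthalpy_set <- function(compound, gas = NULL, water = NULL) {
  check_roles <- function(v, phase) {
    if (is.null(v)) return(NULL)
    bad <- setdiff(names(v), SPECIES_ROLES)
    if (length(bad) > 0L) {
      stop("unknown species role(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(v))) stop("non-finite enthalpy in ", phase, call. = FALSE)
    v
  }
  structure(list(compound = compound, gas = check_roles(gas, "gas"),
                 water = check_roles(water, "water")),
            class = "species_enthalpy_set")
}

species_get <- function(set, phase, roles) {
  v <- set[[phase]]
  missing_roles <- setdiff(roles, names(v))
  if (length(missing_roles) > 0L) {
    stop("species set '", set$compound, "' (", phase, ") is missing: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  v[roles]
}

#' Mechanism descriptor enthalpies
#'
#' Enthalpy differences (kcal/mol) defining the QSAR descriptors:
#' \describe{
#'   \item{BDE}{`H(RO.) + H(H.) - H(ROH)` — homolytic O-H cleavage (HAT)}
#'   \item{PA}{`H(RO-) + H(H+) - H(ROH)` — deprotonation (SPLET step 1)}
#'   \item{ETE}{`H(RO.) + H(e-) - H(RO-)` — electron transfer (SPLET step 2)}
#'   \item{IP}{`H(ROH+.) + H(e-) - H(ROH)` — ionisation (SETPL step 1)}
#'   \item{PDE}{`H(RO.) + H(H+) - H(ROH+.)` — proton loss (SETPL step 2)}
#'   \item{HE}{`H298(aqueous ROH) - H298(gas ROH)` — hydration energy}
#' }
#' For any species set, `PA + ETE - BDE = H(H+) + H(e-) - H(H.)` by
#' algebraic cancellation.
#'
#' @param species a [species_enthalpy_set()].
#' @param constants a [thermo_constants()]; its phase selects the enthalpies.
#' @param which descriptors to compute (HE requires both phases).
#' @return named numeric vector.
#' @export
descriptor_enthalpies <- function(species, constants = thermo_constants("water"),
                                  which = c("BDE", "PA", "ETE", "IP", "PDE",
                                            "HE")) {
  which <- match.arg(which, several.ok = TRUE)
  ph <- constants$phase
  g <- function(role) unname(species_get(species, ph, role))
  out <- numeric(0)
  for (d in which) {
    out[d] <- switch(d,
      BDE = g("ro_radical") + constants$H_hydrogen_atom - g("roh"),
      PA = g("ro_anion") + constants$H_proton - g("roh"),
      ETE = g("ro_radical") + constants$H_electron - g("ro_anion"),
      IP = g("roh_radical_cation") + constants$H_electron - g("roh"),
      PDE = g("ro_radical") + constants$H_proton - g("roh_radical_cation"),
      HE = unname(species_get(species, "water", "roh") -
                    species_get(species, "gas", "roh"))
    )
  }
  out
}

#' Mechanism pathway enthalpies
#'
#' Step and overall reaction enthalpies of the three anti-peroxyl-radical
#' pathways of a flavonoid ROH with a peroxyl radical PO.:
#' \describe{
#'   \item{HAT}{`ROH -> RO. + H.` then `PO. + H. -> POH`}
#'   \item{SPLET}{`ROH + PO. -> RO- + POH+.` then `RO- + POH+. -> RO. + POH`}
#'   \item{SETPL}{`ROH + PO. -> ROH+. + PO-` then `ROH+. + PO- -> RO. + POH`}
#' }
#' All three telescope to the same overall reaction
#' `ROH + PO. -> RO. + POH`, so the overall enthalpy is mechanism-
#' independent and the steps sum to it exactly.
#'
#' @param flavonoid [species_enthalpy_set()] with the ROH-side species.
#' @param peroxyl [species_enthalpy_set()] with the PO.-side species.
#' @param mechanism `"HAT"`, `"SPLET"` or `"SETPL"`.
#' @param phase `"gas"` or `"water"`.
#' @param constants optional [thermo_constants()] (needed for the HAT
#'   hydrogen-atom enthalpy); defaults to the constants of `phase`.
#' @return list of class `pathway_result`: `mechanism`, `phase`, `compound`,
#'   `steps` (named numeric), `overall`.
#' @export
pathway_enthalpies <- function(flavonoid, peroxyl,
                               mechanism = c("HAT", "SPLET", "SETPL"),
                               phase = c("gas", "water"),
                               constants = NULL) {
  mechanism <- match.arg(mechanism)
  phase <- match.arg(phase)
  if (is.null(constants)) constants <- thermo_constants(phase)
  f <- function(role) unname(species_get(flavonoid, phase, role))
  p <- function(role) unname(species_get(peroxyl, phase, role))
  steps <- switch(mechanism,
    HAT = c(
      "ROH -> RO. + H." =
        f("ro_radical") + constants$H_hydrogen_atom - f("roh"),
      "PO. + H. -> POH" =
        p("poh") - p("po_radical") - constants$H_hydrogen_atom),
    SPLET = c(
      "ROH + PO. -> RO- + POH+." =
        f("ro_anion") + p("poh_radical_cation") - f("roh") - p("po_radical"),
      "RO- + POH+. -> RO. + POH" =
        f("ro_radical") + p("poh") - f("ro_anion") - p("poh_radical_cation")),
    SETPL = c(
      "ROH + PO. -> ROH+. + PO-" =
        f("roh_radical_cation") + p("po_anion") - f("roh") - p("po_radical"),
      "ROH+. + PO- -> RO. + POH" =
        f("ro_radical") + p("poh") - f("roh_radical_cation") - p("po_anion"))
  )
  structure(list(mechanism = mechanism, phase = phase,
                 compound = flavonoid$compound, steps = steps,
                 overall = sum(steps)),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("%s pathway, %s (%s phase):\n", x$mechanism, x$compound,
              x$phase))
  for (i in seq_along(x$steps)) {
    cat(sprintf("  %-28s %8.1f kcal/mol\n", names(x$steps)[i], x$steps[i]))
  }
  cat(sprintf("  %-28s %8.1f kcal/mol\n", "overall", x$overall))
  invisible(x)
}

#' Hess-cycle closure check
#'
#' Verifies that a list of step enthalpies sums to the stated overall
#' enthalpy within a tolerance — used to validate externally supplied step
#' tables against their overall row (printed tables carry one-decimal
#' rounding, hence the default 0.15 kcal/mol).
#'
#' @param steps numeric vector of step enthalpies.
#' @param overall stated overall enthalpy.
#' @param tolerance maximum allowed deviation, kcal/mol.
#' @return list with `pass` and `deviation`.
#' @export
hess_closure_check <- function(steps, overall, tolerance = 0.15) {
  dev <- abs(sum(steps) - overall)
  list(pass = dev <= tolerance, deviation = dev)
}

#' Rate-determining-step comparison of pathways
#'
#' Ranks pathways of one compound in one phase by their rate-determining
#' (maximum) step enthalpy, ascending — the thermodynamically most
#' accessible mechanism first.  Ties are broken alphabetically by mechanism
#' name.
#'
#' @param pathways list of [pathway_enthalpies()] results, same compound and
#'   phase.
#' @return data.frame: `mechanism`, `rate_determining_step`, `overall`,
#'   ranked ascending.
#' @export
mechanism_comparison <- function(pathways) {
  if (length(pathways) == 0L) stop("no pathways supplied", call. = FALSE)
  phases <- unique(vapply(pathways, `[[`, "", "phase"))
  if (length(phases) > 1L) {
    stop("cannot compare pathways across phases: ",
         paste(phases, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(
    mechanism = vapply(pathways, `[[`, "", "mechanism"),
    rate_determining_step = vapply(pathways, function(p) max(p$steps), 0),
    overall = vapply(pathways, `[[`, 0, "overall")
  )
  tab[order(tab$rate_determining_step, tab$mechanism), , drop = FALSE]
}

#' Bundled pathway enthalpy table
#'
#' Step and overall reaction enthalpies (kcal/mol) of the HAT, SPLET and
#' SETPL pathways for genistein and quercetin with the AAPH-derived peroxyl
#' radical, in the gas phase and in water, as used throughout the package's
#' thermochemistry examples.
#'
#' @return data.frame with columns `compound`, `phase`, `mechanism`, `step`,
#'   `reaction`, `dh298`.
#' @export
load_pathway_table <- function() {
  path <- system.file("extdata", "aaph_pathways.csv", package = "flavqsar")
  if (!nzchar(path)) stop("bundled pathway table not found")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic species enthalpies consistent with a pathway table
#'
#' Constructs a synthetic [species_enthalpy_set()] pair (flavonoid and
#' peroxyl) whose pathway enthalpies reproduce a step table such as
#' [load_pathway_table()].  Absolute enthalpies are not recoverable from
#' step differences, so anchors are chosen arbitrarily (`H(ROH)` from the
#' supplied value, `H(PO.) = 0`, `H(POH+.) = 0`, `H(PO-) = 0`); every first
#' step and the overall reaction are reproduced exactly, and second steps to
#' within the table's own rounding.
#'
#' @param table a pathway table as from [load_pathway_table()].
#' @param compound compound label present in the table.
#' @param phase `"gas"` or `"water"`.
#' @param h_roh anchor enthalpy of the parent compound.
#' @return list with `flavonoid` and `peroxyl` species sets.
#' @export
species_from_pathway_table <- function(table, compound,
                                       phase = c("gas", "water"),
                                       h_roh = 0) {
  phase <- match.arg(phase)
  constants <- thermo_constants(phase)
  sub <- table[table$compound == compound & table$phase == phase, ]
  if (nrow(sub) == 0L) {
    stop("no rows for ", compound, " in ", phase, call. = FALSE)
  }
  step <- function(mech, s) {
    v <- sub$dh298[sub$mechanism == mech & sub$step == s]
    if (length(v) != 1L) stop("missing ", mech, " step ", s, call. = FALSE)
    v
  }
  hH <- constants$H_hydrogen_atom
  ro_rad <- step("HAT", 1) + h_roh - hH
  poh <- step("HAT", 2) + hH                     # with H(PO.) = 0
  ro_an <- step("SPLET", 1) + h_roh              # with H(POH+.) = 0
  roh_rc <- step("SETPL", 1) + h_roh             # with H(PO-) = 0
  flav <- setNames(c(h_roh, ro_rad, ro_an, roh_rc),
                   c("roh", "ro_radical", "ro_anion", "roh_radical_cation"))
  perox <- setNames(c(0, poh, 0, 0),
                    c("po_radical", "poh", "poh_radical_cation", "po_anion"))
  args <- list(compound = paste0(compound, " (synthetic anchors)"))
  args[[phase]] <- flav
  flavonoid <- do.call(species_enthalpy_set, args)
  args[[phase]] <- perox
  args$compound <- "AAPH peroxyl (synthetic anchors)"
  peroxyl <- do.call(species_enthalpy_set, args)
  list(flavonoid = flavonoid, peroxyl = peroxyl)
}
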