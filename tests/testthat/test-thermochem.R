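test_that("thermochemical constants carry the reference enthalpies", {
  gas <- thermo_constants("gas")
  expect_equal(gas$H_proton, 1.481)
  expect_equal(gas$H_electron, 0.752)
  water <- thermo_constants("water")
  expect_equal(water$H_proton, -250.574)
  expect_equal(water$H_electron, -17.816)
  expect_equal(water$relative_permittivity, 78.4)
  # the water hydrogen-atom enthalpy encodes the 38.818 identity constant
  expect_equal(water$H_proton + water$H_electron - water$H_hydrogen_atom,
               38.818)
})

test_that("descriptor enthalpies are the defining differences", {
  sp <- species_enthalpy_set("toy",
                            gas = c(roh = -100.0, ro_radical = -20.0,
                                    ro_anion = -90.0,
                                    roh_radical_cation = -10.0),
                            water = c(roh = -117.5))
  cst <- thermo_constants("gas")
  cst$H_hydrogen_atom <- 0.5  # direct-arithmetic example
  d <- descriptor_enthalpies(sp, cst)
  expect_equal(unname(d["BDE"]), -20 + 0.5 - (-100))  # 80.5
  expect_equal(unname(d["PA"]), -90 + 1.481 + 100)
  expect_equal(unname(d["ETE"]), -20 + 0.752 + 90)
  expect_equal(unname(d["IP"]), -10 + 0.752 + 100)
  expect_equal(unname(d["PDE"]), -20 + 1.481 + 10)
  expect_equal(unname(d["HE"]), -17.5)
  expect_error(descriptor_enthalpies(
    species_enthalpy_set("x", gas = c(roh = 0)), cst, which = "BDE"),
    "ro_radical")
})

test_that("PA + ETE - BDE reduces to the constants for any species set", {
  for (s in 1:10) {
    set.seed(500 + s)
    v <- rnorm(4, -100, 50)
    sp <- species_enthalpy_set("rand",
                               water = c(roh = v[1], ro_radical = v[2],
                                         ro_anion = v[3],
                                         roh_radical_cation = v[4]))
    cst <- thermo_constants("water")
    d <- descriptor_enthalpies(sp, cst, which = c("BDE", "PA", "ETE"))
    expect_equal(unname(d["PA"] + d["ETE"] - d["BDE"]),
                 cst$H_proton + cst$H_electron - cst$H_hydrogen_atom)
  }
  # and the bundled descriptor table obeys the same identity (38.818)
  flav <- load_bundled_dataset()
  expect_true(all(abs(flav$pa1 + flav$ete1 - flav$bde1 - 38.818) <= 0.002))
})

test_that("pathway enthalpies reproduce the bundled step table", {
  tab <- load_pathway_table()
  gg <- species_from_pathway_table(tab, "genistein", "gas")
  hat <- pathway_enthalpies(gg$flavonoid, gg$peroxyl, "HAT", "gas")
  expect_equal(unname(hat$steps), c(83.8, -78.2))
  expect_equal(hat$overall, 5.6)

  qw <- species_from_pathway_table(tab, "quercetin", "water")
  splet <- pathway_enthalpies(qw$flavonoid, qw$peroxyl, "SPLET", "water")
  expect_equal(unname(splet$steps), c(31.9, -37.5))
  expect_equal(splet$overall, -5.6)

  # steps always telescope exactly, and the overall enthalpy is
  # mechanism-independent for a fixed species set
  for (mech in c("HAT", "SPLET", "SETPL")) {
    p <- pathway_enthalpies(qw$flavonoid, qw$peroxyl, mech, "water")
    expect_equal(sum(p$steps), p$overall)
    expect_equal(p$overall, splet$overall)
  }
  expect_error(pathway_enthalpies(qw$flavonoid, qw$peroxyl, "HAT", "gas"),
               "missing")
})

test_that("Hess closure holds for all printed step pairs within rounding", {
  # direct example: genistein gas SETPL, 144.6 - 138.9 vs 5.6
  chk <- hess_closure_check(c(144.6, -138.9), 5.6, tolerance = 0.15)
  expect_true(chk$pass)
  expect_equal(chk$deviation, 0.1)
  expect_identical(hess_closure_check(c(1, -1), 0)$deviation, 0)

  tab <- load_pathway_table()
  for (comp in c("genistein", "quercetin")) {
    for (ph in c("gas", "water")) {
      overall <- tab$dh298[tab$compound == comp & tab$phase == ph &
                             tab$mechanism == "overall"]
      for (mech in c("HAT", "SPLET", "SETPL")) {
        steps <- tab$dh298[tab$compound == comp & tab$phase == ph &
                             tab$mechanism == mech]
        expect_length(steps, 2)
        expect_true(hess_closure_check(steps, overall, 0.15)$pass)
      }
    }
  }
})

test_that("solvation shifts the SPLET first step by about -100 kcal/mol", {
  tab <- load_pathway_table()
  s1 <- function(ph) tab$dh298[tab$compound == "genistein" &
                                 tab$phase == ph &
                                 tab$mechanism == "SPLET" & tab$step == 1]
  expect_equal(s1("water") - s1("gas"), -101.3)
})

test_that("mechanism comparison ranks by rate-determining step", {
  tab <- load_pathway_table()
  gw <- species_from_pathway_table(tab, "genistein", "water")
  paths <- lapply(c("HAT", "SPLET", "SETPL"), function(m) {
    pathway_enthalpies(gw$flavonoid, gw$peroxyl, m, "water")
  })
  cmp <- mechanism_comparison(paths)
  expect_identical(cmp$mechanism[3], "HAT")  # least favourable
  expect_true(all(cmp$mechanism[1:2] %in% c("SPLET", "SETPL")))
  expect_true(all(diff(cmp$rate_determining_step) >= 0))

  single <- mechanism_comparison(paths[2])
  expect_identical(nrow(single), 1L)
  expect_identical(single$mechanism, "SPLET")

  gg <- species_from_pathway_table(tab, "genistein", "gas")
  pg <- pathway_enthalpies(gg$flavonoid, gg$peroxyl, "HAT", "gas")
  expect_error(mechanism_comparison(list(paths[[1]], pg)), "phases")
})
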