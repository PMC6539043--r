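Package: flavqsar
Title: Linear and Neural-Network QSAR Models of Flavonoid Antioxidant
    Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-activity relationship (QSAR) modelling
    of the oxygen radical absorbance capacity (ORAC) of flavonoids from
    four quantum-mechanical descriptors of the hydrogen atom transfer and
    sequential proton-loss electron transfer mechanisms (minimum bond
    dissociation enthalpy, proton affinity, electron transfer enthalpy,
    and hydration energy).  Provides a SIMPLS partial least squares model
    with leave-one-out cross-validation and Kennard-Stone data splitting,
    a Levenberg-Marquardt trained single-hidden-layer perceptron with a
    repeated-resampling protocol, partial-derivative (PaD) sensitivity
    analysis, leverage-based applicability domains (Williams plots),
    antioxidant mechanism thermochemistry bookkeeping (HAT, SPLET, SETPL
    pathways), combinatorial enumeration of hydroxylated flavones, and a
    synthetic-data generator with known ground truth.  The 36-compound
    ORAC data set with its descriptors is bundled.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
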