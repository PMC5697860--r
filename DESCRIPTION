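Package: lipidfrags
Title: Mass-Balanced Enumeration and Shorthand Nomenclature of Lipid Fragment Ions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates collision-induced dissociation (CID) fragments of intact
    lipid ions as mass-balanced chemical reactions and annotates tandem (MS2) and
    multi-stage (MS3) mass spectra with a systematic shorthand nomenclature for
    charged and neutral lipid fragments. Covers the four fragment types used in
    shotgun and LC-MS lipidomics (lipid class-selective fragments, molecular
    lipid species-specific fragments, intermediate multi-chain fragments and
    double bond location-specific fragments), a parser and serializer for intact
    lipid shorthand names at the species, molecular species and sn-defined
    annotation levels, stable isotope-labeled lipids, a decision tree that
    prioritizes one annotation per m/z value, a queryable fragment database over
    configurable chain-enumeration ranges, and a synthetic spectrum generator for
    validation. Fragmentation rules and lipid class templates are packaged as
    user-extensible tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
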