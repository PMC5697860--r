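# Elemental-composition arithmetic, formula grammar, masses and m/z.

test_that("formula parsing matches printed multiplicities", {
  expect_equal(unclass(parse_formula("C5H15NO4P")),
               c(C = 5L, H = 15L, N = 1L, O = 4L, P = 1L),
               ignore_attr = TRUE)
  expect_length(parse_formula(""), 0)
  d <- parse_formula("+C11H20N2O9P2S")
  expect_equal(as.integer(d[c("C", "H", "N", "O", "P", "S")]),
               c(11L, 20L, 2L, 9L, 2L, 1L))
  neg <- parse_formula("-H2O")
  expect_equal(as.integer(neg[c("H", "O")]), c(-2L, -1L))
  expect_error(parse_formula("C5Xx3"), "unknown element")
  expect_error(parse_formula("C5)2"), "malformed")
})

test_that("monoisotopic masses reproduce printed neutral losses", {
  expect_equal(round(monoisotopic_mass(parse_formula("NH3")), 4), 17.0265)
  expect_equal(round(monoisotopic_mass(parse_formula("C2H4O2")), 4), 60.0211)
  expect_equal(round(monoisotopic_mass(parse_formula("C2H8NO4P")), 4), 141.0191)
  expect_identical(monoisotopic_mass(comp()), 0)
})

test_that("nominal masses match LCF labels", {
  expect_identical(nominal_mass(parse_formula("NH3")), 17L)
  expect_identical(nominal_mass(parse_formula("C5H15NO4P")), 184L)
  expect_identical(nominal_mass(parse_formula("C3H5NO2")), 87L)
  # heavy nuclides count their mass number
  expect_identical(nominal_mass(apply_label(parse_formula("C5H15NO4P"),
                                            parse_label("[2]H13"))), 197L)
})

test_that("m/z includes electron correction for both polarities", {
  expect_equal(round(ion_mz(parse_formula("C5H15NO4P"), 1), 4), 184.0733)
  # acetate adduct of PC 18:3-18:3
  ion <- comp_add(parse_formula("C44H76NO8P"), parse_formula("C2H3O2"))
  expect_equal(round(ion_mz(ion, -1), 4), 836.5447)
  # electron bookkeeping: +1 vs -1 of the same atoms differ by 2 electrons
  x <- parse_formula("C10H20O2")
  m <- monoisotopic_mass(x)
  me <- lipidfrags:::.ELECTRON_MASS
  expect_equal(ion_mz(x, 1), m - me)
  expect_equal(ion_mz(x, -1), m + me)
  expect_equal(ion_mz(x, -1) - ion_mz(x, 1), 2 * me)
  # doubly charged: direct brute-force formula
  expect_equal(ion_mz(x, -2), (m + 2 * me) / 2)
  expect_error(ion_mz(x, 0), "non-zero")
})

test_that("mass is linear in composition", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_composition()
    b <- random_composition()
    expect_equal(monoisotopic_mass(comp_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-12)
    expect_identical(nominal_mass(comp_add(a, b)),
                     nominal_mass(a) + nominal_mass(b))
  }
})

test_that("parse and format are inverse on canonical strings", {
  set.seed(7)
  for (i in 1:25) {
    x <- random_composition()
    expect_length(comp_diff(parse_formula(format_formula(x)), x), 0)
  }
  # canonical ordering conventions: Hill, metals last, heavy inline
  expect_identical(format_formula(comp(O = 1, Na = 1, H = 1)), "HONa")
  expect_identical(format_formula(parse_formula("O2NaC3H6")), "C3H6O2Na")
  expect_identical(format_formula(apply_label(parse_formula("C2H6O"),
                                              parse_label("[2]H3"))),
                   "C2H3[2]H3O")
})

test_that("nominal and monoisotopic mass stay within the sanity bound", {
  set.seed(11)
  for (i in 1:25) {
    x <- random_composition()
    n_atoms <- sum(abs(as.integer(x)))
    expect_lt(abs(monoisotopic_mass(x) - nominal_mass(x)),
              0.5 * max(n_atoms / 10, 1))
  }
})

test_that("isotope labels shift mass by exact nuclide differences", {
  pc <- intact_composition(parse_lipid("PC 16:1-18:1"))
  shift <- monoisotopic_mass(apply_label(pc, parse_label("[2]H13"))) -
    monoisotopic_mass(pc)
  expect_equal(round(shift, 4), 13.0816)
  cer <- intact_composition(parse_lipid("Cer 18:0;3/26:0;1"))
  shift2 <- monoisotopic_mass(apply_label(cer, parse_label("[13]C2[15]N"))) -
    monoisotopic_mass(cer)
  expect_equal(round(shift2, 4), 3.0037)
  expect_identical(apply_label(pc, parse_label("")), pc)
  expect_error(apply_label(parse_formula("C2H4"), parse_label("[2]H80")),
               "over-substitution")
})

test_that("signed deltas render with per-sign groups", {
  expect_identical(format_formula(parse_delta("+O -C7H15"), delta = TRUE),
                   "+O -C7H15")
  expect_identical(format_formula(comp(H = -1), delta = TRUE), "-H")
  expect_identical(format_formula(comp(H = 1, O = 1, Na = 1), delta = TRUE),
                   "+HONa")
})
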