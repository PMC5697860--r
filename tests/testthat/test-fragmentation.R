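# Fragment enumeration: balance, cardinalities, dedup, MS3 chaining,
# rule validation.

test_that("PC acetate enumeration contains the combined-loss reaction", {
  rxs <- enumerate_fragments(precursor_ion("PC 18:3-18:3", "+CH3COO"))
  tab <- fragment_table(rxs)
  i <- which(abs(tab$mz - 502.2940) < 0.001)
  expect_length(i, 1)
  neutrals <- vapply(rxs[[i]]$neutrals, function(p)
    format_formula(p$comp), character(1))
  expect_setequal(neutrals, c("C3H6O2", "C18H28O"))  # methyl acetate + ketene
})

test_that("MLF counts match the curated rule-set cardinalities", {
  n_mlf <- function(name, adduct)
    sum(fragment_table(enumerate_fragments(precursor_ion(name, adduct)))$mlf)
  expect_identical(n_mlf("PS 20:4-22:6", "-H"), 8L)
  expect_identical(n_mlf("TAG 16:0-18:0-18:2", "+NH4"), 12L)
  # two identical chains collapse by deduplication
  expect_identical(n_mlf("TAG 16:0-18:1-18:1", "+NH4"), 8L)
  # dedup ordering property: |A-A-B| < |A-B-C|
  expect_lt(n_mlf("TAG 16:0-16:0-18:1", "+NH4"),
            n_mlf("TAG 14:0-16:0-18:1", "+NH4"))
})

test_that("deduplicated reactions keep the union of chain-slot evidence", {
  rxs <- enumerate_fragments(precursor_ion("TAG 16:0-18:1-18:1", "+NH4"))
  tab <- fragment_table(rxs)
  acyl181 <- rxs[[which(tab$rule == "tag_nh4_acylium" & grepl("18:1", tab$name))]]
  expect_identical(acyl181$mlf_slots, c(2L, 3L))
})

test_that("every enumerated reaction is atom- and mass-balanced", {
  cases <- list(c("PC 18:3-18:3", "+CH3COO"), c("TAG 16:0-18:0-18:2", "+NH4"),
                c("PS 20:4-22:6", "-H"), c("PE O-18:1p/20:4", "+H"),
                c("CL 14:1-14:1-14:1-15:1", "-2H"), c("SM 18:1;2/17:0", "+H"),
                c("Cer 18:1;2/17:0", "-H"), c("SE 27:1/19:0", "+NH4"),
                c("ACar 18:2", "+H"), c("ACoA 19:0", "-H"),
                c("DAG 18:0-20:0", "+Na"), c("PI 16:0-18:1", "-H"),
                c("PC(+[2]H13) 16:1-18:1", "+H"),
                c("Cer 18:0;3(+[13]C2[15]N)/26:0;1", "+HCOO"))
  for (cs in cases) {
    prec <- precursor_ion(cs[1], cs[2])
    rxs <- enumerate_fragments(prec)
    expect_gt(length(rxs), 0)
    for (rx in rxs) {
      total <- Reduce(comp_add, lapply(rx$neutrals, `[[`, "comp"),
                      rx$charged$comp)
      expect_length(comp_diff(total, prec$comp), 0)  # exact atom balance
      expect_lt(abs(monoisotopic_mass(total) - monoisotopic_mass(prec$comp)),
                1e-9)
    }
  }
})

test_that("heavy nuclides are conserved across every labeled reaction", {
  for (cs in list(c("PC(+[2]H13) 16:1-18:1", "+H"),
                  c("PC 16:0(+[2]H3)-16:0(+[2]H3)", "+H"),
                  c("PI(+[2]H6) 16:0-18:1", "-H"),
                  c("Cer 18:0;3(+[13]C2[15]N)/26:0;1", "+HCOO"))) {
    prec <- precursor_ion(cs[1], cs[2])
    heavy_in <- sum(as.integer(prec$comp[lipidfrags:::.is_heavy(names(prec$comp))]))
    for (rx in enumerate_fragments(prec)) {
      total <- Reduce(comp_add, lapply(rx$neutrals, `[[`, "comp"),
                      rx$charged$comp)
      heavy_out <- sum(as.integer(total[lipidfrags:::.is_heavy(names(total))]))
      expect_identical(heavy_out, heavy_in, info = rx$rule_id)
    }
  }
})

test_that("MS3 of a TAG neutral-loss fragment reveals the remaining acyls", {
  t1 <- enumerate_fragments(precursor_ion("TAG 16:0-18:0-18:2", "+NH4"))
  ft <- fragment_table(t1)
  parent <- t1[[which(ft$rule == "tag_nh4_nl_fa" &
                        grepl("FA 18:0(+HO)", ft$name, fixed = TRUE))]]
  expect_equal(round(parent$charged$mz, 1), 575.5)
  ms3 <- fragment_table(enumerate_ms3(parent))
  expect_true(any(ms3$name == "FA 16:0"))
  expect_true(any(ms3$name == "FA 18:2"))
  expect_true(any(ms3$name == "FA 18:2(-HO)"))
  expect_false(any(grepl("18:0", ms3$name)))  # that chain left at MS2
  expect_true(all(ms3$ms_level == 3L))
  # no applicable MS3 rule: empty list
  lcf <- t1[[which(ft$rule == "tag_nh4_nl17")]]
  expect_length(enumerate_ms3(lcf), 0)
})

test_that("MS3 composed losses equal a directly written two-step loss", {
  t1 <- enumerate_fragments(precursor_ion("TAG 16:0-18:0-18:2", "+NH4"))
  ft <- fragment_table(t1)
  parent <- t1[[which(ft$rule == "tag_nh4_nl_fa" &
                        grepl("FA 18:0(+HO)", ft$name, fixed = TRUE))]]
  ms3 <- enumerate_ms3(parent)
  ft3 <- fragment_table(ms3)
  acyl16 <- ms3[[which(ft3$name == "FA 16:0")]]
  # oracle: composition arithmetic straight from the precursor ion
  prec <- precursor_ion("TAG 16:0-18:0-18:2", "+NH4")
  direct <- Reduce(comp_diff, list(parse_formula("NH3"),
                                   parse_formula("C18H36O2"),  # FA 18:0
                                   hca_composition(list(carbons = 16L, db = 0L,
                                                        oh = 0L, hca = "FA",
                                                        label = NULL))),
                   prec$comp)
  rem3 <- acyl16$neutrals[[1]]$comp
  expect_length(comp_diff(rem3, direct), 0)
})

test_that("double-bond-specific MS3 names the cleavage position", {
  pc <- enumerate_fragments(precursor_ion("PC 16:0-18:1(9)", "+CH3COO"))
  ft <- fragment_table(pc)
  parent <- pc[[which(ft$rule == "pc_neg_carbox" & grepl("18:1", ft$name))]]
  dbf <- fragment_table(enumerate_ms3(parent))
  expect_identical(dbf$name, "FA 18:1(9)(+O -C7H15)")
  expect_identical(dbf$type, "DBF")
  expect_equal(round(dbf$mz, 2), 182.13)
})

test_that("the packaged rule table validates cleanly and bad rules are flagged", {
  report <- validate_rules()
  expect_identical(nrow(report), 0L)
  # constructed negative case: an explicit neutral overcounts H2O, so the
  # remainder goes negative on a probe lipid
  bad <- fragmentation_rules()
  bad <- bad[bad$id == "pe_neg_nl_fa", , drop = FALSE]
  bad$id <- "bad_h2o_overcount"
  bad$neutrals <- "hca:FA:+H100O"
  report2 <- validate_rules(bad)
  expect_gt(nrow(report2), 0)
  expect_match(report2$problem[1], "negative|balance")
})

test_that("unknown class/adduct combinations warn and return empty", {
  expect_warning(rxs <- enumerate_fragments(precursor_ion("ACoA 19:0", "+H")),
                 "no fragmentation rules")
  expect_length(rxs, 0)
})
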