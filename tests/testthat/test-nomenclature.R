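# Fragment shorthand: byte-exact printed names, prioritization decision
# tree, dual rendering, name -> composition round trips.

frag_names <- function(name, adduct) {
  fragment_table(enumerate_fragments(precursor_ion(name, adduct)))
}

test_that("printed fragment names are reproduced byte-exactly", {
  pc <- frag_names("PC 18:3-18:3", "+CH3COO")
  expect_true("-FA 18:3(-H) -PC(74)" %in% pc$name)
  expect_true("-PC(74)" %in% pc$name)
  expect_true("FA 18:3(+C7H16NO6P)" %in% sub(".*\\| ", "", pc$dual))

  sm <- frag_names("SM 18:1;2/17:0", "+H")
  expect_true("SM(184)" %in% sm$name)
  expect_true(any(sm$dual == "SM(184) | -Cer 35:1;2(-H2O)"))

  peo <- frag_names("PE O-18:1p/20:4", "+H")
  expect_true("-PE O-(141)" %in% peo$name)

  ps <- frag_names("PS 20:4-22:6", "-H")
  expect_true(all(c("PS(153)", "-PS(87)", "FA 20:4(+O)", "FA 22:6(-CO)",
                    "-FA 20:4(+HO) -PS(87)") %in% ps$name))

  tag <- frag_names("TAG 16:0-18:0-18:2", "+NH4")
  expect_true(all(c("-TAG(17)", "-FA 18:0(+HO) -TAG(17)", "FA 18:2(-HO)")
                  %in% tag$name))

  dag <- frag_names("DAG 18:0-20:0", "+Na")
  expect_true(all(c("-FA 18:0(+HO)", "-FA 18:0(+ONa)", "FA 20:0(+HONa)",
                    "FA 18:0") %in% dag$name))

  acoa <- frag_names("ACoA 19:0", "-H")
  expect_true("FA 19:0(+C11H20N2O9P2S)" %in% acoa$name)

  cl <- frag_names("CL 14:1-14:1-14:1-15:1", "-2H")
  expect_true("DAG 28:2(+C6H11O9P2)" %in% cl$name)
})

test_that("isotope-labeled fragment names follow the extended rules", {
  lab_pc <- frag_names("PC(+[2]H13) 16:1-18:1", "+H")
  expect_true("PC(+[2]H13)(197)" %in% lab_pc$name)
  lab_pc2 <- frag_names("PC 16:0(+[2]H3)-16:0(+[2]H3)", "+H")
  expect_true("-FA 16:0(+[2]H3)(-H)" %in% lab_pc2$name)
  lab_pi <- frag_names("PI(+[2]H6) 16:0-18:1", "-H")
  expect_true("PI(+[2]H6)(247)" %in% lab_pi$name)
  lab_cer <- frag_names("Cer 18:0;3(+[13]C2[15]N)/26:0;1", "+HCOO")
  expect_true("LCB 18:0;3(+[13]C2[15]N)(-[13]CH8[15]NO)" %in% lab_cer$name)
})

test_that("prioritization follows the decision tree", {
  # type tie (MLF on both sides): lower total fragment mass wins -> the
  # 502.2940 ion is annotated by its neutral composite (334.3 Da < 502.3 Da)
  pc <- enumerate_fragments(precursor_ion("PC 18:3-18:3", "+CH3COO"))
  tab <- fragment_table(pc)
  i <- which(abs(tab$mz - 502.2940) < 0.001)
  expect_identical(pc[[i]]$prioritized, "neutral")
  nmass <- sum(vapply(pc[[i]]$neutrals, function(p)
    monoisotopic_mass(p$comp), numeric(1)))
  expect_equal(round(nmass, 1), 334.3)

  # LCF beats iMLF: the phosphocholine cation wins over the ceramide remainder
  sm <- enumerate_fragments(precursor_ion("SM 18:1;2/17:0", "+H"))
  smtab <- fragment_table(sm)
  expect_identical(sm[[which(smtab$name == "SM(184)")]]$prioritized, "charged")

  # MLF beats iMLF: fatty acid + ammonia loss wins over the DAG-type ion
  tag <- enumerate_fragments(precursor_ion("TAG 16:0-18:0-18:2", "+NH4"))
  tagtab <- fragment_table(tag)
  j <- which(tagtab$rule == "tag_nh4_nl_fa")[1]
  expect_identical(tag[[j]]$prioritized, "neutral")
  expect_match(tagtab$dual[j], "\\| DAG ")

  # charge splitting (CL 2-): the charged iMLF annotates its own m/z
  cl <- enumerate_fragments(precursor_ion("CL 14:1-14:1-14:1-15:1", "-2H"))
  cltab <- fragment_table(cl)
  expect_true(all(vapply(cl[cltab$rule == "cl_2neg_pair"], `[[`,
                         character(1), "prioritized") == "charged"))
})

test_that("prioritization is deterministic under neutral-part permutation", {
  pc <- enumerate_fragments(precursor_ion("PC 18:3-18:3", "+CH3COO"))
  tab <- fragment_table(pc)
  i <- which(abs(tab$mz - 502.2940) < 0.001)
  rx <- pc[[i]]
  rx_perm <- rx
  rx_perm$neutrals <- rev(rx_perm$neutrals)
  rx_perm$prioritized <- NULL
  expect_identical(prioritize(rx_perm)$prioritized, rx$prioritized)
  # term order in the composite is fixed (chain parts before head parts)
  expect_identical(prioritized_name(rx_perm), prioritized_name(rx))
})

test_that("dual rendering puts the prioritized side first", {
  pe <- enumerate_fragments(precursor_ion("PE 17:0-17:0", "-H"))
  tab <- fragment_table(pe)
  expect_match(tab$dual[tab$rule == "pe_neg_carbox"], "^FA 17:0\\(\\+O\\) \\| ")
  expect_match(tab$dual[tab$rule == "pe_neg_nl_ket"], "^-FA 17:0\\(-H\\) \\| ")
})

test_that("fragment names parse back to the exact engine compositions", {
  cases <- list(c("PC 18:3-18:3", "+CH3COO"), c("PS 20:4-22:6", "-H"),
                c("TAG 16:0-18:0-18:2", "+NH4"), c("SM 18:1;2/17:0", "+H"),
                c("DAG 18:0-20:0", "+Na"), c("ACar 18:2", "+H"),
                c("CL 14:1-14:1-14:1-15:1", "-2H"),
                c("PC(+[2]H13) 16:1-18:1", "+H"))
  for (cs in cases) {
    for (rx in enumerate_fragments(precursor_ion(cs[1], cs[2]))) {
      for (p in c(list(rx$charged), rx$neutrals)) {
        recovered <- parse_fragment_name(name_part(p))
        expect_length(comp_diff(recovered, p$comp), 0)
      }
    }
  }
})
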