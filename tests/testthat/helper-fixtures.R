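# Shared fixtures: random composition / lipid-name generators for
# property-style tests (fixed seeds set in the tests that use them).

random_composition <- function() {
  keys <- c("C", "H", "N", "O", "P", "S", "Na")
  n <- sample(1:5, 1)
  picked <- sample(keys, n)
  cmp <- stats::setNames(sample(1:40, n, replace = TRUE), picked)
  do.call(comp, as.list(cmp))
}

# a molecular-level lipid name drawn from the class registry
random_lipid_name <- function() {
  reg <- lipid_classes()
  cl <- sample(reg$class, 1)
  tmpl <- lipidfrags:::.class_template(cl)
  toks <- vapply(tmpl$slots, function(slot) {
    c <- sample(14:22, 1)
    db <- sample(0:4, 1)
    oh <- if (slot$linkage %in% c("lcb", "amide")) sample(0:2, 1) else 0L
    if (slot$linkage == "lcb") oh <- max(oh, 1L)
    paste0(c, ":", db, if (oh > 0) paste0(";", oh) else "")
  }, character(1))
  sep <- if (tmpl$category == "sphingolipid" || cl == "SE") "/" else "-"
  if (sep == "-" && length(toks) > 1) {
    # canonical order for unordered chains: carbons, then double bonds
    key <- vapply(strsplit(toks, "[:;]"), function(p)
      as.integer(p[1]) * 100L + as.integer(p[2]), integer(1))
    toks <- toks[order(key)]
  }
  paste0(lipidfrags:::.class_prefix(cl), paste(toks, collapse = sep))
}

# every printed worked-example precursor used across the tests
worked_precursors <- function() {
  list(
    list(name = "PC 18:3-18:3", adduct = "+CH3COO", mz = 836.5447),
    list(name = "TAG 16:0-18:0-18:2", adduct = "+NH4", mz = 876.8015),
    list(name = "DAG 18:0-20:0", adduct = "+Na", mz = 675.5897),
    list(name = "PE 17:0-17:0", adduct = "-H", mz = 718.5379),
    list(name = "PS 20:4-22:6", adduct = "-H", mz = 854.4981),
    list(name = "ACar 18:2", adduct = "+H", mz = 424.3413)
  )
}

ppm_diff <- function(a, b) abs(a - b) / b * 1e6
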