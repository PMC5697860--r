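# Spectrum annotation: peak matching, identification levels, peak-list I/O.

test_that("ion-trap peaks of a PE standard annotate as printed", {
  peaks <- data.frame(mz = c(269.2, 448.2, 466.2), intensity = c(100, 80, 60))
  res <- annotate_spectrum(peaks, "PE 17:0-17:0", adduct = "-H",
                           tol_da = 0.3)[[1]]
  expect_identical(res$matches$name,
                   c("FA 17:0(+O)", "-FA 17:0(+HO)", "-FA 17:0(-H)"))
  expect_identical(res$identification_level, "molecular")
  expect_length(res$unmatched, 0)
})

test_that("empty peak lists and empty candidate sets are handled", {
  empty <- data.frame(mz = numeric(0), intensity = numeric(0))
  res <- annotate_spectrum(empty, "PE 17:0-17:0", adduct = "-H")[[1]]
  expect_identical(nrow(res$matches), 0L)
  expect_identical(res$identification_level, "none")
  expect_error(annotate_spectrum(data.frame(mz = 1, intensity = 1), list()),
               "empty candidate")
})

test_that("identification level distinguishes species from molecular evidence", {
  prec <- precursor_ion("PS 20:4-22:6", "-H")
  theo <- fragment_table(enumerate_fragments(prec))
  # LCF-only evidence: species level
  lcf_peaks <- data.frame(mz = theo$mz[theo$rule %in%
                                         c("ps_neg_lcf153", "ps_neg_nl87")],
                          intensity = 1)
  res1 <- annotate_spectrum(lcf_peaks, prec, tol_ppm = 1)[[1]]
  expect_identical(res1$identification_level, "species")
  # MLF evidence for both chains: molecular level
  mlf_peaks <- data.frame(mz = theo$mz[theo$mlf], intensity = 1)
  res2 <- annotate_spectrum(mlf_peaks, prec, tol_ppm = 1)[[1]]
  expect_identical(res2$identification_level, "molecular")
  expect_true(all(res2$chain_evidence$mlf_fragments >= 1))
  # MLF evidence for one chain only: not molecular
  one_chain <- data.frame(mz = theo$mz[theo$name == "FA 20:4(+O)"],
                          intensity = 1)
  res3 <- annotate_spectrum(one_chain, prec, tol_ppm = 1)[[1]]
  expect_false(res3$identification_level == "molecular")
})

test_that("matches are monotone in the tolerance", {
  prec <- precursor_ion("PS 20:4-22:6", "-H")
  theo <- fragment_table(enumerate_fragments(prec))
  set.seed(5)
  jitter <- theo$mz * (1 + stats::rnorm(nrow(theo), 0, 4e-6))
  peaks <- data.frame(mz = jitter, intensity = 1)
  sizes <- vapply(c(1, 2, 5, 10, 20), function(tol)
    nrow(annotate_spectrum(peaks, prec, tol_ppm = tol)[[1]]$matches),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_identical(sizes[length(sizes)], as.numeric(nrow(theo)))
})

test_that("annotation is deterministic", {
  peaks <- data.frame(mz = c(269.2486, 448.2833), intensity = c(1, 2))
  r1 <- annotate_spectrum(peaks, "PE 17:0-17:0", adduct = "-H")[[1]]
  r2 <- annotate_spectrum(peaks, "PE 17:0-17:0", adduct = "-H")[[1]]
  expect_identical(r1$matches, r2$matches)
})

test_that("one peak may annotate several isomeric candidates", {
  peaks <- data.frame(mz = 239.2369, intensity = 1)  # FA 16:0 acylium
  res <- annotate_spectrum(peaks, list("TAG 16:0-18:0-18:2",
                                       "TAG 16:0-18:1-18:1"),
                           adduct = "+NH4", tol_ppm = 5)
  expect_length(res, 2)
  expect_true(all(vapply(res, function(r) nrow(r$matches) == 1L, logical(1))))
})

test_that("peak lists round-trip through TSV and MGF", {
  peaks <- data.frame(mz = c(100.1234, 500.5678), intensity = c(10, 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(peaks, tsv)
  expect_equal(read_peaklist(tsv), peaks, tolerance = 1e-9)

  mgf <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(title = "[PE 34:0-H]-", pepmass = 718.5392, charge = -1L,
                 peaks = peaks), mgf)
  spectra <- read_mgf(mgf)
  expect_length(spectra, 1)
  expect_identical(spectra[[1]]$title, "[PE 34:0-H]-")
  expect_identical(spectra[[1]]$charge, -1L)
  expect_equal(spectra[[1]]$peaks$mz, peaks$mz, tolerance = 1e-6)

  out <- withr::local_tempfile(fileext = ".tsv")
  res <- annotate_spectrum(peaks, "PE 17:0-17:0", adduct = "-H")[[1]]
  write_annotation(res, out)
  expect_true(file.exists(out))
})
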