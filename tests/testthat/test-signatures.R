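test_that("drug DEG filter is strict at the threshold", {
  sig <- drugSignature("d", c(g1 = 0.5, g2 = -1.2, g3 = 1.0, g4 = 3.0))
  expect_setequal(selectDrugDegs(sig), c("g2", "g4"))  # g3 at 1.0 excluded
  expect_equal(selectDrugDegs(drugSignature("d", c(g1 = -1.0001))), "g1")
  expect_error(selectDrugDegs(drugSignature("d", c(g1 = 0.2))), "no DEG")
})

test_that("disease DEG filter: FDR strict, linear fold-change non-strict", {
  rec <- data.frame(gene = c("g1", "g2", "g3"),
                    log2fc = c(1.5, 0.5, -2.0),
                    fdr = c(0.001, 0.0001, 0.02),
                    z = c(2, 1, -3))
  sig <- diseaseSignature("c", rec)
  expect_equal(selectDiseaseDegs(sig), "g1")  # g2 fails FC, g3 fails FDR
  # log2FC of exactly 1 gives linear FC 2, which qualifies
  sig2 <- diseaseSignature("c", data.frame(gene = "g1", log2fc = 1,
                                           fdr = 0.005, z = 1.5))
  expect_equal(selectDiseaseDegs(sig2), "g1")
  expect_error(selectDiseaseDegs(
    diseaseSignature("c", rec[0, , drop = FALSE])), "no records")
})

test_that("filters are monotone in their thresholds", {
  set.seed(7)
  z <- stats::setNames(rnorm(200, 0, 1.5), sprintf("g%03d", 1:200))
  for (thr in c(0.5, 1, 1.5, 2)) {
    lo <- selectDrugDegs(drugSignature("d", z, degThreshold = thr))
    hiSig <- drugSignature("d", z, degThreshold = thr + 0.5)
    hi <- tryCatch(selectDrugDegs(hiSig), error = function(e) character())
    expect_true(all(hi %in% lo))
    expect_true(all(lo %in% names(z)))
  }
  rec <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200, 0, 2), fdr = runif(200),
                    z = rnorm(200))
  for (fdr in c(0.2, 0.1, 0.05)) {
    lo <- selectDiseaseDegs(diseaseSignature("c", rec, fdrThreshold = fdr))
    hiSig <- diseaseSignature("c", rec, fdrThreshold = fdr / 4)
    hi <- tryCatch(selectDiseaseDegs(hiSig), error = function(e) character())
    expect_true(all(hi %in% lo))
  }
})

test_that("zLookup returns 0 for unmeasured genes so adjustments are neutral", {
  sig <- drugSignature("d", c(TP53 = -2.3))
  expect_equal(zLookup(sig, "TP53"), -2.3)
  expect_equal(zLookup(sig, "EGFR"), 0)
  expect_equal(zLookup(sig, c("EGFR", "TP53")), c(0, -2.3))
  # absent gene leaves a base score unchanged through 0.5^|z|
  expect_equal(2 * 0.5^abs(zLookup(sig, "EGFR")), 2)
})

test_that("signature file readers round-trip", {
  f <- tempfile()
  writeLines(c("g1\t-1.5", "g2\t0.3"), f)
  sig <- readDrugSignature(f, drugId = "drugA", cellLine = "HT29",
                           dose = "10 uM")
  expect_equal(zscores(sig), c(g1 = -1.5, g2 = 0.3))
  expect_equal(drugId(sig), "drugA")

  fd <- tempfile()
  writeLines(c("gene\tlog2fc\tfdr\tz", "g1\t2.1\t0.001\t3.2",
               "g2\t0.1\t0.8\t0.2"), fd)
  dis <- readDiseaseSignature(fd, cohortId = "COAD")
  expect_equal(selectDiseaseDegs(dis), "g1")
  expect_equal(zLookup(dis, "g2"), 0.2)

  # manifest
  dir <- tempfile(); dir.create(dir)
  writeLines(c("g1\t-2.0"), file.path(dir, "d1.tsv"))
  writeLines(c("drug_id\tcell_line\tdose\tpath", "d1\tPC3\t1 uM\td1.tsv"),
             file.path(dir, "manifest.tsv"))
  sigs <- readDrugManifest(file.path(dir, "manifest.tsv"))
  expect_length(sigs, 1L)
  expect_equal(drugId(sigs[[1]]), "d1")
})

test_that("signature validity rejects malformed inputs", {
  expect_error(drugSignature("d", c(g1 = NaN)), "finite")
  expect_error(drugSignature("d", c(1, 2)), "named")
  expect_error(diseaseSignature("c", data.frame(gene = "g1", log2fc = 1,
                                                fdr = 1.2, z = 0)),
               "fdr")
})
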