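test_that("allele grammar parses and serializes as exact inverses", {
  strs <- c("micro:I2G", "micro:I2G+p.G111Vfs*21", "micro:UTR5+p.Q319X",
            "novel:c.292+1G>A", "novel:p.R484Pfs*58", "del:solo",
            "cahx:CH1", "cahx:CH3", "chimera:CH6", "chimera:CH8",
            "dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT",
            "dup:E7E8[p.L308Ffs*6,p.Q319X]")
  for (s in strs) {
    expect_identical(formatAllele(parseAllele(s)), s)
  }
  # the whole fixture round-trips bit-exactly
  df <- patientData(table3Cohort())
  for (s in c(df$allele1, df$allele2)) {
    expect_identical(formatAllele(parseAllele(s)), s)
  }
})

test_that("grammar violations raise parse errors naming the production", {
  expect_error(parseAllele(""), "empty allele string")
  expect_error(parseAllele("foo:I2G"), "unknown allele production")
  expect_error(parseAllele("del:partial"), "del:solo")
  expect_error(parseAllele("cahx:CH4"), "CH1\\|CH2\\|CH3")
  expect_error(parseAllele("chimera:CH12"), "CH1\\.\\.CH9")
  expect_error(parseAllele("dup:E1E2[x]"), "dup:E7E8")
})

test_that("duplication grammar distinguishes fused-only from trimodular", {
  tri <- parseAllele("dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT")
  fused <- parseAllele("dup:E7E8[p.L308Ffs*6,p.Q319X]")
  expect_identical(alleleCopies(tri), 2L)
  expect_identical(alleleCopies(fused), 1L)
  expect_identical(alleleCategory(tri), "DUPLICATION")
})

test_that("junction caller recovers catalogue junctions (round trip)", {
  m <- testModel()
  expected <- list(CH1 = c("E3", "E4"), CH2 = c("E5", "E6"),
                   CH3 = c("E7", "E8"), CH4 = c("E1", "E2"),
                   CH6 = c("I2G_SITE", "DEL8BP_SITE"), CH8 = c("E8", "E9"))
  for (id in names(expected)) {
    mv <- markerVectorForChimera(id, m)
    j <- callJunction(mv, m)
    expect_identical(c(j$left, j$right), expected[[id]], info = id)
    expect_identical(classifyChimera(j, mv, m)$chimera_id, id, info = id)
  }
})

test_that("junction caller handles the degenerate haplotypes", {
  m <- testModel()
  sites <- siteMap(m)$site_id[siteMap(m)$region != "tnxb"]
  wt <- markerVector(setNames(rep("GENE", 13), sites), model = m)
  j <- callJunction(wt, m)
  expect_true(j$none)
  expect_false(j$wholeGeneAbsent)
  absent <- markerVector(setNames(rep("ABSENT", 13), sites), model = m)
  expect_true(callJunction(absent, m)$wholeGeneAbsent)
  expect_error(callJunction(markerVector(setNames(rep("UNKNOWN", 13), sites),
                                         model = m), m),
               "no informative call")
})

test_that("a gene call upstream of a pseudogene call is non-canonical", {
  m <- testModel()
  sites <- siteMap(m)$site_id[siteMap(m)$region != "tnxb"]
  calls <- setNames(rep("GENE", 13), sites)
  calls["E4"] <- "PSEUDO"  # GENE at UTR5..E3 before PSEUDO at E4
  err <- tryCatch(callJunction(markerVector(calls, model = m), m),
                  error = conditionMessage)
  expect_match(err, "non-canonical")
  expect_match(err, "UTR5")
  expect_match(err, "E4")
})

test_that("junction caller agrees with the exhaustive cut-point oracle", {
  m <- testModel()
  set.seed(20241101)
  for (i in 1:1000) {
    calls <- randomJunctionVector(m)
    mv <- markerVector(calls, model = m)
    got <- callJunction(mv, m)
    want <- oracleJunction(calls)
    expect_false(is.null(want))
    expect_identical(got$none, want$none)
    if (!want$none) {
      expect_identical(c(got$left, got$right), c(want$left, want$right))
    }
  }
})

test_that("whole-gene-absent haplotypes are typed by TNXB signature", {
  m <- testModel()
  for (id in c("CAHX_CH1", "CAHX_CH2", "CAHX_CH3", "DEL_SOLO")) {
    mv <- markerVectorForChimera(id, m)
    j <- callJunction(mv, m)
    expect_identical(classifyChimera(j, mv, m)$chimera_id, id, info = id)
  }
  # an unrecognized signature yields an unclassified result, not an error
  sites <- siteMap(m)$site_id[siteMap(m)$region != "tnxb"]
  mv <- markerVector(setNames(rep("ABSENT", 13), sites),
                     tnxbSignature = "TNXB_E39_NOVEL", model = m)
  expect_true(is.na(classifyChimera(callJunction(mv, m), mv, m)$chimera_id))
})

test_that("uncatalogued junctions yield an unclassified result carrying the interval", {
  m <- testModel()
  sites <- siteMap(m)$site_id[siteMap(m)$region != "tnxb"]
  calls <- setNames(c(rep("PSEUDO", 9), rep("GENE", 4)), sites)  # cut at E6/E7
  mv <- markerVector(calls, model = m)
  res <- classifyChimera(callJunction(mv, m), mv, m)
  expect_true(is.na(res$chimera_id))
  expect_identical(c(res$junction$left, res$junction$right), c("E6", "E7"))
})

test_that("classifyAllele follows the taxonomy and is order-invariant", {
  m <- testModel()
  a <- classifyAllele("I2G", model = m)
  expect_identical(alleleCategory(a), "MICROCONVERSION")
  b <- classifyAllele("p.R484Pfs*58", model = m)
  expect_identical(alleleCategory(b), "NOVEL_VARIANT")
  # one non-pseudogene token makes the whole allele a novel variant
  mix <- classifyAllele(c("I2G", "p.S126X"), model = m)
  expect_identical(alleleCategory(mix), "NOVEL_VARIANT")
  expect_identical(alleleVariants(mix), c("I2G", "p.S126X"))
  # order invariance
  x <- classifyAllele(c("p.Q319X", "UTR5"), model = m)
  y <- classifyAllele(c("UTR5", "p.Q319X"), model = m)
  expect_identical(alleleCategory(x), alleleCategory(y))
  expect_identical(alleleCategory(x), "MICROCONVERSION")
  # structural evidence dominates; copy structure wins over tokens
  dup <- classifyAllele(extraCopies = list(character(0),
                                           c("p.V282L", "p.Q319X")),
                        model = m)
  expect_identical(alleleSubtype(dup), "DUP_E7E8")
  expect_error(classifyAllele(model = m), "needs variants")
  sites <- siteMap(m)$site_id[siteMap(m)$region != "tnxb"]
  wt <- markerVector(setNames(rep("GENE", 13), sites), model = m)
  expect_error(classifyAllele(character(0), wt, model = m), "inconsistent")
})

test_that("classifier reproduces every long-read allele call in the fixture", {
  m <- testModel()
  cohort <- table3Cohort()
  n_alleles <- 0L
  for (i in seq_len(nPatients(cohort))) {
    for (k in 1:2) {
      truth <- cohortAlleles(cohort)[[i]][[k]]
      ev <- rccxtyper:::.alleleEvidence(truth, m)
      got <- classifyAllele(ev$variants, ev$mv, ev$extraCopies, m)
      expect_identical(alleleCategory(got), alleleCategory(truth))
      expect_identical(alleleSubtype(got), alleleSubtype(truth))
      n_alleles <- n_alleles + 1L
    }
  }
  expect_identical(n_alleles, 134L)
})
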