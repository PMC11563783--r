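test_that("default locus model satisfies its structural invariants", {
  m <- testModel()
  expect_true(validObject(m, test = TRUE))
  s <- siteMap(m)
  expect_true(all(diff(s$order_index) > 0))
  expect_identical(sum(grepl("^E[0-9]+$", s$site_id)), 10L)
  idx <- function(id) match(id, s$site_id)
  expect_true(idx("E2") < idx("I2G_SITE") &&
              idx("I2G_SITE") < idx("DEL8BP_SITE") &&
              idx("DEL8BP_SITE") < idx("E4"))
  # no probe can see TNXB exons 40-44
  expect_false(any(grepl("E4[0-4]$", probePanel(m)$tnxb_probe_sites)))
  # every chimera span is a contiguous prefix interval of the site order
  for (id in c("CH1", "CH2", "CH3", "CH4", "CH6", "CH8")) {
    calls <- markerVectorForChimera(id, m)@calls
    pseudo <- unname(which(calls == "PSEUDO"))
    expect_identical(pseudo, seq_along(pseudo), info = id)
  }
})

test_that("chimera catalogue encodes I2G carriage and the CH4/CH9 exception", {
  m <- testModel()
  cat_ <- chimeraCatalog(m)
  for (id in c("CH1", "CH2", "CH3", "CH5", "CH6", "CH7", "CH8")) {
    expect_true(cat_[[id]]$carries_I2G, info = id)
  }
  expect_false(cat_[["CH4"]]$carries_I2G)
  expect_false(cat_[["CH9"]]$carries_I2G)
  expect_false(cat_[["CH6"]]$carries_8bp_del)
  # CH4 converted span covers exactly the promoter and exon 1
  calls <- markerVectorForChimera("CH4", m)@calls
  expect_identical(names(calls)[calls == "PSEUDO"], c("UTR5", "E1"))
  # unobserved junctions stay unconstructable
  expect_error(markerVectorForChimera("CH5", m), "no defined junction")
})

test_that("severity table and variant-site lookup match the reference rules", {
  m <- testModel()
  sev <- severityTable(m)
  expect_identical(unname(sev["I173N"]), "B")
  expect_identical(unname(sev["I2G"]), "A")
  expect_true(all(sev[c("Q319X", "R357W", "R484Pfs", "L308Ffs",
                        "G111Vfs", "E6_CLUSTER")] == "Null"))
  expect_true(all(sev[c("P31L", "P454S", "V282L")] == "C"))
  expect_identical(siteForVariant(m, "p.Q319X")$site_id, "E8")
  expect_identical(siteForVariant(m, "I2G")$region, "intron_site")
  expect_identical(siteForVariant(m, "p.G111Vfs*21")$site_id, "E3")
  # legacy spellings resolve through the synonym table
  expect_identical(siteForVariant(m, "p.V281L")$site_id,
                   siteForVariant(m, "p.V282L")$site_id)
  expect_error(siteForVariant(m, "p.X999Y"), "unknown variant")
  expect_error(siteForVariant(m, "c.292+1G>A"), "location-unknown")
})

test_that("every fixture token resolves to a site or is registered unknown", {
  m <- testModel()
  cohort <- table3Cohort()
  toks <- unlist(lapply(unlist(cohortAlleles(cohort), recursive = FALSE),
                        alleleVariants))
  for (tk in unique(normalizeToken(toks))) {
    expect_true(tk %in% names(m@variantSites) || tk %in% m@unknownLocation,
                info = tk)
  }
})

test_that("a YAML configuration can extend the probe panel", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("probe_panel:",
               "  a2_probe_sites: [E1, E3, E4, E6, E7, E8, I2G_SITE]"),
             cfg)
  m2 <- loadLocusModel(cfg)
  expect_true("E8" %in% probePanel(m2)$a2_probe_sites)
  # with an exon-8 probe, CH3 (converted through part of exon 8) and CH8
  # (converted through all of exon 8) dosages diverge
  neutral <- parseAllele("micro:I2G")
  d3 <- simulateProbeDropout(parseAllele("chimera:CH3"), neutral, m2)
  d8 <- simulateProbeDropout(parseAllele("chimera:CH8"), neutral, m2)
  expect_identical(unname(d3["E8"]), 2L)
  expect_identical(unname(d8["E8"]), 1L)
  expect_false(identical(d3, d8))
})

test_that("configurations violating an invariant are rejected by name", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("probe_panel:",
               "  tnxb_probe_sites: [TNXB_E35, TNXB_E41]"), cfg)
  expect_error(loadLocusModel(cfg), "TNXB exons 40-44")
  cfg2 <- tempfile(fileext = ".yaml")
  writeLines(c("severity:", "  X123Y: Q"), cfg2)
  expect_error(loadLocusModel(cfg2), "severity classes")
  expect_error(loadLocusModel("/nonexistent/model.yaml"), "not found")
})

test_that("locus model serializes to YAML and reloads overrides", {
  m <- testModel()
  f <- tempfile(fileext = ".yaml")
  writeLocusModel(m, f)
  doc <- yaml::read_yaml(f)
  expect_setequal(doc$probe_panel$a2_probe_sites,
                  probePanel(m)$a2_probe_sites)
  expect_identical(doc$severity$I173N, "B")
})
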