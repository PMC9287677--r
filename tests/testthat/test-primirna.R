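test_that("intron derivation subtracts exons of all overlapping genes", {
  gm <- twoGeneModels()
  # gA span 101-1000, exons 101-200 and 801-1000, nested gB exon 301-400
  introns <- intronicRegions(gm, "gA")
  expect_identical(GenomicRanges::start(introns), c(201L, 401L))
  expect_identical(GenomicRanges::end(introns), c(300L, 800L))

  # without the neighbour, one contiguous intron
  soloG <- geneSpans(gm)["gA"]
  soloE <- exonRanges(gm)["gA"]
  solo <- GeneModelSet(soloG, soloE)
  i2 <- intronicRegions(solo, "gA")
  expect_identical(GenomicRanges::start(i2), 201L)
  expect_identical(GenomicRanges::end(i2), 800L)

  expect_error(buildIntronSet(gm, "nope"), "unknown")

  # exonless annotation: whole span, with a warning
  g <- GenomicRanges::GRanges("chr2", IRanges::IRanges(10, 100), "+")
  names(g) <- "bare"
  bare <- GeneModelSet(g, GenomicRanges::GRangesList(
    bare = GenomicRanges::GRanges()))
  expect_warning(ib <- intronicRegions(bare, "bare"),
                 "without annotated exons")
  expect_identical(GenomicRanges::width(ib), 91L)
})

test_that("intron subtraction matches a per-base oracle", {
  set.seed(101)
  for (i in 1:8) {
    gm <- randomGeneModels(3)
    for (g in geneIds(gm)) {
      got <- suppressWarnings(intronicRegions(gm, g))
      want <- oracleIntrons(gm, g)
      expect_identical(GenomicRanges::start(got), as.integer(want[, 1]))
      expect_identical(GenomicRanges::end(got), as.integer(want[, 2]))
    }
  }
})

test_that("only reads fully contained in an intron are counted", {
  gm <- twoGeneModels()
  introns <- buildIntronSet(gm, "gA")  # 201-300, 401-800
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(250, 191, 280, 795, 405, 100),
    c(279, 210, 309, 824, 434, 129)))
  counts <- countIntronicReads(list(s1 = reads), introns)
  # contained: 250-279, 405-434; boundary-spanning 191-210 / 280-309 /
  # 795-824 and exonic 100-129 are rejected
  expect_identical(counts["gA", "s1"], 2L)

  # order invariance and exact doubling
  shuf <- countIntronicReads(list(s1 = reads[sample(length(reads))]),
                             introns)
  expect_identical(shuf, counts)
  doubled <- countIntronicReads(list(s1 = c(reads, reads)), introns)
  expect_identical(doubled["gA", "s1"], 4L)
})

test_that("pri fold changes are null for identical conditions and gated", {
  m <- matrix(c(100L, 50L, 100L, 50L, 100L, 50L, 100L, 50L), 2, 4,
              dimnames = list(c("hA", "hB"), paste0("s", 1:4)))
  cond <- c("x", "x", "y", "y")
  pf <- priFoldChange(m, cond, "x", "y")
  expect_equal(pf$pri_log2fc, c(0, 0), tolerance = 1e-12)
  expect_false(any(pf$low_coverage))

  low <- matrix(c(3L, 500L, 2L, 480L, 4L, 520L, 1L, 505L), 2, 4,
                dimnames = list(c("hA", "hB"), paste0("s", 1:4)))
  pf2 <- priFoldChange(low, cond, "x", "y", minCount = 20)
  expect_true(pf2$low_coverage[1L])
  expect_true(is.na(pf2$pri_log2fc[1L]))
  expect_false(pf2$low_coverage[2L])

  expect_error(priFoldChange(m, cond, "x", "zzz"), "present")
})

test_that("regulation calls follow the concordance rules", {
  expect_identical(classifyRegulation(-1, -0.8), "transcriptional")
  expect_identical(classifyRegulation(-1, 0.05), "post_transcriptional")
  expect_identical(classifyRegulation(-0.1, -0.1), "unchanged")
  expect_identical(classifyRegulation(-1, 0.9), "discordant")
  expect_identical(
    classifyRegulation(c(-1, -1, -0.1), c(-0.8, 0.05, -0.1)),
    c("transcriptional", "post_transcriptional", "unchanged"))
  expect_error(classifyRegulation(NA, 1), "present")
})

test_that("mature-vs-pri correlation is exact on identical vectors", {
  lfc <- c(-1.3, -0.5, 0.2, 0.9, -0.1, 1.4)
  mature <- data.frame(feature_id = sprintf("mir_%d", 1:6), log2fc = lfc,
                       pvalue = rep(0.01, 6))
  pri <- data.frame(host_gene_id = sprintf("host_%d", 1:6),
                    pri_log2fc = lfc, total_count = 1000,
                    low_coverage = FALSE)
  hm <- data.frame(mir_id = sprintf("mir_%d", 1:6),
                   host_gene_id = sprintf("host_%d", 1:6))
  res <- correlateMatureVsPri(mature, pri, hm)
  expect_equal(res$correlation$rho, 1, tolerance = 1e-12)
  expect_equal(res$correlation$r, 1, tolerance = 1e-12)
  expect_identical(res$correlation$n_mirs, 6L)

  # low-coverage hosts are excluded and listed
  pri$low_coverage[1L] <- TRUE
  pri$pri_log2fc[1L] <- NA
  res2 <- correlateMatureVsPri(mature, pri, hm)
  expect_identical(res2$excluded, "mir_1")
  expect_identical(res2$correlation$n_mirs, 5L)

  expect_error(correlateMatureVsPri(mature[1:2, ], pri[1:2, ], hm[1:2, ]),
               "fewer than 3")
})

test_that("scenario classification recovers planted regimes", {
  gm <- simulateGeneModels(20)
  introns <- buildIntronSet(gm$models)
  planted <- c(rep(-1.32, 2), rep(0, 18))

  ex <- simulateHostGeneExperiment(gm$models, gm$hostMap,
                                   scenario = "transcriptional",
                                   priLog2fc = planted, seed = 111)
  pf <- priFoldChange(countIntronicReads(ex$reads, introns),
                      ex$condition, "control", "mutant")
  de <- deContrast(ex$mature, "control", "mutant")
  res <- correlateMatureVsPri(de, pf, gm$hostMap)
  calls <- res$rows$scenario_call[match(gm$hostMap$mir_id[1:2],
                                        res$rows$mir_id)]
  expect_true(all(calls == "transcriptional"))

  ex2 <- simulateHostGeneExperiment(gm$models, gm$hostMap,
                                    scenario = "processing",
                                    matureLog2fc = planted, seed = 112)
  pf2 <- priFoldChange(countIntronicReads(ex2$reads, introns),
                       ex2$condition, "control", "mutant")
  de2 <- deContrast(ex2$mature, "control", "mutant")
  res2 <- correlateMatureVsPri(de2, pf2, gm$hostMap)
  calls2 <- res2$rows$scenario_call[match(gm$hostMap$mir_id[1:2],
                                          res2$rows$mir_id)]
  expect_true(all(calls2 == "post_transcriptional"))
})
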