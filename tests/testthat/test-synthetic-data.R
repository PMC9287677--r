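test_that("simulateUtrSet plants the recorded sites and nothing else", {
  mir <- testMirna()
  sim <- simulateUtrSet(100, mirna = mir, targetFraction = 0.3, seed = 11)
  truth <- sim$truth
  expect_length(plantedTargets(truth), 30L)
  expect_setequal(plantedTargets(truth), unique(plantedSites(truth)$gene_id))

  # every recorded (gene, offset, word) is present verbatim
  sites <- plantedSites(truth)
  seqs <- as.character(sim$utrs)
  found <- mapply(function(g, off, w)
    substr(seqs[[g]], off, off + nchar(w) - 1L) == w,
    sites$gene_id, sites$offset, sites$word)
  expect_true(all(found))

  # the planted word is the DNA reverse complement of seed positions 2-8
  expect_identical(unique(sites$word),
                   seedSiteWord(substr(mir, 2, 8)))

  null <- simulateUtrSet(50, mirna = mir, targetFraction = 0, seed = 11)
  expect_length(plantedTargets(null$truth), 0L)
  expect_identical(nrow(plantedSites(null$truth)), 0L)

  expect_error(simulateUtrSet(10, lengthRange = c(5, 10), mirna = mir),
               "site length")
})

test_that("generators are bit-reproducible under a fixed seed", {
  mir <- testMirna()
  a <- simulateUtrSet(40, mirna = mir, seed = 7)
  b <- simulateUtrSet(40, mirna = mir, seed = 7)
  expect_identical(as.character(a$utrs), as.character(b$utrs))
  expect_identical(plantedSites(a$truth), plantedSites(b$truth))

  c1 <- simulateCounts(50, seed = 9)
  c2 <- simulateCounts(50, seed = 9)
  expect_identical(SummarizedExperiment::assay(c1$counts),
                   SummarizedExperiment::assay(c2$counts))

  d1 <- simulateMultiDatasetDe(nMirs = 50, seed = 5)
  d2 <- simulateMultiDatasetDe(nMirs = 50, seed = 5)
  expect_identical(d1$tables, d2$tables)

  gm <- simulateGeneModels(5)
  h1 <- simulateHostGeneExperiment(gm$models, gm$hostMap, seed = 3)
  h2 <- simulateHostGeneExperiment(gm$models, gm$hostMap, seed = 3)
  expect_identical(SummarizedExperiment::assay(h1$mature),
                   SummarizedExperiment::assay(h2$mature))
  expect_identical(h1$reads, h2$reads)
})

test_that("mutateSeedSite deletes the requested site positions only", {
  # site ACTGTAG at offset 3; deleting site positions 2,4,6 keeps A,T,T,G
  expect_identical(mutateSeedSite("AAACTGTAGAA", 3, 7), "AAATTGAA")
  expect_identical(mutateSeedSite("AAACTGTAGAA", 3, 7, positions = integer()),
                   "AAACTGTAGAA")
  expect_error(mutateSeedSite("ACGT", 3, 7), "outside")
  expect_error(mutateSeedSite("AAACTGTAGAA", 3, 7, positions = 9),
               "within the site")
})

test_that("planted count fold changes obey the law of large numbers", {
  sim <- simulateCounts(50, samplesPerCondition = 200,
                        baselineMeanRange = c(200, 500),
                        plantedLog2fc = -1, seed = 21)
  m <- SummarizedExperiment::assay(sim$counts)
  cond <- conditionOf(sim$counts)
  ratio <- rowMeans(m[, cond == "mutant"]) / rowMeans(m[, cond == "control"])
  expect_true(all(abs(ratio - 0.5) < 0.05))

  nullSim <- simulateCounts(50, samplesPerCondition = 200,
                            baselineMeanRange = c(200, 500), seed = 22)
  m0 <- SummarizedExperiment::assay(nullSim$counts)
  cond0 <- conditionOf(nullSim$counts)
  lfc0 <- log2(rowMeans(m0[, cond0 == "mutant"]) /
                 rowMeans(m0[, cond0 == "control"]))
  expect_lt(median(abs(lfc0)), 0.05)
})

test_that("multi-dataset planting is self-consistent with its truth", {
  spec <- data.frame(mir_id = c("mir_0003", "mir_0010", "mir_0020"),
                     n_datasets_sig = c(6L, 4L, 2L),
                     direction = c("down", "down", "up"))
  sim <- simulateMultiDatasetDe(nMirs = 100, plantSpec = spec, seed = 17)
  plan <- plantedConsensus(sim$truth)
  for (i in seq_len(nrow(plan))) {
    hits <- vapply(sim$tables, function(t) {
      row <- t[t$feature_id == plan$mir_id[i], ]
      row$padj < 0.05 && abs(row$log2fc) > 0.5 &&
        sign(row$log2fc) == if (plan$direction[i] == "down") -1 else 1
    }, NA)
    expect_identical(sum(hits), plan$n_datasets_sig[i])
    expect_identical(which(unname(hits)), plan$datasets[[i]])
  }

  empty <- simulateMultiDatasetDe(nMirs = 20, seed = 2)
  expect_identical(nrow(plantedConsensus(empty$truth)), 0L)

  dup <- data.frame(mir_id = c("mir_0001", "mir_0001"),
                    n_datasets_sig = c(3L, 3L),
                    direction = c("down", "down"))
  expect_error(simulateMultiDatasetDe(nMirs = 10, plantSpec = dup),
               "duplicate")
  expect_error(simulateMultiDatasetDe(nMirs = 10, plantSpec = data.frame(
    mir_id = "mir_0001", n_datasets_sig = 7L, direction = "down")),
    "exceed")
})

test_that("host-gene experiments respect their scenario and geometry", {
  gm <- simulateGeneModels(8)
  introns <- buildIntronSet(gm$models)

  ex <- simulateHostGeneExperiment(gm$models, gm$hostMap,
                                   scenario = "null", seed = 19)
  counts <- countIntronicReads(ex$reads, introns)
  pf <- priFoldChange(counts, ex$condition, "control", "mutant")
  expect_true(all(abs(pf$pri_log2fc) < 0.25))
  de <- deContrast(ex$mature, "control", "mutant")
  expect_true(all(abs(de$log2fc) < 0.4))

  # per-gene intronic counts sit at the requested depth (Poisson spread)
  expect_true(all(abs(counts - 500) < 5 * sqrt(500)))

  expect_error(simulateHostGeneExperiment(gm$models, gm$hostMap,
                                          readLength = 5000),
               "shorter than")
})
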