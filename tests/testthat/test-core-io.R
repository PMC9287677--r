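test_that("FASTA readers parse, uppercase and validate records", {
  p <- writeTempFasta(list(gene1 = strrep("ACGTN", 6),
                           gene2 = tolower(strrep("ACGTACGTAC", 5))))
  utrs <- readUtrFasta(p)
  expect_identical(names(utrs), c("gene1", "gene2"))
  expect_identical(unname(Biostrings::width(utrs)), c(30L, 50L))
  expect_identical(as.character(utrs[["gene2"]]), strrep("ACGTACGTAC", 5))

  bad <- writeTempFasta(list(geneX = "ACGTXACGT"))
  expect_error(readUtrFasta(bad), "geneX")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_warning(res <- readUtrFasta(empty), "empty")
  expect_length(res, 0L)

  dup <- writeTempFasta(list(g1 = "ACGT"))
  cat(">g1\nACGT\n", file = dup, append = TRUE)
  expect_error(readUtrFasta(dup), "duplicate")

  mir <- writeTempFasta(list(m1 = "ucuacagug"))
  expect_identical(as.character(readMirnaFasta(mir)[[1L]]), "UCUACAGUG")
  dna <- writeTempFasta(list(m1 = "TCTACAGTG"))
  expect_error(readMirnaFasta(dna), "m1")
})

test_that("GTF import converts coordinates and merges exons per gene", {
  p <- writeTempGtf(list(
    list(chrom = "chr1", type = "gene", start = 101, end = 1000,
         strand = "+", gene_id = "gA"),
    list(chrom = "chr1", type = "exon", start = 101, end = 200,
         strand = "+", gene_id = "gA"),
    list(chrom = "chr1", type = "exon", start = 801, end = 1000,
         strand = "+", gene_id = "gA"),
    # a second transcript whose exon overlaps the first: must merge
    list(chrom = "chr1", type = "exon", start = 150, end = 220,
         strand = "+", gene_id = "gA")))
  gm <- readGtfModels(p)
  span <- geneSpans(gm)["gA"]
  expect_identical(GenomicRanges::start(span), 101L)
  expect_identical(GenomicRanges::end(span), 1000L)
  ex <- exonRanges(gm)[["gA"]]
  expect_identical(GenomicRanges::start(ex), c(101L, 801L))
  expect_identical(GenomicRanges::end(ex), c(220L, 1000L))
})

test_that("GTF validation rejects malformed models", {
  outside <- writeTempGtf(list(
    list(chrom = "chr1", type = "gene", start = 101, end = 500,
         strand = "+", gene_id = "gA"),
    list(chrom = "chr1", type = "exon", start = 400, end = 600,
         strand = "+", gene_id = "gA")))
  expect_error(readGtfModels(outside), "outside.*gA")

  reversed <- writeTempGtf(list(
    list(chrom = "chr1", type = "gene", start = 101, end = 500,
         strand = "+", gene_id = "gA"),
    list(chrom = "chr1", type = "exon", start = 300, end = 200,
         strand = "+", gene_id = "gA")))
  expect_error(readGtfModels(reversed))

  noId <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\ttest\texon\t100\t200\t.\t+\t.\tfoo \"bar\";", noId)
  expect_error(readGtfModels(noId), "gene_id")
})

test_that("BED intervals are converted from 0-based half-open", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t199\t210", p)
  gr <- readBedIntervals(p)
  expect_identical(GenomicRanges::start(gr), 200L)
  expect_identical(GenomicRanges::end(gr), 210L)
  expect_identical(GenomicRanges::width(gr), 11L)

  # round trip through write/read is the identity on coordinates
  p2 <- withr::local_tempfile(fileext = ".bed")
  writeBedIntervals(gr, p2)
  gr2 <- readBedIntervals(p2)
  expect_identical(GenomicRanges::start(gr2), GenomicRanges::start(gr))
  expect_identical(GenomicRanges::end(gr2), GenomicRanges::end(gr))
})

test_that("GMT layout round-trips and is validated", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescr\tg1\tg2", "setB\tother\tg2\tg3\tg4"), p)
  sets <- readGmt(p)
  expect_identical(sets$setA, c("g1", "g2"))
  expect_identical(sets$setB, c("g2", "g3", "g4"))

  p2 <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, p2, descriptions = attr(sets, "description"))
  again <- readGmt(p2)
  expect_identical(unclass(again)[names(sets)], unclass(sets)[names(sets)])

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("setA\tdescr", bad)
  expect_error(readGmt(bad), "at least one gene")
})

test_that("DE tables round-trip bit-for-bit and enforce their schema", {
  de <- data.frame(feature_id = c("a", "b", "c"),
                   log2fc = c(-1.234567890123456, 0, 2/3),
                   pvalue = c(1e-8, 0.5, 1),
                   padj = c(3e-8, 0.75, 1),
                   base_mean = c(10.5, NA, 0))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeDeTable(de, p)
  back <- readDeTable(p)
  expect_identical(back, de)

  noCols <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlfc", "a\t1"), noCols)
  expect_error(readDeTable(noCols), "log2fc.*pvalue|pvalue.*log2fc")

  expect_error(validateDeTable(
    data.frame(feature_id = c("a", "a"), log2fc = 0, pvalue = 0.5)),
    "duplicate")
  expect_error(validateDeTable(
    data.frame(feature_id = "a", log2fc = 0, pvalue = 2)), "\\[0, 1\\]")
  expect_error(validateDeTable(
    data.frame(feature_id = "a", log2fc = 0, pvalue = 0.5, padj = 0.1)),
    "BH")
})

test_that("count matrices round-trip and reject non-counts", {
  m <- matrix(c(0L, 5L, 2L, 7L, 1L, 9L), 2, 3,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTsv(m, p)
  expect_identical(readCountsTsv(p), m)

  se <- makeCountMatrix(m, c("x", "x", "y"))
  expect_identical(conditionOf(se), c("x", "x", "y"))
  writeCountsTsv(se, p)
  expect_identical(readCountsTsv(p), m)

  expect_error(makeCountMatrix(matrix(-1, 1, 1,
    dimnames = list("f", "s")), "x"), "nonnegative")
  expect_error(makeCountMatrix(matrix(1.5, 1, 1,
    dimnames = list("f", "s")), "x"), "integer")
})

test_that("host maps require a unique host gene per miRNA", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mir_id\thost_gene_id", "mir-1\tGENE1", "mir-2\tGENE2"), p)
  hm <- readHostMap(p)
  expect_identical(hm$host_gene_id, c("GENE1", "GENE2"))
  writeLines(c("mir_id\thost_gene_id", "mir-1\tGENE1", "mir-1\tGENE2"), p)
  expect_error(readHostMap(p), "exactly one")
})
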