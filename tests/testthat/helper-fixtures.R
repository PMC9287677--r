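# Shared fixtures, built in code at test time.

# An arbitrary MN-enriched-style mature miRNA sequence, 23 nt (long enough
# for a 7mer scan up to start position 15+).
testMirna <- function() c(mirna = "UCUACAGUGCACGUGUCUCCAGU")

writeTempFasta <- function(records, ext = ".fa") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Minimal GTF writer (1-based inclusive coordinates).
writeTempGtf <- function(rows) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  lines <- vapply(rows, function(r) {
    paste(r$chrom, "test", r$type, r$start, r$end, ".", r$strand, ".",
          paste0('gene_id "', r$gene_id, '"; transcript_id "',
                 r$gene_id, '.t1";'),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  path
}

# A tiny two-gene annotation: gA with two exons and one intron, gB nested
# inside gA's intron (its exon must be subtracted from gA's introns).
twoGeneModels <- function() {
  g <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301), c(1000, 400)), strand = c("+", "+"))
  names(g) <- c("gA", "gB")
  e <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 801), c(200, 1000)), strand = "+"),
    gB = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(301, 400), strand = "+"))
  GeneModelSet(g, e)
}

# Random gene models with irregular exon structure for oracle tests.
randomGeneModels <- function(nGenes, maxSpan = 10000) {
  starts <- cumsum(sample(500:2000, nGenes)) + seq_len(nGenes) * maxSpan
  ids <- sprintf("rg_%03d", seq_len(nGenes))
  spans <- integer(nGenes)
  exl <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    span <- sample(2000:maxSpan, 1)
    spans[i] <- span
    nEx <- sample(1:5, 1)
    bounds <- sort(sample(seq_len(span - 1), 2 * nEx))
    exl[[i]] <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts[i] + bounds[seq(1, 2 * nEx, 2)],
                       starts[i] + bounds[seq(2, 2 * nEx, 2)]),
      strand = "+")
  }
  g <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, starts + spans), strand = "+")
  names(g) <- ids
  names(exl) <- ids
  GeneModelSet(g, GenomicRanges::GRangesList(exl))
}

# Random harmonized input for consensus oracle tests: K datasets, some
# miRNAs unmeasured, a mix of clear signals and borderline values.
randomHarmonized <- function(nMirs = 30, K = 6) {
  mirs <- sprintf("m%03d", seq_len(nMirs))
  lfc <- matrix(stats::rnorm(nMirs * K, 0, 1), nMirs, K,
                dimnames = list(mirs, paste0("d", seq_len(K))))
  pcrit <- matrix(stats::runif(nMirs * K)^2, nMirs, K,
                  dimnames = dimnames(lfc))
  miss <- matrix(stats::runif(nMirs * K) < 0.2, nMirs, K)
  lfc[miss] <- NA
  pcrit[miss] <- NA
  list(lfc = lfc, pcrit = pcrit, measured = !is.na(lfc),
       criteria = stats::setNames(rep("padj", K), colnames(lfc)))
}
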