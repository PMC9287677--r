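#' Gene models: gene spans with merged exon structure
#'
#' Container for a set of gene models: one genomic span per gene plus the
#' merged (reduced, sorted) union of its exons over all transcripts. Introns
#' are derived from it by interval subtraction (see [buildIntronSet()]).
#'
#' @slot genes a [GenomicRanges::GRanges] of gene spans, named by gene id.
#' @slot exons a [GenomicRanges::GRangesList] parallel to `genes`; element
#'   `i` holds the merged exons of gene `i`, each contained in its span.
#'
#' @seealso [readGtfModels()], [simulateGeneModels()], [buildIntronSet()]
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  g <- object@genes
  e <- object@exons
  msg <- character()
  if (length(g) != length(e))
    msg <- c(msg, "genes and exons must have the same length")
  if (is.null(names(g)) || anyDuplicated(names(g)) || any(!nzchar(names(g))))
    msg <- c(msg, "gene ids must be present and unique")
  if (!identical(names(g), names(e)))
    msg <- c(msg, "exon list names must match gene ids")
  if (length(g) && !all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be '+' or '-'")
  if (length(g) == length(e) && length(g)) {
    ne <- S4Vectors::elementNROWS(e)
    has <- ne > 0L
    if (any(has)) {
      rng <- unlist(range(e[has], ignore.strand = TRUE))
      gh <- g[has]
      bad <- GenomicRanges::start(rng) < GenomicRanges::start(gh) |
        GenomicRanges::end(rng) > GenomicRanges::end(gh) |
        as.character(GenomicRanges::seqnames(rng)) !=
          as.character(GenomicRanges::seqnames(gh))
      if (any(bad))
        msg <- c(msg, paste0("exons outside gene span for: ",
                             paste(names(gh)[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#'
#' @param genes named `GRanges` of gene spans (names are gene ids).
#' @param exons `GRangesList` parallel to `genes` with each gene's exons;
#'   exons are merged (reduced) and sorted on construction.
#' @return a validated [GeneModelSet-class] object.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 1000), "+")
#' names(g) <- "gA"
#' e <- GenomicRanges::GRangesList(
#'   gA = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 801), c(200, 1000))))
#' gm <- GeneModelSet(g, e)
#' geneIds(gm)
#' @export
GeneModelSet <- function(genes, exons) {
  exons <- GenomicRanges::reduce(exons)
  if (is.null(names(exons)) && !is.null(names(genes)) &&
      length(exons) == length(genes))
    names(exons) <- names(genes)
  new("GeneModelSet", genes = genes, exons = exons)
}

#' @describeIn GeneModelSet-class gene identifiers
#' @param x a `GeneModelSet`
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@genes))

#' @describeIn GeneModelSet-class gene spans as a named `GRanges`
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneSpans", "GeneModelSet", function(x) x@genes)

#' @describeIn GeneModelSet-class merged exons as a named `GRangesList`
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModelSet-class
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "genes\n")
  if (length(object@genes)) {
    ne <- S4Vectors::elementNROWS(object@exons)
    cat("  exons per gene:", paste(range(ne), collapse = "-"),
        "| intronless genes:", sum(ne <= 1L), "\n")
  }
  invisible(object)
})

#' Planted ground truth of a synthetic scenario
#'
#' Every generator in the package returns, alongside the data, a `SimTruth`
#' recording exactly what was planted: target genes and their seed-site
#' positions, per-feature log2 fold changes, cross-dataset significance
#' plans, and the pri-miRNA regulation scenario. Downstream recovery tests
#' consume the truth object only; they never re-derive it from the data.
#'
#' @slot targetGenes character, gene ids carrying planted seed sites.
#' @slot sites data.frame with columns `gene_id`, `offset` (1-based start of
#'   the planted site in the UTR), `word` (the planted DNA site word).
#' @slot log2fc named numeric, planted per-feature log2 fold changes.
#' @slot consensus data.frame with columns `mir_id`, `n_datasets_sig`,
#'   `direction` and list-column `datasets` (indices where planted).
#' @slot scenario character, one of `"transcriptional"`, `"processing"`,
#'   `"null"` (empty when not a host-gene simulation).
#' @slot scenarioByFeature named character, scenario per host gene.
#' @slot nbDispersion numeric, negative-binomial dispersion used.
#' @slot seed integer seed the generator ran under.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(targetGenes = "character", sites = "data.frame",
    log2fc = "numeric", consensus = "data.frame", scenario = "character",
    scenarioByFeature = "character", nbDispersion = "numeric",
    seed = "integer"),
  prototype(targetGenes = character(), sites = data.frame(),
    log2fc = numeric(), consensus = data.frame(), scenario = character(),
    scenarioByFeature = character(), nbDispersion = numeric(),
    seed = NA_integer_))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (nrow(object@sites) &&
      !all(c("gene_id", "offset", "word") %in% names(object@sites)))
    msg <- c(msg, "sites must have gene_id, offset, word columns")
  if (length(object@scenario) > 1L)
    msg <- c(msg, "scenario must be length 0 or 1")
  if (length(object@scenario) == 1L &&
      !object@scenario %in% c("transcriptional", "processing", "null"))
    msg <- c(msg, "scenario must be transcriptional, processing or null")
  if (length(msg)) msg else TRUE
})

SimTruth <- function(targetGenes = character(), sites = data.frame(),
                     log2fc = numeric(), consensus = data.frame(),
                     scenario = character(),
                     scenarioByFeature = character(),
                     nbDispersion = numeric(), seed = NA_integer_) {
  new("SimTruth", targetGenes = targetGenes, sites = sites, log2fc = log2fc,
      consensus = consensus, scenario = scenario,
      scenarioByFeature = scenarioByFeature, nbDispersion = nbDispersion,
      seed = as.integer(seed))
}

#' @describeIn SimTruth-class gene ids carrying planted seed sites
#' @param x a `SimTruth`
#' @export
setGeneric("plantedTargets", function(x) standardGeneric("plantedTargets"))

#' @rdname SimTruth-class
#' @export
setMethod("plantedTargets", "SimTruth", function(x) x@targetGenes)

#' @describeIn SimTruth-class planted site table (gene_id, offset, word)
#' @export
setGeneric("plantedSites", function(x) standardGeneric("plantedSites"))

#' @rdname SimTruth-class
#' @export
setMethod("plantedSites", "SimTruth", function(x) x@sites)

#' @describeIn SimTruth-class named numeric of planted log2 fold changes
#' @export
setGeneric("plantedLog2fc", function(x) standardGeneric("plantedLog2fc"))

#' @rdname SimTruth-class
#' @export
setMethod("plantedLog2fc", "SimTruth", function(x) x@log2fc)

#' @describeIn SimTruth-class planted cross-dataset significance plan
#' @export
setGeneric("plantedConsensus", function(x) standardGeneric("plantedConsensus"))

#' @rdname SimTruth-class
#' @export
setMethod("plantedConsensus", "SimTruth", function(x) x@consensus)

#' @describeIn SimTruth-class regulation scenario of a host-gene simulation
#' @export
setGeneric("simScenario", function(x) standardGeneric("simScenario"))

#' @rdname SimTruth-class
#' @export
setMethod("simScenario", "SimTruth", function(x) x@scenario)

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth (seed ", object@seed, ")\n", sep = "")
  if (length(object@targetGenes))
    cat("  planted target genes:", length(object@targetGenes),
        "with", nrow(object@sites), "sites\n")
  if (length(object@log2fc))
    cat("  planted log2fc for", length(object@log2fc), "features; ",
        sum(object@log2fc != 0), "non-null\n")
  if (nrow(object@consensus))
    cat("  consensus plan for", nrow(object@consensus), "miRNAs\n")
  if (length(object@scenario))
    cat("  scenario:", object@scenario, "\n")
  invisible(object)
})

#' Assemble a count matrix with sample conditions
#'
#' Wraps a nonnegative integer matrix (features x samples) and a per-sample
#' condition label into a [SummarizedExperiment::SummarizedExperiment], the
#' container all count-based stages consume.
#'
#' @param counts nonnegative integer matrix with feature row names and
#'   sample column names.
#' @param condition character/factor of length `ncol(counts)`, the condition
#'   label of each sample.
#' @return a `SummarizedExperiment` with assay `"counts"` and
#'   `colData$condition`.
#' @examples
#' m <- matrix(0:5, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' se <- makeCountMatrix(m, c("ctrl", "ctrl", "mut"))
#' conditionOf(se)
#' @export
makeCountMatrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  .assertCounts(counts)
  if (length(condition) != ncol(counts))
    stop("condition must have one label per sample")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
}

#' @rdname makeCountMatrix
#' @param se a `SummarizedExperiment` built by [makeCountMatrix()]
#' @export
conditionOf <- function(se) {
  as.character(SummarizedExperiment::colData(se)$condition)
}

.assertCounts <- function(m) {
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be nonnegative integers")
  invisible(m)
}

## ---- DeTable: plain data.frame with a validated schema -------------------

#' Validate a differential-expression table
#'
#' A DE table is a data.frame with columns `feature_id` (unique strings),
#' `log2fc`, `pvalue` in \[0,1\], and optionally `padj` (each `padj >=
#' pvalue`, the Benjamini-Hochberg property) and `base_mean` (nonnegative).
#' All table-consuming stages validate their inputs with this function.
#'
#' @param de data.frame to validate.
#' @param name label used in error messages.
#' @return `de`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validateDeTable <- function(de, name = "DeTable") {
  req <- c("feature_id", "log2fc", "pvalue")
  miss <- setdiff(req, names(de))
  if (length(miss))
    stop(name, ": missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(de$feature_id))
    stop(name, ": duplicate feature_id values (e.g. '",
         de$feature_id[duplicated(de$feature_id)][1L], "')")
  if (!is.numeric(de$log2fc) || !is.numeric(de$pvalue))
    stop(name, ": log2fc and pvalue must be numeric")
  p <- de$pvalue
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop(name, ": pvalue outside [0, 1]")
  if ("padj" %in% names(de)) {
    q <- de$padj
    if (any(!is.na(q) & (q < 0 | q > 1)))
      stop(name, ": padj outside [0, 1]")
    bad <- !is.na(q) & !is.na(p) & q < p - 1e-12
    if (any(bad))
      stop(name, ": padj < pvalue for '", de$feature_id[bad][1L],
           "' (violates the BH step-up property)")
  }
  if ("base_mean" %in% names(de) &&
      any(!is.na(de$base_mean) & de$base_mean < 0))
    stop(name, ": base_mean must be nonnegative")
  invisible(de)
}

.assertHostMap <- function(hm) {
  req <- c("mir_id", "host_gene_id")
  miss <- setdiff(req, names(hm))
  if (length(miss))
    stop("host map: missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(hm$mir_id))
    stop("host map: each mir_id must map to exactly one host gene; ",
         "duplicated: ", hm$mir_id[duplicated(hm$mir_id)][1L])
  invisible(hm)
}
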