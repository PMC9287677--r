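## pri-miRNA transcription inference for intronic miRNAs: intron
## derivation by interval subtraction, containment counting of reads,
## intron-anchored fold changes, mature-vs-pri correlation, and the
## transcriptional / post-transcriptional scenario classifier.

#' Intronic regions of host genes
#'
#' The intron set of a host gene is its span minus the merged exons of
#' *every* gene overlapping that span (not just the host's own), so a
#' neighbour's exonic signal is never counted as intronic. An exonless
#' annotation yields the whole span with a warning; an intronless host
#' yields an empty set with a warning.
#'
#' @param models a [GeneModelSet-class].
#' @param hostGenes gene ids to derive introns for (default: all genes).
#' @return a named `GRangesList` of disjoint, sorted intronic intervals.
#' @export
buildIntronSet <- function(models, hostGenes = geneIds(models)) {
  unknown <- setdiff(hostGenes, geneIds(models))
  if (length(unknown))
    stop("unknown host gene(s): ", paste(unknown, collapse = ", "))
  spans <- BiocGenerics::unstrand(geneSpans(models)[hostGenes])
  exons <- exonRanges(models)
  allExons <- BiocGenerics::unstrand(unlist(exons, use.names = FALSE))
  hasExons <- S4Vectors::elementNROWS(exons)[hostGenes] > 0L
  if (any(!hasExons))
    warning("genes without annotated exons (whole span kept as ",
            "intronic): ", paste(hostGenes[!hasExons], collapse = ", "))
  ## exons of every overlapping gene, grouped per host span, subtracted
  ## elementwise
  hits <- GenomicRanges::findOverlaps(spans, allExons,
                                      ignore.strand = TRUE)
  exPer <- IRanges::extractList(allExons,
    S4Vectors::split(S4Vectors::subjectHits(hits),
                     factor(S4Vectors::queryHits(hits),
                            seq_along(spans))))
  out <- GenomicRanges::psetdiff(spans, GenomicRanges::reduce(exPer))
  out[!hasExons] <- methods::as(spans[!hasExons], "GRangesList")
  names(out) <- hostGenes
  empty <- hasExons & S4Vectors::elementNROWS(out) == 0L
  if (any(empty))
    warning("intronless host gene(s) after exon subtraction: ",
            paste(hostGenes[empty], collapse = ", "))
  out
}

#' @rdname buildIntronSet
#' @param hostGeneId a single host gene id.
#' @return `intronicRegions`: a `GRanges` for one host gene.
#' @export
intronicRegions <- function(models, hostGeneId) {
  stopifnot(length(hostGeneId) == 1L)
  buildIntronSet(models, hostGeneId)[[1L]]
}

#' Count reads fully contained in intronic intervals
#'
#' A read contributes to a host gene only if it lies entirely inside one of
#' the gene's intronic intervals; any overlap with an exon or an
#' exon-intron junction disqualifies it, because only unambiguously
#' unspliced (primary-transcript) signal is wanted. Each read counts at
#' most once per gene.
#'
#' @param reads named list of per-sample `GRanges` (or a `GRangesList`).
#' @param introns named `GRangesList` from [buildIntronSet()].
#' @return integer matrix, host genes x samples.
#' @export
countIntronicReads <- function(reads, introns) {
  if (methods::is(reads, "GRangesList")) reads <- as.list(reads)
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must be a uniquely named per-sample list")
  genes <- names(introns)
  flat <- unlist(introns, use.names = FALSE)
  geneOf <- rep(genes, S4Vectors::elementNROWS(introns))
  m <- matrix(0L, length(genes), length(reads),
              dimnames = list(genes, names(reads)))
  for (s in seq_along(reads)) {
    r <- reads[[s]]
    if (length(r) == 0L || length(flat) == 0L) next
    hits <- GenomicRanges::findOverlaps(r, flat, type = "within",
                                        ignore.strand = TRUE)
    if (length(hits) == 0L) next
    gIdx <- match(geneOf[S4Vectors::subjectHits(hits)], genes)
    key <- (as.numeric(S4Vectors::queryHits(hits)) - 1) *
      length(genes) + gIdx
    gIdx <- gIdx[!duplicated(key)]
    m[, s] <- tabulate(gIdx, nbins = length(genes))
  }
  m
}

#' Intron-anchored pri-miRNA fold changes
#'
#' Size factors come from total *intronic* counts per sample (so changes in
#' exonic amplitude cannot masquerade as pri-miRNA changes); the fold
#' change is `log2` of normalized condition means with a pseudocount,
#' relative to `conditionA` as baseline. Genes whose total intronic count
#' across the contrast is below `minCount` are flagged low-coverage and get
#' `NA`.
#'
#' @param intronic integer matrix (host genes x samples) from
#'   [countIntronicReads()], or a `SummarizedExperiment`.
#' @param condition per-sample condition labels.
#' @param conditionA,conditionB baseline and contrast labels.
#' @param pseudocount added to normalized means (default 0.5).
#' @param minCount minimum total intronic count per gene before a fold
#'   change is reported (default 20).
#' @return data.frame with `host_gene_id`, `pri_log2fc` (`NA` when
#'   low-coverage), `total_count`, `low_coverage`.
#' @export
priFoldChange <- function(intronic, condition = NULL, conditionA,
                          conditionB, pseudocount = 0.5, minCount = 20) {
  if (methods::is(intronic, "SummarizedExperiment")) {
    condition <- conditionOf(intronic)
    intronic <- SummarizedExperiment::assay(intronic, "counts")
  }
  if (is.null(condition) || length(condition) != ncol(intronic))
    stop("condition labels must be supplied for every sample")
  a <- which(condition == conditionA)
  b <- which(condition == conditionB)
  if (length(a) == 0L || length(b) == 0L)
    stop("both conditions must be present among the samples")
  m <- intronic[, c(a, b), drop = FALSE]
  tot <- colSums(m)
  if (any(tot == 0)) stop("a sample has zero intronic counts in total")
  sf <- tot / exp(mean(log(tot)))
  norm <- sweep(m, 2, sf, "/")
  mA <- rowMeans(norm[, seq_along(a), drop = FALSE])
  mB <- rowMeans(norm[, seq_along(b) + length(a), drop = FALSE])
  lfc <- log2(mB + pseudocount) - log2(mA + pseudocount)
  totalCount <- rowSums(m)
  low <- totalCount < minCount
  lfc[low] <- NA_real_
  data.frame(host_gene_id = rownames(m), pri_log2fc = lfc,
             total_count = totalCount, low_coverage = low,
             row.names = NULL)
}

#' Correlate mature miRNA and pri-miRNA (host intron) fold changes
#'
#' Joins mature-miRNA log2 fold changes to host-gene intronic fold changes
#' through the miRNA-to-host map, excludes low-coverage hosts, and reports
#' both rank (Spearman) and linear (Pearson) correlations — a strong
#' positive correlation indicates that mature-miRNA changes are largely
#' transcriptional. Each retained pair also receives a per-miRNA scenario
#' call from [classifyRegulation()].
#'
#' @param matureDe DE table of mature miRNAs (`feature_id` = mir ids).
#' @param priLfc output of [priFoldChange()].
#' @param hostMap data.frame with `mir_id`, `host_gene_id`.
#' @param lfcThreshold,concordanceFraction passed to [classifyRegulation()].
#' @return list with `correlation` (`n_mirs`, `rho`, `rho_p`, `r`, `r_p`),
#'   `rows` (per-miRNA table with `scenario_call`), and `excluded` (mir ids
#'   lacking either measurement or low-coverage).
#' @export
correlateMatureVsPri <- function(matureDe, priLfc, hostMap,
                                 lfcThreshold = 0.5,
                                 concordanceFraction = 0.5) {
  validateDeTable(matureDe, "matureDe")
  .assertHostMap(hostMap)
  mat <- matureDe$log2fc[match(hostMap$mir_id, matureDe$feature_id)]
  idx <- match(hostMap$host_gene_id, priLfc$host_gene_id)
  pri <- priLfc$pri_log2fc[idx]
  keep <- !is.na(mat) & !is.na(pri)
  excluded <- hostMap$mir_id[!keep]
  if (sum(keep) < 3L)
    stop("fewer than 3 miRNAs with both mature and pri measurements (",
         sum(keep), ")")
  mat <- mat[keep]; pri <- pri[keep]
  sp <- stats::cor.test(mat, pri, method = "spearman", exact = FALSE)
  pe <- stats::cor.test(mat, pri, method = "pearson")
  rows <- data.frame(
    mir_id = hostMap$mir_id[keep],
    host_gene_id = hostMap$host_gene_id[keep],
    mature_log2fc = mat, pri_log2fc = pri,
    scenario_call = classifyRegulation(mat, pri,
                                       lfcThreshold = lfcThreshold,
                                       concordanceFraction =
                                         concordanceFraction),
    row.names = NULL)
  list(correlation = list(n_mirs = sum(keep),
                          rho = unname(sp$estimate), rho_p = sp$p.value,
                          r = unname(pe$estimate), r_p = pe$p.value),
       rows = rows, excluded = excluded)
}

#' Classify transcriptional versus post-transcriptional regulation
#'
#' Given a mature-miRNA and a pri-miRNA (host intron) log2 fold change:
#' `transcriptional` when the mature change is substantial
#' (`|mature| >= lfcThreshold`), same-signed, and the pri change carries at
#' least `concordanceFraction` of its magnitude; `discordant` when both are
#' substantial but opposite-signed; `post_transcriptional` when the mature
#' change is substantial but the pri change is proportionally small
#' (implicating biogenesis downstream of transcription); `unchanged`
#' otherwise. Vectorized.
#'
#' @param matureLog2fc,priLog2fc numeric vectors (recycled to a common
#'   length).
#' @param lfcThreshold minimum absolute mature log2fc to call a change
#'   (default 0.5).
#' @param concordanceFraction fraction of the mature magnitude the pri
#'   change must reach to be called transcriptional (default 0.5).
#' @return character vector of scenario calls.
#' @examples
#' classifyRegulation(c(-1, -1, -0.1), c(-0.8, 0.05, -0.1))
#' @export
classifyRegulation <- function(matureLog2fc, priLog2fc, lfcThreshold = 0.5,
                               concordanceFraction = 0.5) {
  n <- max(length(matureLog2fc), length(priLog2fc))
  mat <- rep_len(matureLog2fc, n)
  pri <- rep_len(priLog2fc, n)
  if (any(is.na(mat)) || any(is.na(pri)))
    stop("both fold changes must be present for every call")
  out <- rep("unchanged", n)
  big <- abs(mat) >= lfcThreshold
  concord <- abs(pri) >= concordanceFraction * abs(mat)
  sameSign <- sign(mat) == sign(pri)
  out[big & sameSign & concord] <- "transcriptional"
  out[big & !sameSign & abs(pri) >= lfcThreshold] <- "discordant"
  out[big & !concord &
        !(big & !sameSign & abs(pri) >= lfcThreshold)] <-
    "post_transcriptional"
  out
}
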