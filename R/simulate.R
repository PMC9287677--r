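## Synthetic-data generators. Every generator takes an explicit integer
## seed, isolates the RNG with withr::with_seed (identical parameters +
## seed => bit-identical output), and returns the planted ground truth as
## a SimTruth alongside the data.

#' Simulate a 3' UTR set with planted seed sites
#'
#' Background UTRs are i.i.d. per-base at the requested GC content; a
#' `targetFraction` of genes additionally carry planted seed sites — the
#' DNA reverse complement of the miRNA's canonical seed word (positions
#' 2-8) — at recorded, non-overlapping offsets. The truth object lists
#' every planted `(gene, offset, word)`, so a positional seed scan is
#' expected to place its minimum adjusted p at start position 2.
#'
#' @param nGenes number of UTRs.
#' @param lengthRange integer range of UTR lengths (uniform).
#' @param gcContent background GC fraction (default 0.45, typical of
#'   human 3' UTRs).
#' @param mirna miRNA whose seed is planted (see [mirnaWords()] input
#'   forms).
#' @param targetFraction fraction of genes receiving sites (0..1).
#' @param sitesPerTarget planted sites per target gene (default 1).
#' @param seed integer seed.
#' @return list with `utrs` (named `DNAStringSet`) and `truth`
#'   ([SimTruth-class]).
#' @export
simulateUtrSet <- function(nGenes, lengthRange = c(200, 600),
                           gcContent = 0.45, mirna, targetFraction = 0.3,
                           sitesPerTarget = 1, seed = 1) {
  if (targetFraction < 0 || targetFraction > 1)
    stop("targetFraction must lie in [0, 1]")
  seedWord <- substring(.asMirnaSeq(mirna)$seq, 2, 8)
  site <- seedSiteWord(seedWord)
  k <- nchar(site)
  if (lengthRange[1L] < k)
    stop("minimum UTR length must be at least the site length (", k, ")")
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("gene_%04d", seq_len(nGenes))
    lens <- sample(seq.int(lengthRange[1L], lengthRange[2L]), nGenes,
                   replace = TRUE)
    probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
               G = gcContent / 2, T = (1 - gcContent) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), "")
    names(seqs) <- ids
    nTargets <- round(nGenes * targetFraction)
    targets <- sort(sample(ids, nTargets))
    sites <- list()
    for (g in targets) {
      L <- nchar(seqs[[g]])
      offsets <- .placeSites(L, k, sitesPerTarget)
      for (off in offsets)
        substr(seqs[[g]], off, off + k - 1L) <- site
      sites[[g]] <- data.frame(gene_id = g, offset = offsets, word = site)
    }
    sites <- if (length(sites)) do.call(rbind, c(sites, make.row.names = FALSE))
      else data.frame(gene_id = character(), offset = integer(),
                      word = character())
    list(utrs = Biostrings::DNAStringSet(seqs),
         truth = SimTruth(targetGenes = targets, sites = sites,
                          seed = seed))
  })
}

## non-overlapping site offsets; bounded retries, then error
.placeSites <- function(utrLen, k, nSites, maxTries = 100L) {
  if (utrLen < nSites * k)
    stop("UTR of length ", utrLen, " cannot host ", nSites,
         " non-overlapping sites of length ", k)
  for (tries in seq_len(maxTries)) {
    off <- sort(sample.int(utrLen - k + 1L, nSites))
    if (nSites == 1L || all(diff(off) >= k)) return(off)
  }
  stop("failed to place ", nSites, " non-overlapping sites in a UTR of ",
       "length ", utrLen, " after ", maxTries, " tries")
}

#' Delete positions of a planted seed site
#'
#' Emulates the site-mutagenesis control used in reporter assays: given the
#' location of a predicted miRNA binding site in a UTR, deletes selected
#' positions (1-based within the site; by default 2, 4 and 6), shrinking
#' the sequence by the number of deleted bases and leaving the flanks
#' untouched.
#'
#' @param utrSequence character UTR sequence.
#' @param siteOffset 1-based start of the site in the sequence.
#' @param siteLength site length in nt.
#' @param positions 1-based positions within the site to delete.
#' @return the mutated sequence.
#' @examples
#' mutateSeedSite("AAACTGTAGAA", 3, 7)  # site ACTGTAG -> ATTG
#' @export
mutateSeedSite <- function(utrSequence, siteOffset, siteLength,
                           positions = c(2, 4, 6)) {
  L <- nchar(utrSequence)
  if (siteOffset < 1 || siteOffset + siteLength - 1 > L)
    stop("site [", siteOffset, ", ", siteOffset + siteLength - 1,
         "] falls outside the sequence (length ", L, ")")
  if (length(positions) == 0L) return(utrSequence)
  if (any(positions < 1 | positions > siteLength))
    stop("positions must lie within the site (1..", siteLength, ")")
  chars <- strsplit(utrSequence, "")[[1L]]
  drop <- siteOffset + unique(positions) - 1L
  paste(chars[-drop], collapse = "")
}

#' Simulate a two-condition negative-binomial count matrix
#'
#' Feature-wise NB counts with a shared dispersion; the second condition's
#' mean is the first's scaled by `2^plantedLog2fc`. The truth records the
#' planted values for every feature.
#'
#' @param nFeatures number of features.
#' @param samplesPerCondition samples in each of the two conditions.
#' @param baselineMeanRange uniform range of baseline means.
#' @param nbDispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param plantedLog2fc named numeric of planted log2 fold changes
#'   (unnamed features get 0), or a single value recycled to all features,
#'   or `NULL` for an all-null matrix.
#' @param conditions labels for the two conditions.
#' @param seed integer seed.
#' @return list with `counts` (a `SummarizedExperiment`) and `truth`.
#' @export
simulateCounts <- function(nFeatures, samplesPerCondition = 3,
                           baselineMeanRange = c(50, 500),
                           nbDispersion = 0.05, plantedLog2fc = NULL,
                           conditions = c("control", "mutant"), seed = 1) {
  if (nbDispersion <= 0) stop("dispersion must be positive")
  if (length(conditions) != 2L) stop("exactly two condition labels required")
  ids <- sprintf("feat_%04d", seq_len(nFeatures))
  lfc <- stats::setNames(rep(0, nFeatures), ids)
  if (!is.null(plantedLog2fc)) {
    if (is.null(names(plantedLog2fc))) {
      lfc[] <- rep_len(plantedLog2fc, nFeatures)
    } else {
      unknown <- setdiff(names(plantedLog2fc), ids)
      if (length(unknown)) stop("planted features not in matrix: ",
                                unknown[1L])
      lfc[names(plantedLog2fc)] <- plantedLog2fc
    }
  }
  withr::with_seed(as.integer(seed), {
    mu <- stats::runif(nFeatures, baselineMeanRange[1L],
                       baselineMeanRange[2L])
    size <- 1 / nbDispersion
    n <- samplesPerCondition
    mA <- matrix(stats::rnbinom(nFeatures * n, size = size, mu = mu),
                 nFeatures, n)
    mB <- matrix(stats::rnbinom(nFeatures * n, size = size,
                                mu = mu * 2^lfc), nFeatures, n)
    m <- cbind(mA, mB)
    dimnames(m) <- list(ids, paste0(rep(conditions, each = n), "_",
                                    rep(seq_len(n), 2L)))
    list(counts = makeCountMatrix(m, rep(conditions, each = n)),
         truth = SimTruth(log2fc = lfc, nbDispersion = nbDispersion,
                          seed = seed))
  })
}

#' Simulate differential-expression tables across several datasets
#'
#' Emulates a cross-dataset miRNA meta-comparison: each planted miRNA is
#' made significant (tiny p, `|log2fc|` in `plantedLfcRange` with the
#' stated direction) in exactly `n_datasets_sig` randomly chosen datasets
#' and null elsewhere; non-planted miRNAs are null everywhere (log2fc ~
#' Normal(0, `nullLfcSd`), p ~ Uniform). Adjusted p-values are BH per
#' table.
#'
#' @param nDatasets number of datasets (default 6).
#' @param nMirs miRNAs per dataset.
#' @param plantSpec data.frame with `mir_id`, `n_datasets_sig`, `direction`
#'   (`"down"`/`"up"`); `NULL` for all-null tables.
#' @param nullLfcSd standard deviation of null log2 fold changes
#'   (default 0.15).
#' @param plantedLfcRange magnitude range of planted log2 fold changes
#'   (default `c(1, 2)`).
#' @param seed integer seed.
#' @return list with `tables` (named list of DE tables) and `truth`
#'   (consensus plan with the chosen dataset indices).
#' @export
simulateMultiDatasetDe <- function(nDatasets = 6, nMirs = 200,
                                   plantSpec = NULL, nullLfcSd = 0.15,
                                   plantedLfcRange = c(1, 2), seed = 1) {
  ids <- sprintf("mir_%04d", seq_len(nMirs))
  if (!is.null(plantSpec)) {
    if (anyDuplicated(plantSpec$mir_id))
      stop("duplicate mir_ids in plantSpec: ",
           plantSpec$mir_id[duplicated(plantSpec$mir_id)][1L])
    if (any(plantSpec$n_datasets_sig > nDatasets))
      stop("n_datasets_sig cannot exceed nDatasets")
    unknown <- setdiff(plantSpec$mir_id, ids)
    if (length(unknown)) stop("planted miRNA not in the panel: ",
                              unknown[1L])
  }
  withr::with_seed(as.integer(seed), {
    plan <- if (is.null(plantSpec) || nrow(plantSpec) == 0L) {
      data.frame(mir_id = character(), n_datasets_sig = integer(),
                 direction = character())
    } else plantSpec
    plan$datasets <- lapply(plan$n_datasets_sig, function(k)
      sort(sample.int(nDatasets, k)))
    tables <- lapply(seq_len(nDatasets), function(d) {
      lfc <- stats::rnorm(nMirs, 0, nullLfcSd)
      p <- stats::runif(nMirs)
      for (i in seq_len(nrow(plan))) {
        if (!d %in% plan$datasets[[i]]) next
        j <- match(plan$mir_id[i], ids)
        mag <- stats::runif(1, plantedLfcRange[1L], plantedLfcRange[2L])
        lfc[j] <- if (plan$direction[i] == "down") -mag else mag
        p[j] <- 10^-stats::runif(1, 6, 12)
      }
      data.frame(feature_id = ids, log2fc = lfc, pvalue = p,
                 padj = bhAdjust(p), row.names = NULL)
    })
    names(tables) <- sprintf("dataset_%d", seq_len(nDatasets))
    list(tables = tables,
         truth = SimTruth(consensus = plan, seed = seed))
  })
}

#' Simulate gene models for host-gene experiments
#'
#' Deterministic layout: `nGenes` genes on one chromosome, each with
#' `nExons` exons of `exonLength` nt separated by introns of
#' `intronLength` nt, genes spaced `spacing` nt apart. Suitable as the
#' annotation for [simulateHostGeneExperiment()].
#'
#' @param nGenes number of host genes.
#' @param chrom chromosome name.
#' @param nExons exons per gene (>= 2 so every gene has introns).
#' @param exonLength,intronLength,spacing geometry in nt.
#' @return list with `models` ([GeneModelSet-class]) and `hostMap`
#'   (data.frame `mir_id`, `host_gene_id`, one intronic miRNA per gene).
#' @export
simulateGeneModels <- function(nGenes, chrom = "chr1", nExons = 3,
                               exonLength = 300, intronLength = 2000,
                               spacing = 2000) {
  if (nExons < 2L) stop("nExons must be at least 2 to create introns")
  geneLen <- nExons * exonLength + (nExons - 1L) * intronLength
  starts <- 1L + (seq_len(nGenes) - 1L) * (geneLen + spacing)
  ids <- sprintf("host_%04d", seq_len(nGenes))
  genes <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(starts, starts + geneLen - 1L), strand = "+")
  names(genes) <- ids
  exStarts <- rep(starts, each = nExons) +
    rep((seq_len(nExons) - 1L) * (exonLength + intronLength), nGenes)
  allExons <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(exStarts, exStarts + exonLength - 1L), strand = "+")
  exons <- S4Vectors::split(allExons,
                            factor(rep(ids, each = nExons), levels = ids))
  list(models = GeneModelSet(genes, exons),
       hostMap = data.frame(mir_id = sprintf("mir_%04d", seq_len(nGenes)),
                            host_gene_id = ids))
}

#' Simulate a host-gene experiment (reads + mature miRNA counts)
#'
#' Two regimes of mature-miRNA regulation, each with planted truth. In the
#' `transcriptional` scenario the host gene's intronic read level *and* the
#' mature miRNA counts scale by `2^priLog2fc` in the second condition — the
#' primary transcript drives the mature change. In the `processing`
#' scenario the mature counts scale by `2^matureLog2fc` while intronic
#' levels stay flat — a biogenesis defect downstream of transcription. The
#' `null` scenario changes nothing. Per-sample read numbers are Poisson
#' around the requested depth; reads are uniform within their compartment
#' (fully inside an intron for intronic reads; starting inside an exon for
#' exonic reads, so some naturally straddle exon-intron junctions and must
#' be rejected by containment counting).
#'
#' @param models,hostMap from [simulateGeneModels()] (or real annotation).
#' @param scenario `"transcriptional"`, `"processing"` or `"null"`.
#' @param priLog2fc planted pri-miRNA log2 fold change, scalar or per-host
#'   vector (default -1.32, a 60% reduction).
#' @param matureLog2fc planted mature log2 fold change used by the
#'   processing scenario, scalar or per-miRNA vector (default -0.51, a
#'   30% reduction).
#' @param intronicDepth expected intronic reads per gene per sample.
#' @param exonicDepth expected exonic reads per gene per sample.
#' @param readLength read length (must be shorter than every intron).
#' @param samplesPerCondition samples per condition.
#' @param matureBaselineMean NB mean of mature counts in the baseline.
#' @param nbDispersion NB dispersion of mature counts.
#' @param conditions the two condition labels.
#' @param seed integer seed.
#' @return list with `reads` (named per-sample list of `GRanges`),
#'   `mature` (`SummarizedExperiment` of mature miRNA counts), `truth`
#'   (scenario, per-gene pri and per-miRNA mature planted log2fc), and
#'   `condition` (per-sample labels, parallel to `reads`).
#' @export
simulateHostGeneExperiment <- function(models, hostMap,
    scenario = c("null", "transcriptional", "processing"),
    priLog2fc = -1.32, matureLog2fc = -0.51, intronicDepth = 500,
    exonicDepth = 200, readLength = 75, samplesPerCondition = 3,
    matureBaselineMean = 200, nbDispersion = 0.05,
    conditions = c("control", "mutant"), seed = 1) {
  scenario <- match.arg(scenario)
  .assertHostMap(hostMap)
  hosts <- hostMap$host_gene_id
  introns <- suppressWarnings(buildIntronSet(models, hosts))
  minIntron <- min(GenomicRanges::width(unlist(introns)))
  if (readLength >= minIntron)
    stop("read length (", readLength, ") must be shorter than the ",
         "shortest intron (", minIntron, ")")
  nH <- length(hosts)
  priEff <- rep_len(priLog2fc, nH)
  matEff <- rep_len(matureLog2fc, nH)
  intronScale <- switch(scenario, transcriptional = 2^priEff,
                        processing = rep(1, nH), null = rep(1, nH))
  matureScale <- switch(scenario, transcriptional = 2^priEff,
                        processing = 2^matEff, null = rep(1, nH))
  exons <- exonRanges(models)[hosts]
  n <- samplesPerCondition
  sampleNames <- paste0(rep(conditions, each = n), "_", rep(seq_len(n), 2L))
  condOf <- rep(conditions, each = n)
  ## flattened interval tables so each sample is built in one pass
  intrFlat <- unlist(introns, use.names = FALSE)
  intrGene <- rep(seq_len(nH), S4Vectors::elementNROWS(introns))
  intrFeas <- GenomicRanges::width(intrFlat) - readLength + 1L
  intrByGene <- split(seq_along(intrFlat), intrGene)
  exFlat <- unlist(exons, use.names = FALSE)
  exGene <- rep(seq_len(nH), S4Vectors::elementNROWS(exons))
  exW <- GenomicRanges::width(exFlat)
  exByGene <- split(seq_along(exFlat), exGene)
  drawIdx <- function(byGene, weights, nPerGene) {
    unlist(lapply(seq_along(byGene), function(i) {
      ii <- byGene[[i]]
      n <- nPerGene[i]
      if (n == 0L) return(integer())
      if (length(ii) == 1L) rep(ii, n) else
        ii[sample.int(length(ii), n, replace = TRUE, prob = weights[ii])]
    }), use.names = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    reads <- lapply(seq_along(sampleNames), function(s) {
      mut <- condOf[s] == conditions[2L]
      lamI <- intronicDepth * if (mut) intronScale else rep(1, nH)
      nInt <- stats::rpois(nH, lamI)
      nEx <- stats::rpois(nH, exonicDepth)
      iIdx <- drawIdx(intrByGene, intrFeas, nInt)
      eIdx <- drawIdx(exByGene, exW, nEx)
      starts <- c(
        GenomicRanges::start(intrFlat)[iIdx] +
          floor(stats::runif(length(iIdx)) * intrFeas[iIdx]),
        GenomicRanges::start(exFlat)[eIdx] +
          floor(stats::runif(length(eIdx)) * exW[eIdx]))
      chroms <- c(as.character(GenomicRanges::seqnames(intrFlat))[iIdx],
                  as.character(GenomicRanges::seqnames(exFlat))[eIdx])
      GenomicRanges::GRanges(chroms,
        IRanges::IRanges(starts, width = readLength))
    })
    names(reads) <- sampleNames
    size <- 1 / nbDispersion
    mature <- vapply(seq_along(sampleNames), function(s) {
      mut <- condOf[s] == conditions[2L]
      mu <- matureBaselineMean * if (mut) matureScale else rep(1, nH)
      as.integer(stats::rnbinom(nH, size = size, mu = mu))
    }, integer(nH))
    dimnames(mature) <- list(hostMap$mir_id, sampleNames)
    truthPri <- stats::setNames(
      if (scenario == "transcriptional") priEff else rep(0, nH), hosts)
    truthMat <- stats::setNames(log2(matureScale), hostMap$mir_id)
    list(reads = reads,
         mature = makeCountMatrix(mature, condOf),
         truth = SimTruth(log2fc = c(truthMat, truthPri),
                          scenario = scenario,
                          scenarioByFeature = stats::setNames(
                            rep(scenario, nH), hosts),
                          nbDispersion = nbDispersion, seed = seed),
         condition = stats::setNames(condOf, sampleNames))
  })
}
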