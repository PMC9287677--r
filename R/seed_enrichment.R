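## Positional seed-word enrichment, CDF-shift target tests and
## multi-database target voting.

.asMirnaSeq <- function(mirna) {
  if (methods::is(mirna, "RNAStringSet")) {
    if (length(mirna) != 1L)
      stop("expected a single miRNA sequence, got ", length(mirna))
    return(list(id = names(mirna) %||% "mirna",
                seq = as.character(mirna[[1L]])))
  }
  if (methods::is(mirna, "RNAString"))
    return(list(id = "mirna", seq = as.character(mirna)))
  if (is.character(mirna) && length(mirna) == 1L) {
    s <- toupper(mirna)
    if (!grepl("^[ACGU]+$", s))
      stop("miRNA sequence must be RNA over {A,C,G,U}")
    return(list(id = names(mirna) %||% "mirna", seq = s))
  }
  stop("mirna must be an RNAStringSet of length 1, an RNAString, ",
       "or a single RNA character string")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DNA site word complementary to a miRNA word
#'
#' The putative binding site of a miRNA word in a 3' UTR is its reverse
#' complement under RNA->DNA pairing (A-T, C-G, G-C, U-A). For example the
#' RNA word `ACGUACG` yields the DNA site word `CGTACGT`.
#'
#' @param word RNA word over `{A,C,G,U}`.
#' @return the DNA reverse-complement word over `{A,C,G,T}`.
#' @examples
#' seedSiteWord("ACGUACG")
#' @export
seedSiteWord <- function(word) {
  word <- toupper(word)
  if (!grepl("^[ACGU]+$", word))
    stop("word must be RNA over {A,C,G,U}")
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", word))))
}

#' Positional k-mers of a miRNA and their site words
#'
#' Enumerates the words of length `k` starting at positions `startMin` to
#' `startMax` (1-based from the miRNA 5' end) together with the DNA site
#' word (reverse complement) each would leave in a target UTR.
#'
#' @param mirna miRNA sequence ([Biostrings::RNAStringSet] of length 1,
#'   `RNAString`, or RNA character string).
#' @param k word length (default 7).
#' @param startMin,startMax first and last start position scanned
#'   (defaults 1 and 15).
#' @return data.frame with columns `start_pos`, `mirna_word`, `site_word`.
#' @examples
#' mirnaWords("ACGUACGUACGU", k = 4, startMin = 1, startMax = 3)
#' @export
mirnaWords <- function(mirna, k = 7, startMin = 1, startMax = 15) {
  m <- .asMirnaSeq(mirna)
  need <- startMax + k - 1L
  if (nchar(m$seq) < need)
    stop("miRNA '", m$id, "' is ", nchar(m$seq), " nt; scanning words of ",
         "length ", k, " starting up to position ", startMax,
         " requires at least ", need, " nt")
  starts <- seq.int(startMin, startMax)
  words <- substring(m$seq, starts, starts + k - 1L)
  data.frame(start_pos = starts, mirna_word = words,
             site_word = vapply(words, seedSiteWord, ""),
             row.names = NULL)
}

#' Genes whose UTR contains a site word
#'
#' Presence/absence semantics: a gene qualifies if its UTR contains at
#' least one exact occurrence; multiplicity is ignored and `N` never
#' matches.
#'
#' @param utrs named [Biostrings::DNAStringSet] of 3' UTRs.
#' @param siteWord DNA word over `{A,C,G,T}`.
#' @return character vector of gene ids containing the word.
#' @export
genesWithWord <- function(utrs, siteWord) {
  siteWord <- toupper(siteWord)
  if (!grepl("^[ACGT]+$", siteWord))
    stop("siteWord must be DNA over {A,C,G,T}")
  hits <- Biostrings::vcountPattern(siteWord, utrs, fixed = TRUE) > 0L
  names(utrs)[hits]
}

#' Exact hypergeometric upper-tail probability
#'
#' Probability of drawing at least `nQueryWith` marked genes when `nQuery`
#' genes are drawn without replacement from a universe of `nUniverse` genes
#' of which `nUniverseWith` are marked: `P(X >= nQueryWith)` for
#' `X ~ Hypergeometric(nUniverse, nUniverseWith, nQuery)`. Exact (via
#' `phyper`), never approximated.
#'
#' @param nUniverse universe size.
#' @param nUniverseWith marked genes in the universe.
#' @param nQuery draw size.
#' @param nQueryWith marked genes observed in the draw.
#' @return the upper-tail p-value.
#' @examples
#' hypergeomTail(10, 4, 5, 3)  # 66/252
#' @export
hypergeomTail <- function(nUniverse, nUniverseWith, nQuery, nQueryWith) {
  v <- c(nUniverse, nUniverseWith, nQuery, nQueryWith)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop("counts must be nonnegative integers")
  if (nUniverseWith > nUniverse || nQuery > nUniverse ||
      nQueryWith > min(nQuery, nUniverseWith) ||
      nQueryWith < max(0L, nQuery - (nUniverse - nUniverseWith)))
    stop("inconsistent counts: require nQueryWith <= min(nQuery, ",
         "nUniverseWith) and all counts <= nUniverse")
  stats::phyper(nQueryWith - 1, nUniverseWith, nUniverse - nUniverseWith,
                nQuery, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over the standard BH procedure: sort p ascending,
#' take `adj_i = min_{j >= i}(p_(j) * m / j)` capped at 1, return in input
#' order. Errors on p outside \[0,1\].
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("pvalues must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Positional seed-word enrichment scan
#'
#' For each miRNA word of length `k` starting at positions `startMin` to
#' `startMax`, counts genes whose 3' UTR contains the complementary DNA
#' site word, in a query set (e.g. genes downregulated on miRNA
#' overexpression) versus a gene universe, and tests enrichment with the
#' exact hypergeometric upper tail. p-values are BH-adjusted across the
#' scanned positions (one family per scan). For a genuine target the
#' minimum is expected at start position 2, the canonical seed.
#'
#' @inheritParams mirnaWords
#' @param utrs named [Biostrings::DNAStringSet] of 3' UTRs.
#' @param queryGenes gene ids of the query set (must be a subset of
#'   `universeGenes`).
#' @param universeGenes gene ids forming the universe (default: all genes
#'   in `utrs`).
#' @param reportThreshold adjusted-p threshold for the `significant` flag
#'   (default 0.01).
#' @param matchLiteral search the miRNA word itself (transcribed to DNA)
#'   instead of its reverse complement; the complement is the canonical
#'   target-site convention and the default.
#' @return data.frame with one row per start position: `start_pos`,
#'   `mirna_word`, `site_word`, `n_universe`, `n_universe_with_site`,
#'   `n_query`, `n_query_with_site`, `pvalue`, `padj`, `significant`.
#' @export
seedScan <- function(mirna, utrs, queryGenes, universeGenes = names(utrs),
                     k = 7, startMin = 1, startMax = 15,
                     reportThreshold = 0.01, matchLiteral = FALSE) {
  if (length(queryGenes) == 0L || length(universeGenes) == 0L)
    stop("query and universe must be non-empty")
  if (anyDuplicated(universeGenes) || anyDuplicated(queryGenes))
    stop("gene sets must not contain duplicates")
  missingU <- setdiff(universeGenes, names(utrs))
  if (length(missingU))
    stop("universe genes without a UTR: ", missingU[1L], " and ",
         length(missingU) - 1L, " more")
  if (length(setdiff(queryGenes, universeGenes)))
    stop("queryGenes must be a subset of universeGenes")
  words <- mirnaWords(mirna, k = k, startMin = startMin, startMax = startMax)
  uutrs <- utrs[universeGenes]
  search <- if (matchLiteral) chartr("U", "T", words$mirna_word) else
    words$site_word
  res <- lapply(search, function(w) {
    withSite <- genesWithWord(uutrs, w)
    qWith <- sum(queryGenes %in% withSite)
    c(n_universe_with_site = length(withSite), n_query_with_site = qWith)
  })
  res <- do.call(rbind, res)
  out <- cbind(words,
               n_universe = length(universeGenes),
               n_universe_with_site = res[, "n_universe_with_site"],
               n_query = length(queryGenes),
               n_query_with_site = res[, "n_query_with_site"])
  out$pvalue <- mapply(hypergeomTail, out$n_universe,
                       out$n_universe_with_site, out$n_query,
                       out$n_query_with_site)
  out$padj <- bhAdjust(out$pvalue)
  out$significant <- out$padj < reportThreshold
  rownames(out) <- NULL
  out
}

#' CDF shift of query fold changes against a background
#'
#' Two-sample two-sided Kolmogorov-Smirnov comparison of the log2
#' fold-change distributions of a query gene set (e.g. predicted miRNA
#' targets) and a background (e.g. all genes). The p-value is exact for
#' small samples (`min(n, m) <= 25`, no ties) and asymptotic otherwise.
#' Direction is read from `median_shift` (median query minus median
#' background), since the KS statistic itself is unsigned.
#'
#' @param queryLog2fc,backgroundLog2fc non-empty numeric vectors.
#' @return list with `d_stat`, `pvalue`, `n_query`, `n_background`,
#'   `median_shift`.
#' @examples
#' cdfShift(c(1, 2), c(3, 4))  # D = 1, exact p = 1/3
#' @export
cdfShift <- function(queryLog2fc, backgroundLog2fc) {
  q <- queryLog2fc[!is.na(queryLog2fc)]
  b <- backgroundLog2fc[!is.na(backgroundLog2fc)]
  if (length(q) == 0L || length(b) == 0L)
    stop("query and background fold changes must be non-empty")
  exact <- min(length(q), length(b)) <= 25
  hasTies <- anyDuplicated(c(q, b)) > 0L
  kt <- if (hasTies) {
    suppressWarnings(stats::ks.test(q, b, alternative = "two.sided"))
  } else {
    stats::ks.test(q, b, alternative = "two.sided", exact = exact)
  }
  list(d_stat = unname(kt$statistic), pvalue = kt$p.value,
       n_query = length(q), n_background = length(b),
       median_shift = stats::median(q) - stats::median(b))
}

#' Vote score of predicted targets across databases
#'
#' Counts, for every gene in the union of the supplied prediction tables,
#' the number of databases supporting the interaction.
#'
#' @param sources named list; each element is a character vector of
#'   predicted target gene ids from one database. Names must be unique.
#' @return data.frame with `gene_id`, `score` (number of supporting
#'   sources) and `supporting_sources` (comma-separated source names),
#'   sorted by score descending then gene id.
#' @examples
#' voteScore(list(A = c("g1", "g2"), B = "g2", C = c("g2", "g3")))
#' @export
voteScore <- function(sources) {
  if (length(sources) == 0L) stop("at least one prediction source required")
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("every source must be named")
  if (anyDuplicated(names(sources)))
    stop("duplicate source names: ",
         names(sources)[duplicated(names(sources))][1L])
  sources <- lapply(sources, unique)
  genes <- sort(unique(unlist(sources, use.names = FALSE)))
  support <- vapply(genes, function(g)
    paste(names(sources)[vapply(sources, function(s) g %in% s, NA)],
          collapse = ","), "")
  score <- vapply(strsplit(support, ",", fixed = TRUE), length, 0L)
  out <- data.frame(gene_id = genes, score = score,
                    supporting_sources = support, row.names = NULL)
  out[order(-out$score, out$gene_id), , drop = FALSE]
}
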