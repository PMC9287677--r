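## Permutation gene-set enrichment: ranked list, weighted running-sum
## enrichment score, gene-label permutation p-values, BH across sets.

#' Rank genes from most up- to most downregulated
#'
#' Produces the total ordering the enrichment score walks: genes sorted by
#' the ranking metric descending, ties broken lexicographically by gene id
#' so the order is deterministic.
#'
#' @param de a DE table (see [validateDeTable()]).
#' @param metric `"log2fc"` (default) or `"signed_logp"`
#'   (`sign(log2fc) * -log10(pvalue)`); if p-values are missing the metric
#'   falls back to `log2fc` with a warning.
#' @return data.frame with `gene_id` and `score`, ordered most upregulated
#'   first.
#' @export
rankGenes <- function(de, metric = c("log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  validateDeTable(de)
  if (nrow(de) == 0L) stop("empty DE table")
  score <- if (metric == "signed_logp") {
    if (any(is.na(de$pvalue))) {
      warning("missing p-values; falling back to the log2fc metric")
      de$log2fc
    } else {
      sign(de$log2fc) * -log10(pmax(de$pvalue, 1e-300))
    }
  } else de$log2fc
  ord <- order(-score, de$feature_id)
  data.frame(gene_id = de$feature_id[ord], score = score[ord],
             row.names = NULL)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; at a gene-set hit the running sum rises by
#' `|score|^weight / sum(|score|^weight over hits)`, at a miss it falls by
#' `1 / (N - n_hits)`. The enrichment score is the extremum of largest
#' magnitude; the leading edge is the hits at or before a positive
#' extremum (at or after, for a negative one). Set members absent from the
#' ranking are dropped with a message.
#'
#' @param ranked output of [rankGenes()] (data.frame `gene_id`, `score` in
#'   ranked order).
#' @param geneSet character vector of member gene ids.
#' @param weight exponent on `|score|` at hits; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic, 1 (default) the classic weighted
#'   form.
#' @return list with `es`, `running_sum` (length-N vector) and
#'   `leading_edge`.
#' @export
enrichmentScore <- function(ranked, geneSet, weight = 1) {
  geneSet <- unique(geneSet)
  hit <- ranked$gene_id %in% geneSet
  nDropped <- length(geneSet) - sum(hit)
  if (nDropped > 0L)
    message(nDropped, " gene-set members absent from the ranking; dropped")
  nHits <- sum(hit)
  if (nHits == 0L) stop("gene set has no overlap with the ranked list")
  N <- nrow(ranked)
  sw <- abs(ranked$score[hit])^weight
  if (sum(sw) == 0) {
    warning("all hit scores are zero at this weight; using equal weights")
    sw <- rep(1, nHits)
  }
  step <- numeric(N)
  step[hit] <- sw / sum(sw)
  if (N > nHits) step[!hit] <- -1 / (N - nHits)
  rs <- cumsum(step)
  iMax <- which.max(rs)
  iMin <- which.min(rs)
  ## extremum of largest magnitude; a (numerical) tie resolves positive
  if (rs[iMax] >= -rs[iMin] - 1e-12) {
    es <- rs[iMax]; iExt <- iMax
  } else {
    es <- rs[iMin]; iExt <- iMin
  }
  le <- if (es >= 0) ranked$gene_id[hit & seq_len(N) <= iExt] else
    ranked$gene_id[hit & seq_len(N) >= iExt]
  list(es = es, running_sum = rs, leading_edge = le)
}

## Enrichment score from hit positions only: the running-sum extrema can
## only occur at a hit (maximum) or just before one / at the end (minimum),
## so permutations cost O(m log m) instead of O(N).
.esFromPositions <- function(pos, sw, N) {
  m <- length(pos)
  tot <- sum(sw)
  if (tot == 0) { sw <- rep(1, m); tot <- m }
  cum <- cumsum(sw) / tot
  missStep <- if (N > m) 1 / (N - m) else 0
  behind <- (pos - seq_len(m)) * missStep
  atHit <- cum - behind
  beforeHit <- c(0, cum[-m]) - behind
  up <- max(atHit)
  down <- min(beforeHit, 0)
  if (up >= -down - 1e-12) up else down
}

#' Permutation p-value for one gene set
#'
#' The null is gene-label permutation: random same-size sets drawn from the
#' ranked genes. With `n_s` null scores of the same sign as the observed
#' score `es`, the p-value is `(1 + #{|es_perm| >= |es|, same sign}) /
#' (1 + n_s)`, so it is never zero. The normalized score `nes` divides `es`
#' by the mean magnitude of same-sign permutation scores and is reported as
#' `NA` when fewer than 10 same-sign permutations exist.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of random sets (>= 100; default 1000).
#' @param seed integer seed; identical seeds give identical results.
#' @return list with `es`, `nes`, `pvalue`, `n_hits`, `leading_edge`,
#'   `n_perm`, `n_same_sign`.
#' @export
gseaPermutation <- function(ranked, geneSet, nPerm = 1000, weight = 1,
                            seed = 1) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  obs <- enrichmentScore(ranked, geneSet, weight = weight)
  m <- sum(ranked$gene_id %in% geneSet)
  N <- nrow(ranked)
  swAll <- abs(ranked$score)^weight
  esPerm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(i) {
      idx <- sort(sample.int(N, m))
      .esFromPositions(idx, swAll[idx], N)
    }, 0)
  })
  sameSign <- if (obs$es >= 0) esPerm >= 0 else esPerm < 0
  nSame <- sum(sameSign)
  if (nSame == 0L) {
    warning("no same-sign permutation scores; p-value set to 1")
    p <- 1
  } else {
    p <- (1 + sum(sameSign & abs(esPerm) >= abs(obs$es))) / (1 + nSame)
  }
  nes <- if (nSame >= 10L) obs$es / mean(abs(esPerm[sameSign])) else NA_real_
  list(es = obs$es, nes = nes, pvalue = p, n_hits = m,
       leading_edge = obs$leading_edge, n_perm = nPerm, n_same_sign = nSame)
}

#' Enrichment over a gene-set collection
#'
#' Runs [gseaPermutation()] for every set with at least one member in the
#' ranking, BH-adjusts p-values across the collection, and sorts by
#' adjusted p. Sets with no overlap are skipped and listed in
#' `attr(, "skipped")`.
#'
#' @inheritParams gseaPermutation
#' @param collection named list of gene-id vectors (e.g. from [readGmt()]).
#' @return data.frame with `set_id`, `es`, `nes`, `pvalue`, `padj`,
#'   `n_hits`; leading edges in `attr(, "leading_edge")`.
#' @export
gseaCollection <- function(ranked, collection, nPerm = 1000, weight = 1,
                           seed = 1) {
  if (length(collection) == 0L || is.null(names(collection)))
    stop("collection must be a named list of gene sets")
  overlap <- vapply(collection,
                    function(s) sum(ranked$gene_id %in% s) > 0L, NA)
  skipped <- names(collection)[!overlap]
  collection <- collection[overlap]
  if (length(collection) == 0L)
    stop("no gene set overlaps the ranked list")
  res <- withr::with_seed(as.integer(seed), {
    lapply(collection, function(s)
      suppressMessages(gseaPermutation(ranked, s, nPerm = nPerm,
                                       weight = weight,
                                       seed = sample.int(2^30, 1))))
  })
  out <- data.frame(
    set_id = names(collection),
    es = vapply(res, `[[`, 0, "es"),
    nes = vapply(res, `[[`, 0, "nes"),
    pvalue = vapply(res, `[[`, 0, "pvalue"),
    n_hits = vapply(res, `[[`, 0L, "n_hits"),
    row.names = NULL)
  out$padj <- bhAdjust(out$pvalue)
  out <- out[c("set_id", "es", "nes", "pvalue", "padj", "n_hits")]
  le <- lapply(res, `[[`, "leading_edge")
  ord <- order(out$padj, out$pvalue, out$set_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "leading_edge") <- le[out$set_id]
  attr(out, "skipped") <- skipped
  out
}
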