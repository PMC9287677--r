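# Independent brute-force oracles. These deliberately avoid the package's
# own code paths so agreement is evidence, not tautology.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws of n genes from
# a universe of N in which genes 1..K are marked.
enumHypergeomTail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# BH by the literal double-loop definition: adj_i = min over all j with
# p_j >= p_i of p_j * m / rank(p_j), capped at 1.
naiveBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    candidates <- vapply(seq_len(m), function(j) {
      if (ranks[j] >= ranks[i]) p[j] * m / ranks[j] else Inf
    }, 0)
    min(1, min(candidates))
  }, 0)
}

# Two-sample KS D as the literal supremum of ECDF differences.
naiveKsD <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# Running-sum enrichment score by the literal O(N) walk.
naiveES <- function(scores, hit, weight) {
  N <- length(scores)
  nh <- sum(hit)
  sw <- abs(scores[hit])^weight
  tot <- sum(sw)
  rs <- numeric(N)
  cur <- 0
  j <- 0L
  for (i in seq_len(N)) {
    if (hit[i]) {
      j <- j + 1L
      cur <- cur + sw[j] / tot
    } else {
      cur <- cur - 1 / (N - nh)
    }
    rs[i] <- cur
  }
  # extremum of largest magnitude; ties resolve to the positive extremum
  if (max(rs) >= -min(rs) - 1e-12) max(rs) else min(rs)
}

# Consensus retention/direction flags by explicit set algebra over
# per-dataset significant-down/up gene sets.
oracleConsensus <- function(lfc, pcrit, padjThr, lfcThr, minDatasets) {
  mirs <- rownames(lfc)
  K <- ncol(lfc)
  downSets <- upSets <- measSets <- vector("list", K)
  for (j in seq_len(K)) {
    measSets[[j]] <- mirs[!is.na(lfc[, j])]
    sig <- mirs[!is.na(pcrit[, j]) & pcrit[, j] < padjThr &
                  !is.na(lfc[, j]) & abs(lfc[, j]) > lfcThr]
    downSets[[j]] <- intersect(sig, mirs[!is.na(lfc[, j]) & lfc[, j] < 0])
    upSets[[j]] <- intersect(sig, mirs[!is.na(lfc[, j]) & lfc[, j] > 0])
  }
  do.call(rbind, lapply(mirs, function(m) {
    meas <- which(vapply(measSets, function(s) m %in% s, NA))
    nd <- sum(vapply(downSets, function(s) m %in% s, NA))
    nu <- sum(vapply(upSets, function(s) m %in% s, NA))
    data.frame(mir_id = m, n_datasets_measured = length(meas),
               n_datasets_sig = nd + nu, n_sig_down = nd, n_sig_up = nu,
               retained = (nd + nu) >= minDatasets,
               all_down = length(meas) > 0 &&
                 all(vapply(meas, function(j) m %in% downSets[[j]], NA)),
               all_up = length(meas) > 0 &&
                 all(vapply(meas, function(j) m %in% upSets[[j]], NA)))
  }))
}

# Intronic intervals by per-base membership: positions of the host span
# covered by no exon of any overlapping gene.
oracleIntrons <- function(models, hostId) {
  span <- geneSpans(models)[hostId]
  pos <- seq(GenomicRanges::start(span), GenomicRanges::end(span))
  covered <- rep(FALSE, length(pos))
  allEx <- unlist(exonRanges(models), use.names = FALSE)
  for (i in seq_along(allEx)) {
    s <- GenomicRanges::start(allEx)[i]
    e <- GenomicRanges::end(allEx)[i]
    covered[pos >= s & pos <= e] <- TRUE
  }
  intronPos <- pos[!covered]
  if (length(intronPos) == 0L) return(matrix(numeric(), ncol = 2))
  brk <- c(0, which(diff(intronPos) > 1), length(intronPos))
  t(vapply(seq_len(length(brk) - 1L), function(i)
    c(intronPos[brk[i] + 1L], intronPos[brk[i + 1L]]), c(0, 0)))
}
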