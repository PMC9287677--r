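## Cross-dataset differential-expression consensus: a minimal DE contrast
## for synthetic counts, harmonization of per-dataset tables, and the
## >= m-of-K vote-counting retention rule with direction classification.

#' Minimal two-condition differential-expression contrast
#'
#' Plumbing for synthetic counts (real data should arrive as externally
#' produced DE tables): median-of-ratios library-size normalization, log2
#' fold change of normalized condition means with a pseudocount, a Welch
#' t-test on `log2(CPM + pseudocount)` per feature, and BH adjustment.
#' Swapping the condition labels negates every log2fc exactly.
#'
#' @param counts `SummarizedExperiment` from [makeCountMatrix()], or an
#'   integer matrix (then supply `condition`).
#' @param conditionA,conditionB baseline and contrast condition labels;
#'   log2fc is `log2(B / A)`.
#' @param condition per-sample labels when `counts` is a matrix.
#' @param pseudocount added to normalized means and CPM (default 0.5).
#' @return a DE table data.frame (`feature_id`, `log2fc`, `pvalue`, `padj`,
#'   `base_mean`).
#' @export
deContrast <- function(counts, conditionA, conditionB, condition = NULL,
                       pseudocount = 0.5) {
  if (methods::is(counts, "SummarizedExperiment")) {
    condition <- conditionOf(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(condition) || length(condition) != ncol(counts))
    stop("condition labels must be supplied for every sample")
  a <- which(condition == conditionA)
  b <- which(condition == conditionB)
  if (length(a) < 2L || length(b) < 2L)
    stop("each condition needs at least 2 samples (got ", length(a), " '",
         conditionA, "', ", length(b), " '", conditionB, "')")
  m <- counts[, c(a, b), drop = FALSE]
  sf <- .sizeFactors(m)
  norm <- sweep(m, 2, sf, "/")
  ia <- seq_along(a)
  ib <- seq_along(b) + length(a)
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2(mB + pseudocount) - log2(mA + pseudocount)
  cpm <- sweep(m, 2, colSums(m) / 1e6, "/")
  y <- log2(cpm + pseudocount)
  pvalue <- .welchRows(y[, ia, drop = FALSE], y[, ib, drop = FALSE])
  de <- data.frame(feature_id = rownames(m), log2fc = log2fc,
                   pvalue = pvalue, padj = bhAdjust(pvalue),
                   base_mean = (mA + mB) / 2, row.names = NULL)
  validateDeTable(de)
  de
}

## DESeq-style median-of-ratios size factors; falls back to library-size
## ratios when no feature is positive in all samples.
.sizeFactors <- function(m) {
  lg <- rowMeans(log(m))
  ok <- is.finite(lg)
  if (any(ok)) {
    sf <- apply(m[ok, , drop = FALSE], 2, function(col)
      exp(stats::median(log(col[col > 0]) - lg[ok][col > 0])))
  } else {
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  sf / exp(mean(log(sf)))
}

## Row-wise Welch t-test; degenerate rows (zero pooled variance) get p = 1
## when the means agree and p = 0 otherwise.
.welchRows <- function(ya, yb) {
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- apply(ya, 1, stats::var); vb <- apply(yb, 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0 | !is.finite(p)
  p[degenerate] <- ifelse(abs(mb - ma)[degenerate] < 1e-12, 1, 0)
  p
}

#' Harmonize per-dataset DE tables over a shared miRNA key
#'
#' Outer-joins the tables on `feature_id`. A miRNA absent from a table is
#' *missing* there, which is distinct from measured-but-not-significant in
#' all downstream counting. Each table's significance criterion uses `padj`
#' when present (and not all missing) and falls back to the raw p-value
#' otherwise, with a message; the criterion used per dataset is recorded.
#'
#' @param tables named list of DE tables (>= 2; see [validateDeTable()]).
#' @return list with matrices (miRNA x dataset) `lfc`, `pcrit` (the p used
#'   for significance calls), `measured`, and the per-dataset `criteria`
#'   (`"padj"` or `"pvalue"`).
#' @export
harmonizeDeTables <- function(tables) {
  if (length(tables) < 2L) stop("at least 2 datasets required")
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop("tables must be a uniquely named list")
  if (all(vapply(tables, nrow, 0L) == 0L)) stop("all tables are empty")
  for (nm in names(tables)) {
    if (anyDuplicated(tables[[nm]]$feature_id))
      stop("duplicate feature_id in dataset '", nm, "'")
    validateDeTable(tables[[nm]], name = paste0("dataset '", nm, "'"))
  }
  ids <- sort(unique(unlist(lapply(tables, `[[`, "feature_id"))))
  K <- length(tables)
  lfc <- pcrit <- matrix(NA_real_, length(ids), K,
                         dimnames = list(ids, names(tables)))
  criteria <- stats::setNames(character(K), names(tables))
  for (j in seq_len(K)) {
    t <- tables[[j]]
    i <- match(t$feature_id, ids)
    lfc[i, j] <- t$log2fc
    usePadj <- "padj" %in% names(t) && any(!is.na(t$padj))
    criteria[j] <- if (usePadj) "padj" else "pvalue"
    if (!usePadj)
      message("dataset '", names(tables)[j],
              "': no adjusted p-values; using raw p for significance")
    pcrit[i, j] <- if (usePadj) t$padj else t$pvalue
  }
  list(lfc = lfc, pcrit = pcrit, measured = !is.na(lfc),
       criteria = criteria)
}

#' Vote-counting consensus across datasets
#'
#' Applies the retention rule — keep miRNAs significant (`pcrit <
#' padjThreshold` and `|log2fc| > lfcThreshold`) in at least `minDatasets`
#' datasets — and classifies direction consistency. A miRNA is `all_down`
#' (resp. `all_up`) when it is significant *and* down (up) in every dataset
#' in which it was measured; `requireAllDatasets = TRUE` additionally
#' demands measurement in every dataset.
#'
#' @param harmonized output of [harmonizeDeTables()].
#' @param minDatasets minimum number of significant datasets to retain
#'   (default 3).
#' @param padjThreshold significance threshold on the per-dataset criterion
#'   (default 0.05).
#' @param lfcThreshold minimum absolute log2 fold change (default 0.5).
#' @param requireAllDatasets strict mode for the all-direction flags.
#' @return data.frame with one row per miRNA: `mir_id`,
#'   `n_datasets_measured`, `n_datasets_sig`, `n_sig_down`, `n_sig_up`,
#'   `retained`, `all_down`, `all_up`, and one `lfc.<dataset>` column per
#'   dataset; sorted retained-first by `n_datasets_sig` descending.
#' @export
consensusFilter <- function(harmonized, minDatasets = 3,
                            padjThreshold = 0.05, lfcThreshold = 0.5,
                            requireAllDatasets = FALSE) {
  if (minDatasets < 1 || padjThreshold <= 0 || lfcThreshold < 0)
    stop("thresholds must be positive")
  lfc <- harmonized$lfc
  pcrit <- harmonized$pcrit
  measured <- harmonized$measured
  sig <- !is.na(pcrit) & pcrit < padjThreshold &
    !is.na(lfc) & abs(lfc) > lfcThreshold
  down <- sig & lfc < 0
  up <- sig & lfc > 0
  nMeas <- rowSums(measured)
  nSig <- rowSums(sig)
  nDown <- rowSums(down)
  nUp <- rowSums(up)
  K <- ncol(lfc)
  allDown <- nMeas > 0L & nDown == nMeas
  allUp <- nMeas > 0L & nUp == nMeas
  if (requireAllDatasets) {
    allDown <- allDown & nMeas == K
    allUp <- allUp & nMeas == K
  }
  out <- data.frame(mir_id = rownames(lfc), n_datasets_measured = nMeas,
                    n_datasets_sig = nSig, n_sig_down = nDown,
                    n_sig_up = nUp, retained = nSig >= minDatasets,
                    all_down = allDown, all_up = allUp, row.names = NULL)
  lfcDf <- as.data.frame(lfc)
  names(lfcDf) <- paste0("lfc.", colnames(lfc))
  out <- cbind(out, lfcDf)
  out <- out[order(-out$retained, -out$n_datasets_sig, out$mir_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
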