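## Readers/writers for the standard formats the pipeline consumes.
## Coordinate conventions: GTF is 1-based inclusive, BED is 0-based
## half-open; both are converted by rtracklayer to the internal GRanges
## (1-based closed) representation at this boundary and nowhere else.

.readValidatedFasta <- function(path, alphabet, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("empty FASTA: ", path)
    return(stats::setNames(character(), character()))
  }
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", ids[!nzchar(seqs)][1L], "'")
  pat <- paste0("^[", alphabet, "]+$")
  bad <- !grepl(pat, seqs)
  if (any(bad))
    stop(what, " record '", ids[bad][1L],
         "' contains letters outside {",
         paste(strsplit(alphabet, "")[[1L]], collapse = ","), "}")
  stats::setNames(seqs, ids)
}

#' Read mature miRNA sequences (RNA FASTA)
#'
#' Sequences are uppercased and must use the RNA alphabet `{A,C,G,U}`;
#' miRNAs are kept as RNA throughout — conversion to DNA site words happens
#' explicitly in [seedSiteWord()].
#'
#' @param path FASTA file of mature miRNA sequences, 5'->3'.
#' @return a named [Biostrings::RNAStringSet].
#' @export
readMirnaFasta <- function(path) {
  Biostrings::RNAStringSet(.readValidatedFasta(path, "ACGU", "miRNA"))
}

#' Read 3' UTR sequences (DNA FASTA)
#'
#' Sequences are uppercased; alphabet `{A,C,G,T,N}` (an `N` never matches
#' any seed word). Duplicate gene ids are rejected at load.
#'
#' @param path FASTA file of per-gene 3' UTR sequences.
#' @return a named [Biostrings::DNAStringSet], the seed-scan universe.
#' @export
readUtrFasta <- function(path) {
  Biostrings::DNAStringSet(.readValidatedFasta(path, "ACGTN", "UTR"))
}

#' Read gene models from a GTF file
#'
#' Uses `gene` features for spans and `exon` features for structure; when a
#' gene has no `gene` feature its span is the range of its exons. Exons are
#' merged across transcripts. An exon outside its gene's recorded span is a
#' validation error.
#'
#' @param path GTF file (1-based inclusive coordinates).
#' @return a [GeneModelSet-class].
#' @export
readGtfModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$type)) stop("GTF without a feature type column: ", path)
  if (is.null(gr$gene_id) || any(is.na(gr$gene_id)) ||
      any(!nzchar(gr$gene_id)))
    stop("GTF feature missing the gene_id attribute in ", path)
  ex <- gr[gr$type == "exon"]
  gn <- gr[gr$type == "gene"]
  ids <- unique(c(gn$gene_id, ex$gene_id))
  exl <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex), factor(ex$gene_id, ids)))
  spans <- GenomicRanges::granges(gn)
  names(spans) <- gn$gene_id
  noSpan <- setdiff(ids, names(spans))
  if (length(noSpan)) {
    derived <- unlist(range(exl[noSpan], ignore.strand = FALSE))
    spans <- c(spans, derived)
  }
  spans <- spans[ids]
  ## explicit span check so the error names the offending gene
  rng <- unlist(range(exl, ignore.strand = TRUE))
  has <- names(exl)[S4Vectors::elementNROWS(exl) > 0L]
  bad <- has[GenomicRanges::start(rng[has]) < GenomicRanges::start(spans[has]) |
             GenomicRanges::end(rng[has]) > GenomicRanges::end(spans[has])]
  if (length(bad))
    stop("exon outside the annotated gene span for: ",
         paste(bad, collapse = ", "))
  GeneModelSet(spans, exl)
}

#' Read and write differential-expression tables (TSV)
#'
#' Schema: `feature_id`, `log2fc`, `pvalue`, optional `padj` and
#' `base_mean`. Numbers are written at full double precision so that
#' `readDeTable(writeDeTable(x))` reproduces `x` exactly.
#'
#' @param path TSV file with a header row.
#' @return `readDeTable`: a validated DE data.frame.
#' @seealso [validateDeTable()] for the schema contract.
#' @export
readDeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("feature_id", "log2fc", "pvalue")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("DE table ", path, ": missing required columns: ",
         paste(miss, collapse = ", "))
  df$feature_id <- as.character(df$feature_id)
  for (cl in intersect(c("log2fc", "pvalue", "padj", "base_mean"), names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  validateDeTable(df, name = paste0("DE table ", path))
  df
}

.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' @rdname readDeTable
#' @param de a DE table data.frame (see [validateDeTable()]).
#' @export
writeDeTable <- function(de, path) {
  validateDeTable(de)
  keep <- intersect(c("feature_id", "log2fc", "pvalue", "padj", "base_mean"),
                    names(de))
  out <- de[keep]
  for (cl in setdiff(keep, "feature_id")) out[[cl]] <- .fmtNum(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned-read intervals from BED
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed, so a
#' BED line `chr1 199 210` becomes `chr1:200-210` (width 11).
#'
#' @param path BED file of per-sample read intervals.
#' @return a [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' @rdname readBedIntervals
#' @param gr a `GRanges` of intervals to write.
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write gene-set collections (GMT)
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Empty sets and duplicate set ids are rejected.
#'
#' @param path GMT file.
#' @return `readGmt`: a named list of character vectors of gene ids, with
#'   set descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L],
         ": expected set_id, description and at least one gene")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set ids in ", path, ": ", ids[duplicated(ids)][1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ", ids[lengths(sets) == 0L][1L])
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, d, g) paste(c(id, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write count matrices (TSV)
#'
#' Layout: a `feature_id` column followed by one integer column per sample.
#'
#' @param path TSV file.
#' @param condition optional per-sample condition labels (in column order);
#'   when given, a `SummarizedExperiment` is returned via
#'   [makeCountMatrix()], otherwise a plain integer matrix.
#' @export
readCountsTsv <- function(path, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"feature_id" %in% names(df))
    stop("count table ", path, ": missing required columns: feature_id")
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in ", path)
  m <- as.matrix(df[setdiff(names(df), "feature_id")])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  .assertCounts(m)
  storage.mode(m) <- "integer"
  if (is.null(condition)) m else makeCountMatrix(m, condition)
}

#' @rdname readCountsTsv
#' @param x integer matrix or `SummarizedExperiment` with a `counts` assay.
#' @export
writeCountsTsv <- function(x, path) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intronic-miRNA to host-gene map (TSV)
#'
#' Two-column table, `mir_id <TAB> host_gene_id`, as exported from
#' intronic-miRNA catalogues such as MiRIAD. Each miRNA must map to exactly
#' one host gene.
#'
#' @param path TSV file with a header row.
#' @return data.frame with columns `mir_id`, `host_gene_id`.
#' @export
readHostMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hm <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertHostMap(hm)
  hm[c("mir_id", "host_gene_id")]
}
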