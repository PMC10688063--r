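#' Read a locus-by-sample count matrix with sample metadata
#'
#' Reads a tabular counts file (first column \code{locus}, one column per
#' sample id) and a metadata table with columns
#' \code{sample,lineage,condition,generation}, validates them against the
#' MA-design invariants (even generations, unique (lineage, generation),
#' exactly one founder per lineage, non-negative integer counts) and returns
#' an \linkS4class{MAExperiment}. Loci with zero counts in every sample are
#' flagged removable, mirroring the standard pre-filter of dropping genes
#' never seen expressed. A load report (loci, samples, flagged loci) is
#' stored in \code{metadata(x)$loadReport}.
#'
#' @param path counts file (TSV, or CSV if the file ends in .csv)
#' @param metaPath metadata file in the same dialect
#' @return \linkS4class{MAExperiment}
#' @export
readCountMatrix <- function(path, metaPath) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "locus")
        .stopf("counts file must have 'locus' as its first column")
    msep <- if (grepl("\\.csv$", metaPath)) "," else "\t"
    meta <- utils::read.table(metaPath, header = TRUE, sep = msep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample", "lineage", "condition", "generation")
    if (!all(need %in% colnames(meta)))
        .stopf("metadata must have columns %s", paste(need, collapse = ","))
    bad <- meta$sample[is.na(meta$generation)]
    if (length(bad))
        .stopf("metadata missing generation for sample(s): %s",
               paste(bad, collapse = ", "))
    samples <- colnames(tab)[-1]
    unknown <- setdiff(samples, meta$sample)
    if (length(unknown))
        .stopf("unknown sample id(s) in counts header: %s",
               paste(unknown, collapse = ", "))
    cm <- as.matrix(tab[, -1, drop = FALSE])
    if (any(is.na(cm)) || any(cm != round(cm)) || any(cm < 0))
        .stopf("counts must be non-negative integers")
    rownames(cm) <- tab$locus
    meta <- meta[match(samples, meta$sample), ]
    x <- MAExperiment(cm, lineage = meta$lineage, condition = meta$condition,
                      generation = meta$generation)
    validObject(x)
    S4Vectors::metadata(x)$loadReport <- list(
        n_loci = nrow(cm), n_samples = ncol(cm),
        n_flagged_zero = sum(SummarizedExperiment::rowData(x)$removable))
    x
}

#' Write an MAExperiment back to counts + metadata TSV
#'
#' Inverse of \code{\link{readCountMatrix}}; the write/read round trip is
#' lossless for counts and metadata.
#'
#' @param x \linkS4class{MAExperiment}
#' @param path,metaPath output file paths (TSV)
#' @export
writeCountMatrix <- function(x, path, metaPath) {
    cm <- counts(x)
    tab <- data.frame(locus = rownames(cm), cm, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- data.frame(sample = colnames(cm), lineage = lineages(x),
                       condition = conditions(x), generation = generations(x))
    utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(x)
}

#' Read / write BED6 interval files
#'
#' BED uses 0-based half-open coordinates; internally intervals are held as
#' \link[GenomicRanges]{GRanges} (1-based closed), converted once at this
#' boundary: \code{start = bed_start + 1}, \code{end = bed_end}. Name and
#' score columns are preserved so that a write/read round trip reproduces
#' the file.
#'
#' @param path BED6 file
#' @return \code{GRanges} with metadata columns \code{name} and \code{score}
#' @export
readBed <- function(path) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand"))
    if (any(tab$end <= tab$start))
        .stopf("BED record with end <= start (e.g. %s:%d-%d)",
               tab$chrom[tab$end <= tab$start][1],
               tab$start[tab$end <= tab$start][1],
               tab$end[tab$end <= tab$start][1])
    if (!all(tab$strand %in% c("+", "-")))
        .stopf("malformed strand value(s): %s",
               paste(unique(setdiff(tab$strand, c("+", "-"))), collapse = " "))
    GenomicRanges::GRanges(tab$chrom,
                           IRanges::IRanges(tab$start + 1L, tab$end),
                           strand = tab$strand, name = tab$name,
                           score = tab$score)
}

#' @rdname readBed
#' @param gr \code{GRanges} to write; \code{name}/\code{score} metadata
#'   columns are used when present
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = S4Vectors::mcols(gr)$name %||% ".",
        score = S4Vectors::mcols(gr)$score %||% 0L,
        strand = as.character(GenomicRanges::strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(gr)
}

#' Read / write per-sample variant observations
#'
#' Variant tables are TSV with columns
#' \code{chrom,pos,ref,alt,vtype,lineage,generation}; \code{pos} is 1-based
#' (the variant-caller dialect) and \code{vtype} is \code{SNP} or
#' \code{indel}. A SNP must have single-base ref and alt.
#'
#' @param path variants TSV
#' @return data.frame of variant observations
#' @export
readVariants <- function(path) {
    v <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "vtype", "lineage", "generation")
    if (!all(need %in% colnames(v)))
        .stopf("variants file must have columns %s",
               paste(need, collapse = ","))
    bad <- v$vtype == "SNP" & (nchar(v$ref) != 1L | nchar(v$alt) != 1L)
    if (any(bad))
        .stopf("SNP with multi-base ref/alt at %s:%d",
               v$chrom[bad][1], v$pos[bad][1])
    v
}

#' @rdname readVariants
#' @param variants data.frame as returned by \code{readVariants}
#' @export
writeVariants <- function(variants, path) {
    utils::write.table(variants, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(variants)
}
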