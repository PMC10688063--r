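#' Assign small-RNA reads to tRNA loci and build start-position profiles
#'
#' Reads of 18-36 nt are assigned to a tRNA locus when their interval
#' overlaps it by at least 1 bp (loci must be non-overlapping). The read
#' start in tRNA coordinates (5'->3' of the tRNA) is
#' \code{read_start - locus_start} on the plus strand and
#' \code{locus_end - read_end} on the minus strand. Reads whose start falls
#' outside [0, locus length) through partial overlap are dropped and
#' counted. The profile of a locus is the vector of read-start counts per
#' position.
#'
#' @param reads \code{GRanges} of alignment intervals
#' @param loci \code{GRanges} of tRNA loci with a \code{trna_type} metadata
#'   column; all widths must be >= 36
#' @return list with \code{profiles} (named list of integer vectors, one
#'   per locus) and \code{stats} (total, assigned, dropped_length,
#'   dropped_clamped, unassigned); read conservation holds:
#'   assigned + dropped + unassigned = total
#' @export
assignReads <- function(reads, loci) {
    if (any(GenomicRanges::width(loci) < 36))
        .stopf("tRNA locus shorter than 36 bp cannot hold halves")
    self <- GenomicRanges::findOverlaps(loci, loci,
                                        ignore.strand = TRUE)
    if (length(self) > length(loci)) .stopf("overlapping tRNA loci")
    total <- length(reads)
    w <- GenomicRanges::width(reads)
    lenOK <- w >= 18 & w <= 36
    droppedLength <- sum(!lenOK)
    reads <- reads[lenOK]
    hits <- GenomicRanges::findOverlaps(reads, loci, minoverlap = 1L,
                                        ignore.strand = TRUE)
    # non-overlapping loci with >=200bp gaps make double hits impossible;
    # keep the first hit defensively
    hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    unassigned <- sum(lenOK) - length(q)
    L <- GenomicRanges::width(loci)
    plus <- as.character(GenomicRanges::strand(loci)) == "+"
    sp <- ifelse(plus[s],
                 GenomicRanges::start(reads)[q] - GenomicRanges::start(loci)[s],
                 GenomicRanges::end(loci)[s] - GenomicRanges::end(reads)[q])
    inBounds <- sp >= 0L & sp < L[s]
    droppedClamped <- sum(!inBounds)
    s <- s[inBounds]; sp <- sp[inBounds]
    profiles <- lapply(seq_along(loci), function(l) {
        tabulate(sp[s == l] + 1L, nbins = L[l])
    })
    names(profiles) <- S4Vectors::mcols(loci)$name %||%
        paste0("locus", seq_along(loci))
    list(profiles = profiles,
         stats = c(total = total, assigned = length(sp),
                   dropped_length = droppedLength,
                   dropped_clamped = droppedClamped,
                   unassigned = unassigned))
}

#' Per-sample start-position profiles
#'
#' Convenience wrapper running \code{\link{assignReads}} once per sample
#' (reads carry a \code{sample} metadata column).
#'
#' @param reads \code{GRanges} with a \code{sample} column
#' @param loci tRNA loci \code{GRanges}
#' @return named list (per sample) of \code{assignReads} results
#' @export
fragmentProfiles <- function(reads, loci) {
    samples <- unique(S4Vectors::mcols(reads)$sample)
    out <- lapply(samples, function(s)
        assignReads(reads[S4Vectors::mcols(reads)$sample == s], loci))
    names(out) <- samples
    out
}

#' Normalized 3' half fragment counts per tRNA type
#'
#' A read is a 3' half fragment when its tRNA-coordinate start position is
#' at or beyond the locus midpoint, \code{floor(length / 2)} (the midpoint
#' position itself belongs to the 3' half). Counts are summed over all loci
#' of the same tRNA type and divided by the sample's size factor.
#'
#' @param profilesBySample output of \code{\link{fragmentProfiles}}
#' @param loci tRNA loci \code{GRanges} with \code{trna_type}
#' @param sizeFactors named per-sample factors (default all 1)
#' @return numeric matrix, tRNA type x sample
#' @export
threePrimeHalfCounts <- function(profilesBySample, loci, sizeFactors = NULL) {
    types <- S4Vectors::mcols(loci)$trna_type
    L <- GenomicRanges::width(loci)
    half <- floor(L / 2)
    samples <- names(profilesBySample)
    if (is.null(sizeFactors))
        sizeFactors <- stats::setNames(rep(1, length(samples)), samples)
    out <- matrix(0, length(unique(types)), length(samples),
                  dimnames = list(unique(types), samples))
    for (si in samples) {
        prof <- profilesBySample[[si]]$profiles
        cnt <- vapply(seq_along(prof), function(l)
            sum(prof[[l]][(half[l] + 1L):L[l]]), numeric(1))
        agg <- tapply(cnt, types, sum)
        out[names(agg), si] <- agg / sizeFactors[[si]]
    }
    out
}

#' Call epimutations on a tRNA fragment table
#'
#' Applies the residual-Z epimutation caller (linear model, as for all
#' small-RNA classes) and run detection to a tRNA-type-by-sample table of
#' normalized 3' half counts.
#'
#' @param table numeric matrix, tRNA type x sample (already normalized)
#' @param sampleMeta data.frame(sample, lineage, condition, generation)
#'   matching the table columns; must include generation 0 per lineage
#' @param cutoff,pseudocount as in \code{\link{callEpimutations}}
#' @param strict passed to \code{\link{detectRuns}}
#' @return list with \code{calls} (\linkS4class{EpimutationCalls}) and
#'   \code{runs}
#' @export
trnaEpimutations <- function(table, sampleMeta, cutoff = 2.25,
                             pseudocount = 1, strict = FALSE) {
    meta <- sampleMeta[match(colnames(table), sampleMeta$sample), ]
    if (!0L %in% meta$generation)
        .stopf("tRNA table must include the founder (generation 0)")
    calls <- .callFromNormalized(table, meta, model = "linear",
                                 cutoff = cutoff, span = NA,
                                 pseudocount = pseudocount)
    list(calls = calls, runs = detectRuns(calls))
}

#' Argonaute IP enrichment of tRNA fragments
#'
#' Enrichment of tRNA-derived reads in an immunoprecipitate relative to its
#' paired input: \code{(tRNA_IP / total_IP) / (tRNA_input / total_input)}.
#' Upstream filtering keeps only reads strictly longer than 25 nt so
#' 22G-RNAs cannot contribute. Zero tRNA reads in the input make the
#' enrichment undefined (NA).
#'
#' @param ip data.frame with columns \code{ago}, \code{trna_reads},
#'   \code{total_reads}
#' @param input paired input counts, same columns and AGO order
#' @return data.frame (ago, enrichment)
#' @export
agoEnrichment <- function(ip, input) {
    stopifnot(identical(ip$ago, input$ago))
    if (any(ip$total_reads <= 0) || any(input$total_reads <= 0))
        .stopf("total read counts must be positive")
    ipShare <- ip$trna_reads / ip$total_reads
    inShare <- input$trna_reads / input$total_reads
    enr <- ifelse(input$trna_reads == 0, NA_real_, ipShare / inShare)
    data.frame(ago = ip$ago, enrichment = enr)
}

#' Filter reads to those strictly longer than a width
#'
#' @param reads \code{GRanges}
#' @param minWidthExclusive reads must be strictly longer than this
#'   (default 25, excluding 22G-RNAs and other short classes)
#' @export
filterLongReads <- function(reads, minWidthExclusive = 25L) {
    reads[GenomicRanges::width(reads) > minWidthExclusive]
}

#' Mismatch-tolerant search for putative tRNA-fragment target genes
#'
#' Scans every genomic window of fragment length on both strands (reverse
#' complement on the minus strand) for matches with Hamming distance at
#' most \code{maxMismatches} (ungapped; an N in the fragment mismatches
#' every genome base). Hits overlapping a gene body by >= 1 bp produce one
#' output row per (gene, hit).
#'
#' @param fragments \code{DNAStringSet} of fragment sequences (length >=
#'   15) with names, and tRNA types given by \code{trnaTypes} (defaults to
#'   the names)
#' @param genome \code{DNAStringSet} of chromosome sequences
#' @param geneBodies \code{GRanges} of whole-gene intervals with a
#'   \code{name} column
#' @param maxMismatches maximum Hamming distance (default 3)
#' @param trnaTypes character vector parallel to \code{fragments}
#' @return data.frame (gene, trna_type, chrom, start0, strand, mismatches);
#'   \code{start0} is the 0-based window start
#' @export
findTargets <- function(fragments, genome, geneBodies, maxMismatches = 3,
                        trnaTypes = names(fragments)) {
    if (any(Biostrings::width(fragments) < 15))
        .stopf("fragments must be >= 15 nt")
    hits <- list()
    for (fi in seq_along(fragments)) {
        frag <- fragments[[fi]]
        for (ch in names(genome)) {
            subj <- genome[[ch]]
            for (str in c("+", "-")) {
                pat <- if (str == "+") frag else
                    Biostrings::reverseComplement(frag)
                mt <- Biostrings::matchPattern(pat, subj,
                                               max.mismatch = maxMismatches,
                                               with.indels = FALSE,
                                               fixed = TRUE)
                if (!length(mt)) next
                mm <- Biostrings::neditStartingAt(
                    pat, subj, starting.at = Biostrings::start(mt),
                    with.indels = FALSE, fixed = TRUE)
                hits[[length(hits) + 1L]] <- data.frame(
                    frag = fi, chrom = ch,
                    start = Biostrings::start(mt),
                    end = Biostrings::end(mt),
                    strand = str, mismatches = mm)
            }
        }
    }
    if (!length(hits))
        return(data.frame(gene = character(), trna_type = character(),
                          chrom = character(), start0 = integer(),
                          strand = character(), mismatches = integer()))
    hd <- do.call(rbind, hits)
    hgr <- GenomicRanges::GRanges(hd$chrom,
                                  IRanges::IRanges(hd$start, hd$end),
                                  strand = hd$strand)
    ov <- GenomicRanges::findOverlaps(hgr, geneBodies, minoverlap = 1L,
                                      ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    geneNames <- S4Vectors::mcols(geneBodies)$name %||%
        as.character(seq_along(geneBodies))
    data.frame(gene = geneNames[s],
               trna_type = trnaTypes[hd$frag[q]],
               chrom = hd$chrom[q],
               start0 = hd$start[q] - 1L,
               strand = hd$strand[q],
               mismatches = hd$mismatches[q])
}
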