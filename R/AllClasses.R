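#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MAExperiment: multigenerational mutation-accumulation count data
#'
#' A \linkS4class{SummarizedExperiment} holding a locus-by-sample matrix of
#' raw counts from a mutation-accumulation (MA) experiment in which each
#' lineage is propagated through bottlenecks and sampled every two
#' generations. Column metadata carries, per sample, the \code{lineage}
#' (e.g. C1, C2, L1, L2, H1, H2), the exposure \code{condition}
#' (\code{control}, \code{low_dose} or \code{high_dose}) and the even
#' \code{generation} number. Generation 0 is the founder, sampled exactly
#' once per lineage before any epimutation accumulation. Row metadata
#' carries a \code{locus_class} (gene, g22, g26, pirna, mirna, trna_half or
#' other) and a \code{removable} flag marking loci with zero counts in every
#' sample.
#'
#' Missing samples (generations omitted from sequencing) are represented as
#' absent columns, never as all-zero columns.
#'
#' @slot .. see \code{\link[SummarizedExperiment]{SummarizedExperiment}}
#' @seealso \code{\link{MAExperiment}} (constructor),
#'   \code{\link{readCountMatrix}}, \code{\link{simulateCounts}}
#' @export
setClass("MAExperiment", contains = "SummarizedExperiment")

.validMAExperiment <- function(object) {
    msgs <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("lineage", "condition", "generation")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
    gen <- cd$generation
    if (any(is.na(gen)) || any(gen < 0) || any(gen %% 2 != 0))
        msgs <- c(msgs, "generations must be even integers >= 0")
    key <- paste(cd$lineage, gen)
    if (anyDuplicated(key))
        msgs <- c(msgs, paste("duplicate (lineage, generation):",
                              paste(unique(key[duplicated(key)]), collapse = "; ")))
    for (ln in unique(cd$lineage)) {
        n0 <- sum(cd$lineage == ln & gen == 0)
        if (n0 != 1L)
            msgs <- c(msgs, sprintf(
                "lineage %s has %d founder (generation 0) samples; exactly 1 required",
                ln, n0))
    }
    cm <- SummarizedExperiment::assay(object, "counts")
    if (any(cm < 0)) msgs <- c(msgs, "counts contain negative entries")
    if (length(msgs)) msgs else TRUE
}
setValidity("MAExperiment", .validMAExperiment)

#' Construct an MAExperiment
#'
#' @param counts integer matrix, loci in rows (rownames = locus ids),
#'   samples in columns.
#' @param lineage,condition,generation per-sample metadata vectors, parallel
#'   to the columns of \code{counts}.
#' @param locusClass per-locus class label; recycled if length 1.
#' @return A validated \linkS4class{MAExperiment}. Loci with no counts in
#'   any sample are flagged in \code{rowData(x)$removable}.
#' @examples
#' cm <- matrix(rpois(12, 50), 3, 4,
#'              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- MAExperiment(cm, lineage = c("C1","C1","C2","C2"),
#'                   condition = "control", generation = c(0, 2, 0, 2))
#' @export
MAExperiment <- function(counts, lineage, condition, generation,
                         locusClass = "gene") {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    cd <- DataFrame(lineage = as.character(lineage),
                    condition = as.character(rep(condition,
                                                 length.out = ncol(counts))),
                    generation = as.integer(generation),
                    row.names = colnames(counts))
    rd <- DataFrame(locus_class = rep(as.character(locusClass),
                                      length.out = nrow(counts)),
                    removable = rowSums(counts) == 0L,
                    row.names = rownames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("MAExperiment", se)
}

#' EpimutationCalls: residual Z-scores and ternary epimutation calls
#'
#' A \linkS4class{SummarizedExperiment} with two assays over the same
#' locus-by-sample grid (founder columns excluded): \code{z}, the residual
#' Z-score of each locus in each (lineage, generation) against the founder
#' regression, and \code{calls}, the ternary call matrix with +1 (up
#' epimutation) where z >= cutoff, -1 (down) where z <= -cutoff and 0
#' otherwise. The cutoff (default 2.25) and the regression model used are
#' stored in \code{metadata()}.
#'
#' @seealso \code{\link{callEpimutations}}, \code{\link{detectRuns}}
#' @export
setClass("EpimutationCalls", contains = "SummarizedExperiment")

.validEpimutationCalls <- function(object) {
    msgs <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("z", "calls") %in% an))
        return("assays 'z' and 'calls' are required")
    z <- SummarizedExperiment::assay(object, "z")
    calls <- SummarizedExperiment::assay(object, "calls")
    co <- metadata(object)$cutoff
    if (is.null(co) || !is.numeric(co) || co <= 0)
        msgs <- c(msgs, "metadata()$cutoff must be a positive number")
    if (!all(calls %in% c(-1L, 0L, 1L)))
        msgs <- c(msgs, "calls must be in {-1, 0, +1}")
    else if (!is.null(co) && is.numeric(co) &&
             any(calls != 0L & abs(z) < co))
        msgs <- c(msgs, "nonzero calls found where |z| < cutoff")
    if (length(msgs)) msgs else TRUE
}
setValidity("EpimutationCalls", .validEpimutationCalls)

#' @describeIn MAExperiment-class compact display
#' @param object an \code{MAExperiment}
#' @export
setMethod("show", "MAExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("MAExperiment:", nrow(object), "loci x", ncol(object), "samples\n")
    cat("  lineages:", paste(unique(cd$lineage), collapse = " "), "\n")
    cat("  generations:", paste(sort(unique(cd$generation)), collapse = " "),
        "\n")
    cat("  removable (all-zero) loci:",
        sum(SummarizedExperiment::rowData(object)$removable), "\n")
})

setMethod("show", "EpimutationCalls", function(object) {
    calls <- SummarizedExperiment::assay(object, "calls")
    cat("EpimutationCalls:", nrow(object), "loci x", ncol(object),
        "(lineage, generation) columns\n")
    cat("  cutoff:", metadata(object)$cutoff,
        " model:", metadata(object)$model %||% "?", "\n")
    cat("  calls: +1:", sum(calls == 1L), " -1:", sum(calls == -1L),
        " 0:", sum(calls == 0L), "\n")
})
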