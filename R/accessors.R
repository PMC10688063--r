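#' @importFrom BiocGenerics counts sizeFactors
NULL

#' Accessors for MAExperiment and EpimutationCalls
#'
#' \code{counts} returns the raw count matrix; \code{lineages},
#' \code{generations} and \code{conditions} return the per-sample metadata
#' vectors; \code{zMatrix} and \code{callMatrix} return the Z-score and
#' ternary call assays of an \linkS4class{EpimutationCalls} object;
#' \code{callCutoff} returns the Z cutoff used.
#'
#' @param object,x an \linkS4class{MAExperiment} or
#'   \linkS4class{EpimutationCalls}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "MAExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
lineages <- function(x) as.character(SummarizedExperiment::colData(x)$lineage)

#' @rdname accessors
#' @export
generations <- function(x)
    as.integer(SummarizedExperiment::colData(x)$generation)

#' @rdname accessors
#' @export
conditions <- function(x)
    as.character(SummarizedExperiment::colData(x)$condition)

#' @rdname accessors
#' @export
zMatrix <- function(x) SummarizedExperiment::assay(x, "z")

#' @rdname accessors
#' @export
callMatrix <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname accessors
#' @export
callCutoff <- function(x) S4Vectors::metadata(x)$cutoff
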