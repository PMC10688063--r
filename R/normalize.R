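#' Median-of-ratios size factors
#'
#' For each locus with strictly positive counts in every sample, a
#' pseudo-reference is formed as the geometric mean across samples; the size
#' factor of a sample is the median over those loci of the ratio
#' count / pseudo-reference. Loci containing any zero are excluded from the
#' median (their geometric mean is zero on the count scale). This is the
#' normalisation dialect popularised by DESeq2.
#'
#' @param object \linkS4class{MAExperiment} or a numeric count matrix
#' @return named numeric vector of positive size factors, one per sample
#' @examples
#' m <- matrix(c(2, 4, 4, 8), 2, 2, dimnames = list(c("a","b"), c("s1","s2")))
#' sizeFactors(m)   # 1/sqrt(2), sqrt(2)
#' @export
setMethod("sizeFactors", "MAExperiment", function(object)
    .medianOfRatios(counts(object)))

#' @rdname sizeFactors-MAExperiment-method
#' @export
setMethod("sizeFactors", "matrix", function(object) .medianOfRatios(object))

.medianOfRatios <- function(cm) {
    ok <- rowSums(cm <= 0) == 0
    if (!any(ok))
        .stopf("size factors undefined: no locus has all-positive counts")
    sub <- cm[ok, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    apply(sub / geo, 2, stats::median)
}

#' Normalize counts by size factors
#'
#' Divides each sample's raw counts by that sample's size factor.
#'
#' @param x \linkS4class{MAExperiment} or count matrix
#' @param factors size factors covering every sample; computed from \code{x}
#'   when omitted
#' @return real-valued matrix of normalized counts
#' @export
normalizeCounts <- function(x, factors = NULL) {
    cm <- if (is(x, "MAExperiment")) counts(x) else as.matrix(x)
    if (is.null(factors)) factors <- .medianOfRatios(cm)
    if (!is.null(names(factors))) {
        miss <- setdiff(colnames(cm), names(factors))
        if (length(miss))
            .stopf("missing size factor for sample(s): %s",
                   paste(miss, collapse = ", "))
        factors <- factors[colnames(cm)]
    } else if (length(factors) != ncol(cm)) {
        .stopf("need one size factor per sample")
    }
    sweep(cm, 2, factors, "/")
}

#' Shifted log2 transform
#'
#' \code{log2(x + pseudocount)} elementwise. The default pseudocount of 1
#' keeps zero normalized counts finite (and maps them to 0).
#'
#' @param x numeric matrix or vector
#' @param pseudocount non-negative shift; 0 requires all values > 0
#' @export
log2p <- function(x, pseudocount = 1) {
    if (pseudocount < 0) .stopf("pseudocount must be >= 0")
    if (pseudocount == 0 && any(x <= 0))
        .stopf("zero or negative values with pseudocount 0")
    log2(x + pseudocount)
}
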