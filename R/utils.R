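`%||%` <- function(a, b) if (is.null(a)) b else a

# (lineage, generation) pairs present in an experiment or call set
.availablePairs <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    unique(data.frame(lineage = as.character(cd$lineage),
                      generation = as.integer(cd$generation),
                      stringsAsFactors = FALSE))
}

# map lineage -> condition from column metadata
.conditionMap <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- unique(data.frame(lineage = as.character(cd$lineage),
                           condition = as.character(cd$condition)))
    stats::setNames(m$condition, m$lineage)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
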