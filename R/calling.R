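#' Regress one generation's log2 counts against the founder
#'
#' The founder (generation 0) log2 counts are the predictor and the log2
#' counts of generation g in the same lineage are the response. Gene
#' expression uses local regression (loess, tricube weights, degree 2);
#' small-RNA classes use ordinary least squares with intercept. Residuals
#' (response minus fitted) feed the Z-score statistic.
#'
#' @param log2Founder,log2Gen numeric vectors of equal length (>= 10)
#' @param model \code{"loess"} or \code{"linear"}
#' @param span loess span in (0, 1]
#' @return a \code{RegressionFit} list: model, span, fitted, residuals
#' @export
fitGeneration <- function(log2Founder, log2Gen,
                          model = c("loess", "linear"), span = 0.75) {
    model <- match.arg(model)
    if (length(log2Founder) != length(log2Gen))
        .stopf("founder and generation vectors differ in length (%d vs %d)",
               length(log2Founder), length(log2Gen))
    n <- length(log2Founder)
    if (n < 10) .stopf("need at least 10 loci to fit (got %d)", n)
    if (model == "loess") {
        if (span <= 0 || span > 1) .stopf("span must be in (0, 1]")
        if (n < 30)
            .stopf("only %d loci: too few for loess; use model = 'linear'", n)
        fit <- stats::loess(log2Gen ~ log2Founder, span = span, degree = 2,
                            family = "gaussian",
                            control = stats::loess.control(surface = "interpolate"))
        fitted <- stats::fitted(fit)
    } else {
        fit <- stats::lm.fit(cbind(1, log2Founder), log2Gen)
        fitted <- log2Gen - fit$residuals
    }
    structure(list(model = model, span = if (model == "loess") span else NA,
                   fitted = as.numeric(fitted),
                   residuals = as.numeric(log2Gen - fitted)),
              class = "RegressionFit")
}

#' Residual Z-scores
#'
#' Centers the regression residuals on their mean and scales by their
#' standard deviation (n - 1 denominator), so each (lineage, generation)
#' column has mean 0 and SD 1 by construction.
#'
#' @param fit a \code{RegressionFit} from \code{\link{fitGeneration}}
#' @return numeric vector of Z-scores
#' @export
residualZ <- function(fit) {
    r <- fit$residuals
    s <- stats::sd(r)
    # residual SD at floating-point noise relative to the fitted scale is
    # as degenerate as exactly zero (e.g. a response identical to the fit)
    floor <- if (!is.null(fit$fitted)) 1e-8 * stats::sd(fit$fitted) else 0
    if (!is.finite(s) || s <= max(floor, 0))
        .stopf("degenerate column: residuals have zero variance")
    (r - mean(r)) / s
}

#' Ternary epimutation calls from Z-scores
#'
#' +1 (up epimutation) where z >= cutoff, -1 (down) where z <= -cutoff,
#' 0 otherwise. The comparison is inclusive at the boundary.
#'
#' @param z numeric vector or matrix of Z-scores
#' @param cutoff positive Z cutoff (default 2.25)
#' @return integer vector/matrix of calls in {-1, 0, +1}
#' @export
binarizeCalls <- function(z, cutoff = 2.25) {
    if (cutoff <= 0) .stopf("cutoff must be > 0")
    out <- (z >= cutoff) - (z <= -cutoff)
    storage.mode(out) <- "integer"
    if (is.matrix(z)) dimnames(out) <- dimnames(z)
    out
}

# shared core: normalized matrix + sample metadata -> EpimutationCalls
.callFromNormalized <- function(norm, meta, model, cutoff, span,
                                pseudocount) {
    lg <- log2p(norm, pseudocount)
    founderIdx <- which(meta$generation == 0L)
    names(founderIdx) <- meta$lineage[founderIdx]
    keep <- which(meta$generation != 0L)
    z <- matrix(NA_real_, nrow(lg), length(keep),
                dimnames = list(rownames(lg), colnames(lg)[keep]))
    for (j in seq_along(keep)) {
        col <- keep[j]
        f <- founderIdx[[meta$lineage[col]]]
        if (is.null(f) || is.na(f))
            .stopf("no founder sample for lineage %s", meta$lineage[col])
        fit <- fitGeneration(lg[, f], lg[, col], model = model, span = span)
        z[, j] <- tryCatch(residualZ(fit), error = function(e) {
            # a column identical to its fit (e.g. a constant table) carries
            # no deviation signal: score it all-zero rather than aborting
            warning(sprintf("column %s: zero residual variance; z set to 0",
                            colnames(lg)[col]), call. = FALSE)
            rep(0, nrow(lg))
        })
    }
    calls <- binarizeCalls(z, cutoff)
    cd <- S4Vectors::DataFrame(lineage = meta$lineage[keep],
                               condition = meta$condition[keep],
                               generation = meta$generation[keep],
                               row.names = colnames(lg)[keep])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(z = z, calls = calls), colData = cd)
    S4Vectors::metadata(se)$cutoff <- cutoff
    S4Vectors::metadata(se)$model <- model
    new("EpimutationCalls", se)
}

#' Call epimutations against the founder generation
#'
#' For every lineage and every sampled generation g > 0, regresses the
#' log2 normalized counts at g on the founder's, converts residuals to
#' Z-scores and makes ternary calls at |Z| >= cutoff. All-zero loci
#' (flagged removable) are dropped before fitting. Gene count matrices
#' default to loess; small-RNA class matrices default to the linear model,
#' matching how each data type is treated.
#'
#' @param x \linkS4class{MAExperiment}
#' @param model \code{"loess"} or \code{"linear"}; if \code{NULL}, chosen
#'   from the predominant \code{locus_class} (gene -> loess, else linear)
#' @param cutoff Z cutoff, default 2.25
#' @param span loess span
#' @param pseudocount added before log2 (default 1)
#' @param normalize apply median-of-ratios size factors first (default TRUE)
#' @return \linkS4class{EpimutationCalls}
#' @export
callEpimutations <- function(x, model = NULL, cutoff = 2.25, span = 0.75,
                             pseudocount = 1, normalize = TRUE) {
    stopifnot(is(x, "MAExperiment"))
    if (is.null(model)) {
        cls <- SummarizedExperiment::rowData(x)$locus_class
        model <- if (mean(cls == "gene") >= 0.5) "loess" else "linear"
    }
    keep <- !SummarizedExperiment::rowData(x)$removable
    x <- x[keep, ]
    norm <- if (normalize) normalizeCounts(x) else counts(x)
    meta <- data.frame(lineage = lineages(x), condition = conditions(x),
                       generation = generations(x))
    .callFromNormalized(norm, meta, model, cutoff, span, pseudocount)
}

# observed inherited fraction: nonzero calls (not at the lineage's last
# available generation) whose direction recurs at the next available
# generation of the same lineage
.inheritedCallPct <- function(calls, meta) {
    num <- 0L; den <- 0L
    for (ln in unique(meta$lineage)) {
        idx <- which(meta$lineage == ln)
        idx <- idx[order(meta$generation[idx])]
        if (length(idx) < 2) next
        for (j in seq_len(length(idx) - 1L)) {
            cur <- calls[, idx[j]]
            nxt <- calls[, idx[j + 1L]]
            nz <- cur != 0L
            den <- den + sum(nz)
            num <- num + sum(nz & nxt == cur)
        }
    }
    if (den == 0L) return(c(pct = NA_real_, n = 0))
    c(pct = 100 * num / den, n = den)
}

#' Calibrate the Z cutoff against an independent-call null
#'
#' For each candidate cutoff, compares the observed percentage of
#' epimutation calls inherited into the next sampled generation with the
#' percentage expected if calls arose independently per (locus, generation)
#' at the empirical per-column, per-direction rates. The expected value and
#' a one-sided Monte-Carlo p-value come from \code{nSim} redrawn call
#' matrices. The recommended cutoff is the largest grid value whose
#' observed inheritance significantly exceeds the null (p < 0.05) --
#' the logic behind adopting 2.25 as the working cutoff.
#'
#' @param x \linkS4class{MAExperiment}
#' @param cutoffs ascending grid of candidate cutoffs
#' @param nSim number of null simulations (>= 1)
#' @param seed integer seed for the null redraws
#' @param model,span,pseudocount,normalize passed to the caller
#' @return data.frame (cutoff, observed_pct, expected_pct, difference, p)
#'   with the recommended cutoff in \code{attr(, "recommended")}
#'   (NA when no cutoff reaches significance)
#' @export
calibrateCutoff <- function(x, cutoffs = c(1.5, 1.75, 2, 2.25, 2.5, 3),
                            nSim = 100, seed = NULL,
                            model = NULL, span = 0.75, pseudocount = 1,
                            normalize = TRUE) {
    if (!length(cutoffs)) .stopf("empty cutoff grid")
    if (is.unsorted(cutoffs)) .stopf("cutoff grid must be ascending")
    if (nSim < 1) .stopf("nSim must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    ec <- callEpimutations(x, model = model, cutoff = min(cutoffs),
                           span = span, pseudocount = pseudocount,
                           normalize = normalize)
    z <- zMatrix(ec)
    meta <- data.frame(lineage = lineages(ec), generation = generations(ec))
    nAvail <- sum(vapply(split(meta$generation, meta$lineage),
                         function(g) length(g) >= 2, logical(1)))
    if (nAvail == 0)
        .stopf("need at least 2 sampled generations in some lineage")
    out <- lapply(cutoffs, function(co) {
        calls <- binarizeCalls(z, co)
        obs <- .inheritedCallPct(calls, meta)
        pUp <- colMeans(calls == 1L)
        pDn <- colMeans(calls == -1L)
        sims <- vapply(seq_len(nSim), function(s) {
            u <- matrix(stats::runif(length(calls)), nrow(calls))
            up <- rep(pUp, each = nrow(calls))
            dn <- rep(pDn, each = nrow(calls))
            sim <- matrix(0L, nrow(calls), ncol(calls))
            sim[u < up] <- 1L
            sim[u >= up & u < up + dn] <- -1L
            .inheritedCallPct(sim, meta)[["pct"]]
        }, numeric(1))
        expPct <- mean(sims, na.rm = TRUE)
        p <- (1 + sum(sims >= obs[["pct"]], na.rm = TRUE)) / (1 + nSim)
        data.frame(cutoff = co, observed_pct = obs[["pct"]],
                   expected_pct = expPct,
                   difference = obs[["pct"]] - expPct, p = p)
    })
    res <- do.call(rbind, out)
    sig <- res$cutoff[res$p < 0.05]
    attr(res, "recommended") <- if (length(sig)) max(sig) else NA_real_
    res
}
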