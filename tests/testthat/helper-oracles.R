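# independent brute-force oracles, deliberately written with different
# algorithms than the package implementation

# median-of-ratios recomputed sample by sample with explicit loops
oracleSizeFactors <- function(cm) {
    keep <- apply(cm, 1, function(r) all(r > 0))
    sub <- cm[keep, , drop = FALSE]
    out <- numeric(ncol(cm))
    for (j in seq_len(ncol(sub))) {
        ratios <- numeric(nrow(sub))
        for (i in seq_len(nrow(sub)))
            ratios[i] <- sub[i, j] / prod(sub[i, ])^(1 / ncol(sub))
        out[j] <- median(ratios)
    }
    names(out) <- colnames(cm)
    out
}

# OLS through the normal equations
oracleLinearResiduals <- function(x, y) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    as.numeric(y - X %*% beta)
}

# per-locus state-machine re-walk for run detection (single locus/lineage)
oracleRuns <- function(calls, gens) {
    runs <- list()
    cur <- 0L; start <- NA; end <- NA; cnt <- 0L
    flush <- function() {
        if (cur != 0L)
            runs[[length(runs) + 1L]] <<- c(dir = cur, start = start,
                                            end = end, n = cnt)
    }
    for (j in seq_along(gens)) {
        d <- calls[j]
        if (d == cur && d != 0L) {
            cnt <- cnt + 1L; end <- gens[j]
        } else {
            flush()
            if (d != 0L) {
                cur <- d; start <- gens[j]; end <- gens[j]; cnt <- 1L
            } else cur <- 0L
        }
    }
    flush()
    if (!length(runs)) return(NULL)
    out <- as.data.frame(do.call(rbind, runs))
    out$censored <- out$end == gens[length(gens)]
    out
}

# two-sided Fisher p via explicit lchoose enumeration
oracleFisherP <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0, k - n2); hi <- min(k, m)
    xs <- lo:hi
    logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
    pr <- exp(logp)
    pobs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# exhaustive Jonckheere null via explicit permutation of pooled values
# (recursive multiset arrangement, counting J with a sort-free double loop)
oracleJonckheereP <- function(groups) {
    jval <- function(gl) {
        tot <- 0
        for (i in seq_along(gl)) for (j in seq_along(gl)) {
            if (j <= i) next
            for (x in gl[[i]]) for (y in gl[[j]])
                tot <- tot + (x < y) + 0.5 * (x == y)
        }
        tot
    }
    obs <- jval(groups)
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    count <- 0; ge <- 0
    recur <- function(remaining, gi, acc) {
        if (gi > length(sizes)) {
            count <<- count + 1
            ge <<- ge + (jval(acc) >= obs - 1e-9)
            return()
        }
        for (pick in combn(seq_along(remaining), sizes[gi],
                           simplify = FALSE)) {
            recur(remaining[-pick], gi + 1,
                  c(acc, list(remaining[pick])))
        }
    }
    recur(pooled, 1, list())
    ge / count
}

# quadratic-time read assignment: loop every read x locus, 1-based closed
# genome coordinates, tRNA-space start as the spec's arithmetic
oracleAssign <- function(reads, loci) {
    rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
    ls <- GenomicRanges::start(loci); le <- GenomicRanges::end(loci)
    strand <- as.character(GenomicRanges::strand(loci))
    out <- list()
    for (i in seq_along(reads)) {
        w <- re[i] - rs[i] + 1L
        if (w < 18 || w > 36) next
        for (l in seq_along(loci)) {
            if (rs[i] <= le[l] && re[i] >= ls[l]) {
                s <- if (strand[l] == "+") rs[i] - ls[l] else le[l] - re[i]
                L <- le[l] - ls[l] + 1L
                if (s >= 0 && s < L)
                    out[[length(out) + 1L]] <- c(read = i, locus = l,
                                                 start = s)
                break
            }
        }
    }
    if (!length(out)) return(data.frame(read = integer(), locus = integer(),
                                        start = integer()))
    as.data.frame(do.call(rbind, out))
}

# all-window Hamming scan over a character genome, both strands
oracleTargets <- function(fragSeq, genomeSeq, maxMismatch) {
    g <- utf8ToInt(genomeSeq)
    hits <- list()
    for (str in c("+", "-")) {
        pat <- if (str == "+") fragSeq else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(fragSeq)))
        p <- utf8ToInt(pat)
        k <- length(p); n <- length(g)
        if (n < k) next
        mm <- integer(n - k + 1)
        for (j in seq_len(k))
            mm <- mm + (g[j:(n - k + j)] != p[j])
        pos <- which(mm <= maxMismatch)
        if (length(pos))
            hits[[str]] <- data.frame(start = pos, strand = str,
                                      mismatches = mm[pos])
    }
    if (!length(hits)) return(data.frame(start = integer(),
                                         strand = character(),
                                         mismatches = integer()))
    do.call(rbind, c(hits, make.row.names = FALSE))
}

# brute-force variant/gene interval scan (1-based positions, GRanges genes)
oracleGeneHits <- function(pos, span, genes) {
    gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
    nm <- S4Vectors::mcols(genes)$name
    found <- character(0)
    for (gi in seq_along(genes))
        if (pos <= ge[gi] && (pos + span - 1) >= gs[gi])
            found <- c(found, nm[gi])
    found
}
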