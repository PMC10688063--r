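#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one. The odds ratio is the sample cross-product ratio a*d / (b*c)
#' (the convention behind the printed values in the study's tables):
#' +Inf when b*c = 0 with a*d > 0, NaN when both products are zero. The
#' conditional maximum-likelihood estimate from
#' \code{\link[stats]{fisher.test}} is also reported.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise: a b / c d)
#' @param labels optional list(rows = , cols = ) of dimension labels
#' @param cmle also compute the conditional-MLE odds ratio (default TRUE;
#'   disable in bulk enumeration where only p is needed)
#' @return an \code{Assoc2x2} list: counts, odds_ratio, odds_ratio_cmle, p
#' @examples
#' fisher2x2(75, 2, 912, 16)   # OR 0.66, p 0.64
#' @export
fisher2x2 <- function(a, b, c, d, labels = NULL, cmle = TRUE) {
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        .stopf("cell counts must be non-negative integers")
    if (sum(cells) == 0) .stopf("all-zero 2x2 table")
    or <- if (b * c > 0) (a * d) / (b * c) else
        if (a * d > 0) Inf else NaN
    p <- .fisherP(a, b, c, d)
    cmleEst <- if (cmle)
        unname(stats::fisher.test(matrix(cells, 2, byrow = TRUE))$estimate)
    else NA_real_
    structure(list(counts = matrix(cells, 2, byrow = TRUE),
                   labels = labels, odds_ratio = or,
                   odds_ratio_cmle = cmleEst, p = p),
              class = "Assoc2x2")
}

# sum of hypergeometric probabilities <= P(observed), with a relative
# guard so ties at the observed probability are included robustly
.fisherP <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0L, k - n2); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n2, k)
    pObs <- stats::dhyper(a, m, n2, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' @export
print.Assoc2x2 <- function(x, ...) {
    cat("2x2 association:\n")
    print(x$counts)
    cat(sprintf("odds ratio (sample) %.4g, (CMLE) %.4g, p = %.4g\n",
                x$odds_ratio, x$odds_ratio_cmle, x$p))
    invisible(x)
}

# do two runs share >= 1 sampled generation (interval overlap on the grid)?
.runsOverlap <- function(s1, e1, s2, e2) pmax(s1, s2) <= pmin(e1, e2)

#' Gene-centric integration of expression and small-RNA epimutation runs
#'
#' Builds, per (gene, lineage), the state needed for the association
#' battery: whether the gene has an expression change, whether any such
#' change is inherited (spans >= 2 sampled generations), whether the gene
#' has a small-RNA epimutation, whether expression and small-RNA runs are
#' simultaneous (share >= 1 sampled generation in the same lineage),
#' whether any simultaneous pair is concordant (same direction), and
#' whether any simultaneous small-RNA run is itself inherited.
#'
#' @param exprRuns expression runs from \code{\link{detectRuns}}
#' @param srnaRuns small-RNA runs mapped to gene ids (for tRNA fragments,
#'   via \code{\link{findTargets}}: a gene's tRNA state is the union over
#'   targeting tRNA types)
#' @param universe character vector of all genes (the background)
#' @param conditionMap named vector lineage -> condition
#' @return list with \code{states} (one row per (gene, lineage) having at
#'   least one run) plus the \code{universe} and \code{conditionMap}
#' @export
geneStates <- function(exprRuns, srnaRuns, universe, conditionMap) {
    keyse <- unique(rbind(exprRuns[c("locus", "lineage")],
                          srnaRuns[c("locus", "lineage")]))
    rows <- lapply(seq_len(nrow(keyse)), function(i) {
        g <- keyse$locus[i]; ln <- keyse$lineage[i]
        er <- exprRuns[exprRuns$locus == g & exprRuns$lineage == ln, ]
        sr <- srnaRuns[srnaRuns$locus == g & srnaRuns$lineage == ln, ]
        simul <- FALSE; conc <- FALSE; simulInh <- FALSE
        dirMatch <- NA
        if (nrow(er) && nrow(sr)) {
            pairs <- expand.grid(e = seq_len(nrow(er)), s = seq_len(nrow(sr)))
            ov <- .runsOverlap(er$start_gen[pairs$e], er$end_gen[pairs$e],
                               sr$start_gen[pairs$s], sr$end_gen[pairs$s])
            same <- er$direction[pairs$e] == sr$direction[pairs$s]
            simul <- any(ov)
            conc <- any(ov & same)
            simulInh <- any(ov & sr$n_sampled[pairs$s] >= 2L)
            dirMatch <- if (simul) any(ov & same) else any(same)
        }
        data.frame(gene = g, lineage = ln,
                   condition = unname(conditionMap[ln]),
                   has_expr = nrow(er) > 0,
                   expr_inherited = any(er$n_sampled >= 2L),
                   has_srna = nrow(sr) > 0,
                   srna_inherited = any(sr$n_sampled >= 2L),
                   simultaneous = simul, concordant = conc,
                   simultaneous_inherited_srna = simulInh,
                   direction_matched = dirMatch)
    })
    states <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene = character(), lineage = character(),
                   condition = character(), has_expr = logical(),
                   expr_inherited = logical(), has_srna = logical(),
                   srna_inherited = logical(), simultaneous = logical(),
                   concordant = logical(),
                   simultaneous_inherited_srna = logical(),
                   direction_matched = logical())
    list(states = states, universe = universe, conditionMap = conditionMap)
}

# gene-level aggregation over the lineages of one condition (lineages are
# combined within condition, as in the study's tables)
.geneLevel <- function(gs, condition) {
    st <- gs$states
    if (!is.null(condition)) st <- st[st$condition == condition, ]
    agg <- function(v) tapply(v, st$gene, any)
    if (!nrow(st))
        return(data.frame(gene = character(), has_expr = logical(),
                          expr_inherited = logical(), has_srna = logical(),
                          simultaneous = logical(),
                          simultaneous_inherited_srna = logical()))
    data.frame(gene = sort(unique(st$gene)),
               has_expr = agg(st$has_expr)[sort(unique(st$gene))],
               expr_inherited = agg(st$expr_inherited)[sort(unique(st$gene))],
               has_srna = agg(st$has_srna)[sort(unique(st$gene))],
               simultaneous = agg(st$simultaneous)[sort(unique(st$gene))],
               simultaneous_inherited_srna =
                   agg(st$simultaneous_inherited_srna)[sort(unique(st$gene))],
               row.names = NULL)
}

#' Stepwise association battery between expression changes and sRNA
#' epimutations
#'
#' Four nested Fisher tests per condition: (1) expression change x sRNA
#' epimutation over all genes; (2) inherited expression change x sRNA
#' epimutation over genes with expression changes; (3) inherited expression
#' change x simultaneous sRNA epimutation over genes with expression
#' changes; (4) as (3) over genes with both an expression change and an
#' sRNA epimutation. Tests whose table has an empty margin are reported
#' with p = NA.
#'
#' @param gs output of \code{\link{geneStates}}
#' @param condition condition label to restrict to (NULL = all)
#' @return named list of four \code{Assoc2x2} (or NA entries)
#' @export
stepwiseAssociation <- function(gs, condition = NULL) {
    gl <- .geneLevel(gs, condition)
    nUniverse <- length(gs$universe)
    t2x2 <- function(f1, f2, nTotal) {
        a <- sum(f1 & f2); b <- sum(f1 & !f2)
        c <- sum(!f1 & f2); d <- nTotal - a - b - c
        if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
            return(NA)
        fisher2x2(a, b, c, d)
    }
    withExpr <- gl[gl$has_expr, ]
    withBoth <- gl[gl$has_expr & gl$has_srna, ]
    list(
        test1 = t2x2(gl$has_expr, gl$has_srna, nUniverse),
        test2 = t2x2(withExpr$expr_inherited, withExpr$has_srna,
                     nrow(withExpr)),
        test3 = t2x2(withExpr$expr_inherited, withExpr$simultaneous,
                     nrow(withExpr)),
        test4 = t2x2(withBoth$expr_inherited, withBoth$simultaneous,
                     nrow(withBoth)))
}

#' Concordance of simultaneous expression and sRNA changes
#'
#' Among (gene, lineage) units carrying both an expression run and an sRNA
#' run, classifies direction-matched vs unmatched pairs and tests whether
#' matching is enriched among simultaneous units relative to
#' non-simultaneous ones: a 2x2 of {direction matched, unmatched} x
#' {simultaneous, non-simultaneous}. The concordant odds ratio is the
#' cross-product of that table; the discordant odds ratio is its
#' reciprocal orientation (same p).
#'
#' @param gs output of \code{\link{geneStates}}
#' @param condition condition to restrict to (NULL = all)
#' @return list (n_concordant, n_discordant, n_nonsimultaneous,
#'   concordant_or, discordant_or, p)
#' @export
concordance <- function(gs, condition = NULL) {
    st <- gs$states
    if (!is.null(condition)) st <- st[st$condition == condition, ]
    both <- st[st$has_expr & st$has_srna, ]
    if (!nrow(both) || !any(both$simultaneous))
        .stopf("no simultaneous expression/sRNA pairs in this condition")
    sim <- both[both$simultaneous, ]
    non <- both[!both$simultaneous, ]
    a <- sum(sim$direction_matched)          # matched, simultaneous
    b <- sum(!sim$direction_matched)         # unmatched, simultaneous
    c <- sum(non$direction_matched)
    d <- sum(!non$direction_matched)
    ft <- if ((c + d) > 0) fisher2x2(a, c, b, d) else NULL
    list(n_concordant = a, n_discordant = b, n_nonsimultaneous = nrow(non),
         concordant_or = if (is.null(ft)) NA else ft$odds_ratio,
         discordant_or = if (is.null(ft)) NA else {
             if (is.nan(ft$odds_ratio)) NaN else 1 / ft$odds_ratio
         },
         p = if (is.null(ft)) NA else ft$p)
}

#' Simultaneity breakdown of sRNA epimutations by expression inheritance
#'
#' Among genes with both an expression change and an sRNA epimutation,
#' stratified by whether the expression change is inherited, gives the
#' percentage split into: simultaneous with an inherited sRNA epimutation,
#' simultaneous with a non-inherited one, and non-simultaneous.
#' Percentages sum to 100 within each stratum.
#'
#' @param gs output of \code{\link{geneStates}}
#' @param condition condition to restrict to (NULL = all)
#' @return data.frame (stratum, simultaneous_inherited_pct,
#'   simultaneous_noninherited_pct, nonsimultaneous_pct, n_genes)
#' @export
simultaneityBreakdown <- function(gs, condition = NULL) {
    gl <- .geneLevel(gs, condition)
    both <- gl[gl$has_expr & gl$has_srna, ]
    if (!nrow(both)) .stopf("no genes with both change types")
    strat <- function(sub, label) {
        n <- nrow(sub)
        if (!n) return(data.frame(
            stratum = label, simultaneous_inherited_pct = NA_real_,
            simultaneous_noninherited_pct = NA_real_,
            nonsimultaneous_pct = NA_real_, n_genes = 0L))
        si <- sum(sub$simultaneous & sub$simultaneous_inherited_srna)
        sn <- sum(sub$simultaneous & !sub$simultaneous_inherited_srna)
        ns <- sum(!sub$simultaneous)
        data.frame(stratum = label,
                   simultaneous_inherited_pct = 100 * si / n,
                   simultaneous_noninherited_pct = 100 * sn / n,
                   nonsimultaneous_pct = 100 * ns / n, n_genes = n)
    }
    rbind(strat(both[both$expr_inherited, ], "inherited_expr"),
          strat(both[!both$expr_inherited, ], "noninherited_expr"))
}

#' Compare association odds between two sRNA classes
#'
#' Builds, per condition, the 2x2 table {expression change with
#' simultaneous class-X epimutation, expression change only} x {X = class
#' A, X = class B} and applies Fisher's exact test (the comparison behind
#' the printed 22G-RNA vs tRNA odds ratios).
#'
#' @param gsA,gsB \code{\link{geneStates}} outputs for the two classes
#'   (same expression runs and universe)
#' @param condition condition to restrict to (NULL = all)
#' @return \code{Assoc2x2}
#' @export
classComparison <- function(gsA, gsB, condition = NULL) {
    glA <- .geneLevel(gsA, condition)
    glB <- .geneLevel(gsB, condition)
    a <- sum(glA$has_expr & glA$simultaneous)
    b <- sum(glB$has_expr & glB$simultaneous)
    c <- sum(glA$has_expr & !glA$simultaneous)
    d <- sum(glB$has_expr & !glB$simultaneous)
    fisher2x2(a, b, c, d,
              labels = list(rows = c("expr change + simultaneous X",
                                     "expr change only"),
                            cols = c("classA", "classB")))
}

#' Fisher-based term enrichment with a minimum-gene rule
#'
#' For each annotation term with at least \code{minGenes} annotated genes
#' in the test list or in the background, tests the 2x2 {test vs
#' background} x {annotated vs not} with Fisher's exact test. P-values are
#' Bonferroni-adjusted by default. Terms failing the minimum-gene rule are
#' omitted and counted in \code{attr(, "n_excluded")}.
#'
#' @param testGenes character vector of test genes
#' @param backgroundGenes background gene set (disjoint from test)
#' @param annotation data.frame(gene, term)
#' @param minGenes minimum annotated genes in test or background (default 5)
#' @param p.adjust.method default "bonferroni"
#' @return data.frame (term, a, b, c, d, odds_ratio, p, p_adj)
#' @export
termEnrichment <- function(testGenes, backgroundGenes, annotation,
                           minGenes = 5L, p.adjust.method = "bonferroni") {
    terms <- unique(annotation$term)
    nT <- length(testGenes); nB <- length(backgroundGenes)
    rows <- list(); excluded <- 0L
    for (tm in terms) {
        ann <- unique(annotation$gene[annotation$term == tm])
        a <- sum(testGenes %in% ann)
        c <- sum(backgroundGenes %in% ann)
        if (a < minGenes && c < minGenes) {
            excluded <- excluded + 1L
            next
        }
        ft <- fisher2x2(a, nT - a, c, nB - c)
        rows[[length(rows) + 1L]] <- data.frame(
            term = tm, a = a, b = nT - a, c = c, d = nB - c,
            odds_ratio = ft$odds_ratio, p = ft$p)
    }
    res <- if (length(rows)) do.call(rbind, rows) else
        data.frame(term = character(), a = integer(), b = integer(),
                   c = integer(), d = integer(), odds_ratio = numeric(),
                   p = numeric())
    res$p_adj <- pmin(1, stats::p.adjust(res$p, p.adjust.method))
    attr(res, "n_excluded") <- excluded
    res
}
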