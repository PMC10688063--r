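run1 <- function(gene, lineage, dir = 1L, s = 2L, e = 2L) {
    data.frame(locus = gene, lineage = lineage, direction = dir,
               start_gen = s, end_gen = e,
               n_sampled = as.integer((e - s) / 2 + 1), censored = FALSE)
}
noRuns <- data.frame(locus = character(), lineage = character(),
                     direction = integer(), start_gen = integer(),
                     end_gen = integer(), n_sampled = integer(),
                     censored = logical())
cmap <- c(A = "control", B = "control")

test_that("Fisher 2x2 reproduces the published association tables", {
    ctrl <- fisher2x2(75, 2, 912, 16)
    expect_equal(round(ctrl$odds_ratio, 2), 0.66)
    expect_equal(round(ctrl$p, 2), 0.64)
    low <- fisher2x2(73, 4, 936, 8)
    expect_equal(round(low$odds_ratio, 2), 0.16)
    expect_equal(signif(low$p, 3), 9.30e-3)
    high <- fisher2x2(65, 6, 851, 8)
    expect_equal(round(high$odds_ratio, 2), 0.10)
    expect_equal(signif(high$p, 3), 2.96e-4)
    # zero cross-product: infinite odds
    expect_equal(fisher2x2(5, 0, 10, 10)$odds_ratio, Inf)
    expect_true(is.nan(fisher2x2(0, 0, 5, 0)$odds_ratio))
    expect_error(fisher2x2(0, 0, 0, 0), "all-zero")
})

test_that("two-sided p matches the lchoose enumeration oracle", {
    set.seed(41)
    for (i in 1:200) {
        cells <- rpois(4, 6)
        if (sum(cells) == 0) next
        got <- fisher2x2(cells[1], cells[2], cells[3], cells[4],
                         cmle = FALSE)$p
        want <- oracleFisherP(cells[1], cells[2], cells[3], cells[4])
        expect_equal(got, want, tolerance = 1e-12)
        # and stats::fisher.test at its own tolerance
        expect_equal(got, fisher.test(matrix(cells, 2,
                                             byrow = TRUE))$p.value,
                     tolerance = 1e-7)
    }
})

test_that("transposing a 2x2 table changes neither OR nor p", {
    set.seed(43)
    for (i in 1:50) {
        cells <- rpois(4, 5) + c(1, 0, 0, 1)
        f1 <- fisher2x2(cells[1], cells[2], cells[3], cells[4],
                        cmle = FALSE)
        f2 <- fisher2x2(cells[1], cells[3], cells[2], cells[4],
                        cmle = FALSE)
        expect_equal(f1$odds_ratio, f2$odds_ratio)
        expect_equal(f1$p, f2$p, tolerance = 1e-12)
    }
})

test_that("stepwise association flags coupling and degenerate margins", {
    # no sRNA epimutations anywhere: test1 margin empty, reported NA
    gs0 <- geneStates(run1("g1", "A"), noRuns,
                      universe = paste0("g", 1:50), conditionMap = cmap)
    expect_true(all(is.na(stepwiseAssociation(gs0)$test1)))

    # forced coupling: expression change wherever an sRNA run is active
    genes <- paste0("g", 1:50)
    expr <- do.call(rbind, lapply(genes[1:25], run1, lineage = "A",
                                  s = 4L, e = 6L))
    srna <- do.call(rbind, lapply(genes[1:25], run1, lineage = "A",
                                  s = 4L, e = 6L))
    gs <- geneStates(expr, srna, universe = genes, conditionMap = cmap)
    t1 <- stepwiseAssociation(gs)$test1
    expect_gt(t1$odds_ratio, 1)
    expect_lt(t1$p, 0.05)
})

test_that("independent runs do not inflate the stepwise association", {
    set.seed(50)
    genes <- paste0("g", 1:1000)
    sig <- 0
    for (s in 1:10) {
        pick1 <- sample(genes, 60); pick2 <- sample(genes, 60)
        expr <- do.call(rbind, lapply(pick1, run1, lineage = "A",
                                      s = 4L, e = 6L))
        srna <- do.call(rbind, lapply(pick2, run1, lineage = "A",
                                      s = 4L, e = 6L))
        gs <- geneStates(expr, srna, universe = genes,
                         conditionMap = cmap)
        t1 <- stepwiseAssociation(gs)$test1
        if (!all(is.na(t1)) && t1$p < 0.05) sig <- sig + 1
    }
    # null coupling: significant in at most ~1 of 10 replicates
    expect_lte(sig / 10, 0.2)
})

test_that("concordance separates matched from anticorrelated couplings", {
    genes <- paste0("g", 1:40)
    # all simultaneous pairs direction-matched: zero discordant
    expr <- do.call(rbind, lapply(genes[1:10], run1, lineage = "A",
                                  dir = 1L, s = 4L, e = 6L))
    srna <- do.call(rbind, lapply(genes[1:10], run1, lineage = "A",
                                  dir = 1L, s = 4L, e = 6L))
    gs <- geneStates(expr, srna, universe = genes, conditionMap = cmap)
    res <- concordance(gs)
    expect_equal(res$n_discordant, 0L)

    # anticorrelated: sRNA up forces expression down when simultaneous
    exprA <- rbind(
        do.call(rbind, lapply(genes[1:15], run1, lineage = "A",
                              dir = -1L, s = 4L, e = 6L)),
        do.call(rbind, lapply(genes[16:23], run1, lineage = "A",
                              dir = 1L, s = 14L, e = 16L)),
        do.call(rbind, lapply(genes[24:30], run1, lineage = "A",
                              dir = -1L, s = 14L, e = 16L)))
    srnaA <- do.call(rbind, lapply(genes[1:30], run1, lineage = "A",
                                   dir = 1L, s = 4L, e = 6L))
    gsA <- geneStates(exprA, srnaA, universe = genes, conditionMap = cmap)
    resA <- concordance(gsA)
    expect_gt(resA$discordant_or, 1)

    # no simultaneous pairs at all: explicit error
    exprN <- run1("g1", "A", s = 10L, e = 10L)
    srnaN <- run1("g1", "A", s = 2L, e = 2L)
    gsN <- geneStates(exprN, srnaN, universe = genes, conditionMap = cmap)
    expect_error(concordance(gsN), "simultaneous")
})

test_that("simultaneity breakdown percentages partition each stratum", {
    genes <- paste0("g", 1:10)
    # one gene, simultaneous inherited sRNA pair: 100 / 0 / 0
    expr <- run1("g1", "A", s = 4L, e = 8L)
    srna <- run1("g1", "A", s = 6L, e = 8L)
    gs <- geneStates(expr, srna, universe = genes, conditionMap = cmap)
    bd <- simultaneityBreakdown(gs)
    row <- bd[bd$stratum == "inherited_expr", ]
    expect_equal(row$simultaneous_inherited_pct, 100)
    expect_equal(row$nonsimultaneous_pct, 0)

    # constructed 60/20/20 split in the non-inherited stratum
    expr2 <- do.call(rbind, lapply(genes, run1, lineage = "A",
                                   s = 10L, e = 10L))
    srna2 <- rbind(
        do.call(rbind, lapply(genes[1:6], run1, lineage = "A",
                              s = 10L, e = 12L)),   # simultaneous inherited
        do.call(rbind, lapply(genes[7:8], run1, lineage = "A",
                              s = 10L, e = 10L)),   # simultaneous single
        do.call(rbind, lapply(genes[9:10], run1, lineage = "A",
                              s = 2L, e = 2L)))     # non-simultaneous
    gs2 <- geneStates(expr2, srna2, universe = genes, conditionMap = cmap)
    bd2 <- simultaneityBreakdown(gs2)
    row2 <- bd2[bd2$stratum == "noninherited_expr", ]
    expect_equal(row2$simultaneous_inherited_pct, 60)
    expect_equal(row2$simultaneous_noninherited_pct, 20)
    expect_equal(row2$nonsimultaneous_pct, 20)
    expect_equal(row2$simultaneous_inherited_pct +
                 row2$simultaneous_noninherited_pct +
                 row2$nonsimultaneous_pct, 100, tolerance = 1e-9)
})

test_that("class comparison reproduces a printed-table construction", {
    # identical classes: odds ratio exactly 1
    genes <- paste0("g", 1:30)
    expr <- do.call(rbind, lapply(genes[1:20], run1, lineage = "A",
                                  s = 4L, e = 6L))
    srna <- do.call(rbind, lapply(genes[1:10], run1, lineage = "A",
                                  s = 4L, e = 6L))
    gs <- geneStates(expr, srna, universe = genes, conditionMap = cmap)
    cc <- classComparison(gs, gs)
    expect_equal(cc$odds_ratio, 1)

    # and the published control-condition counts through fisher2x2
    tab3 <- fisher2x2(75, 2, 912, 16)
    expect_equal(round(tab3$odds_ratio, 2), 0.66)
    expect_equal(round(tab3$p, 2), 0.64)
})

test_that("term enrichment applies the five-gene rule and the oracle p", {
    genes <- paste0("g", 1:100)
    test <- genes[1:20]; bg <- genes[21:100]
    ann <- rbind(
        data.frame(gene = genes[c(1:2, 21:22)], term = "rare"),   # 4 genes
        data.frame(gene = genes[c(1:6, 21:30)], term = "common"))
    res <- termEnrichment(test, bg, ann)
    expect_false("rare" %in% res$term)
    expect_true("common" %in% res$term)
    expect_equal(attr(res, "n_excluded"), 1L)
    # p agrees with a direct hypergeometric tail computation
    want <- oracleFisherP(6, 14, 10, 70)
    expect_equal(res$p[res$term == "common"], want, tolerance = 1e-10)

    # equal annotation proportions: OR 1, p 1
    annEq <- data.frame(gene = genes[c(1:10, 21:60)], term = "eq")
    resEq <- termEnrichment(test, bg, annEq)
    expect_equal(resEq$odds_ratio, 1)
    expect_equal(resEq$p, 1, tolerance = 1e-12)
})
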