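mkLoci <- function(starts, widths, strands, types = NULL) {
    n <- length(starts)
    if (is.null(types)) types <- rep("GlyGCC", n)
    GenomicRanges::GRanges("chrT",
                           IRanges::IRanges(starts, width = widths),
                           strand = strands,
                           name = paste0("t", seq_len(n)),
                           trna_type = types)
}

test_that("read starts convert to tRNA coordinates per strand", {
    # BED-style locus [100,170) is GRanges 101..170
    lociP <- mkLoci(101, 70, "+")
    readP <- GenomicRanges::GRanges("chrT", IRanges::IRanges(141, 162))
    res <- assignReads(readP, lociP)
    expect_equal(which(res$profiles[[1]] == 1L) - 1L, 40L)

    lociM <- mkLoci(101, 70, "-")
    readM <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 122))
    res <- assignReads(readM, lociM)
    expect_equal(which(res$profiles[[1]] == 1L) - 1L, 48L)
})

test_that("assignment matches the quadratic oracle and conserves reads", {
    set.seed(55)
    loci <- mkLoci(seq(1000, by = 400, length.out = 8),
                   sample(60:90, 8, replace = TRUE),
                   rep(c("+", "-"), 4))
    n <- 1000
    rs <- sample(500:5000, n, replace = TRUE)
    w <- sample(15:40, n, replace = TRUE)   # some out of the 18-36 window
    reads <- GenomicRanges::GRanges("chrT",
                                    IRanges::IRanges(rs, width = w))
    res <- assignReads(reads, loci)
    want <- oracleAssign(reads, loci)
    # profile totals equal the oracle's per-locus assignment counts
    for (l in seq_along(loci))
        expect_equal(sum(res$profiles[[l]]),
                     sum(want$locus == l))
    # position-level agreement
    for (l in seq_along(loci)) {
        tab <- tabulate(want$start[want$locus == l] + 1L,
                        nbins = GenomicRanges::width(loci)[l])
        expect_equal(res$profiles[[l]], tab)
    }
    st <- res$stats
    expect_equal(st[["assigned"]] + st[["dropped_length"]] +
                 st[["dropped_clamped"]] + st[["unassigned"]],
                 st[["total"]])
    expect_error(assignReads(reads, mkLoci(c(100, 120), c(60, 60),
                                           c("+", "+"))), "overlapping")
})

test_that("the 3' half boundary sits at floor(length/2)", {
    loci <- mkLoci(1, 70, "+")
    r35 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(36, 55))
    r34 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(35, 54))
    p35 <- list(s = assignReads(r35, loci))
    p34 <- list(s = assignReads(r34, loci))
    expect_equal(threePrimeHalfCounts(p35, loci)["GlyGCC", "s"], 1)
    expect_equal(threePrimeHalfCounts(p34, loci)["GlyGCC", "s"], 0)
})

test_that("3' half counts aggregate by type and divide by size factors", {
    loci <- mkLoci(c(101, 501), c(70, 70), c("+", "+"))
    starts <- c(rep(141, 3), rep(541, 4))   # tRNA coordinate 40: 3' half
    reads <- GenomicRanges::GRanges("chrT",
                                    IRanges::IRanges(starts, width = 20),
                                    sample = "s1")
    prof <- fragmentProfiles(reads, loci)
    tab <- threePrimeHalfCounts(prof, loci,
                                sizeFactors = c(s1 = 1))
    expect_equal(tab["GlyGCC", "s1"], 7)
    tab2 <- threePrimeHalfCounts(prof, loci, sizeFactors = c(s1 = 2))
    expect_equal(tab2["GlyGCC", "s1"], 3.5)
})

test_that("simulated positional bias is recovered", {
    p <- simParams(trna = list(bias = 1, nLoci = 4, readsPerLocus = 50))
    sim <- simulateTrnaReads(p, seed = 3)
    prof <- fragmentProfiles(sim$reads, sim$loci)
    tab <- threePrimeHalfCounts(prof, sim$loci)
    total <- sum(vapply(prof, function(x) x$stats[["assigned"]],
                        numeric(1)))
    # bias 1: every assigned read is a 3' half read
    expect_equal(sum(tab), total)

    p <- simParams(trna = list(bias = 0.5, nLoci = 2,
                               readsPerLocus = 2500),
                   lineages = c(C1 = "control"),
                   generations = c(0L, 2L))
    sim <- simulateTrnaReads(p, seed = 4)
    prof <- fragmentProfiles(sim$reads, sim$loci)
    tab <- threePrimeHalfCounts(prof, sim$loci)
    total <- sum(vapply(prof, function(x) x$stats[["assigned"]],
                        numeric(1)))
    expect_equal(sum(tab) / total, 0.5, tolerance = 0.04)
})

test_that("minus-strand 3' halves sit at low genomic coordinates", {
    p <- simParams(trna = list(bias = 1, nLoci = 2, readsPerLocus = 100),
                   lineages = c(C1 = "control"), generations = c(0L, 2L))
    sim <- simulateTrnaReads(p, seed = 5)
    minus <- sim$loci[GenomicRanges::strand(sim$loci) == "-"]
    rds <- IRanges::subsetByOverlaps(sim$reads, minus)
    mid <- GenomicRanges::start(minus) + GenomicRanges::width(minus) / 2
    # 3' half of a minus-strand tRNA occupies the genomic first half
    expect_true(all(GenomicRanges::end(rds) <= mid + 1))
})

test_that("profiles are invariant under genome reverse-complement", {
    set.seed(66)
    G <- 6000L
    loci <- mkLoci(c(1001, 3001), c(70, 80), c("+", "-"))
    rs <- sample(900:3200, 300, replace = TRUE)
    reads <- GenomicRanges::GRanges("chrT",
                                    IRanges::IRanges(rs, width = 22))
    res1 <- assignReads(reads, loci)
    # flip all coordinates: pos' = G - end + 1, strand reversed
    flip <- function(gr) {
        GenomicRanges::GRanges(
            "chrT",
            IRanges::IRanges(G - GenomicRanges::end(gr) + 1L,
                             G - GenomicRanges::start(gr) + 1L),
            strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                            "-", "+"))
    }
    lociF <- flip(loci)
    S4Vectors::mcols(lociF) <- S4Vectors::mcols(loci)
    res2 <- assignReads(flip(reads), lociF)
    expect_equal(res1$profiles, res2$profiles)
})

test_that("tRNA table epimutation calling finds injected shifts", {
    shifts <- data.frame(type = "GlyGCC", lineage = "C1", log2fc = 3)
    shifts$generations <- list(c(10L, 12L))
    p <- simParams(trna = list(nLoci = 12, readsPerLocus = 300,
                               typeShifts = shifts))
    sim <- simulateTrnaReads(p, seed = 21)
    prof <- fragmentProfiles(sim$reads, sim$loci)
    tab <- threePrimeHalfCounts(prof, sim$loci)
    res <- trnaEpimutations(tab, sim$samples)
    hit <- res$runs[res$runs$locus == "GlyGCC" & res$runs$lineage == "C1", ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$direction, 1L)
    expect_equal(hit$start_gen, 10L)
    expect_equal(hit$end_gen, 12L)

    # constant table: no deviation signal, zero calls
    c1 <- sim$samples$sample[sim$samples$lineage == "C1"]
    const <- matrix(rep(seq(10, 120, 10), length(c1)), 12,
                    dimnames = list(paste0("t", 1:12), c1))
    suppressWarnings(
        res0 <- trnaEpimutations(const, sim$samples))
    expect_true(all(callMatrix(res0$calls) == 0L))

    # cutoff monotonicity carries over to the tRNA table
    n1 <- sum(callMatrix(trnaEpimutations(tab, sim$samples,
                                          cutoff = 2)$calls) != 0)
    n2 <- sum(callMatrix(trnaEpimutations(tab, sim$samples,
                                          cutoff = 3)$calls) != 0)
    expect_lte(n2, n1)
})

test_that("AGO enrichment is the input-normalized share ratio", {
    ip <- data.frame(ago = c("wago10", "ergo1"),
                     trna_reads = c(120, 0), total_reads = c(1e5, 1e5))
    inp <- data.frame(ago = c("wago10", "ergo1"),
                      trna_reads = c(100, 0), total_reads = c(1e5, 1e5))
    res <- agoEnrichment(ip, inp)
    expect_equal(res$enrichment[1], 1.2)
    expect_true(is.na(res$enrichment[2]))
    # IP identical to input
    expect_equal(agoEnrichment(ip[1, ], ip[1, ])$enrichment, 1)
    # the published-style construction: shares 1.2e-3 vs 1.0e-3
    res20 <- agoEnrichment(
        data.frame(ago = "x", trna_reads = 1200, total_reads = 1e6),
        data.frame(ago = "x", trna_reads = 1000, total_reads = 1e6))
    expect_equal(res20$enrichment, 1.2)
})

test_that("the >25 nt filter is strict", {
    reads <- GenomicRanges::GRanges("chrT",
                                    IRanges::IRanges(c(1, 100),
                                                     width = c(25, 26)))
    kept <- filterLongReads(reads)
    expect_equal(length(kept), 1L)
    expect_equal(GenomicRanges::width(kept), 26L)
})

test_that("target search matches the all-window Hamming oracle", {
    set.seed(88)
    chrSeq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                    collapse = "")
    genome <- Biostrings::DNAStringSet(c(chr1 = chrSeq))
    genes <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1, 2501),
                                                     c(2500, 5000)),
                                    name = c("geneA", "geneB"))
    # an exact planted match inside geneA
    frag <- substr(chrSeq, 1000, 1019)
    hits <- findTargets(Biostrings::DNAStringSet(c(GlyGCC = frag)), genome,
                        genes, maxMismatches = 0)
    expect_true(any(hits$gene == "geneA" & hits$start0 == 999 &
                    hits$mismatches == 0))

    # mismatch threshold: a 3-mismatch window needs k = 3
    f3 <- frag
    substr(f3, 1, 1) <- chartr("ACGT", "CAGT", substr(f3, 1, 1))
    substr(f3, 5, 5) <- chartr("ACGT", "GTAC", substr(f3, 5, 5))
    substr(f3, 9, 9) <- chartr("ACGT", "TGCA", substr(f3, 9, 9))
    fs <- Biostrings::DNAStringSet(c(GlyGCC = f3))
    h2 <- findTargets(fs, genome, genes, maxMismatches = 2)
    h3 <- findTargets(fs, genome, genes, maxMismatches = 3)
    expect_false(any(h2$start0 == 999))
    expect_true(any(h3$start0 == 999))

    # random fragments vs oracle
    for (i in 1:6) {
        fr <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE),
                    collapse = "")
        got <- findTargets(Biostrings::DNAStringSet(c(t1 = fr)), genome,
                           genes, maxMismatches = 3)
        want <- oracleTargets(fr, chrSeq, 3)
        gotKey <- sort(unique(paste(got$start0 + 1, got$strand,
                                    got$mismatches)))
        wantKey <- sort(unique(paste(want$start, want$strand,
                                     want$mismatches)))
        expect_equal(gotKey, wantKey)
    }
    expect_error(findTargets(Biostrings::DNAStringSet(c(x = "ACGTACGT")),
                             genome, genes), "15 nt")
})
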