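#' Mutation-accumulation fixation filter
#'
#' Separates true, fixed mutations from transient calls, per lineage:
#' (1) variant keys (chrom, pos, ref, alt) present at generation 0 are the
#' founder baseline and are discarded; (2) a key is fixed iff from its
#' first observed generation through the lineage's last available
#' generation it is observed at every available generation; (3) keys first
#' observed at the last available generation are discarded (they cannot be
#' verified by a later generation). Generations that were never assayed do
#' not break fixation. \code{maxDropout} optionally tolerates that many
#' missing intermediate observations (default 0, strict; the last available
#' generation must always be observed).
#'
#' @param variants data.frame of per-generation observations
#'   (chrom, pos, ref, alt, vtype, lineage, generation)
#' @param available data.frame(lineage, generation) of assayed pairs
#' @param maxDropout tolerated missing intermediate generations
#' @return data.frame of fixed mutations
#'   (chrom, pos, ref, alt, vtype, lineage, first_gen)
#' @export
fixationFilter <- function(variants, available, maxDropout = 0L) {
    out <- list()
    for (ln in unique(variants$lineage)) {
        v <- variants[variants$lineage == ln, , drop = FALSE]
        avail <- sort(available$generation[available$lineage == ln])
        if (!length(avail)) .stopf("no available generations for lineage %s",
                                   ln)
        last <- max(avail)
        key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
        gensByKey <- split(v$generation, key)
        first <- vapply(gensByKey, min, numeric(1))
        baseline <- vapply(gensByKey, function(g) 0L %in% g, logical(1))
        lastOnly <- first == last
        fixed <- vapply(seq_along(gensByKey), function(i) {
            g <- gensByKey[[i]]
            span <- avail[avail >= first[i]]
            if (!last %in% g) return(FALSE)
            sum(!span %in% g) <= maxDropout
        }, logical(1))
        sel <- names(gensByKey)[fixed & !baseline & !lastOnly]
        if (!length(sel)) next
        idx <- match(sel, key)
        out[[ln]] <- data.frame(
            chrom = v$chrom[idx], pos = v$pos[idx], ref = v$ref[idx],
            alt = v$alt[idx], vtype = v$vtype[idx], lineage = ln,
            first_gen = as.integer(first[sel]))
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), vtype = character(),
                   lineage = character(), first_gen = integer())
    rownames(res) <- NULL
    res
}

#' New fixed mutations per generation
#'
#' Counts fixed mutations by the generation at which they first appeared,
#' split by variant type, with zeros for every available (lineage,
#' generation > 0). Feeds \code{\link{rateTests}} for across-condition
#' comparisons of mutation rates.
#'
#' @param fixed data.frame from \code{\link{fixationFilter}}
#' @param available data.frame(lineage, generation)
#' @return data.frame (lineage, generation, vtype, n_new)
#' @export
perGenerationCounts <- function(fixed, available) {
    av <- available[available$generation > 0L, , drop = FALSE]
    grid <- merge(av, data.frame(vtype = c("SNP", "indel")))
    cnt <- table(paste(fixed$lineage, fixed$first_gen, fixed$vtype))
    key <- paste(grid$lineage, grid$generation, grid$vtype)
    grid$n_new <- as.integer(cnt[key])
    grid$n_new[is.na(grid$n_new)] <- 0L
    grid[order(grid$lineage, grid$generation, grid$vtype), ] |>
        (\(d) { rownames(d) <- NULL; d })()
}

#' Annotate fixed mutations with overlapping gene bodies
#'
#' A SNP hits a gene when its (1-based) position falls within the gene
#' body; an indel uses its reference-allele span. Gene bodies include
#' exons and introns (whole-gene intervals).
#'
#' @param fixed data.frame from \code{\link{fixationFilter}}
#' @param geneBodies \code{GRanges} with a \code{name} column
#' @return \code{fixed} with a \code{gene_hits} character column
#'   (comma-separated gene names, "" when none)
#' @export
geneOverlap <- function(fixed, geneBodies) {
    if (!nrow(fixed)) {
        fixed$gene_hits <- character(0)
        return(fixed)
    }
    span <- ifelse(fixed$vtype == "indel", nchar(fixed$ref), 1L)
    vgr <- GenomicRanges::GRanges(
        fixed$chrom, IRanges::IRanges(fixed$pos, fixed$pos + span - 1L))
    ov <- GenomicRanges::findOverlaps(vgr, geneBodies, minoverlap = 1L,
                                      ignore.strand = TRUE)
    geneNames <- S4Vectors::mcols(geneBodies)$name %||%
        as.character(seq_along(geneBodies))
    hitList <- split(geneNames[S4Vectors::subjectHits(ov)],
                     factor(S4Vectors::queryHits(ov),
                            levels = seq_len(nrow(fixed))))
    fixed$gene_hits <- vapply(hitList, paste, character(1), collapse = ",")
    fixed
}

#' Genes with both an expression change and a fixed DNA mutation
#'
#' Joins gene-annotated fixed mutations with gene-expression epimutation
#' runs on (gene, lineage) and flags simultaneity: any expression-run
#' generation at or after the mutation's first generation (once fixed, the
#' mutation is present in every later generation).
#'
#' @param fixedWithGenes output of \code{\link{geneOverlap}}
#' @param runs gene-expression runs from \code{\link{detectRuns}} (locus =
#'   gene id)
#' @return data.frame (gene, lineage, expr_generations, mutation_first_gen,
#'   simultaneous)
#' @export
mutationExpressionOverlap <- function(fixedWithGenes, runs) {
    empty <- data.frame(gene = character(), lineage = character(),
                        expr_generations = character(),
                        mutation_first_gen = integer(),
                        simultaneous = logical())
    if (!nrow(fixedWithGenes) || !nrow(runs)) return(empty)
    hasHit <- fixedWithGenes$gene_hits != ""
    if (!any(hasHit)) return(empty)
    mut <- fixedWithGenes[hasHit, , drop = FALSE]
    expanded <- do.call(rbind, lapply(seq_len(nrow(mut)), function(i)
        data.frame(gene = strsplit(mut$gene_hits[i], ",")[[1]],
                   lineage = mut$lineage[i],
                   first_gen = mut$first_gen[i])))
    out <- list()
    for (i in seq_len(nrow(expanded))) {
        rr <- runs[runs$locus == expanded$gene[i] &
                   runs$lineage == expanded$lineage[i], , drop = FALSE]
        if (!nrow(rr)) next
        gens <- unlist(lapply(seq_len(nrow(rr)), function(j)
            seq(rr$start_gen[j], rr$end_gen[j], by = 2L)))
        out[[length(out) + 1L]] <- data.frame(
            gene = expanded$gene[i], lineage = expanded$lineage[i],
            expr_generations = paste(sort(unique(gens)), collapse = "_"),
            mutation_first_gen = expanded$first_gen[i],
            simultaneous = any(gens >= expanded$first_gen[i]))
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
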