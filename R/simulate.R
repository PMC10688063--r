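#' Simulation parameters for a synthetic MA-line experiment
#'
#' \code{SimParams} bundles every knob of the synthetic data generator that
#' emulates the study design: six lineages (two per exposure condition)
#' bottlenecked for 20 generations and sampled on the even-generation grid,
#' negative-binomial baseline counts, epimutations born at a per-locus
#' per-generation rate with geometrically distributed persistence, tRNA loci
#' emitting positionally biased small-RNA reads, and per-generation variant
#' calls containing fixed, transient, founder-baseline and
#' last-generation-only variants.
#'
#' @slot nLoci number of expression loci
#' @slot lineages named character vector mapping lineage id to condition
#' @slot generations strictly increasing even sampling grid (founder = 0)
#' @slot baselineLog2MeanRange founder log2 mean counts drawn uniformly
#'   from this interval
#' @slot nbDispersion negative-binomial size (shape) parameter shared
#'   across loci; larger is less overdispersed
#' @slot birthRate per-locus, per-sampled-generation epimutation birth
#'   probability
#' @slot persistenceP probability that an active epimutation persists one
#'   more sampled generation (duration is 1 + geometric)
#' @slot effectSizeSD injected shift in units of the regression residual SD
#' @slot missingSamples data.frame(lineage, generation) of omitted samples
#' @slot trna list of tRNA-read simulation knobs (see
#'   \code{\link{simulateTrnaReads}})
#' @slot variants list of variant simulation knobs (see
#'   \code{\link{simulateVariants}})
#' @export
setClass("SimParams", representation(
    nLoci = "integer", lineages = "character", generations = "integer",
    baselineLog2MeanRange = "numeric", nbDispersion = "numeric",
    birthRate = "numeric", persistenceP = "numeric", effectSizeSD = "numeric",
    missingSamples = "data.frame", trna = "list", variants = "list"))

.validSimParams <- function(object) {
    msgs <- character()
    g <- object@generations
    if (g[1] != 0L || any(diff(g) <= 0) || any(g %% 2L != 0L))
        msgs <- c(msgs,
            "generations must start at 0, be even and strictly increasing")
    for (p in c(birthRate = object@birthRate,
                persistenceP = object@persistenceP))
        if (p < 0 || p > 1)
            msgs <- c(msgs, "probabilities must lie in [0, 1]")
    if (object@nbDispersion <= 0)
        msgs <- c(msgs, "nbDispersion must be > 0")
    r <- object@baselineLog2MeanRange
    if (length(r) != 2 || r[1] >= r[2])
        msgs <- c(msgs, "baselineLog2MeanRange must be an interval (lo, hi)")
    if (length(msgs)) msgs else TRUE
}
setValidity("SimParams", .validSimParams)

#' @rdname SimParams-class
#' @param nLoci,lineages,generations,baselineLog2MeanRange,nbDispersion
#'   see slots
#' @param birthRate,persistenceP,effectSizeSD,missingSamples,trna,variants
#'   see slots
#' @details Defaults reproduce the study conditions: lineages C1/C2
#'   (control), L1/L2 (low dose), H1/H2 (high dose); generations 0-20 step
#'   2; RNA-seq samples C2 generation 12 and H1 generation 20 omitted. The
#'   epimutation birth rate defaults to 1e-3 per locus per sampled
#'   generation (an order-of-magnitude choice; the observed per-generation
#'   rate is not pinned down numerically) and persistence to 0.5, giving a
#'   mean duration of two sampled generations.
#' @export
simParams <- function(nLoci = 2000,
                      lineages = c(C1 = "control", C2 = "control",
                                   L1 = "low_dose", L2 = "low_dose",
                                   H1 = "high_dose", H2 = "high_dose"),
                      generations = seq(0L, 20L, 2L),
                      baselineLog2MeanRange = c(5, 12),
                      nbDispersion = 10,
                      birthRate = 1e-3,
                      persistenceP = 0.5,
                      effectSizeSD = 4,
                      missingSamples = data.frame(
                          lineage = c("C2", "H1"),
                          generation = c(12L, 20L)),
                      trna = list(),
                      variants = list()) {
    trna <- utils::modifyList(list(
        nLoci = 12L,
        lengths = NULL,
        bias = 0.8,
        readsPerLocus = 200,
        conditionMultipliers = c(control = 1, low_dose = 1.5, high_dose = 2),
        typeShifts = NULL), trna)
    variants <- utils::modifyList(list(
        nFixed = 8L, nTransient = 8L, nBaseline = 4L, nLastOnly = 2L),
        variants)
    new("SimParams", nLoci = as.integer(nLoci), lineages = lineages,
        generations = as.integer(generations),
        baselineLog2MeanRange = baselineLog2MeanRange,
        nbDispersion = nbDispersion, birthRate = birthRate,
        persistenceP = persistenceP, effectSizeSD = effectSizeSD,
        missingSamples = missingSamples, trna = trna, variants = variants)
}

# Predicted residual SD of the log2(count + 1) regression of one generation
# against the founder. Per-locus log2 noise variance by the delta method is
# (1/mu + 1/size) / ln(2)^2; both response and predictor carry that noise,
# so the regression residual variance is v * (2 * Vm + v) / (Vm + v) with
# Vm the variance of the uniform baseline log2 means (errors-in-variables
# slope attenuation).
.predictedResidualSD <- function(params) {
    lo <- params@baselineLog2MeanRange[1]
    hi <- params@baselineLog2MeanRange[2]
    Einvmu <- (2^(-lo) - 2^(-hi)) / ((hi - lo) * log(2))
    v <- (Einvmu + 1 / params@nbDispersion) / log(2)^2
    Vm <- (hi - lo)^2 / 12
    sqrt(v * (2 * Vm + v) / (Vm + v))
}

.availForLineage <- function(params, lineage) {
    g <- params@generations
    ms <- params@missingSamples
    drop <- ms$generation[ms$lineage == lineage]
    setdiff(g, drop)
}

#' Simulate a multigenerational count matrix with known epimutations
#'
#' Draws founder log2 means uniformly from the baseline range, injects
#' epimutations (Bernoulli births per locus and sampled generation,
#' geometric persistence on the sampled grid, equiprobable direction) as
#' shifts of \code{effectSizeSD} regression-residual SDs in log2 mean, and
#' emits negative-binomial counts around \code{2^(log2mean + shift)}.
#' Listed missing samples are omitted from the output columns (the injected
#' truth keeps the full span).
#'
#' @param params \linkS4class{SimParams}
#' @param seed integer seed; all randomness flows from it
#' @param founderNoise draw the founder sample with the same
#'   negative-binomial noise as every other sample (TRUE, the study
#'   design: the founder is sequenced once). FALSE is a diagnostic mode
#'   with deterministic founder counts \code{round(2^log2mean)}: it
#'   removes the founder-measurement-noise channel that correlates the
#'   residuals of consecutive generations (all generations regress on the
#'   same founder sample), isolating true inheritance from that artifact.
#' @return list with \code{experiment} (\linkS4class{MAExperiment}) and
#'   \code{truth}, a data.frame of injected epimutations
#'   (locus, lineage, direction, start_gen, end_gen)
#' @export
simulateCounts <- function(params, seed = NULL, founderNoise = TRUE) {
    if (!is.null(seed)) set.seed(seed)
    n <- params@nLoci
    loci <- sprintf("L%05d", seq_len(n))
    m <- stats::runif(n, params@baselineLog2MeanRange[1],
                      params@baselineLog2MeanRange[2])
    delta <- params@effectSizeSD * .predictedResidualSD(params)
    k <- params@nbDispersion
    gens <- params@generations
    g2 <- gens[-1]
    counts <- list(); meta <- list()
    truth <- list()
    for (ln in names(params@lineages)) {
        cond <- params@lineages[[ln]]
        avail <- .availForLineage(params, ln)
        # founder
        if (0L %in% avail) {
            sid <- sprintf("%s_g0", ln)
            counts[[sid]] <- if (founderNoise)
                stats::rnbinom(n, mu = 2^m, size = k)
            else round(2^m)
            meta[[sid]] <- data.frame(sample = sid, lineage = ln,
                                      condition = cond, generation = 0L)
        }
        activeUntil <- integer(n)   # index into g2; 0 = inactive
        dirCur <- numeric(n)
        for (j in seq_along(g2)) {
            idle <- activeUntil < j
            born <- which(idle & stats::runif(n) < params@birthRate)
            if (length(born)) {
                dur <- stats::rgeom(length(born),
                                    1 - params@persistenceP) + 1L
                endj <- pmin(j + dur - 1L, length(g2))
                dirs <- sample(c(-1, 1), length(born), replace = TRUE)
                activeUntil[born] <- endj
                dirCur[born] <- dirs
                truth[[length(truth) + 1L]] <- data.frame(
                    locus = loci[born], lineage = ln, direction = dirs,
                    start_gen = g2[j], end_gen = g2[endj])
            }
            eff <- ifelse(activeUntil >= j, dirCur, 0)
            if (g2[j] %in% avail) {
                sid <- sprintf("%s_g%d", ln, g2[j])
                counts[[sid]] <- stats::rnbinom(
                    n, mu = 2^(m + delta * eff), size = k)
                meta[[sid]] <- data.frame(sample = sid, lineage = ln,
                                          condition = cond,
                                          generation = g2[j])
            }
        }
    }
    cm <- do.call(cbind, counts)
    rownames(cm) <- loci
    md <- do.call(rbind, meta)
    x <- MAExperiment(cm, lineage = md$lineage, condition = md$condition,
                      generation = md$generation)
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(locus = character(), lineage = character(),
                   direction = numeric(), start_gen = integer(),
                   end_gen = integer())
    list(experiment = x, truth = truth)
}

.defaultTrnaTypes <- c("GlyGCC", "GluCTC", "GlnTTG", "ValAAC", "SerCGA",
                       "LysCTT", "AlaAGC", "ProAGG", "ThrAGT", "IleAAT",
                       "LeuAAG", "ArgACG")

#' Simulate tRNA loci and positionally biased small-RNA reads
#'
#' Places tRNA loci non-overlapping on a synthetic chromosome (alternating
#' strands), then draws 18-36 nt reads per locus and sample whose start
#' position (in tRNA 5'->3' coordinates) falls in the 3' half of the locus
#' with probability \code{bias}, uniform within the chosen half. Read counts
#' per locus scale with the condition multiplier of the sample's lineage;
#' optional \code{typeShifts} (data.frame type, lineage, generations list,
#' log2fc) inject tRNA-level epimutations.
#'
#' @param params \linkS4class{SimParams} (uses the \code{trna} list)
#' @param seed integer seed
#' @return list with \code{loci} (GRanges with \code{trna_type}),
#'   \code{reads} (GRanges with \code{sample} column), \code{samples}
#'   (data.frame sample metadata) and \code{truth}
#' @export
simulateTrnaReads <- function(params, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    tc <- params@trna
    nl <- tc$nLoci
    lens <- tc$lengths %||% rep(c(72L, 76L, 80L, 84L, 88L, 90L, 74L, 78L,
                                  82L, 86L, 73L, 77L), length.out = nl)
    if (length(lens) != nl) lens <- rep(lens, length.out = nl)
    types <- rep(.defaultTrnaTypes, length.out = nl)
    gap <- 200L
    starts <- cumsum(c(1000L, utils::head(lens, -1) + gap))
    loci <- GenomicRanges::GRanges(
        "chrSim", IRanges::IRanges(starts, width = lens),
        strand = rep(c("+", "-"), length.out = nl),
        name = paste0("t", types, "-", seq_len(nl)), score = 0L,
        trna_type = types)
    gens <- params@generations
    meta <- expand.grid(lineage = names(params@lineages), generation = gens,
                        stringsAsFactors = FALSE)
    meta$condition <- params@lineages[meta$lineage]
    meta$sample <- sprintf("%s_g%d", meta$lineage, meta$generation)
    half <- floor(lens / 2)
    out <- list()
    for (i in seq_len(nrow(meta))) {
        mult <- tc$conditionMultipliers[[meta$condition[i]]] %||% 1
        for (l in seq_len(nl)) {
            lam <- tc$readsPerLocus * mult
            ts <- tc$typeShifts
            if (!is.null(ts)) {
                hit <- ts$type == types[l] & ts$lineage == meta$lineage[i] &
                    vapply(ts$generations, function(g)
                        meta$generation[i] %in% g, logical(1))
                if (any(hit)) lam <- lam * 2^sum(ts$log2fc[hit])
            }
            nr <- stats::rpois(1, lam)
            if (nr == 0) next
            in3p <- stats::runif(nr) < tc$bias
            s <- integer(nr)
            L <- lens[l]; h <- half[l]
            s[in3p] <- h + sample.int(L - h, sum(in3p), replace = TRUE) - 1L
            s[!in3p] <- sample.int(h, sum(!in3p), replace = TRUE) - 1L
            w <- sample(18:36, nr, replace = TRUE)
            if (as.character(GenomicRanges::strand(loci[l])) == "+") {
                rs <- starts[l] + s
                re <- rs + w - 1L
            } else {
                re <- starts[l] + L - 1L - s
                rs <- re - w + 1L
            }
            out[[length(out) + 1L]] <- data.frame(
                start = rs, end = re,
                strand = as.character(GenomicRanges::strand(loci[l])),
                sample = meta$sample[i])
        }
    }
    df <- do.call(rbind, out)
    reads <- GenomicRanges::GRanges(
        "chrSim", IRanges::IRanges(df$start, df$end), strand = df$strand,
        sample = df$sample)
    list(loci = loci, reads = reads,
         samples = meta[, c("sample", "lineage", "condition", "generation")],
         truth = list(bias = tc$bias,
                      conditionMultipliers = tc$conditionMultipliers,
                      typeShifts = tc$typeShifts))
}

#' Simulate per-generation variant observations with known fixation status
#'
#' Generates, per lineage: founder-baseline variants (observed at every
#' available generation including 0), fixed variants (first seen at an
#' intermediate generation and observed at every available generation from
#' then through the last), last-generation-only variants, and transient
#' variants whose observations stop before the last available generation
#' (violating fixation).
#'
#' @param params \linkS4class{SimParams} (uses the \code{variants} list)
#' @param seed integer seed
#' @return list with \code{observations} (data.frame of per-generation
#'   variant records) and \code{truth} (one row per variant with its
#'   category and first generation)
#' @export
simulateVariants <- function(params, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    vc <- params@variants
    bases <- c("A", "C", "G", "T")
    obs <- list(); truth <- list()
    nTot <- (vc$nFixed + vc$nTransient + vc$nBaseline + vc$nLastOnly) *
        length(params@lineages)
    pos <- sample.int(1e6, nTot)
    i <- 0L
    for (ln in names(params@lineages)) {
        avail <- .availForLineage(params, ln)
        last <- max(avail)
        mid <- setdiff(avail, c(0L, last))
        mk <- function(category, firstGen, gensObs) {
            i <<- i + 1L
            isSNP <- (i %% 2L) == 0L
            ref <- sample(bases, 1)
            alt <- if (isSNP) sample(setdiff(bases, ref), 1) else
                paste0(ref, sample(bases, 1))
            vt <- if (isSNP) "SNP" else "indel"
            truth[[i]] <<- data.frame(chrom = "chrSim", pos = pos[i],
                                      ref = ref, alt = alt, vtype = vt,
                                      lineage = ln, category = category,
                                      first_gen = firstGen)
            obs[[i]] <<- data.frame(chrom = "chrSim", pos = pos[i],
                                    ref = ref, alt = alt, vtype = vt,
                                    lineage = ln, generation = gensObs)
        }
        for (v in seq_len(vc$nBaseline))
            mk("baseline", 0L, avail)
        for (v in seq_len(vc$nFixed)) {
            fg <- sample(mid, 1)
            mk("fixed", fg, avail[avail >= fg])
        }
        for (v in seq_len(vc$nLastOnly))
            mk("last_only", last, last)
        for (v in seq_len(vc$nTransient)) {
            fg <- sample(mid, 1)
            span <- avail[avail >= fg & avail < last]
            endIdx <- sample.int(length(span), 1)
            mk("transient", fg, span[seq_len(endIdx)])
        }
    }
    list(observations = do.call(rbind, obs), truth = do.call(rbind, truth))
}
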