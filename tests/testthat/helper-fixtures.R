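# small in-code fixtures shared across test files

# minimal two-lineage experiment: 2 lineages x generations 0..gmax step 2
tinyExperiment <- function(nLoci = 50, gens = c(0, 2, 4), seed = 11) {
    set.seed(seed)
    meta <- expand.grid(lineage = c("A", "B"), generation = gens,
                        stringsAsFactors = FALSE)
    cm <- matrix(rnbinom(nLoci * nrow(meta), mu = 200, size = 10),
                 nLoci, nrow(meta))
    rownames(cm) <- sprintf("g%03d", seq_len(nLoci))
    colnames(cm) <- sprintf("%s_g%d", meta$lineage, meta$generation)
    MAExperiment(cm, lineage = meta$lineage,
                 condition = ifelse(meta$lineage == "A", "control",
                                    "low_dose"),
                 generation = meta$generation)
}

# a call matrix + meta wrapper for run-detection tests: one locus, one
# lineage, calls given per generation
callFixture <- function(calls, gens = seq(2, by = 2,
                                          length.out = length(calls)),
                        lineage = "A") {
    m <- matrix(as.integer(calls), nrow = 1,
                dimnames = list("locus1", sprintf("%s_g%d", lineage, gens)))
    list(calls = m,
         meta = data.frame(lineage = lineage, generation = gens))
}
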