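# shared fixtures, built in code; heavyweight ones are memoized per run

toyGenome <- function() {
    Biostrings::DNAStringSet(c(chr1 = "AACATGGGCATGTT"))
}

toyMap <- function(indexed = TRUE, minLength = 2L) {
    fm <- digestGenome(toyGenome())
    if (indexed) fm <- buildSequenceIndex(fm, toyGenome(),
                                          minLength = minLength)
    fm
}

# a ChainSet built directly from member id lists (unit-test scaffolding)
makeChainSet <- function(members, viewpointId) {
    new("ChainSet",
        readId = sprintf("r%03d", seq_along(members)),
        viewpointId = as.integer(viewpointId),
        members = IRanges::IntegerList(lapply(members, as.integer)),
        orientation = IRanges::CharacterList(
            lapply(lengths(members), function(n) rep("+", n))),
        rejections = c(retained = length(members), OFF_TARGET = 0L,
                       EMPTY_AFTER_FILTER = 0L),
        memberDrops = integer(0))
}

# synthetic fragment map: one chromosome tiled by uniform fragments,
# without going through sequence simulation (fast, for binning tests)
uniformMap <- function(n = 100L, width = 1000L, chrom = "chrU") {
    gr <- GenomicRanges::GRanges(
        chrom,
        IRanges::IRanges(start = (seq_len(n) - 1L) * width + 1L,
                         width = width),
        fragment_id = seq_len(n) - 1L)
    new("FragmentMap",
        enzyme = restrictionEnzyme("NlaIII-like", "CATG", 4L),
        fragments = gr,
        seqIndex = new.env(), indexStats = integer(0))
}

.fixtureCache <- new.env()

# one 100 kb simulated locus shared by the module tests
smallSim <- function() {
    if (is.null(.fixtureCache$smallSim)) {
        m <- locusModel(genomeLength = 1e5, viewpointPos = 5e4)
        .fixtureCache$smallSim <- list(model = m,
                                       sim = simulateGenome(m, seed = 42))
    }
    .fixtureCache$smallSim
}

# the full-size study locus (500 kb) shared by calibration tests
studySim <- function() {
    if (is.null(.fixtureCache$studySim)) {
        m <- locusModel(boundaryPos = 350000)
        .fixtureCache$studySim <- list(model = m,
                                       sim = simulateGenome(m, seed = 2024))
    }
    .fixtureCache$studySim
}
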