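test_that("simulated genomes have the planted fragment density", {
    sm <- smallSim()                     # 100 kb, 150 bp mean spacing
    nf <- length(fragmentRanges(sm$sim$map))
    expect_gt(nf, 1e5 / 150 * 0.9)
    expect_lt(nf, 1e5 / 150 * 1.1)
    # all fragment sequences unique (index has no ambiguous entries)
    expect_equal(unname(sm$sim$map@indexStats[["ambiguous"]]), 0L)
})

test_that("digesting the emitted FASTA reproduces the planted map", {
    sm <- smallSim()
    f <- withr::local_tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(sm$sim$genome, f)
    gr2 <- fragmentRanges(digestGenome(f, mapEnzyme(sm$sim$map)))
    gr <- fragmentRanges(sm$sim$map)
    expect_equal(start(gr2), start(gr))
    expect_equal(end(gr2), end(gr))
})

test_that("simulation is deterministic under a fixed seed", {
    m <- locusModel(genomeLength = 3e4, viewpointPos = 1.5e4)
    a <- simulateGenome(m, seed = 5)
    b <- simulateGenome(m, seed = 5)
    expect_identical(as.character(a$genome), as.character(b$genome))
    la <- simulateReads(m, a, 100, seed = 9)
    lb <- simulateReads(m, b, 100, seed = 9)
    expect_identical(la$reads, lb$reads)
    expect_identical(la$truth, lb$truth)
    # FASTQ files are byte-identical
    f1 <- withr::local_tempfile(fileext = ".fq")
    f2 <- withr::local_tempfile(fileext = ".fq")
    writeSimFastq(la, f1); writeSimFastq(lb, f2)
    expect_identical(readLines(f1), readLines(f2))
    lc <- simulateReads(m, a, 100, seed = 10)
    expect_false(identical(la$reads, lc$reads))
})

test_that("planted chains are recovered by the read pipeline", {
    sm <- smallSim()
    lib <- simulateReads(sm$model, sm$sim, 1000, seed = 77)
    ch <- readsToChains(lib$reads, sm$sim$map, lib$viewpointId)
    truthCh <- truthChains(lib)
    # >= 99.9% of reads recovered identically post-filter
    expect_gte(length(ch), 999L)
    expect_identical(as.list(chainMembers(ch)),
                     as.list(chainMembers(truthCh))[match(ch@readId,
                                                  truthCh@readId)])
})

test_that("pairwise co-occurrence is independent without planted triads", {
    sm <- studySim()
    model <- sm$model                    # gamma 1, no triads
    lib <- simulateReads(model, sm$sim, 20000, seed = 301,
                         emitSequences = FALSE)
    mem <- lapply(strsplit(lib$truth$members, ","), as.integer)
    gr <- fragmentRanges(sm$sim$map)
    mids <- setNames(floor(((start(gr) - 1L) + end(gr)) / 2),
                     as.character(gr$fragment_id))
    inInt <- function(m, lo, hi) {
        mm <- mids[as.character(m)]
        any(mm >= lo & mm < hi)
    }
    hitA <- vapply(mem, inInt, logical(1), 2.2e5, 2.3e5)
    hitB <- vapply(mem, inInt, logical(1), 2.7e5, 2.8e5)
    pA <- mean(hitA); pB <- mean(hitB); pAB <- mean(hitA & hitB)
    se <- sqrt(pA * pB * (1 - pA * pB) / length(mem))
    expect_lt(abs(pAB - pA * pB), 3 * se + 3e-4)
})

test_that("insulation scales cross-boundary contacts by gamma", {
    base <- locusModel(genomeLength = 2e5, viewpointPos = 5e4,
                       boundaryPos = 1.2e5)
    sim <- simulateGenome(base, seed = 33)
    m1 <- base; m1@insulationFactor <- 1
    m2 <- base; m2@insulationFactor <- 0.25
    l1 <- simulateReads(m1, sim, 20000, seed = 44, emitSequences = FALSE)
    l2 <- simulateReads(m2, sim, 20000, seed = 44, emitSequences = FALSE)
    gr <- fragmentRanges(sim$map)
    mids <- setNames(floor(((start(gr) - 1L) + end(gr)) / 2),
                     as.character(gr$fragment_id))
    crossFrac <- function(lib) {
        mem <- unlist(strsplit(lib$truth$members, ","))
        mean(mids[mem] >= 1.2e5)
    }
    f1 <- crossFrac(l1); f2 <- crossFrac(l2)
    # odds ratio of drawing a cross-boundary partner scales by ~gamma
    odds <- (f2 / (1 - f2)) / (f1 / (1 - f1))
    expect_gt(odds, 0.25 * 0.8)
    expect_lt(odds, 0.25 * 1.2)
})

test_that("distance decay is recovered from the pairwise profile", {
    sm <- studySim()
    lib <- simulateReads(sm$model, sm$sim, 20000, seed = 55,
                        emitSequences = FALSE)
    ch <- truthChains(lib)
    prof <- countPairwise(ch, "all_members")
    gr <- fragmentRanges(sm$sim$map)
    mids <- setNames(floor(((start(gr) - 1L) + end(gr)) / 2),
                     as.character(gr$fragment_id))
    vpMid <- mids[[as.character(viewpointId(ch))]]
    d <- abs(mids[names(prof@counts)] - vpMid)
    keep <- d > 2000           # avoid the excluded near-viewpoint zone
    fit <- lm(log(as.numeric(prof@counts[keep])) ~ log(d[keep]))
    alpha_hat <- -coef(fit)[[2L]]
    expect_lt(abs(alpha_hat - sm$model@decayExponent), 0.3)
})

test_that("triad effects boost or deplete co-occurrence as planted", {
    base <- locusModel(genomeLength = 2e5, viewpointPos = 1e5,
        triads = data.frame(startA = 8e4, endA = 8.5e4,
                            startB = 1.2e5, endB = 1.25e5, beta = 4))
    sim <- simulateGenome(base, seed = 66)
    noTriad <- base
    noTriad@triads <- base@triads[0, ]
    lt <- simulateReads(base, sim, 15000, seed = 88, emitSequences = FALSE)
    l0 <- simulateReads(noTriad, sim, 15000, seed = 88,
                        emitSequences = FALSE)
    gr <- fragmentRanges(sim$map)
    mids <- setNames(floor(((start(gr) - 1L) + end(gr)) / 2),
                     as.character(gr$fragment_id))
    co <- function(lib) {
        mem <- lapply(strsplit(lib$truth$members, ","), as.integer)
        hitA <- vapply(mem, function(m)
            any(mids[as.character(m)] >= 8e4 &
                mids[as.character(m)] < 8.5e4), logical(1))
        hitB <- vapply(mem, function(m)
            any(mids[as.character(m)] >= 1.2e5 &
                mids[as.character(m)] < 1.25e5), logical(1))
        mean(hitB[hitA])
    }
    expect_gt(co(lt), 2 * co(l0))   # beta = 4 at least doubles it
})

test_that("condition pairs differ only in insulation", {
    base <- locusModel(genomeLength = 2e5, viewpointPos = 5e4,
                       boundaryPos = 1.2e5)
    sim <- simulateGenome(base, seed = 12)
    expect_error(emitConditionPair(base, sim, 100, seed = 1,
                                   gammaWT = 1, gammaKO = 1),
                 "must differ")
    noB <- locusModel(genomeLength = 2e5, viewpointPos = 5e4)
    expect_error(emitConditionPair(noB, simulateGenome(noB, seed = 12),
                                   100, seed = 1), "no boundary")

    pair <- emitConditionPair(base, sim, 8000, seed = 21,
                              gammaWT = 1, gammaKO = 0.5,
                              emitSequences = FALSE)
    grid <- binGrid(base@chrom, 0, 2e5, 10000)
    mWT <- normalizeMatrixTotal(buildThreewayMatrix(
        truthChains(pair$wt), grid, sim$map, "all_triples"))
    mKO <- normalizeMatrixTotal(buildThreewayMatrix(
        truthChains(pair$ko), grid, sim$map, "all_triples"))
    d <- subtractMatrices(mKO, mWT)
    # KO - WT loses cross-boundary contacts in aggregate
    expect_lt(crossBoundarySum(d, 1.2e5), 0)

    # identical seed and gamma subtract to the zero matrix
    sameA <- simulateReads(base, sim, 500, seed = 3, emitSequences = FALSE)
    sameB <- simulateReads(base, sim, 500, seed = 3, emitSequences = FALSE)
    z <- subtractMatrices(
        normalizeMatrixTotal(buildThreewayMatrix(truthChains(sameA),
                                                 grid, sim$map)),
        normalizeMatrixTotal(buildThreewayMatrix(truthChains(sameB),
                                                 grid, sim$map)))
    expect_true(all(contactValues(z) == 0))
})
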