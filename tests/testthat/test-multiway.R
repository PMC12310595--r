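# grid over the uniform map: 100 fragments of 1 kb, bins of 5 kb
.grid20 <- function() binGrid("chrU", 0, 1e5, 5000)

test_that("three-way matrices count first-two pairs and all triples", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    # members in bins A=3 (id 12), B=7 (id 33), C=11 (id 52)
    cs <- makeChainSet(list(c(12L, 33L, 52L)), 0L)
    m1 <- buildThreewayMatrix(cs, g, map, "first_two")
    expect_equal(contactTotal(m1), 1)
    expect_equal(contactValues(m1)[3, 7], 1)
    expect_equal(contactValues(m1)[7, 3], 1)   # mirrored
    expect_equal(sum(contactValues(m1) != 0), 2L)

    m2 <- buildThreewayMatrix(cs, g, map, "all_triples")
    expect_equal(contactTotal(m2), 3)
    expect_equal(contactValues(m2)[3, 7] + contactValues(m2)[3, 11] +
                 contactValues(m2)[7, 11], 3)

    # single-member chain contributes nothing
    m0 <- buildThreewayMatrix(makeChainSet(list(12L), 0L), g, map)
    expect_equal(contactTotal(m0), 0)
    expect_equal(m0@skippedChains, 1L)

    # same-bin pair increments the diagonal once
    md <- buildThreewayMatrix(makeChainSet(list(c(12L, 13L)), 0L), g, map)
    expect_equal(contactValues(md)[3, 3], 1)
    expect_equal(contactTotal(md), 1)
})

test_that("fragments outside the window are skipped", {
    map <- uniformMap(n = 100L)
    g <- binGrid("chrU", 0, 5e4, 5000)        # half the locus
    cs <- makeChainSet(list(c(12L, 80L), c(12L, 33L)), 0L)
    m <- buildThreewayMatrix(cs, g, map, "first_two")
    expect_equal(contactTotal(m), 1)           # only the in-window pair
    expect_equal(m@skippedChains, 1L)
})

test_that("normalization scales any nonzero matrix to one million", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    cs <- makeChainSet(list(c(12L, 33L), c(12L, 33L), c(12L, 33L),
                            c(12L, 52L)), 0L)
    m <- buildThreewayMatrix(cs, g, map, "first_two")
    nm <- normalizeMatrixTotal(m)
    expect_equal(contactValues(nm)[3, 7], 750000)
    expect_equal(contactValues(nm)[3, 11], 250000)
    expect_equal(contactTotal(nm), 1e6)
    v <- contactValues(nm)
    expect_equal(sum(v[upper.tri(v, diag = TRUE)]), 1e6, tolerance = 1e-12)

    # zero matrix stays zero
    z <- buildThreewayMatrix(makeChainSet(list(), 0L), g, map)
    expect_true(all(contactValues(normalizeMatrixTotal(z)) == 0))
})

test_that("subtraction requires matching grids and is entrywise", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    a <- normalizeMatrixTotal(buildThreewayMatrix(
        makeChainSet(list(c(12L, 33L)), 0L), g, map))
    d0 <- subtractMatrices(a, a)
    expect_true(all(contactValues(d0) == 0))
    expect_equal(d0@kind, "difference")

    b <- normalizeMatrixTotal(buildThreewayMatrix(
        makeChainSet(list(c(12L, 33L), c(12L, 52L)), 0L), g, map))
    d <- subtractMatrices(a, b)
    expect_equal(contactValues(d)[3, 7], 1e6 - 5e5)
    expect_true(isSymmetric(contactValues(d)))

    g2 <- binGrid("chrU", 0, 1e5, 10000)
    b2 <- normalizeMatrixTotal(buildThreewayMatrix(
        makeChainSet(list(c(12L, 33L)), 0L), g2, map))
    expect_error(subtractMatrices(a, b2), "grid mismatch")
    expect_error(subtractMatrices(buildThreewayMatrix(
        makeChainSet(list(c(12L, 33L)), 0L), g, map), a), "normalized")
})

test_that("loop calling is >= threshold, off-diagonal, sorted", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    mem <- c(replicate(5, c(12L, 33L), simplify = FALSE),
             replicate(4, c(12L, 52L), simplify = FALSE),
             replicate(9, c(40L, 41L), simplify = FALSE))  # same-bin pair
    m <- buildThreewayMatrix(makeChainSet(mem, 0L), g, map, "first_two")
    loops <- callLoops(m, threshold = 5L)
    expect_equal(nrow(loops), 1L)              # boundary inclusive, 4 < 5
    expect_equal(unlist(loops[1, ]), c(bin_i = 3, bin_j = 7, count = 5))
    expect_equal(nrow(callLoops(m, threshold = 10L)), 0L)
    # diagonal entries (the 9x same-bin pair) are never loops
    expect_false(any(loops$bin_i == loops$bin_j))
    # ordering: descending count, then (i, j)
    m2 <- buildThreewayMatrix(makeChainSet(c(
        replicate(6, c(12L, 52L), simplify = FALSE),
        replicate(6, c(12L, 33L), simplify = FALSE),
        replicate(7, c(33L, 52L), simplify = FALSE)), 0L), g, map,
        "first_two")
    l2 <- callLoops(m2, 5L)
    expect_equal(l2$count, c(7, 6, 6))
    expect_equal(l2$bin_i, c(7, 3, 3))
    expect_equal(l2$bin_j, c(11, 7, 11))
})

test_that("matrix operations agree with a brute-force pair oracle", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    set.seed(41)
    mem <- replicate(100, sample(setdiff(0:99, 0:1),
                                 sample(1:5, 1L)), simplify = FALSE)
    cs <- makeChainSet(mem, 0L)
    binOf <- fragmentBins(map, g)
    bins <- lapply(mem, function(m) unname(binOf[as.character(m)]))
    for (mode in c("first_two", "all_triples")) {
        m <- buildThreewayMatrix(cs, g, map, mode)
        oracle <- oraclePairCounts(bins, mode)
        expect_equal(contactTotal(m), sum(unlist(oracle)))
        for (key in names(oracle)) {
            ij <- as.integer(strsplit(key, " ")[[1L]])
            expect_equal(contactValues(m)[ij[1L], ij[2L]],
                         oracle[[key]])
        }
        # symmetry preserved by every operation
        expect_true(isSymmetric(contactValues(m)))
        expect_true(isSymmetric(contactValues(normalizeMatrixTotal(m))))
    }
    # mode dominance: all_triples >= first_two entrywise
    mf <- contactValues(buildThreewayMatrix(cs, g, map, "first_two"))
    ma <- contactValues(buildThreewayMatrix(cs, g, map, "all_triples"))
    expect_true(all(ma - mf >= 0))
})

test_that("matrices export as dense and sparse TSV", {
    map <- uniformMap(n = 100L)
    g <- .grid20()
    m <- buildThreewayMatrix(makeChainSet(list(c(12L, 33L)), 0L), g, map)
    f <- withr::local_tempfile(fileext = ".tsv")
    dense <- writeContactMatrix(m, f)
    expect_equal(dim(dense), c(20L, 20L))
    expect_match(rownames(dense)[1], "^chrU:0-5000$")
    expect_equal(length(readLines(f)), 21L)
    sp <- writeContactMatrix(m, f, sparse = TRUE)
    expect_equal(nrow(sp), 1L)
    expect_equal(sp$value, 1)
})
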