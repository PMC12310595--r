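# uniform 100 x 1 kb fragment map; bins of 5 kb; viewpoint fragment 10
.soiSetup <- function(members) {
    list(map = uniformMap(n = 100L),
         grid = binGrid("chrU", 0, 1e5, 5000),
         chains = makeChainSet(members, 10L))
}

test_that("partitionReads splits by SOI membership", {
    # fragment 60 has midpoint 60499: SOI [60000, 61000) captures it
    s <- .soiSetup(list(c(60L, 40L), 40L, 60L))
    part <- partitionReads(s$chains, s$map, c(60000, 61000))
    expect_equal(part$positive, c(1L, 3L))
    expect_equal(part$negative, 2L)

    # SOI overlapping the viewpoint fragment is an error
    expect_error(partitionReads(s$chains, s$map, c(10500, 11500)),
                 "overlaps the viewpoint")

    # SOI hit by no read -> empty positive set, error downstream
    part0 <- partitionReads(s$chains, s$map, c(90000, 91000))
    expect_length(part0$positive, 0L)
    expect_error(positiveProfile(s$chains, s$map, s$grid, part0),
                 "positive set is empty")
})

test_that("positiveProfile reports per-read presence frequencies", {
    # positive reads' members: [S, A], [S, A], [S] with S = 60, A = 30
    s <- .soiSetup(list(c(60L, 30L), c(60L, 30L), 60L, 40L))
    part <- partitionReads(s$chains, s$map, c(60000, 61000))
    freq <- positiveProfile(s$chains, s$map, s$grid, part)
    binA <- unname(fragmentBins(s$map, s$grid, 30L))
    expect_equal(freq[binA], 2 / 3)
    # untouched bin
    expect_equal(freq[2L], 0)
})

test_that("resampled negative profile matches the enumeration oracle", {
    # negative reads [VP, A, B], [VP, A, C]: members {A,B}, {A,C}
    # with A=30, B=40, C=50 in distinct bins; two positive reads
    s <- .soiSetup(list(c(60L, 77L), c(60L, 77L),
                        c(30L, 40L), c(30L, 50L)))
    part <- partitionReads(s$chains, s$map, c(60000, 61000))
    expect_length(part$positive, 2L)
    expect_length(part$negative, 2L)
    neg <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                   nIterations = 1000L, seed = 7L)
    binOf <- fragmentBins(s$map, s$grid)
    bins <- lapply(list(c(30L, 40L), c(30L, 50L)),
                   function(m) unname(binOf[as.character(m)]))
    oracle <- oracleEnumNegative(bins, s$grid@nBins)
    binA <- bins[[1L]][1L]
    expect_equal(oracle$mean[binA], 0.5)
    expect_equal(oracle$sd[binA], sqrt(0.125))
    # 3 standard errors of the mean over 1000 iterations
    se <- oracle$sd / sqrt(1000)
    expect_true(all(abs(neg$mean - oracle$mean) <= 3 * se + 1e-12))
    # convergence: more iterations tighten toward the enumerated values
    neg2 <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                    nIterations = 10000L, seed = 8L)
    expect_true(all(abs(neg2$mean - oracle$mean) <=
                    3 * oracle$sd / sqrt(10000) + 1e-12))
})

test_that("degenerate resampling cases behave as defined", {
    # a bin covered twice in every negative read keeps mean 1, sd 0
    s <- .soiSetup(list(c(60L, 40L), c(30L, 31L, 77L), c(30L, 31L, 50L)))
    part <- partitionReads(s$chains, s$map, c(60000, 61000))
    neg <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                   nIterations = 200L, seed = 1L)
    binA <- unname(fragmentBins(s$map, s$grid, 30L))  # holds 30 and 31
    expect_equal(neg$mean[binA], 1)
    expect_equal(neg$sd[binA], 0)

    # a single iteration has population sd zero everywhere
    neg1 <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                    nIterations = 1L, seed = 1L)
    expect_true(all(neg1$sd == 0))

    # negative smaller than positive: error unless replacement allowed
    s2 <- .soiSetup(list(c(60L, 40L), c(60L, 30L), 30L))
    p2 <- partitionReads(s2$chains, s2$map, c(60000, 61000))
    expect_error(resampleNegativeProfile(s2$chains, s2$map, s2$grid, p2,
                                         nIterations = 5L, seed = 1L),
                 "smaller than")
    negr <- resampleNegativeProfile(s2$chains, s2$map, s2$grid, p2,
                                    nIterations = 5L, seed = 1L,
                                    allowReplacement = TRUE)
    expect_length(negr$mean, s2$grid@nBins)
})

test_that("identical seeds give bit-identical resampling results", {
    s <- .soiSetup(c(list(c(60L, 40L), c(60L, 30L)),
                     replicate(20, sample(c(20:50, 70:90),
                                          sample(1:4, 1L)),
                               simplify = FALSE)))
    part <- partitionReads(s$chains, s$map, c(60000, 61000))
    a <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                 nIterations = 50L, seed = 123L)
    b <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                 nIterations = 50L, seed = 123L)
    expect_identical(a, b)
    c_ <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                  nIterations = 50L, seed = 124L)
    expect_false(identical(a$mean, c_$mean))
})

test_that("z-scores classify cooperative, random and competitive bins", {
    g <- binGrid("chrU", 0, 2e4, 5000)   # 4 bins
    neg <- list(mean = c(0.5, 0.2, 0.2, 0.5),
                sd = c(0.3535534, 0.1, 0.1, 0))
    pos <- c(1.0, 0.45, 0.2 - 0.25, 0.5)
    tab <- computeZscores(pos, neg, g, zThreshold = 2)
    expect_equal(tab$z[1], (1 - 0.5) / 0.3535534, tolerance = 1e-6)
    expect_equal(tab$label[1], "random")       # z ~ 1.414 < 2
    expect_equal(tab$label[2], "cooperative")  # z = 2.5
    expect_equal(tab$z[3], -2.5)
    expect_equal(tab$label[3], "competitive")
    expect_true(is.na(tab$z[4]))               # sd 0, pos == mean
    expect_equal(tab$label[4], "random")

    # sd 0 with a difference gives signed infinity
    tabInf <- computeZscores(c(0.6, 0.1), list(mean = c(0.5, 0.2),
                                               sd = c(0, 0)),
                             binGrid("chrU", 0, 1e4, 5000))
    expect_equal(tabInf$z, c(Inf, -Inf))
    expect_equal(tabInf$label, c("cooperative", "competitive"))
})

test_that("vpSoiTest excludes viewpoint and SOI bins and writes output", {
    set.seed(5)
    mem <- replicate(300, sample(c(20:50, 60:90), sample(1:4, 1L)),
                     simplify = FALSE)
    s <- .soiSetup(mem)
    res <- vpSoiTest(s$chains, s$map, s$grid, c(60000, 61000),
                     nIterations = 100L, seed = 9L)
    tab <- vpSoiTable(res)
    binVp <- unname(fragmentBins(s$map, s$grid, 10L))
    binSoi <- unname(fragmentBins(s$map, s$grid, 60L))
    expect_equal(tab$label[binVp], "excluded")
    expect_equal(tab$label[binSoi], "excluded")
    expect_equal(nrow(tab), s$grid@nBins)
    expect_true(all(tab$positive_freq >= 0 & tab$positive_freq <= 1))
    expect_true(all(tab$negative_mean >= 0 & tab$negative_mean <= 1))

    f <- withr::local_tempfile(fileext = ".tsv")
    j <- withr::local_tempfile(fileext = ".json")
    writeVpSoi(res, f, j)
    out <- read.table(f, header = TRUE, sep = "\t")
    expect_equal(nrow(out), s$grid@nBins)
    meta <- jsonlite::read_json(j)
    expect_equal(meta$n_iterations, 100L)
    expect_equal(meta$n_positive, res@nPositive)
})

test_that("size-matched and size-blind resampling draw valid samples", {
    set.seed(6)
    mem <- replicate(200, sample(c(20:50, 60:90), sample(1:5, 1L)),
                     simplify = FALSE)
    s <- .soiSetup(mem)
    part <- partitionReads(s$chains, s$map, c(60000, 62000))
    a <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                 nIterations = 50L, seed = 2L,
                                 matchCardinality = TRUE)
    b <- resampleNegativeProfile(s$chains, s$map, s$grid, part,
                                 nIterations = 50L, seed = 2L,
                                 matchCardinality = FALSE)
    expect_length(a$mean, s$grid@nBins)
    expect_length(b$mean, s$grid@nBins)
    expect_true(all(a$mean >= 0 & a$mean <= 1))
    expect_true(all(b$mean >= 0 & b$mean <= 1))
})
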