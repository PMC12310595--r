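#' Partition chains into positive and negative read sets
#'
#' Splits a viewpoint-anchored chain set by co-occurrence with a second
#' site of interest (SOI): the positive set contains the chains with at
#' least one member fragment whose midpoint lies in the SOI interval, the
#' negative set the chains with none.
#'
#' @param chains A [ChainSet-class].
#' @param map The matching [FragmentMap-class].
#' @param soi Numeric length-2 vector `c(start, end)`, 0-based half-open,
#'   or a string `"chrom:start-end"`; must lie on the viewpoint chromosome
#'   and must not overlap the viewpoint fragment.
#' @return A list with integer index vectors `positive` and `negative`
#'   into the chain set, and `soi` as the parsed interval.
#' @export
partitionReads <- function(chains, map, soi) {
    stopifnot(is(chains, "ChainSet"), is(map, "FragmentMap"))
    soi <- .parseInterval(soi)
    gr <- fragmentRanges(map)
    vp <- gr[match(chains@viewpointId, gr$fragment_id)]
    # viewpoint fragment as 0-based half-open
    vps <- start(vp) - 1L; vpe <- end(vp)
    if (soi[1L] < vpe && soi[2L] > vps)
        stop(sprintf(
            "SOI [%s, %s) overlaps the viewpoint fragment [%d, %d)",
            format(soi[1L], scientific = FALSE),
            format(soi[2L], scientific = FALSE), vps, vpe))
    mids <- setNames(floor(((start(gr) - 1L) + end(gr)) / 2),
                     as.character(gr$fragment_id))
    inSoi <- mids >= soi[1L] & mids < soi[2L]
    flat <- unlist(as.list(chains@members), use.names = FALSE)
    reps <- rep.int(seq_len(length(chains)),
                    elementNROWS(chains@members))
    hit <- inSoi[as.character(flat)]
    posIdx <- sort(unique(reps[hit]))
    list(positive = posIdx,
         negative = setdiff(seq_len(length(chains)), posIdx),
         soi = soi)
}

.parseInterval <- function(x) {
    if (is.numeric(x) && length(x) == 2L) return(as.numeric(x))
    parts <- strsplit(sub("^.*:", "", as.character(x)), "-")[[1L]]
    if (length(parts) != 2L)
        stop("interval must be c(start, end) or 'chrom:start-end'")
    as.numeric(gsub(",", "", parts))
}

# per-chain unique bin lists for a subset of chains
.chainBins <- function(chains, map, grid, idx) {
    binOf <- fragmentBins(map, grid)
    lapply(as.list(chains@members[idx]), function(m) {
        b <- unname(binOf[as.character(m)])
        unique(b[!is.na(b)])
    })
}

#' Positive-set contact profile
#'
#' For each bin of the grid, the fraction of positive reads (chains
#' containing both viewpoint and SOI) with at least one member fragment
#' in the bin.
#'
#' @param chains A [ChainSet-class].
#' @param map The matching [FragmentMap-class].
#' @param grid A [BinGrid-class].
#' @param partition Output of [partitionReads()].
#' @return Numeric vector of per-bin frequencies (length `nBins`).
#' @export
positiveProfile <- function(chains, map, grid, partition) {
    if (length(partition$positive) == 0L)
        stop("no VP-SOI co-occurring reads: the positive set is empty")
    bl <- .chainBins(chains, map, grid, partition$positive)
    tab <- tabulate(unlist(bl, use.names = FALSE), nbins = grid@nBins)
    tab / length(partition$positive)
}

#' Resampled negative contact profile
#'
#' The resampling null of the VP-SOI test: each iteration draws from the
#' negative set as many reads as the positive set holds (without
#' replacement by default), removes one uniformly chosen member fragment
#' from each drawn read — substituting for the SOI fragment that every
#' positive read necessarily carries — and tallies the per-bin fraction
#' of reads touching each bin.  Across `nIterations` iterations the
#' per-bin mean and population standard deviation form the negative
#' profile.
#'
#' With `matchCardinality = TRUE` (the default) each iteration draws
#' negative reads whose member counts match the positive set's member
#' counts (nearest available count when a stratum is exhausted).  The
#' one-fragment removal equalizes the mean number of informative
#' fragments between the sets only when their read-size distributions
#' agree; since larger reads are more likely to contain the SOI, plain
#' size-blind sampling leaves the positive set enriched for large reads
#' and biases z-scores upward genome-wide.  Set
#' `matchCardinality = FALSE` for size-blind sampling.
#'
#' @param chains A [ChainSet-class].
#' @param map The matching [FragmentMap-class].
#' @param grid A [BinGrid-class].
#' @param partition Output of [partitionReads()].
#' @param nIterations Number of resampling iterations (default 1000).
#' @param seed Integer RNG seed; the result is fully determined by it.
#' @param allowReplacement Sample negative reads with replacement
#'   (default FALSE; required if the negative set is smaller than the
#'   positive set).
#' @param matchCardinality Match the sampled reads' member counts to the
#'   positive set's member counts (default TRUE).
#' @return A list with numeric vectors `mean` and `sd` (length `nBins`).
#' @export
resampleNegativeProfile <- function(chains, map, grid, partition,
                                    nIterations = 1000L, seed = 1L,
                                    allowReplacement = FALSE,
                                    matchCardinality = TRUE) {
    stopifnot(nIterations >= 1L)
    P <- length(partition$positive)
    N <- length(partition$negative)
    if (P == 0L)
        stop("no VP-SOI co-occurring reads: the positive set is empty")
    if (!allowReplacement && N < P)
        stop(sprintf(
            "negative set (%d reads) smaller than positive set (%d reads); set allowReplacement = TRUE",
            N, P))
    memNeg <- as.list(chains@members[partition$negative])
    nmem <- lengths(memNeg)
    # flat member -> bin arrays for vectorized per-iteration tallies
    binOf <- fragmentBins(map, grid)
    flatBins <- lapply(memNeg, function(m) unname(binOf[as.character(m)]))
    startOf <- cumsum(c(0L, nmem))[seq_len(N)]   # 0-based offsets
    flatBin <- unlist(flatBins, use.names = FALSE)
    flatIdx <- split(seq_along(flatBin), rep.int(seq_len(N), nmem))
    nb <- grid@nBins

    if (matchCardinality) {
        sizesPos <- lengths(as.list(chains@members[partition$positive]))
        plan <- .sizeMatchPlan(sizesPos, nmem, allowReplacement)
    }

    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))

    sums <- numeric(nb)
    sqsums <- numeric(nb)
    removedMark <- logical(length(flatBin))
    for (it in seq_len(nIterations)) {
        S <- if (matchCardinality) {
            unlist(lapply(plan, function(p)
                p$stratum[sample.int(length(p$stratum), p$take,
                                     replace = allowReplacement)]),
                use.names = FALSE)
        } else {
            sample.int(N, P, replace = allowReplacement)
        }
        m <- nmem[S]
        # one uniformly chosen member per sampled read
        u <- floor(runif(P) * m)         # 0 .. m-1
        removed <- startOf[S] + u + 1L   # flat positions
        idx <- unlist(flatIdx[S], use.names = FALSE)
        readRep <- rep.int(seq_len(P), m)
        if (allowReplacement) {
            # duplicate draws of a read must each lose their own fragment:
            # work positionally within the concatenated sample
            offs <- cumsum(c(0L, m))[seq_len(P)]
            keep <- rep(TRUE, length(idx))
            keep[offs + u + 1L] <- FALSE
        } else {
            removedMark[removed] <- TRUE
            keep <- !removedMark[idx]
            removedMark[removed] <- FALSE
        }
        b <- flatBin[idx[keep]]
        r <- readRep[keep]
        ok <- !is.na(b)
        key <- (r[ok] - 1) * (nb + 1L) + b[ok]
        first <- !duplicated(key)
        freq <- tabulate(b[ok][first], nbins = nb) / P
        sums <- sums + freq
        sqsums <- sqsums + freq * freq
    }
    mu <- sums / nIterations
    varp <- pmax(sqsums / nIterations - mu * mu, 0)
    list(mean = mu, sd = sqrt(varp))
}

# allocate, once, how many reads to draw from each negative size stratum
# so that drawn member counts match the positive set's member counts,
# borrowing from the nearest available size when a stratum is exhausted
.sizeMatchPlan <- function(sizesPos, sizesNeg, allowReplacement = FALSE) {
    need <- table(sizesPos)
    strata <- split(seq_along(sizesNeg), sizesNeg)
    stratSizes <- as.integer(names(strata))
    cap <- lengths(strata)
    takes <- setNames(integer(length(strata)), names(strata))
    for (s in sort(as.integer(names(need)))) {
        n <- need[[as.character(s)]]
        for (k in order(abs(stratSizes - s), stratSizes)) {
            if (n == 0L) break
            avail <- if (allowReplacement) n else cap[[k]] - takes[[k]]
            t <- min(n, avail)
            takes[[k]] <- takes[[k]] + t
            n <- n - t
        }
        if (n > 0L)
            stop("internal error: negative set exhausted during size matching")
    }
    lapply(which(takes > 0L), function(k)
        list(stratum = strata[[k]], take = takes[[k]]))
}

.saveRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' z-scores and cooperative/random/competitive labels
#'
#' `z = (positive_freq - negative_mean) / negative_sd` per bin.  Bins
#' overlapping the viewpoint fragment or the SOI are labelled `excluded`.
#' Where the negative standard deviation is zero the z-score is undefined:
#' the label is `random` if the positive frequency equals the negative
#' mean, otherwise cooperative/competitive by sign with z reported as
#' +/-Inf.  Otherwise the label is `cooperative` if `z >= zThreshold`,
#' `competitive` if `z <= -zThreshold`, else `random`.
#'
#' @param positiveFreq Numeric per-bin positive frequencies.
#' @param negative List with `mean` and `sd` from
#'   [resampleNegativeProfile()].
#' @param grid The [BinGrid-class].
#' @param excludeBins Integer bin indices to label `excluded`.
#' @param zThreshold Classification threshold (default 2).
#' @return A data.frame with chrom, start, end, bin, positive_freq,
#'   negative_mean, negative_sd, z, label.
#' @export
computeZscores <- function(positiveFreq, negative, grid,
                           excludeBins = integer(0), zThreshold = 2) {
    nb <- grid@nBins
    stopifnot(length(positiveFreq) == nb, length(negative$mean) == nb)
    z <- rep(NA_real_, nb)
    sd0 <- negative$sd == 0
    z[!sd0] <- (positiveFreq[!sd0] - negative$mean[!sd0]) /
        negative$sd[!sd0]
    diff0 <- positiveFreq - negative$mean
    z[sd0 & diff0 > 0] <- Inf
    z[sd0 & diff0 < 0] <- -Inf
    z[sd0 & diff0 == 0] <- NA_real_
    label <- rep("random", nb)
    label[which(z >= zThreshold)] <- "cooperative"
    label[which(z <= -zThreshold)] <- "competitive"
    label[excludeBins] <- "excluded"
    starts <- grid@windowStart + (seq_len(nb) - 1L) * grid@resolution
    data.frame(chrom = grid@chrom, start = starts,
               end = pmin(starts + grid@resolution, grid@windowEnd),
               bin = seq_len(nb), positive_freq = positiveFreq,
               negative_mean = negative$mean, negative_sd = negative$sd,
               z = z, label = label)
}

#' VP-SOI cooperativity test
#'
#' Full resampling z-score test for three-way chromatin contacts: given a
#' viewpoint-anchored chain set and a second site of interest (SOI),
#' classifies every bin of the grid as a cooperative, random or
#' competitive third partner of the viewpoint-SOI pair.  Reads are split
#' into a positive set (viewpoint and SOI co-occur) and a negative set
#' (viewpoint only); the positive per-bin contact frequency is compared
#' to a resampled negative profile built by repeatedly drawing
#' positive-set-sized samples of negative reads with one member fragment
#' removed from each (see [resampleNegativeProfile()]).
#'
#' @param chains A [ChainSet-class].
#' @param map The matching [FragmentMap-class].
#' @param grid A [BinGrid-class].
#' @param soi SOI interval, `c(start, end)` (0-based half-open) or
#'   `"chrom:start-end"`.
#' @param nIterations Resampling iterations (default 1000).
#' @param seed Integer RNG seed.
#' @param zThreshold Classification threshold (default 2).
#' @param allowReplacement Sample negative reads with replacement.
#' @param matchCardinality Match sampled read sizes to the positive set
#'   (default TRUE; see [resampleNegativeProfile()]).
#' @return A [VPSOIResult-class].
#' @export
vpSoiTest <- function(chains, map, grid, soi, nIterations = 1000L,
                      seed = 1L, zThreshold = 2,
                      allowReplacement = FALSE, matchCardinality = TRUE) {
    part <- partitionReads(chains, map, soi)
    pos <- positiveProfile(chains, map, grid, part)
    neg <- resampleNegativeProfile(chains, map, grid, part,
                                   nIterations = nIterations, seed = seed,
                                   allowReplacement = allowReplacement,
                                   matchCardinality = matchCardinality)
    # bins overlapping the viewpoint fragment or the SOI are excluded
    gr <- fragmentRanges(map)
    vp <- gr[match(chains@viewpointId, gr$fragment_id)]
    excl <- unique(c(
        .binsOverlapping(grid, as.character(seqnames(vp)),
                         start(vp) - 1L, end(vp)),
        .binsOverlapping(grid, grid@chrom, part$soi[1L], part$soi[2L])))
    tab <- computeZscores(pos, neg, grid, excludeBins = excl,
                          zThreshold = zThreshold)
    new("VPSOIResult", table = tab, viewpointId = chains@viewpointId,
        soi = part$soi, grid = grid,
        nPositive = length(part$positive),
        nNegative = length(part$negative),
        nIterations = as.integer(nIterations), seed = as.integer(seed),
        zThreshold = as.numeric(zThreshold))
}

# 1-based indices of bins overlapping [s, e) on the grid chromosome
.binsOverlapping <- function(grid, chrom, s, e) {
    if (chrom != grid@chrom) return(integer(0))
    lo <- floor((max(s, grid@windowStart) - grid@windowStart) /
                grid@resolution) + 1L
    hi <- ceiling((min(e, grid@windowEnd) - grid@windowStart) /
                  grid@resolution)
    if (hi < lo) return(integer(0))
    seq.int(lo, hi)
}

setMethod("show", "VPSOIResult", function(object) {
    tab <- object@table
    cat(sprintf(
        "VPSOIResult: viewpoint fragment %d, SOI [%s, %s), %d bins\n",
        object@viewpointId,
        format(object@soi[1L], scientific = FALSE),
        format(object@soi[2L], scientific = FALSE), nrow(tab)))
    cat(sprintf("  positive %d reads, negative %d reads, %d iterations (seed %d)\n",
        object@nPositive, object@nNegative, object@nIterations,
        object@seed))
    print(table(tab$label))
})

#' Result table of a VP-SOI test
#' @param result A [VPSOIResult-class].
#' @return The per-bin data.frame.
#' @export
vpSoiTable <- function(result) {
    stopifnot(is(result, "VPSOIResult"))
    result@table
}

#' Write a VP-SOI result as TSV plus metadata JSON
#'
#' @param result A [VPSOIResult-class].
#' @param file TSV output path; infinite z-scores are written as
#'   `inf`/`-inf`.
#' @param metadataFile Optional JSON path for the run metadata (seed,
#'   iterations, set sizes, threshold).
#' @return Invisibly, the data.frame written.
#' @export
writeVpSoi <- function(result, file, metadataFile = NULL) {
    tab <- vpSoiTable(result)
    out <- tab
    out$z <- ifelse(is.infinite(tab$z), ifelse(tab$z > 0, "inf", "-inf"),
                    as.character(tab$z))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metadataFile))
        jsonlite::write_json(list(
            viewpoint_id = result@viewpointId, soi = result@soi,
            chrom = result@grid@chrom, resolution = result@grid@resolution,
            n_positive = result@nPositive, n_negative = result@nNegative,
            n_iterations = result@nIterations, seed = result@seed,
            z_threshold = result@zThreshold), metadataFile,
            auto_unbox = TRUE)
    invisible(tab)
}
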