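#' Bin index of fragments on a grid
#'
#' Assigns fragments to bins by midpoint: bin `b` covers
#' `[windowStart + (b-1)*resolution, windowStart + b*resolution)` in
#' 0-based coordinates.  Fragments off the grid chromosome or with
#' midpoint outside the window get NA.
#'
#' @param map A [FragmentMap-class].
#' @param grid A [BinGrid-class].
#' @param fragmentIds Integer ids to place (default: all fragments).
#' @return Integer vector of 1-based bin indices (NA when outside),
#'   named by fragment id.
#' @export
fragmentBins <- function(map, grid, fragmentIds = NULL) {
    gr <- fragmentRanges(map)
    if (!is.null(fragmentIds))
        gr <- gr[match(fragmentIds, gr$fragment_id)]
    mid <- floor(((start(gr) - 1L) + end(gr)) / 2)   # 0-based midpoints
    bin <- floor((mid - grid@windowStart) / grid@resolution) + 1L
    bad <- as.character(seqnames(gr)) != grid@chrom |
        mid < grid@windowStart | mid >= grid@windowEnd
    bin[bad] <- NA_integer_
    setNames(as.integer(bin), as.character(gr$fragment_id))
}

#' Build a three-way contact matrix
#'
#' Bins the non-viewpoint members of each fragment chain and counts
#' viewpoint-anchored bin pairs.  Mode `"first_two"` uses only the first
#' two digested fragments following the viewpoint (one pair per chain);
#' `"all_triples"` counts every unordered pair of distinct members per
#' chain (each pair, co-occurring with the viewpoint, is one triple).
#' Pairs with either fragment outside the window are skipped; pairs
#' falling in the same bin increment the diagonal once.  Each unordered
#' pair is counted once in `total`; the stored matrix mirrors off-diagonal
#' counts to both triangles.
#'
#' @param chains A [ChainSet-class] (post-filter).
#' @param grid A [BinGrid-class].
#' @param map The matching [FragmentMap-class].
#' @param mode `"first_two"` (default) or `"all_triples"`.
#' @return A raw [ContactMatrix-class].
#' @export
buildThreewayMatrix <- function(chains, grid, map,
                                mode = c("first_two", "all_triples")) {
    mode <- match.arg(mode)
    stopifnot(is(chains, "ChainSet"), is(grid, "BinGrid"))
    n <- grid@nBins
    vals <- matrix(0, n, n)
    binOf <- fragmentBins(map, grid)
    ml <- as.list(chains@members)
    skipped <- 0L
    pairs_i <- integer(0); pairs_j <- integer(0)
    for (m in ml) {
        if (length(m) < 2L) { skipped <- skipped + 1L; next }
        b <- unname(binOf[as.character(m)])
        if (mode == "first_two") {
            bi <- b[1L]; bj <- b[2L]
            if (is.na(bi) || is.na(bj)) { skipped <- skipped + 1L; next }
            pairs_i <- c(pairs_i, min(bi, bj))
            pairs_j <- c(pairs_j, max(bi, bj))
        } else {
            b <- b[!is.na(b)]
            if (length(b) < 2L) { skipped <- skipped + 1L; next }
            cmb <- utils::combn(length(b), 2L)
            pi <- pmin(b[cmb[1L, ]], b[cmb[2L, ]])
            pj <- pmax(b[cmb[1L, ]], b[cmb[2L, ]])
            pairs_i <- c(pairs_i, pi)
            pairs_j <- c(pairs_j, pj)
        }
    }
    if (length(pairs_i)) {
        tab <- table(paste(pairs_i, pairs_j))
        ij <- do.call(rbind, strsplit(names(tab), " "))
        i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
        cnt <- as.integer(tab)
        for (k in seq_along(i)) {
            vals[i[k], j[k]] <- vals[i[k], j[k]] + cnt[k]
            if (i[k] != j[k])
                vals[j[k], i[k]] <- vals[j[k], i[k]] + cnt[k]
        }
    }
    new("ContactMatrix", grid = grid, values = vals,
        total = as.numeric(length(pairs_i)), kind = "raw",
        skippedChains = skipped)
}

#' Normalize a contact matrix to one million interactions
#'
#' Scales a raw matrix so that its interactions (each unordered pair
#' counted once) total 1,000,000.  A zero matrix maps to a zero matrix.
#'
#' @param matrix A raw [ContactMatrix-class].
#' @return A normalized [ContactMatrix-class].
#' @export
normalizeMatrixTotal <- function(matrix) {
    stopifnot(is(matrix, "ContactMatrix"))
    if (matrix@kind != "raw")
        stop("normalizeMatrixTotal() expects a raw matrix")
    scale <- if (matrix@total > 0) 1e6 / matrix@total else 0
    new("ContactMatrix", grid = matrix@grid,
        values = matrix@values * scale,
        total = matrix@total * scale, kind = "normalized",
        skippedChains = matrix@skippedChains)
}

#' Subtract two normalized contact matrices
#'
#' Entrywise `a - b` on identical grids, as used for knockout-minus-
#' wild-type subtraction heatmaps.
#'
#' @param a,b Normalized [ContactMatrix-class] objects on the same grid.
#' @return A difference [ContactMatrix-class] (entries may be negative).
#' @export
subtractMatrices <- function(a, b) {
    stopifnot(is(a, "ContactMatrix"), is(b, "ContactMatrix"))
    if (a@kind != "normalized" || b@kind != "normalized")
        stop("subtractMatrices() expects two normalized matrices")
    ga <- a@grid; gb <- b@grid
    if (ga@chrom != gb@chrom || ga@windowStart != gb@windowStart ||
        ga@windowEnd != gb@windowEnd || ga@resolution != gb@resolution)
        stop("grid mismatch: matrices are binned on different grids")
    d <- a@values - b@values
    new("ContactMatrix", grid = ga, values = d,
        total = sum(d[upper.tri(d, diag = TRUE)]), kind = "difference",
        skippedChains = NA_integer_)
}

#' Call interaction loops from raw contact frequencies
#'
#' Returns upper-triangle bin pairs whose raw contact frequency is at
#' least `threshold` (boundary inclusive), the diagonal excluded, sorted
#' by descending count then by (i, j).
#'
#' @param matrix A raw [ContactMatrix-class].
#' @param threshold Minimum raw count (default 5).
#' @return A data.frame with columns bin_i, bin_j, count (possibly empty).
#' @export
callLoops <- function(matrix, threshold = 5L) {
    stopifnot(is(matrix, "ContactMatrix"))
    if (matrix@kind != "raw")
        stop("callLoops() uses raw contact frequencies")
    v <- matrix@values
    sel <- which(upper.tri(v) & v >= threshold, arr.ind = TRUE)
    df <- data.frame(bin_i = sel[, 1L], bin_j = sel[, 2L],
                     count = v[sel])
    df <- df[order(-df$count, df$bin_i, df$bin_j), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Sum of difference-matrix entries across a boundary
#'
#' For a difference matrix and a boundary coordinate, sums the entries of
#' all unordered bin pairs whose two bins lie on opposite sides of the
#' boundary — the aggregate change of cross-boundary contacts.
#'
#' @param matrix A [ContactMatrix-class] (typically kind "difference").
#' @param boundaryPos Boundary position in bp (0-based).
#' @return A single number.
#' @export
crossBoundarySum <- function(matrix, boundaryPos) {
    stopifnot(is(matrix, "ContactMatrix"))
    g <- matrix@grid
    mids <- g@windowStart + (seq_len(g@nBins) - 0.5) * g@resolution
    side <- mids < boundaryPos
    cross <- outer(side, side, `!=`) & upper.tri(matrix@values)
    sum(matrix@values[cross])
}

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix (%s): %d x %d bins at %g bp, total %s\n",
        object@kind, object@grid@nBins, object@grid@nBins,
        object@grid@resolution,
        format(object@total, big.mark = ",", scientific = FALSE)))
})

#' Contact matrix values
#' @param matrix A [ContactMatrix-class].
#' @return The symmetric numeric matrix of bin-pair values.
#' @export
contactValues <- function(matrix) {
    stopifnot(is(matrix, "ContactMatrix"))
    matrix@values
}

#' Total interactions of a contact matrix
#' @param matrix A [ContactMatrix-class].
#' @return Sum over unordered bin pairs (upper triangle plus diagonal).
#' @export
contactTotal <- function(matrix) {
    stopifnot(is(matrix, "ContactMatrix"))
    matrix@total
}

#' Write a contact matrix as TSV
#'
#' Dense form: a header of bin intervals, then the full symmetric matrix.
#' Sparse form (`sparse = TRUE`): triplets bin_i, bin_j, value over the
#' upper triangle (diagonal included) with nonzero values.
#'
#' @param matrix A [ContactMatrix-class].
#' @param file Output path.
#' @param sparse Write triplet form instead of dense (default FALSE).
#' @return Invisibly, the object written.
#' @export
writeContactMatrix <- function(matrix, file, sparse = FALSE) {
    stopifnot(is(matrix, "ContactMatrix"))
    g <- matrix@grid
    starts <- g@windowStart + (seq_len(g@nBins) - 1L) * g@resolution
    labs <- sprintf("%s:%s-%s", g@chrom,
                    format(starts, scientific = FALSE, trim = TRUE),
                    format(pmin(starts + g@resolution, g@windowEnd),
                           scientific = FALSE, trim = TRUE))
    if (sparse) {
        v <- matrix@values
        keep <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
        df <- data.frame(bin_i = labs[keep[, 1L]], bin_j = labs[keep[, 2L]],
                         value = v[keep])
        write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(df))
    }
    m <- matrix@values
    dimnames(m) <- list(labs, labs)
    write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
    invisible(m)
}
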