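#' Tally viewpoint-anchored pairwise contacts
#'
#' Counts contacts per restriction fragment over a set of fragment chains
#' sharing one viewpoint.  Mode `"first_only"` counts only the first
#' member of each chain (the initial digested fragment ligated behind the
#' viewpoint, the conventional 4C-style signal); `"all_members"` counts
#' every distinct member of each chain once.
#'
#' @param chains A [ChainSet-class].
#' @param mode `"first_only"` (default) or `"all_members"`.
#' @return A [ViewpointProfile-class] with raw counts filled.
#' @export
countPairwise <- function(chains, mode = c("first_only", "all_members")) {
    mode <- match.arg(mode)
    stopifnot(is(chains, "ChainSet"))
    if (length(chains) == 0L) {
        return(new("ViewpointProfile", viewpointId = chains@viewpointId,
                   counts = setNames(integer(0), character(0)),
                   normalized = numeric(0), cisTotal = 0L, mode = mode))
    }
    ml <- chains@members
    frags <- if (mode == "first_only") {
        vapply(as.list(ml), `[`, integer(1), 1L)
    } else {
        unlist(as.list(ml), use.names = FALSE)   # members are distinct per chain
    }
    tab <- table(frags)
    counts <- setNames(as.integer(tab), names(tab))
    new("ViewpointProfile", viewpointId = chains@viewpointId,
        counts = counts, normalized = numeric(0), cisTotal = 0L,
        mode = mode)
}

#' Counts-per-million-in-cis normalization
#'
#' Scales a viewpoint profile so that counts on the viewpoint's chromosome
#' (cis) total one million: `scale = 1e6 / cis_total`, applied to every
#' fragment including trans fragments.  A profile with no cis counts
#' normalizes to all zeros.
#'
#' @param profile A [ViewpointProfile-class] from [countPairwise()].
#' @param map The [FragmentMap-class] the chains were assigned against.
#' @param dropTrans If TRUE, fragments off the viewpoint chromosome are
#'   removed from the normalized profile (default FALSE: retained, scaled
#'   by the cis factor).
#' @return The profile with `normalized` and `cisTotal` filled.
#' @export
cpmCisNormalize <- function(profile, map, dropTrans = FALSE) {
    stopifnot(is(profile, "ViewpointProfile"), is(map, "FragmentMap"))
    gr <- fragmentRanges(map)
    chromOf <- setNames(as.character(seqnames(gr)),
                        as.character(gr$fragment_id))
    vpChrom <- chromOf[[as.character(profile@viewpointId)]]
    if (length(profile@counts) == 0L) {
        profile@normalized <- numeric(0)
        profile@cisTotal <- 0L
        return(profile)
    }
    fragChrom <- chromOf[names(profile@counts)]
    cis <- fragChrom == vpChrom
    cisTotal <- sum(profile@counts[cis])
    scale <- if (cisTotal > 0L) 1e6 / cisTotal else 0
    norm <- profile@counts * scale
    if (dropTrans)
        norm <- norm[cis]
    profile@normalized <- setNames(as.numeric(norm), names(norm))
    profile@cisTotal <- as.integer(cisTotal)
    profile
}

setMethod("show", "ViewpointProfile", function(object) {
    cat(sprintf(
        "ViewpointProfile at fragment %d (%s): %d fragments, %d counts",
        object@viewpointId, object@mode, length(object@counts),
        sum(object@counts)))
    if (length(object@normalized))
        cat(sprintf(", cis total %d (CPM-in-cis)", object@cisTotal))
    cat("\n")
})

#' Export a viewpoint profile as bedGraph
#'
#' One record per fragment with a nonzero normalized value: chrom, start,
#' end (0-based half-open), value, sorted by coordinate.
#'
#' @param profile A normalized [ViewpointProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param file Output path.
#' @param trackName Track header name; `NULL` suppresses the header.
#' @return Invisibly, the data.frame written.
#' @export
writeBedGraph <- function(profile, map, file,
                          trackName = "CPM_in_cis") {
    stopifnot(is(profile, "ViewpointProfile"))
    if (length(profile@normalized) == 0L && length(profile@counts) > 0L)
        stop("profile is not normalized; run cpmCisNormalize() first")
    gr <- fragmentRanges(map)
    idx <- match(as.integer(names(profile@normalized)), gr$fragment_id)
    df <- data.frame(chrom = as.character(seqnames(gr))[idx],
                     start = start(gr)[idx] - 1L,
                     end = end(gr)[idx],
                     value = unname(profile@normalized))
    df <- df[df$value != 0, , drop = FALSE]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    con <- file(file, "w")
    on.exit(close(con))
    if (!is.null(trackName))
        writeLines(sprintf('track type=bedGraph name="%s"', trackName), con)
    if (nrow(df))
        write.table(format(df, scientific = FALSE, trim = TRUE), con,
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(df)
}

#' Per-window count table
#'
#' Sums raw profile counts over consecutive fixed-size windows of `k`
#' restriction fragments along the viewpoint chromosome, for export to
#' external differential-interaction statistics.
#'
#' @param profile A [ViewpointProfile-class] (raw counts suffice).
#' @param map The matching [FragmentMap-class].
#' @param k Fragments per window (default 30).
#' @return A data.frame with chrom, start, end (0-based half-open) and
#'   count per window.
#' @export
windowCounts <- function(profile, map, k = 30L) {
    stopifnot(is(profile, "ViewpointProfile"), k >= 1L)
    gr <- fragmentRanges(map)
    chromOf <- setNames(as.character(seqnames(gr)),
                        as.character(gr$fragment_id))
    vpChrom <- chromOf[[as.character(profile@viewpointId)]]
    g <- gr[as.character(seqnames(gr)) == vpChrom]
    g <- g[order(start(g))]
    win <- (seq_along(g) - 1L) %/% k
    cnt <- setNames(numeric(length(g)), as.character(g$fragment_id))
    hit <- names(profile@counts)[names(profile@counts) %in% names(cnt)]
    cnt[hit] <- profile@counts[hit]
    agg <- tapply(cnt, win, sum)
    starts <- tapply(start(g) - 1L, win, min)
    ends <- tapply(end(g), win, max)
    data.frame(chrom = vpChrom, start = as.integer(starts),
               end = as.integer(ends), count = as.integer(agg),
               row.names = NULL)
}
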