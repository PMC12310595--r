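#' In-silico restriction digest of a genome
#'
#' Scans every chromosome for occurrences of the enzyme recognition
#' sequence on both strands and cuts at `occurrence_start + cutOffset`
#' (forward strand) and the mirrored position `occurrence_start +
#' site_length - cutOffset` (reverse strand; identical for palindromic
#' sites).  Boundary positions are deduplicated and, together with 0 and
#' the chromosome length, delimit the restriction fragments, which tile
#' each chromosome without gaps or overlaps.  Fragment ids are global,
#' 0-based, strictly increasing in (chromosome order, start).
#'
#' IUPAC ambiguity codes in the recognition sequence match their base
#' sets; code N matches any base and a literal N in the genome, while a
#' literal N in the genome is matched by no other code (so runs of N
#' cannot create spurious sites).  Overlapping occurrences each contribute
#' a boundary.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file
#'   (gzip allowed).
#' @param enzyme A [RestrictionEnzyme-class]; default is an NlaIII-like
#'   4-cutter (site CATG, cut after the site).
#' @return A [FragmentMap-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACATGGGCATGTT"))
#' fm <- digestGenome(g)
#' fragmentRanges(fm)
#' @export
digestGenome <- function(genome, enzyme = restrictionEnzyme("NlaIII-like",
                                                            "CATG", 4L)) {
    validObject(enzyme)
    if (is.character(genome))
        genome <- readDNAStringSet(genome)
    if (!is(genome, "DNAStringSet"))
        stop("'genome' must be a DNAStringSet or a FASTA path")
    if (length(genome) == 0L)
        stop("genome has no sequences")
    if (any(Biostrings::width(genome) == 0L))
        stop("genome contains an empty sequence")
    if (is.null(names(genome)))
        names(genome) <- paste0("seq", seq_along(genome))
    names(genome) <- sub("\\s.*$", "", names(genome))

    site <- DNAString(enzyme@recognitionSequence)
    rcsite <- reverseComplement(site)
    slen <- nchar(enzyme@recognitionSequence)
    co <- enzyme@cutOffset

    frags <- vector("list", length(genome))
    next_id <- 0L
    for (i in seq_along(genome)) {
        chr <- names(genome)[i]
        subj <- genome[[i]]
        L <- length(subj)
        # forward-strand occurrences: cut at start + cutOffset
        fwd <- start(matchPattern(site, subj, fixed = "subject")) - 1L
        cuts <- fwd + co
        # reverse-strand occurrences (scan revcomp site on forward seq):
        # the physical cut mirrors to start + (slen - cutOffset)
        if (as.character(rcsite) != as.character(site)) {
            rev <- start(matchPattern(rcsite, subj, fixed = "subject")) - 1L
            cuts <- c(cuts, rev + (slen - co))
        }
        bounds <- sort(unique(c(0L, cuts[cuts > 0L & cuts < L], L)))
        n <- length(bounds) - 1L
        frags[[i]] <- data.frame(
            chrom = chr,
            start = bounds[-length(bounds)],
            end = bounds[-1L],
            fragment_id = next_id + seq_len(n) - 1L
        )
        next_id <- next_id + n
    }
    df <- do.call(rbind, frags)
    gr <- GRanges(df$chrom,
                  IRanges(start = df$start + 1L, end = df$end),
                  fragment_id = df$fragment_id)
    new("FragmentMap", enzyme = enzyme, fragments = gr,
        seqIndex = new.env(hash = TRUE, parent = emptyenv()),
        indexStats = integer(0))
}

#' Fragment ranges of a FragmentMap
#'
#' @param map A [FragmentMap-class].
#' @return A [GenomicRanges::GRanges] of fragments (1-based closed
#'   intervals internally; see [writeFragmentBed()] for 0-based output)
#'   with a `fragment_id` metadata column.
#' @export
fragmentRanges <- function(map) {
    stopifnot(is(map, "FragmentMap"))
    map@fragments
}

#' Enzyme of a FragmentMap
#' @param map A [FragmentMap-class].
#' @return The [RestrictionEnzyme-class] used for the digest.
#' @export
mapEnzyme <- function(map) {
    stopifnot(is(map, "FragmentMap"))
    map@enzyme
}

setMethod("show", "FragmentMap", function(object) {
    gr <- object@fragments
    chroms <- as.character(runValue(seqnames(gr)))
    cat(sprintf("FragmentMap: %d fragments on %d chromosome(s) [%s]\n",
        length(gr), length(unique(chroms)), object@enzyme@name))
    if (length(object@indexStats))
        cat(sprintf("  sequence index: %d indexed, %d short, %d ambiguous\n",
            object@indexStats[["indexed"]], object@indexStats[["short"]],
            object@indexStats[["ambiguous"]]))
})

# per-chromosome lookup tables, computed on demand
.chromTable <- function(map, chrom) {
    gr <- map@fragments
    g <- gr[as.character(seqnames(gr)) == chrom]
    if (length(g) == 0L)
        stop(sprintf("chromosome '%s' not in fragment map", chrom))
    o <- order(start(g))
    g[o]
}

#' Locate the fragment containing a position
#'
#' @param map A [FragmentMap-class].
#' @param chrom Chromosome name.
#' @param pos 0-based position(s) in bp, `0 <= pos < chrom_length`.
#' @return Integer fragment id(s): the unique fragment with
#'   `start <= pos < end`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACATGGGCATGTT"))
#' fm <- digestGenome(g)
#' locateFragment(fm, "chr1", c(0, 6, 13))
#' @export
locateFragment <- function(map, chrom, pos) {
    stopifnot(is(map, "FragmentMap"))
    g <- .chromTable(map, chrom)
    starts0 <- start(g) - 1L          # 0-based starts
    ends0 <- end(g)                   # 0-based exclusive ends
    L <- ends0[length(ends0)]
    bad <- pos < 0 | pos >= L
    if (any(bad))
        stop(sprintf("position %s out of range on %s (length %d)",
                     paste(pos[bad], collapse = ","), chrom, L))
    idx <- findInterval(pos, starts0)
    g$fragment_id[idx]
}

#' Build the exact-match fragment sequence index
#'
#' Maps each fragment's sequence and its reverse complement to the
#' fragment id with orientation "+" or "-".  Fragments shorter than
#' `minLength` are excluded; sequences shared by more than one fragment
#' (in either orientation) are flagged ambiguous and excluded.  This index
#' is the desk-scale stand-in for aligning digested sub-reads to the
#' digested genome.
#'
#' @param map A [FragmentMap-class] built from `genome`.
#' @param genome The same [Biostrings::DNAStringSet] (or FASTA path) the
#'   map was digested from.
#' @param minLength Minimum fragment length to index, bp.
#' @return `map` with its sequence index filled (slots `seqIndex`,
#'   `indexStats`); also records exclusion counts.
#' @export
buildSequenceIndex <- function(map, genome, minLength = 20L) {
    stopifnot(is(map, "FragmentMap"))
    if (is.character(genome))
        genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    gr <- map@fragments
    chrom <- as.character(seqnames(gr))
    if (!all(unique(chrom) %in% names(genome)))
        stop("genome is missing chromosomes present in the map")
    seqs <- character(length(gr))
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        seqs[sel] <- as.character(Biostrings::extractAt(
            genome[[chr]], IRanges(start(gr)[sel], end(gr)[sel])))
    }
    keep <- nchar(seqs) >= minLength
    fwd <- seqs[keep]
    ids <- gr$fragment_id[keep]
    rev <- as.character(reverseComplement(DNAStringSet(fwd)))
    allseq <- c(fwd, rev)
    # a sequence is ambiguous if it maps to >1 fragment in any orientation
    dup <- allseq[duplicated(allseq)]
    ambiguous_ids <- unique(c(ids, ids)[allseq %in% dup])
    env <- new.env(hash = TRUE, parent = emptyenv())
    ok <- !(fwd %in% dup) & !(rev %in% dup)
    for (j in which(ok)) {
        assign(fwd[j], c(ids[j], 1L), envir = env)    # orientation +
        if (rev[j] != fwd[j])
            assign(rev[j], c(ids[j], -1L), envir = env)
    }
    map@seqIndex <- env
    map@indexStats <- c(indexed = sum(ok),
                        short = sum(!keep),
                        ambiguous = length(ambiguous_ids))
    map
}

#' Look up a sequence in the fragment index
#'
#' @param map An indexed [FragmentMap-class].
#' @param sequence A character vector of sequences.
#' @return A data.frame with columns `fragment_id` (NA if unassigned) and
#'   `orientation` ("+", "-", or NA).
#' @export
lookupSequence <- function(map, sequence) {
    stopifnot(is(map, "FragmentMap"))
    hit <- lapply(sequence, function(s) {
        v <- get0(s, envir = map@seqIndex, inherits = FALSE)
        if (is.null(v)) c(NA_integer_, NA_integer_) else v
    })
    hit <- do.call(rbind, hit)
    data.frame(fragment_id = hit[, 1L],
               orientation = c("-", NA, "+")[hit[, 2L] + 2L])
}

#' Write a fragment map as BED4
#'
#' Emits one line per fragment — chrom, start, end, fragment_id — with
#' 0-based half-open coordinates.
#'
#' @param map A [FragmentMap-class].
#' @param file Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeFragmentBed <- function(map, file) {
    gr <- fragmentRanges(map)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,
                     end = end(gr),
                     fragment_id = gr$fragment_id)
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(df)
}
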