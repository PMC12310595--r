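#' Split a read at restriction recognition sites
#'
#' Cuts a read at every occurrence of the enzyme recognition sequence, on
#' both strands, using the same cut-offset convention as [digestGenome()]:
#' a ligated concatemer of restriction fragments is thereby decomposed
#' back into its constituent pieces, each carrying the recognition-site
#' remnant at the junction.  Concatenating the pieces reproduces the read.
#'
#' @param sequence A single read sequence (character or
#'   [Biostrings::DNAString]).
#' @param enzyme A [RestrictionEnzyme-class].
#' @return Character vector of sub-sequences, in read order.
#' @examples
#' splitRead("AACATGGGCATG", restrictionEnzyme("NlaIII-like", "CATG", 4L))
#' @export
splitRead <- function(sequence, enzyme = restrictionEnzyme("NlaIII-like",
                                                           "CATG", 4L)) {
    validObject(enzyme)
    siteTxt <- enzyme@recognitionSequence
    slen <- nchar(siteTxt)
    co <- enzyme@cutOffset
    unambiguous <- !grepl("[^ACGT]", siteTxt)
    if (unambiguous && is.character(sequence)) {
        # overlap-safe literal scan via lookahead; avoids XString overhead
        txt <- sequence
        L <- nchar(txt)
        rctxt <- as.character(reverseComplement(DNAString(siteTxt)))
        occ <- gregexpr(paste0("(?=", siteTxt, ")"), txt, perl = TRUE)[[1L]]
        cuts <- if (occ[1L] == -1L) integer(0) else as.integer(occ) - 1L + co
        if (rctxt != siteTxt) {
            occ <- gregexpr(paste0("(?=", rctxt, ")"), txt, perl = TRUE)[[1L]]
            if (occ[1L] != -1L)
                cuts <- c(cuts, as.integer(occ) - 1L + (slen - co))
        }
    } else {
        s <- if (is.character(sequence)) DNAString(sequence) else sequence
        L <- length(s)
        txt <- as.character(s)
        site <- DNAString(siteTxt)
        rcsite <- reverseComplement(site)
        cuts <- start(matchPattern(site, s, fixed = "subject")) - 1L + co
        if (as.character(rcsite) != as.character(site))
            cuts <- c(cuts,
                      start(matchPattern(rcsite, s, fixed = "subject")) -
                          1L + (slen - co))
    }
    bounds <- sort(unique(c(0L, cuts[cuts > 0L & cuts < L], L)))
    substring(txt, bounds[-length(bounds)] + 1L, bounds[-1L])
}

#' Assign read pieces to restriction fragments by exact lookup
#'
#' Each piece is looked up in the fragment sequence index in either
#' orientation; unassigned pieces are recorded and skipped, order is
#' preserved.  Pieces shorter than `minLength` are dropped before lookup
#' (logged separately).
#'
#' @param pieces Character vector of sub-sequences from [splitRead()].
#' @param map An indexed [FragmentMap-class] (see [buildSequenceIndex()]).
#' @param minLength Minimum piece length submitted to lookup, bp.
#' @return A data.frame with columns `fragment_id`, `orientation` for the
#'   assigned pieces (in read order), plus attributes `n_unassigned` and
#'   `n_short`.
#' @export
assignFragments <- function(pieces, map, minLength = 20L) {
    long <- nchar(pieces) >= minLength
    hits <- lookupSequence(map, pieces[long])
    ok <- !is.na(hits$fragment_id)
    out <- hits[ok, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_unassigned") <- sum(!ok)
    attr(out, "n_short") <- sum(!long)
    out
}

#' Build a filtered fragment chain from assigned pieces
#'
#' Applies the multi-contact read filters in order: (1) the read is
#' rejected as `OFF_TARGET` unless its first assigned fragment is the
#' viewpoint fragment; (2) members within `selfLigationWindow` fragment
#' ids of the viewpoint are dropped (`SELF_LIGATION`, undigested or
#' self-ligated bait products); (3) runs of consecutive members that are
#' genomically adjacent (id difference at most 1) are collapsed to their
#' first member (`CONTINUOUS`, undigested neighbors); (4) exact duplicate
#' members are dropped keeping the first occurrence.  A chain left with no
#' members is rejected as `EMPTY_AFTER_FILTER`.
#'
#' @param fragmentIds Integer vector of assigned fragment ids, read order.
#' @param orientations Character vector of "+"/"-" matching `fragmentIds`.
#' @param viewpointId Integer viewpoint fragment id.
#' @param selfLigationWindow Integer; members with
#'   `|id - viewpointId| <= selfLigationWindow` are dropped (default 1).
#' @return A list with `status` ("retained", "OFF_TARGET" or
#'   "EMPTY_AFTER_FILTER"), `members`, `orientation`, and named drop
#'   counts `drops` (SELF_LIGATION, CONTINUOUS, DUPLICATE).
#' @examples
#' buildChain(c(10L, 11L, 25L), c("+", "+", "+"), 10L)$members  # 25
#' @export
buildChain <- function(fragmentIds, orientations = rep("+",
                           length(fragmentIds)),
                       viewpointId, selfLigationWindow = 1L) {
    drops <- c(SELF_LIGATION = 0L, CONTINUOUS = 0L, DUPLICATE = 0L)
    if (length(fragmentIds) == 0L ||
        fragmentIds[1L] != viewpointId)
        return(list(status = "OFF_TARGET", members = integer(0),
                    orientation = character(0), drops = drops))
    m <- fragmentIds[-1L]
    o <- orientations[-1L]
    # self-ligation: viewpoint fragment and immediate neighbors
    keep <- abs(m - viewpointId) > selfLigationWindow
    drops[["SELF_LIGATION"]] <- sum(!keep)
    m <- m[keep]; o <- o[keep]
    # continuous fragments: collapse runs of genomic adjacency, keep first
    if (length(m) > 1L) {
        adj <- c(FALSE, abs(diff(m)) <= 1L)
        drops[["CONTINUOUS"]] <- sum(adj)
        m <- m[!adj]; o <- o[!adj]
    }
    # duplicates: keep first occurrence
    if (length(m) > 1L) {
        dup <- duplicated(m)
        drops[["DUPLICATE"]] <- sum(dup)
        m <- m[!dup]; o <- o[!dup]
    }
    if (length(m) == 0L)
        return(list(status = "EMPTY_AFTER_FILTER", members = integer(0),
                    orientation = character(0), drops = drops))
    list(status = "retained", members = m, orientation = o, drops = drops)
}

#' Convert a read library to a ChainSet
#'
#' Runs the full read decomposition for every read: split at recognition
#' sites, assign pieces by exact lookup, then build the filtered fragment
#' chain anchored at the viewpoint.
#'
#' @param reads A named character vector, [Biostrings::DNAStringSet], or
#'   path to a FASTQ/FASTA file.
#' @param map An indexed [FragmentMap-class].
#' @param viewpoint Either an integer fragment id, or a string
#'   `"chrom:pos"` (0-based) locating the viewpoint fragment.
#' @param selfLigationWindow See [buildChain()].
#' @param minLength Minimum piece length for assignment, bp.
#' @param dedupReads If TRUE, drop reads whose (viewpoint, members) tuple
#'   duplicates an earlier read (PCR deduplication; default FALSE).
#' @return A [ChainSet-class].
#' @export
readsToChains <- function(reads, map, viewpoint, selfLigationWindow = 1L,
                          minLength = 20L, dedupReads = FALSE) {
    stopifnot(is(map, "FragmentMap"))
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
        fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
        reads <- readDNAStringSet(reads, format = fmt)
    }
    if (is(reads, "DNAStringSet")) {
        nm <- names(reads)
        reads <- as.character(reads)
        names(reads) <- nm
    }
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    vpId <- .resolveViewpoint(map, viewpoint)
    enzyme <- map@enzyme

    ids <- names(reads)
    members <- vector("list", length(reads))
    orient <- vector("list", length(reads))
    status <- character(length(reads))
    drops <- c(SELF_LIGATION = 0L, CONTINUOUS = 0L, DUPLICATE = 0L,
               UNASSIGNED = 0L, SHORT_PIECE = 0L)
    for (i in seq_along(reads)) {
        pieces <- splitRead(reads[[i]], enzyme)
        asg <- assignFragments(pieces, map, minLength = minLength)
        drops[["UNASSIGNED"]] <- drops[["UNASSIGNED"]] +
            attr(asg, "n_unassigned")
        drops[["SHORT_PIECE"]] <- drops[["SHORT_PIECE"]] +
            attr(asg, "n_short")
        ch <- buildChain(asg$fragment_id, asg$orientation, vpId,
                         selfLigationWindow)
        status[i] <- ch$status
        members[[i]] <- ch$members
        orient[[i]] <- ch$orientation
        drops[c("SELF_LIGATION", "CONTINUOUS", "DUPLICATE")] <-
            drops[c("SELF_LIGATION", "CONTINUOUS", "DUPLICATE")] + ch$drops
    }
    retained <- status == "retained"
    if (dedupReads && any(retained)) {
        key <- vapply(members, paste, "", collapse = ",")
        dup <- retained & duplicated(ifelse(retained, key, NA))
        retained[dup] <- FALSE
        status[dup] <- "DUPLICATE_READ"
    }
    rej <- c(retained = sum(retained),
             OFF_TARGET = sum(status == "OFF_TARGET"),
             EMPTY_AFTER_FILTER = sum(status == "EMPTY_AFTER_FILTER"),
             DUPLICATE_READ = sum(status == "DUPLICATE_READ"))
    new("ChainSet",
        readId = ids[retained],
        viewpointId = vpId,
        members = IntegerList(members[retained]),
        orientation = CharacterList(orient[retained]),
        rejections = rej,
        memberDrops = drops)
}

.resolveViewpoint <- function(map, viewpoint) {
    if (is.numeric(viewpoint) && length(viewpoint) == 1L &&
        !grepl(":", as.character(viewpoint)))
        return(as.integer(viewpoint))
    parts <- strsplit(as.character(viewpoint), ":")[[1L]]
    if (length(parts) != 2L)
        stop("viewpoint must be a fragment id or 'chrom:pos'")
    locateFragment(map, parts[1L], as.numeric(gsub(",", "", parts[2L])))
}

#' @describeIn ChainSet-class Number of retained chains.
#' @param x A [ChainSet-class].
#' @export
setMethod("length", "ChainSet", function(x) length(x@readId))

setMethod("show", "ChainSet", function(object) {
    cat(sprintf(
        "ChainSet: %d chains at viewpoint fragment %d\n",
        length(object), object@viewpointId))
    if (length(object@rejections))
        cat("  rejections:",
            paste(names(object@rejections), object@rejections,
                  sep = "=", collapse = " "), "\n")
    if (length(object@memberDrops))
        cat("  member drops:",
            paste(names(object@memberDrops), object@memberDrops,
                  sep = "=", collapse = " "), "\n")
})

#' Members of a ChainSet
#' @param chains A [ChainSet-class].
#' @return An [IRanges::IntegerList] of ordered member fragment ids.
#' @export
chainMembers <- function(chains) {
    stopifnot(is(chains, "ChainSet"))
    chains@members
}

#' Viewpoint fragment id of a ChainSet
#' @param chains A [ChainSet-class].
#' @return Integer fragment id.
#' @export
viewpointId <- function(chains) {
    stopifnot(is(chains, "ChainSet"))
    chains@viewpointId
}

#' Write chains as TSV
#'
#' One line per retained chain: read_id, viewpoint_id, comma-separated
#' member ids, comma-separated orientations.
#'
#' @param chains A [ChainSet-class].
#' @param file Output path.
#' @param rejectionFile Optional path for the rejection/drop summary TSV.
#' @return Invisibly, the data.frame written.
#' @export
writeChains <- function(chains, file, rejectionFile = NULL) {
    df <- data.frame(
        read_id = chains@readId,
        viewpoint_id = chains@viewpointId,
        members = vapply(as.list(chains@members), paste, "",
                         collapse = ","),
        orientations = vapply(as.list(chains@orientation), paste, "",
                              collapse = ","))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rejectionFile)) {
        summ <- rbind(
            data.frame(category = names(chains@rejections),
                       level = "read", count = unname(chains@rejections)),
            data.frame(category = names(chains@memberDrops),
                       level = "member", count = unname(chains@memberDrops)))
        write.table(summ, rejectionFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(df)
}

#' Read chains from TSV
#'
#' @param file Path written by [writeChains()].
#' @return A [ChainSet-class] (rejection counts empty).
#' @export
readChains <- function(file) {
    df <- read.table(file, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "character",
                                    "character"))
    new("ChainSet",
        readId = df$read_id,
        viewpointId = df$viewpoint_id[1L],
        members = IntegerList(lapply(strsplit(df$members, ","),
                                     as.integer)),
        orientation = CharacterList(strsplit(df$orientations, ",")),
        rejections = integer(0),
        memberDrops = integer(0))
}

#' Naive overlap merge of read pairs
#'
#' Convenience merging of paired-end reads into single reads by exact
#' suffix-prefix overlap of read 1 with the reverse complement of read 2
#' (minimum overlap, no mismatches).  Pairs without such an overlap are
#' dropped.
#'
#' @param read1,read2 Character vectors of equal length.
#' @param minOverlap Minimum exact overlap, bp.
#' @return Character vector of merged reads, named by the read-1 names;
#'   unmergeable pairs are omitted.
#' @export
mergeReadPairs <- function(read1, read2, minOverlap = 20L) {
    stopifnot(length(read1) == length(read2))
    r2 <- as.character(reverseComplement(DNAStringSet(read2)))
    out <- character(0)
    for (i in seq_along(read1)) {
        a <- read1[[i]]; b <- r2[[i]]
        la <- nchar(a); lb <- nchar(b)
        merged <- NA_character_
        for (ov in seq(min(la, lb), minOverlap)) {
            if (substring(a, la - ov + 1L, la) == substring(b, 1L, ov)) {
                merged <- paste0(a, substring(b, ov + 1L, lb))
                break
            }
        }
        if (!is.na(merged)) {
            out <- c(out, merged)
            names(out)[length(out)] <-
                if (!is.null(names(read1))) names(read1)[i] else
                    paste0("merged", i)
        }
    }
    out
}
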