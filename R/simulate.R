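#' Construct a LocusModel
#'
#' Defaults describe a half-megabase locus with dense 4-cutter fragments,
#' a mid-locus viewpoint, power-law distance decay with exponent 1, and
#' reads carrying one to five ligated partner fragments — the regime of a
#' viewpoint-primed multi-contact 3C library over a single locus.
#'
#' @param genomeLength Locus length, bp.
#' @param siteSpacing Mean planted inter-site distance, bp.
#' @param minFragLength Minimum planted fragment length, bp.
#' @param viewpointPos Viewpoint coordinate, 0-based bp.
#' @param decayExponent Distance-decay exponent (alpha > 0).
#' @param cardinalityProbs Probabilities for k = 1..5 partner fragments
#'   per read.
#' @param triads data.frame(startA, endA, startB, endB, beta); see
#'   [LocusModel-class].
#' @param boundaryPos Insulating boundary position, bp, or NA for none.
#' @param insulationFactor Gamma in (0, 1]: cross-boundary weight factor.
#' @param chrom Simulated chromosome name.
#' @param enzyme Planted [RestrictionEnzyme-class].
#' @return A [LocusModel-class].
#' @examples
#' locusModel(genomeLength = 1e5, viewpointPos = 5e4)
#' @export
locusModel <- function(genomeLength = 5e5, siteSpacing = 150,
                       minFragLength = 50, viewpointPos = 2.5e5,
                       decayExponent = 1,
                       cardinalityProbs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                       triads = data.frame(startA = numeric(0),
                                           endA = numeric(0),
                                           startB = numeric(0),
                                           endB = numeric(0),
                                           beta = numeric(0)),
                       boundaryPos = NA_real_, insulationFactor = 1,
                       chrom = "chrSim",
                       enzyme = restrictionEnzyme("NlaIII-like",
                                                  "CATG", 4L)) {
    new("LocusModel", chrom = chrom, genomeLength = genomeLength,
        siteSpacing = siteSpacing, minFragLength = minFragLength,
        viewpointPos = viewpointPos, decayExponent = decayExponent,
        cardinalityProbs = cardinalityProbs, triads = triads,
        boundaryPos = as.numeric(boundaryPos),
        insulationFactor = insulationFactor, enzyme = enzyme)
}

setMethod("show", "LocusModel", function(object) {
    cat(sprintf(
        "LocusModel: %s bp locus, ~%g bp fragments, viewpoint at %s, alpha=%g\n",
        format(object@genomeLength, big.mark = ","), object@siteSpacing,
        format(object@viewpointPos, big.mark = ","),
        object@decayExponent))
    if (nrow(object@triads))
        cat(sprintf("  %d planted triad(s), beta: %s\n",
            nrow(object@triads),
            paste(object@triads$beta, collapse = ", ")))
    if (!is.na(object@boundaryPos))
        cat(sprintf("  boundary at %s, insulation gamma=%g\n",
            format(object@boundaryPos, big.mark = ","),
            object@insulationFactor))
})

#' Simulate a toy genome with planted restriction sites
#'
#' Emits a random sequence with recognition sites planted at
#' exponentially distributed spacing (mean `siteSpacing`, fragments no
#' shorter than `minFragLength`), accidental occurrences of the site
#' scrubbed from fragment interiors, and all fragment sequences unique.
#' Digesting the emitted FASTA reproduces the planted fragment boundaries
#' exactly (verified internally).
#'
#' @param model A [LocusModel-class].
#' @param seed Integer RNG seed.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and `map`
#'   (the [FragmentMap-class] of the digest).
#' @export
simulateGenome <- function(model, seed = 1L) {
    stopifnot(is(model, "LocusModel"))
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))

    enz <- model@enzyme
    site <- enz@recognitionSequence
    slen <- nchar(site)
    co <- enz@cutOffset
    L <- as.integer(model@genomeLength)
    minF <- max(model@minFragLength, slen + 2)
    # planted boundaries: cumulative exponential gaps, truncated at minF
    gaps <- integer(0)
    total <- 0L
    meanGap <- max(model@siteSpacing - minF, 1)
    while (total < L) {
        g <- as.integer(minF + round(rexp(1L, rate = 1 / meanGap)))
        gaps <- c(gaps, g)
        total <- total + g
    }
    bounds <- cumsum(gaps)
    bounds <- bounds[bounds < L - minF]       # keep last fragment long enough
    if (any(strsplit(site, "")[[1L]] %in% c("R","Y","S","W","K","M",
                                            "B","D","H","V","N")))
        stop("simulateGenome() plants literal sites; use an unambiguous recognition sequence")
    seqc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # plant the site so that occurrence_start + cutOffset = boundary
    for (b in bounds) {
        s0 <- b - co                           # 0-based occurrence start
        seqc[(s0 + 1):(s0 + slen)] <- strsplit(site, "")[[1L]]
    }
    planted0 <- vapply(bounds, function(b) b - co, numeric(1))  # 0-based
    seqc <- .scrubSites(seqc, enz, planted0)
    txt <- paste(seqc, collapse = "")
    genome <- DNAStringSet(setNames(txt, model@chrom))
    map <- digestGenome(genome, enz)
    gr <- fragmentRanges(map)
    got <- start(gr)[-1L] - 1L                 # 0-based internal boundaries
    if (!identical(sort(as.integer(got)), sort(as.integer(bounds))))
        stop("internal error: digest does not reproduce planted boundaries")
    # fragment sequence uniqueness: regenerate colliding interiors
    map <- buildSequenceIndex(map, genome, minLength = 20L)
    tries <- 0L
    while (map@indexStats[["ambiguous"]] > 0L && tries < 10L) {
        genome <- .regenerateAmbiguous(genome, map, enz)
        map <- digestGenome(genome, enz)
        map <- buildSequenceIndex(map, genome, minLength = 20L)
        tries <- tries + 1L
    }
    list(genome = genome, map = map)
}

# mutate accidental site occurrences (either strand) outside planted starts
.scrubSites <- function(seqc, enz, planted0) {
    site <- enz@recognitionSequence
    rcsite <- as.character(reverseComplement(DNAString(site)))
    slen <- nchar(site)
    pats <- unique(c(site, rcsite))
    repeat {
        txt <- paste(seqc, collapse = "")
        occ0 <- integer(0)
        for (p in pats) {
            hits <- gregexpr(p, txt, fixed = TRUE)[[1L]]
            if (hits[1L] != -1L) occ0 <- c(occ0, as.integer(hits) - 1L)
            # overlapping occurrences: rescan shifted
            for (h in hits[hits > 0]) {
                sub <- substring(txt, h + 1L, h + 2L * slen - 2L)
                ih <- gregexpr(p, sub, fixed = TRUE)[[1L]]
                if (ih[1L] != -1L) occ0 <- c(occ0, h + as.integer(ih) - 1L)
            }
        }
        occ0 <- setdiff(unique(occ0), as.integer(planted0))
        # drop occurrences that overlap a planted site (mutating them
        # would destroy the planted boundary)
        if (length(occ0)) {
            overlapsPlanted <- vapply(occ0, function(s)
                any(abs(s - planted0) < slen), logical(1))
            occ0 <- occ0[!overlapsPlanted]
        }
        if (!length(occ0)) return(seqc)
        for (s0 in occ0) {
            # mutate one base not shared with a planted site
            cand <- (s0 + 1L):(s0 + slen)
            inPlanted <- vapply(cand - 1L, function(p)
                any(p >= planted0 & p < planted0 + slen), logical(1))
            j <- cand[!inPlanted][1L]
            seqc[j] <- sample(setdiff(c("A", "C", "G", "T"), seqc[j]), 1L)
        }
    }
}

.regenerateAmbiguous <- function(genome, map, enz) {
    # resample the interior of duplicated fragment sequences
    gr <- fragmentRanges(map)
    txt <- as.character(genome[[1L]])
    seqs <- substring(txt, start(gr), end(gr))
    rcs <- as.character(reverseComplement(DNAStringSet(seqs)))
    allseq <- c(seqs, rcs)
    dup <- allseq[duplicated(allseq)]
    bad <- which(seqs %in% dup | rcs %in% dup)
    seqc <- strsplit(txt, "")[[1L]]
    slen <- nchar(enz@recognitionSequence)
    for (i in bad) {
        lo <- start(gr)[i]; hi <- end(gr)[i] - slen  # keep terminal site
        if (hi - lo > 4L) {
            mid <- seq(lo + 1L, hi - 1L)
            seqc[mid] <- sample(c("A", "C", "G", "T"), length(mid),
                                replace = TRUE)
        }
    }
    planted0 <- start(gr)[-1L] - 1L - enz@cutOffset
    seqc <- .scrubSites(seqc, enz, planted0)
    DNAStringSet(setNames(paste(seqc, collapse = ""), names(genome)[1L]))
}

# base partner weights for a model + map: distance decay and insulation
.partnerWeights <- function(model, map) {
    gr <- fragmentRanges(map)
    mids <- floor(((start(gr) - 1L) + end(gr)) / 2)
    vpId <- locateFragment(map, model@chrom, model@viewpointPos)
    vpMid <- mids[match(vpId, gr$fragment_id)]
    d <- pmax(abs(mids - vpMid), 1)
    w <- d^(-model@decayExponent)
    # viewpoint fragment and immediate neighbors never ligate as partners
    # (they would be removed by the self-ligation filter anyway)
    w[abs(gr$fragment_id - vpId) <= 1L] <- 0
    if (!is.na(model@boundaryPos)) {
        vpSide <- vpMid < model@boundaryPos
        cross <- (mids < model@boundaryPos) != vpSide
        w[cross] <- w[cross] * model@insulationFactor
    }
    list(weights = w, vpId = vpId, mids = mids,
         ids = gr$fragment_id)
}

#' Simulate a multi-contact concatemer library
#'
#' Draws, for each read, a partner cardinality k from the model's
#' cardinality distribution and then k distinct partner fragments with
#' probability proportional to (midpoint distance to viewpoint)^-alpha,
#' scaled by the insulation factor for cross-boundary partners.  After a
#' fragment inside a triad's A interval has been drawn, the weights of
#' fragments in the B interval are multiplied by beta for the remaining
#' draws.  Reads are emitted as the viewpoint fragment sequence followed
#' by the partner fragment sequences in drawn order (junctions carry the
#' recognition-site remnants by the cut-offset construction).
#'
#' @param model A [LocusModel-class].
#' @param sim Output of [simulateGenome()] (list with `genome`, `map`).
#' @param nReads Number of reads.
#' @param seed Integer RNG seed.
#' @param emitSequences If FALSE, skip sequence emission and return only
#'   the ground truth (faster for chain-level studies).
#' @return A list: `reads` (named character vector of read sequences, or
#'   NULL), `truth` (data.frame read_id, members [comma-separated ids in
#'   drawn order]), `viewpointId`.
#' @export
simulateReads <- function(model, sim, nReads, seed = 1L,
                          emitSequences = TRUE) {
    stopifnot(is(model, "LocusModel"))
    map <- sim$map
    pw <- .partnerWeights(model, map)
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))

    nf <- length(pw$weights)
    kmax <- length(model@cardinalityProbs)
    k <- sample.int(kmax, nReads, replace = TRUE,
                    prob = model@cardinalityProbs)
    triads <- model@triads
    # indicator sets for triad intervals (by fragment midpoint)
    inA <- inB <- list()
    if (nrow(triads)) {
        for (t in seq_len(nrow(triads))) {
            inA[[t]] <- pw$mids >= triads$startA[t] &
                pw$mids < triads$endA[t]
            inB[[t]] <- pw$mids >= triads$startB[t] &
                pw$mids < triads$endB[t]
        }
    }
    # vectorized base draws (alias sampling), then per-read dedup and, if
    # triads are planted, reweighted redraws after the first A hit
    drawBase <- function(n) sample.int(nf, n, replace = TRUE,
                                       prob = pw$weights)
    members <- vector("list", nReads)
    pool <- drawBase(sum(k) + ceiling(0.2 * sum(k)) + 64L)
    pos <- 1L
    takeBase <- function(n) {
        if (pos + n - 1L > length(pool)) {
            pool <<- c(pool[seq.int(pos, length(pool))],
                       drawBase(max(n, 4096L)))
            pos <<- 1L
        }
        out <- pool[seq.int(pos, pos + n - 1L)]
        pos <<- pos + n
        out
    }
    for (i in seq_len(nReads)) {
        ki <- k[i]
        got <- integer(0)
        wMod <- NULL      # NULL until a triad fires
        while (length(got) < ki) {
            if (is.null(wMod)) {
                cand <- takeBase(1L)
            } else {
                cand <- sample.int(nf, 1L, prob = wMod)
            }
            if (cand %in% got) next
            got <- c(got, cand)
            if (nrow(triads) && is.null(wMod)) {
                fired <- FALSE
                w2 <- pw$weights
                for (t in seq_len(nrow(triads))) {
                    if (inA[[t]][cand]) {
                        w2[inB[[t]]] <- w2[inB[[t]]] * triads$beta[t]
                        fired <- TRUE
                    }
                }
                if (fired) wMod <- w2
            } else if (nrow(triads) && !is.null(wMod)) {
                for (t in seq_len(nrow(triads)))
                    if (inA[[t]][cand])
                        wMod[inB[[t]]] <- wMod[inB[[t]]] * triads$beta[t]
            }
        }
        members[[i]] <- pw$ids[got]
    }
    ids <- sprintf("read%06d", seq_len(nReads))
    truth <- data.frame(read_id = ids,
                        members = vapply(members, paste, "",
                                         collapse = ","))
    reads <- NULL
    if (emitSequences) {
        gr <- fragmentRanges(map)
        txt <- as.character(sim$genome[[1L]])
        fragSeq <- substring(txt, start(gr), end(gr))
        names(fragSeq) <- as.character(gr$fragment_id)
        vpSeq <- fragSeq[[as.character(pw$vpId)]]
        reads <- vapply(members, function(m)
            paste0(vpSeq, paste(fragSeq[as.character(m)], collapse = "")),
            "")
        names(reads) <- ids
    }
    list(reads = reads, truth = truth, viewpointId = pw$vpId)
}

#' Ground-truth chains from a simulated library
#'
#' Converts the planted fragment lists of [simulateReads()] into a
#' [ChainSet-class] by applying the same chain filters as the read
#' pipeline ([buildChain()]): self-ligation window, continuous-fragment
#' collapsing and duplicate removal.
#'
#' @param truthOrSim The list returned by [simulateReads()].
#' @param selfLigationWindow See [buildChain()].
#' @return A [ChainSet-class].
#' @export
truthChains <- function(truthOrSim, selfLigationWindow = 1L) {
    truth <- truthOrSim$truth
    vpId <- truthOrSim$viewpointId
    mem <- lapply(strsplit(truth$members, ","), as.integer)
    # fast path: planted partners exclude the viewpoint and neighbors by
    # construction, so only adjacency runs / duplicates need buildChain
    needs <- vapply(mem, function(m)
        length(m) > 1L && (any(abs(diff(m)) <= 1L) || anyDuplicated(m) > 0L),
        logical(1))
    keep <- rep(TRUE, length(mem))
    drops <- c(SELF_LIGATION = 0L, CONTINUOUS = 0L, DUPLICATE = 0L)
    for (i in which(needs)) {
        ch <- buildChain(c(vpId, mem[[i]]),
                         rep("+", length(mem[[i]]) + 1L), vpId,
                         selfLigationWindow)
        drops <- drops + ch$drops
        if (ch$status == "retained") mem[[i]] <- ch$members
        else keep[i] <- FALSE
    }
    new("ChainSet",
        readId = truth$read_id[keep],
        viewpointId = as.integer(vpId),
        members = IntegerList(mem[keep]),
        orientation = CharacterList(lapply(lengths(mem[keep]),
                                           function(n) rep("+", n))),
        rejections = c(retained = sum(keep), OFF_TARGET = 0L,
                       EMPTY_AFTER_FILTER = sum(!keep)),
        memberDrops = drops)
}

#' Write a simulated library as FASTQ
#'
#' @param sim Output of [simulateReads()] (with sequences emitted).
#' @param file FASTQ path (".gz" suffix compresses).
#' @return Invisibly, `file`.
#' @export
writeSimFastq <- function(sim, file) {
    if (is.null(sim$reads))
        stop("library was simulated without sequences")
    x <- DNAStringSet(sim$reads)
    writeXStringSet(x, file, format = "fastq",
                    compress = grepl("\\.gz$", file))
    invisible(file)
}

#' Simulate a matched condition pair (wild type vs knockout)
#'
#' Emits two libraries from the same locus model differing only in the
#' boundary insulation factor — emulating a wild-type library and a
#' boundary-element knockout in which cross-boundary insulation is
#' weakened or strengthened.  The seed stream is split per condition so
#' the pair is matched but independent.
#'
#' @param model A [LocusModel-class] with a non-NA `boundaryPos`.
#' @param sim Output of [simulateGenome()].
#' @param nReads Reads per library.
#' @param seed Integer master seed.
#' @param gammaWT,gammaKO Insulation factors of the two conditions; must
#'   differ.
#' @param emitSequences Passed to [simulateReads()].
#' @return A list with `wt` and `ko` (each as from [simulateReads()]),
#'   plus `gammaWT`, `gammaKO`.
#' @export
emitConditionPair <- function(model, sim, nReads, seed = 1L,
                              gammaWT = 1.0, gammaKO = 0.5,
                              emitSequences = TRUE) {
    if (gammaWT == gammaKO)
        stop("the two conditions must differ in insulation factor")
    if (is.na(model@boundaryPos))
        stop("model has no boundary; set boundaryPos")
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))
    seeds <- sample.int(.Machine$integer.max - 1L, 2L)
    mWT <- model; mWT@insulationFactor <- gammaWT
    mKO <- model; mKO@insulationFactor <- gammaKO
    list(wt = simulateReads(mWT, sim, nReads, seed = seeds[1L],
                            emitSequences = emitSequences),
         ko = simulateReads(mKO, sim, nReads, seed = seeds[2L],
                            emitSequences = emitSequences),
         gammaWT = gammaWT, gammaKO = gammaKO)
}
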