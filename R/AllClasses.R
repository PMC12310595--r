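#' @import methods
#' @importFrom S4Vectors isSingleString isSingleNumber
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' RestrictionEnzyme class
#'
#' A restriction enzyme as used for in-silico digestion: a recognition
#' sequence in IUPAC nucleotide code and a cut offset giving the fragment
#' boundary as a distance (in bases) from the 5' start of a recognized
#' occurrence.
#'
#' @slot name Single string, enzyme name.
#' @slot recognitionSequence Single uppercase string over the IUPAC
#'   nucleotide alphabet.
#' @slot cutOffset Integer in `[0, nchar(recognitionSequence)]`; the
#'   boundary produced by an occurrence starting at position `s` (0-based)
#'   is `s + cutOffset`.
#'
#' @examples
#' nla <- restrictionEnzyme("NlaIII-like", "CATG", 4L)
#' nla
#' @export
setClass("RestrictionEnzyme",
    representation(
        name = "character",
        recognitionSequence = "character",
        cutOffset = "integer"
    )
)

setValidity("RestrictionEnzyme", function(object) {
    msg <- NULL
    if (!isSingleString(object@name))
        msg <- c(msg, "'name' must be a single string")
    if (!isSingleString(object@recognitionSequence) ||
        nchar(object@recognitionSequence) == 0L)
        msg <- c(msg, "'recognitionSequence' must be a non-empty string")
    else {
        letters <- strsplit(object@recognitionSequence, "")[[1L]]
        bad <- setdiff(letters, IUPAC_LETTERS)
        if (length(bad))
            msg <- c(msg, paste0("invalid IUPAC characters in recognition ",
                                 "sequence: ", paste(bad, collapse = ", ")))
    }
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L ||
        object@cutOffset > nchar(object@recognitionSequence))
        msg <- c(msg, "'cutOffset' must lie in [0, site length]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RestrictionEnzyme
#'
#' @param name Enzyme name.
#' @param recognitionSequence Recognition site, uppercase IUPAC code.
#' @param cutOffset Bases from the 5' start of an occurrence to the cut;
#'   defaults to the site length (cut after the site, leaving the site at
#'   the 3' end of the upstream fragment, as for NlaIII).
#' @return A [RestrictionEnzyme-class] object.
#' @export
restrictionEnzyme <- function(name, recognitionSequence,
                              cutOffset = nchar(recognitionSequence)) {
    new("RestrictionEnzyme", name = as.character(name),
        recognitionSequence = toupper(as.character(recognitionSequence)),
        cutOffset = as.integer(cutOffset))
}

setMethod("show", "RestrictionEnzyme", function(object) {
    cat("RestrictionEnzyme", object@name, ": site",
        object@recognitionSequence, "cut at +", object@cutOffset, "\n")
})

#' FragmentMap class
#'
#' The in-silico restriction digest of a genome: a genome-wide tiling by
#' restriction fragments, with 0-based half-open coordinates and globally
#' unique fragment ids increasing in (chromosome order, start).  Optionally
#' carries an exact-match sequence index (fragment sequence and its reverse
#' complement -> fragment id and orientation), the desk-scale stand-in for
#' aligning digested sub-reads.
#'
#' @slot enzyme A [RestrictionEnzyme-class].
#' @slot fragments A [GenomicRanges::GRanges] of fragments (1-based internal
#'   representation; exported BED uses 0-based half-open) with metadata
#'   column `fragment_id`, sorted, tiling each chromosome.
#' @slot seqIndex An environment keyed by fragment sequence (and reverse
#'   complement) holding `c(id, orientation)` pairs; empty until
#'   [buildSequenceIndex()] is called.
#' @slot indexStats Named integer vector with counts of indexed, short and
#'   ambiguous fragments (empty before indexing).
#' @export
setClass("FragmentMap",
    representation(
        enzyme = "RestrictionEnzyme",
        fragments = "GRanges",
        seqIndex = "environment",
        indexStats = "integer"
    )
)

setValidity("FragmentMap", function(object) {
    gr <- object@fragments
    if (length(gr) == 0L)
        return("fragment map is empty")
    if (is.null(gr$fragment_id))
        return("fragments must carry a 'fragment_id' metadata column")
    ids <- gr$fragment_id
    if (any(duplicated(ids)))
        return("fragment ids must be unique")
    # per chromosome: tiling with no gaps/overlaps, consecutive ids
    for (chr in as.character(unique(GenomicRanges::seqnames(gr)))) {
        g <- gr[GenomicRanges::seqnames(gr) == chr]
        o <- order(GenomicRanges::start(g))
        g <- g[o]
        if (length(g) > 1L) {
            if (any(GenomicRanges::start(g)[-1L] !=
                    GenomicRanges::end(g)[-length(g)] + 1L))
                return(sprintf("fragments do not tile chromosome %s", chr))
            if (any(diff(g$fragment_id) != 1L))
                return(sprintf("fragment ids not consecutive on %s", chr))
        }
        if (GenomicRanges::start(g)[1L] != 1L)
            return(sprintf("first fragment on %s does not start at 1", chr))
    }
    TRUE
})

#' ChainSet class
#'
#' A collection of fragment chains sharing one viewpoint: each retained
#' read, reduced to the ordered list of restriction fragment ids it ligates
#' to the viewpoint (the viewpoint fragment itself excluded), after
#' off-target rejection, self-ligation filtering, continuous-fragment
#' collapsing and duplicate-member removal.
#'
#' @slot readId Character vector of read identifiers, one per retained chain.
#' @slot viewpointId Integer, the shared viewpoint fragment id.
#' @slot members An [IRanges::IntegerList]; element `i` is the ordered
#'   member fragment ids of chain `i`.
#' @slot orientation A [IRanges::CharacterList] of "+"/"-" per member.
#' @slot rejections Named integer vector: reads rejected by category
#'   (`OFF_TARGET`, `EMPTY_AFTER_FILTER`) plus `retained`.
#' @slot memberDrops Named integer vector: member-level drops by category
#'   (`SELF_LIGATION`, `CONTINUOUS`, `DUPLICATE`, `UNASSIGNED`, `SHORT_PIECE`).
#' @export
setClass("ChainSet",
    representation(
        readId = "character",
        viewpointId = "integer",
        members = "IntegerList",
        orientation = "CharacterList",
        rejections = "integer",
        memberDrops = "integer"
    )
)

setValidity("ChainSet", function(object) {
    n <- length(object@readId)
    if (length(object@members) != n || length(object@orientation) != n)
        return("readId, members and orientation lengths differ")
    if (length(object@viewpointId) != 1L || is.na(object@viewpointId))
        return("viewpointId must be a single integer")
    if (any(S4Vectors::elementNROWS(object@members) == 0L))
        return("retained chains must have non-empty members")
    TRUE
})

#' ViewpointProfile class
#'
#' Per-fragment contact counts for one viewpoint, with optional
#' counts-per-million-in-cis normalized values: counts on the viewpoint's
#' chromosome are scaled to total one million, and every fragment
#' (including trans) is scaled by that same cis factor.
#'
#' @slot viewpointId Integer viewpoint fragment id.
#' @slot counts Named integer vector, fragment id -> raw contact count.
#' @slot normalized Named numeric vector, fragment id -> CPM-in-cis value
#'   (length 0 until [cpmCisNormalize()]).
#' @slot cisTotal Integer, total raw counts on the viewpoint chromosome.
#' @slot mode Counting mode used, `"first_only"` or `"all_members"`.
#' @export
setClass("ViewpointProfile",
    representation(
        viewpointId = "integer",
        counts = "integer",
        normalized = "numeric",
        cisTotal = "integer",
        mode = "character"
    )
)

#' BinGrid class
#'
#' A fixed-resolution binning of an analysis window on one chromosome:
#' half-open bins `[start, start + resolution)` in 0-based window
#' coordinates, the last bin clipped at the window end.
#'
#' @slot chrom Chromosome name.
#' @slot windowStart,windowEnd 0-based half-open window, in bp.
#' @slot resolution Bin width in bp (typically 3000, 5000 or 10000).
#' @slot nBins Number of bins, `ceiling((windowEnd - windowStart)/resolution)`.
#' @export
setClass("BinGrid",
    representation(
        chrom = "character",
        windowStart = "numeric",
        windowEnd = "numeric",
        resolution = "numeric",
        nBins = "integer"
    )
)

setValidity("BinGrid", function(object) {
    msg <- NULL
    if (object@windowEnd <= object@windowStart)
        msg <- c(msg, "windowEnd must exceed windowStart")
    if (object@resolution <= 0)
        msg <- c(msg, "resolution must be positive")
    expect <- as.integer(ceiling(
        (object@windowEnd - object@windowStart) / object@resolution))
    if (length(object@nBins) != 1L || object@nBins != expect)
        msg <- c(msg, "nBins inconsistent with window and resolution")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BinGrid
#'
#' @param chrom Chromosome name.
#' @param windowStart,windowEnd Analysis window, 0-based half-open bp.
#' @param resolution Bin width in bp.
#' @return A [BinGrid-class].
#' @examples
#' binGrid("chr14", 53738375, 54282925, 5000)
#' @export
binGrid <- function(chrom, windowStart, windowEnd, resolution) {
    new("BinGrid", chrom = as.character(chrom),
        windowStart = as.numeric(windowStart),
        windowEnd = as.numeric(windowEnd),
        resolution = as.numeric(resolution),
        nBins = as.integer(ceiling((windowEnd - windowStart) / resolution)))
}

setMethod("show", "BinGrid", function(object) {
    cat(sprintf("BinGrid %s:%s-%s, %g bp resolution, %d bins\n",
        object@chrom, format(object@windowStart, scientific = FALSE),
        format(object@windowEnd, scientific = FALSE),
        object@resolution, object@nBins))
})

#' ContactMatrix class
#'
#' A symmetric binned co-occurrence matrix of fragment pairs anchored at a
#' viewpoint.  `total` counts each unordered pair once; the stored matrix
#' mirrors counts to both triangles for display.  `kind` is `"raw"`
#' (integer counts), `"normalized"` (total scaled to one million) or
#' `"difference"` (entrywise difference of two normalized matrices; may be
#' negative).
#'
#' @slot grid The [BinGrid-class] the matrix is binned on.
#' @slot values Numeric `nBins x nBins` symmetric matrix.
#' @slot total Numeric; sum over unordered pairs (upper triangle plus
#'   diagonal). For `difference` matrices this is the signed sum.
#' @slot kind `"raw"`, `"normalized"` or `"difference"`.
#' @slot skippedChains Integer; chains that contributed no pair (fewer than
#'   two members or outside the window).
#' @export
setClass("ContactMatrix",
    representation(
        grid = "BinGrid",
        values = "matrix",
        total = "numeric",
        kind = "character",
        skippedChains = "integer"
    )
)

setValidity("ContactMatrix", function(object) {
    msg <- NULL
    n <- object@grid@nBins
    if (!all(dim(object@values) == c(n, n)))
        msg <- c(msg, "values must be nBins x nBins")
    if (!isSymmetric(unname(object@values), tol = 1e-8))
        msg <- c(msg, "values must be symmetric")
    if (!object@kind %in% c("raw", "normalized", "difference"))
        msg <- c(msg, "kind must be raw, normalized or difference")
    if (object@kind == "raw" &&
        any(object@values != round(object@values)))
        msg <- c(msg, "raw matrices must have integer entries")
    if (object@kind != "difference" && any(object@values < 0))
        msg <- c(msg, "raw/normalized matrices must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' VPSOIResult class
#'
#' Per-bin result of the viewpoint / site-of-interest (VP-SOI) resampling
#' test: observed third-site frequency in the positive read set, resampled
#' negative mean and standard deviation, z-score, and class label
#' (`cooperative`, `random`, `competitive`, or `excluded` for bins
#' overlapping the viewpoint or SOI).
#'
#' @slot table A data.frame with columns chrom, start, end, bin,
#'   positive_freq, negative_mean, negative_sd, z, label.
#' @slot viewpointId Integer viewpoint fragment id.
#' @slot soi Numeric length-2 vector, the SOI interval (0-based half-open).
#' @slot grid The [BinGrid-class] used.
#' @slot nPositive,nNegative Integer read-set sizes.
#' @slot nIterations Integer resampling iterations.
#' @slot seed Integer RNG seed used.
#' @slot zThreshold Numeric classification threshold.
#' @export
setClass("VPSOIResult",
    representation(
        table = "data.frame",
        viewpointId = "integer",
        soi = "numeric",
        grid = "BinGrid",
        nPositive = "integer",
        nNegative = "integer",
        nIterations = "integer",
        seed = "integer",
        zThreshold = "numeric"
    )
)

#' LocusModel class
#'
#' Generative model for synthetic multi-contact concatemer libraries over a
#' single toy locus: restriction sites planted at exponential spacing, a
#' viewpoint fragment, power-law distance decay of pairwise contacts,
#' optional cooperative/competitive triads and an optional insulating
#' boundary scaling cross-boundary contact weights.
#'
#' @slot chrom Name of the simulated chromosome.
#' @slot genomeLength Locus length in bp.
#' @slot siteSpacing Mean distance between planted recognition sites, bp.
#' @slot minFragLength Minimum planted fragment length, bp.
#' @slot viewpointPos Viewpoint coordinate (0-based bp).
#' @slot decayExponent Positive real; pairwise contact probability is
#'   proportional to (midpoint distance)^-decayExponent.
#' @slot cardinalityProbs Probabilities for the number of non-viewpoint
#'   fragments per read, k = 1..length(cardinalityProbs); sums to 1.
#' @slot triads data.frame with columns startA, endA, startB, endB, beta:
#'   once a fragment in A is drawn into a read, weights of fragments in B
#'   are multiplied by beta for the remaining draws (beta > 1 cooperative,
#'   beta < 1 competitive).
#' @slot boundaryPos Position of an insulating boundary in bp, or NA.
#' @slot insulationFactor Gamma in (0, 1]; weight multiplier for partners
#'   on the far side of the boundary from the viewpoint.
#' @slot enzyme The [RestrictionEnzyme-class] planted in the genome.
#' @export
setClass("LocusModel",
    representation(
        chrom = "character",
        genomeLength = "numeric",
        siteSpacing = "numeric",
        minFragLength = "numeric",
        viewpointPos = "numeric",
        decayExponent = "numeric",
        cardinalityProbs = "numeric",
        triads = "data.frame",
        boundaryPos = "numeric",
        insulationFactor = "numeric",
        enzyme = "RestrictionEnzyme"
    )
)

setValidity("LocusModel", function(object) {
    msg <- NULL
    if (object@genomeLength < 10 * object@siteSpacing)
        msg <- c(msg, "genomeLength must be at least 10 x siteSpacing")
    if (abs(sum(object@cardinalityProbs) - 1) > 1e-8 ||
        any(object@cardinalityProbs < 0))
        msg <- c(msg, "cardinalityProbs must be non-negative and sum to 1")
    if (object@decayExponent <= 0)
        msg <- c(msg, "decayExponent must be positive")
    if (object@viewpointPos < 0 || object@viewpointPos >= object@genomeLength)
        msg <- c(msg, "viewpointPos outside the locus")
    if (!is.na(object@boundaryPos) &&
        (object@insulationFactor <= 0 || object@insulationFactor > 1))
        msg <- c(msg, "insulationFactor must lie in (0, 1]")
    if (nrow(object@triads) &&
        !all(c("startA", "endA", "startB", "endB", "beta") %in%
             colnames(object@triads)))
        msg <- c(msg, "triads needs columns startA, endA, startB, endB, beta")
    if (is.null(msg)) TRUE else msg
})
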