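# independent oracles; deliberately share no code with the implementation

# brute-force IUPAC digest oracle: regex character classes, lookahead for
# overlapping occurrences, both strands; genome N matched only by code N
.iupacClass <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGTN]")

.iupacComplement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y",
                      Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

.siteRegex <- function(site) {
    paste0("(?=", paste(.iupacClass[strsplit(site, "")[[1L]]],
                        collapse = ""), ")")
}

.siteRevComp <- function(site) {
    paste(rev(.iupacComplement[strsplit(site, "")[[1L]]]), collapse = "")
}

# all 0-based occurrence starts of an IUPAC site in a sequence
oracleOccurrences <- function(txt, site) {
    occ <- gregexpr(.siteRegex(site), txt, perl = TRUE)[[1L]]
    if (occ[1L] == -1L) integer(0) else as.integer(occ) - 1L
}

# 0-based boundary set of the digest, including 0 and L
oracleBoundaries <- function(txt, site, cutOffset) {
    L <- nchar(txt)
    slen <- nchar(site)
    cuts <- oracleOccurrences(txt, site) + cutOffset
    rc <- .siteRevComp(site)
    if (rc != site)
        cuts <- c(cuts, oracleOccurrences(txt, rc) + (slen - cutOffset))
    sort(unique(c(0L, cuts[cuts > 0L & cuts < L], L)))
}

# random toy genome over ACGT (optionally salted with N runs)
randomGenome <- function(len, withN = FALSE) {
    alpha <- c("A", "C", "G", "T")
    s <- sample(alpha, len, replace = TRUE)
    if (withN) {
        k <- sample(3:8, 1L)
        at <- sample(len - k, 1L)
        s[at:(at + k)] <- "N"
    }
    paste(s, collapse = "")
}

# enumeration oracle for the negative resampling on tiny inputs: exhausts
# every equally likely combination of one-fragment removals over a fixed
# full draw of the negative set, returning exact per-bin mean and
# population sd of the presence frequency
oracleEnumNegative <- function(memberBins, nBins) {
    combos <- expand.grid(lapply(memberBins, function(b) seq_along(b)))
    freqs <- matrix(0, nrow(combos), nBins)
    for (r in seq_len(nrow(combos))) {
        tal <- numeric(nBins)
        for (i in seq_along(memberBins)) {
            left <- memberBins[[i]][-combos[r, i]]
            for (b in unique(left)) tal[b] <- tal[b] + 1
        }
        freqs[r, ] <- tal / length(memberBins)
    }
    list(mean = colMeans(freqs),
         sd = sqrt(colMeans(freqs^2) - colMeans(freqs)^2))
}

# brute-force pair enumeration oracle for three-way matrices
oraclePairCounts <- function(memberBinsList, mode = "all_triples") {
    `%||%` <- function(a, b) if (is.null(a)) b else a
    out <- new.env()
    bump <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        assign(key, (get0(key, envir = out) %||% 0) + 1, envir = out)
    }
    for (bins in memberBinsList) {
        if (mode == "first_two") {
            if (length(bins) < 2L || is.na(bins[1L]) || is.na(bins[2L]))
                next
            bump(bins[1L], bins[2L])
        } else {
            bins <- bins[!is.na(bins)]
            if (length(bins) < 2L) next
            for (i in seq_len(length(bins) - 1L))
                for (j in seq.int(i + 1L, length(bins)))
                    bump(bins[i], bins[j])
        }
    }
    env <- as.list(out)
    env[order(names(env))]
}
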