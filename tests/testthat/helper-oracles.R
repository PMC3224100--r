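## Independent oracles used to cross-check the implementation.
## These deliberately use different algorithms (per-start unit extension for
## the SSR scan, read-by-read product arithmetic for the quality model) from
## the package internals.

oraclePrimitive <- function(unit) {
    k <- length(unit)
    for (d in seq_len(k - 1L)) {
        if (k %% d == 0L && all(unit == rep(unit[seq_len(d)], k %/% d)))
            return(FALSE)
    }
    TRUE
}

oracleCanonical <- function(unit) {
    s <- paste(unit, collapse = "")
    k <- nchar(s)
    d <- paste0(s, s)
    min(vapply(seq_len(k), function(i) substr(d, i, i + k - 1L),
               character(1L)))
}

## Brute-force perfect-SSR scanner: tests every (start, motif length) and
## extends unit by unit, then applies maximality, the class minima,
## primitivity, and the same declared greedy overlap-resolution rule.
bruteForceSsrScan <- function(seq, rules = SsrRules()) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    rows <- list()
    for (k in rules@motifLengths) {
        minRep <- rules@minRepeats[[as.character(k)]]
        if (L < k * minRep) next
        for (i in seq_len(L - k * minRep + 1L)) {
            unit <- ch[i:(i + k - 1L)]
            if (any(unit == "N")) next
            ## maximal runs only: not extendable by one position to the left
            if (i > 1L && ch[i - 1L] != "N" && ch[i - 1L] == ch[i - 1L + k])
                next
            reps <- 1L
            j <- i + k
            while (j + k - 1L <= L && !any(ch[j:(j + k - 1L)] == "N") &&
                   all(ch[j:(j + k - 1L)] == unit)) {
                reps <- reps + 1L
                j <- j + k
            }
            if (reps < minRep) next
            if (!oraclePrimitive(unit)) next
            rows[[length(rows) + 1L]] <- data.frame(
                start = i, end = i + reps * k - 1L, width = reps * k,
                motif = oracleCanonical(unit), motifLength = k,
                repeats = reps, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          width = integer(), motif = character(),
                          motifLength = integer(), repeats = integer(),
                          stringsAsFactors = FALSE))
    cand <- do.call(rbind, rows)
    ## greedy resolution: longest span, then leftmost, then shortest motif
    cand <- cand[order(-cand$width, cand$start, cand$motifLength), ,
                 drop = FALSE]
    keep <- logical(nrow(cand))
    ks <- integer(0); ke <- integer(0)
    for (r in seq_len(nrow(cand))) {
        if (!length(ks) || all(cand$end[r] < ks | cand$start[r] > ke)) {
            keep[r] <- TRUE
            ks <- c(ks, cand$start[r]); ke <- c(ke, cand$end[r])
        }
    }
    out <- cand[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## Exact-likelihood oracle for the polymorphism posterior: multiplies the
## per-read emission probabilities one read at a time, no logs.
oracleQuality <- function(nMajor, nMinor, errorRate = 0.01) {
    L0 <- 1
    for (r in seq_len(nMajor)) L0 <- L0 * (1 - errorRate)
    for (r in seq_len(nMinor)) L0 <- L0 * (errorRate / 3)
    p1 <- (1 - errorRate) / 2 + errorRate / 6
    L1 <- 1
    for (r in seq_len(nMajor + nMinor)) L1 <- L1 * p1
    L1 / (L0 + L1)
}

## Convert a GRanges of perfect loci to the oracle's table layout.
ssrGrangesToTable <- function(gr) {
    d <- data.frame(start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    width = GenomicRanges::width(gr),
                    motif = S4Vectors::mcols(gr)$motif,
                    motifLength = S4Vectors::mcols(gr)$motifLength,
                    repeats = S4Vectors::mcols(gr)$repeats,
                    stringsAsFactors = FALSE)
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")
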