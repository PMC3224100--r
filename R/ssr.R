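## Perfect and compound microsatellite mining.
##
## Loci are reported as GRanges in 1-based closed coordinates on the contig.
## A perfect locus spans exactly repeats * motifLength bases (partial trailing
## units are trimmed); a compound locus spans from the first to the last of a
## chain of perfect loci whose pairwise gaps are <= compoundMaxGap.

#' Primitive root of a DNA word
#'
#' The shortest word whose repetition yields `word` (e.g. `"ATAT"` -> `"AT"`).
#'
#' @param word a DNA word.
#' @return The primitive root of `word`.
#' @export
primitiveRoot <- function(word) {
    n <- nchar(word)
    for (d in seq_len(n)) {
        if (n %% d != 0L) next
        root <- substr(word, 1L, d)
        if (strrep(root, n %/% d) == word) return(root)
    }
    word
}

#' Canonical form of a microsatellite motif
#'
#' Extracts the primitive root of `word` and returns its lexicographically
#' smallest rotation.  The reverse complement is deliberately not folded in:
#' transcript strand is meaningful for EST contigs, so `AG` and `CT` remain
#' distinct motifs.  Mononucleotide motifs are unsupported.
#'
#' @param word a DNA word over \{A,C,G,T\}, length 2-6 (or a repetition of
#'   such a word).
#' @return The canonical primitive motif.
#' @examples
#' canonicalMotif("GAC")   # "ACG"
#' canonicalMotif("ATAT")  # "AT"
#' @export
canonicalMotif <- function(word) {
    if (length(word) != 1L || is.na(word) || grepl("[^ACGT]", word))
        stop("motif must be a single word over {A,C,G,T}")
    root <- primitiveRoot(word)
    k <- nchar(root)
    if (k < 2L)
        stop("mononucleotide motifs unsupported")
    if (k > 6L)
        stop("motif length must be 2-6, got ", k)
    ch <- strsplit(root, "", fixed = TRUE)[[1L]]
    rots <- vapply(seq_len(k), function(i)
        paste(ch[c(i:k, seq_len(i - 1L))[seq_len(k)]], collapse = ""),
        character(1L))
    min(rots)
}

.isPrimitive <- function(chars) {
    k <- length(chars)
    for (d in seq_len(k - 1L)) {
        if (k %% d != 0L) next
        if (all(chars == rep_len(chars[seq_len(d)], k))) return(FALSE)
    }
    TRUE
}

## Greedy overlap resolution among candidate runs: longest span first, ties
## by leftmost start, then shortest motif.  Deterministic.
.resolveOverlaps <- function(cand) {
    if (nrow(cand) <= 1L) return(cand)
    o <- order(-cand$width, cand$start, cand$motifLength)
    cand <- cand[o, , drop = FALSE]
    kept <- logical(nrow(cand))
    keptStart <- integer(0)
    keptEnd <- integer(0)
    for (i in seq_len(nrow(cand))) {
        s <- cand$start[i]; e <- cand$end[i]
        if (!length(keptStart) || all(e < keptStart | s > keptEnd)) {
            kept[i] <- TRUE
            keptStart <- c(keptStart, s)
            keptEnd <- c(keptEnd, e)
        }
    }
    out <- cand[kept, , drop = FALSE]
    out[order(out$start), , drop = FALSE]
}

.scanSequence <- function(chars, rules) {
    L <- length(chars)
    res <- list()
    for (k in rules@motifLengths) {
        minRep <- rules@minRepeats[[as.character(k)]]
        if (L < k * minRep) next
        a <- chars[seq_len(L - k)]
        b <- chars[seq_len(L - k) + k]
        m <- a == b & a != "N" & b != "N"
        r <- rle(m)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values)
        for (h in hit) {
            i <- starts[h]
            runLen <- r$lengths[h]
            reps <- (runLen + k) %/% k
            if (reps < minRep) next
            unit <- chars[i:(i + k - 1L)]
            if (!.isPrimitive(unit)) next
            res[[length(res) + 1L]] <- data.frame(
                start = i, end = i + reps * k - 1L, width = reps * k,
                motif = canonicalMotif(paste(unit, collapse = "")),
                motifLength = k, repeats = reps,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          width = integer(), motif = character(),
                          motifLength = integer(), repeats = integer(),
                          stringsAsFactors = FALSE))
    .resolveOverlaps(do.call(rbind, res))
}

#' Find perfect microsatellites
#'
#' Scans contigs for maximal uninterrupted runs of a primitive 2-6 nt motif
#' meeting the per-class minimum repeat counts of `rules`.  Runs are broken at
#' `N`; each fragment is evaluated independently.  Overlapping candidate runs
#' of different motif classes are resolved greedily: longest span wins, ties
#' go to the leftmost start, then the shortest motif.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (or a single named
#'   character vector of sequences).
#' @param rules an [SsrRules] object.
#' @return A [GenomicRanges::GRanges] (1-based closed) with metadata columns
#'   `motif` (canonical), `motifLength`, `repeats` and `ssrClass = "perfect"`.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = "TTGGACACACACACACGGTT"))
#' findPerfectSsrs(ctg, SsrRules())
#' @export
findPerfectSsrs <- function(contigs, rules = SsrRules()) {
    validObject(rules)
    seqs <- as.character(contigs)
    if (is.null(names(seqs)))
        stop("contigs must be named")
    all <- lapply(names(seqs), function(id) {
        chars <- strsplit(seqs[[id]], "", fixed = TRUE)[[1L]]
        d <- .scanSequence(chars, rules)
        if (nrow(d)) d$contig <- id
        d
    })
    all <- all[vapply(all, nrow, integer(1L)) > 0L]
    if (!length(all)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(motif = character(), motifLength = integer(),
                               repeats = integer(), ssrClass = character())
        return(gr)
    }
    d <- do.call(rbind, all)
    gr <- GRanges(d$contig, IRanges(d$start, d$end))
    mcols(gr) <- DataFrame(motif = d$motif, motifLength = d$motifLength,
                           repeats = d$repeats,
                           ssrClass = rep("perfect", nrow(d)))
    gr
}

#' Merge near-adjacent loci into compound repeats
#'
#' Maximal chains of perfect loci on one contig whose inter-locus gaps are
#' at most `compoundMaxGap` nt (boundary inclusive) are merged into compound
#' loci spanning the first start to the last end.  Singleton chains stay
#' perfect.  Component motifs, repeat counts and spans are kept in list
#' columns in chain order.
#'
#' @param ssrs a [GenomicRanges::GRanges] of perfect loci as returned by
#'   [findPerfectSsrs()]; must be position-sorted per contig, non-duplicated
#'   and non-overlapping.
#' @param rules an [SsrRules] supplying `compoundMaxGap`.
#' @return A [GenomicRanges::GRanges] of perfect and compound loci with the
#'   columns of [findPerfectSsrs()] plus `componentMotif`, `componentRepeats`,
#'   `componentStart`, `componentEnd` list-columns.  For a compound locus
#'   `motif` is the motif of its widest component and `repeats` is `NA`.
#' @export
mergeCompound <- function(ssrs, rules = SsrRules()) {
    validObject(rules)
    maxGap <- rules@compoundMaxGap
    if (length(ssrs) == 0L) {
        mcols(ssrs)$componentMotif <- CharacterList()
        mcols(ssrs)$componentRepeats <- IntegerList()
        mcols(ssrs)$componentStart <- IntegerList()
        mcols(ssrs)$componentEnd <- IntegerList()
        return(ssrs)
    }
    out <- list()
    for (ctg in unique(as.character(seqnames(ssrs)))) {
        g <- ssrs[as.character(seqnames(ssrs)) == ctg]
        s <- start(g); e <- end(g)
        if (is.unsorted(s, strictly = FALSE))
            stop("input loci must be sorted by start within each contig")
        if (anyDuplicated(paste(s, e)))
            stop("input loci must be non-duplicated")
        if (length(g) > 1L && any(s[-1L] <= e[-length(g)]))
            stop("input loci must be non-overlapping")
        gap <- if (length(g) > 1L) s[-1L] - e[-length(g)] - 1L else integer()
        chain <- cumsum(c(0L, as.integer(gap > maxGap))) + 1L
        for (ch in unique(chain)) {
            idx <- which(chain == ch)
            gi <- g[idx]
            if (length(idx) == 1L) {
                m <- mcols(gi)
                row <- GRanges(ctg, IRanges(start(gi), end(gi)))
                mcols(row) <- DataFrame(
                    motif = m$motif, motifLength = m$motifLength,
                    repeats = m$repeats, ssrClass = "perfect",
                    componentMotif = CharacterList(m$motif),
                    componentRepeats = IntegerList(m$repeats),
                    componentStart = IntegerList(start(gi)),
                    componentEnd = IntegerList(end(gi)))
            } else {
                m <- mcols(gi)
                widest <- which.max(width(gi))
                row <- GRanges(ctg, IRanges(min(start(gi)), max(end(gi))))
                mcols(row) <- DataFrame(
                    motif = m$motif[widest],
                    motifLength = m$motifLength[widest],
                    repeats = NA_integer_, ssrClass = "compound",
                    componentMotif = CharacterList(m$motif),
                    componentRepeats = IntegerList(m$repeats),
                    componentStart = IntegerList(start(gi)),
                    componentEnd = IntegerList(end(gi)))
            }
            out[[length(out) + 1L]] <- row
        }
    }
    res <- suppressWarnings(do.call(c, out))
    res[order(as.character(seqnames(res)), start(res))]
}

#' Summarise a set of SSR loci
#'
#' @param ssrs a [GenomicRanges::GRanges] from [findPerfectSsrs()] or
#'   [mergeCompound()].
#' @return A list with `byMotifLength` (locus counts for perfect loci by
#'   motif length), `repeatDist` and `lengthDist` (tables over perfect loci),
#'   `nPerfect`, `nCompound` and `total`.
#' @export
ssrSummary <- function(ssrs) {
    cls <- if (length(ssrs)) mcols(ssrs)$ssrClass else character()
    perfect <- ssrs[cls == "perfect"]
    byLen <- integer(5L)
    names(byLen) <- as.character(2:6)
    if (length(perfect)) {
        t <- table(mcols(perfect)$motifLength)
        byLen[names(t)] <- as.integer(t)
    }
    list(byMotifLength = byLen,
         repeatDist = if (length(perfect))
             table(mcols(perfect)$repeats) else table(integer()),
         lengthDist = if (length(perfect))
             table(width(perfect)) else table(integer()),
         nPerfect = length(perfect),
         nCompound = sum(cls == "compound"),
         total = length(ssrs))
}

#' Minimum attainable SSR length under a rule set
#'
#' The shortest locus the rules can emit: the minimum over motif classes of
#' motif length times the class's minimum repeat count (12 nt under the
#' default rules, from the dinucleotide class 2 x 6).
#'
#' @param rules an [SsrRules].
#' @return Integer length in nt.
#' @export
minAttainableSsrLength <- function(rules = SsrRules()) {
    validObject(rules)
    ks <- rules@motifLengths
    min(ks * rules@minRepeats[as.character(ks)])
}
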