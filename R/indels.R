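## Indel detection in gapped per-genotype consensus alignments, and the
## candidate polymorphic-SSR report built from indels overlapping SSR loci.

.alnMatrix <- function(aln) {
    do.call(rbind, strsplit(alignmentRows(aln), "", fixed = TRUE))
}

## Reference-frame positions: refPos[c] = number of ungapped reference (row 1)
## bases at or before column c.
.refPositions <- function(gapRow1) {
    cumsum(!gapRow1)
}

#' Read a gapped per-genotype alignment from aligned FASTA
#'
#' @param path aligned-FASTA file; records are per-sample gapped consensi of
#'   equal length, named by sample id.
#' @param contig contig id; defaults to the file name without extension.
#' @return A [GappedAlignment].
#' @export
readGappedFasta <- function(path, contig = sub("\\.[^.]*(\\.[^.]*)?$", "",
                                               basename(path))) {
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) < 2L)
        stop("aligned FASTA needs >= 2 rows: ", path)
    rows <- toupper(as.character(raw))
    names(rows) <- sub("\\s.*$", "", names(raw))
    GappedAlignment(contig, rows)
}

#' Write a gapped alignment as aligned FASTA
#'
#' @param aln a [GappedAlignment].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGappedFasta <- function(aln, path) {
    rows <- alignmentRows(aln)
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(rows))
        writeLines(c(paste0(">", names(rows)[i]), rows[[i]]), con)
    invisible(path)
}

#' Detect indels between genotype consensi
#'
#' Finds maximal runs of alignment columns in which a constant, non-empty,
#' proper subset of rows is gapped (the carriers).  A run is emitted when its
#' length lies in `[minLen, maxLen]` and at least `minFlank` columns that are
#' gap-free in every row border it on each side; runs failing any bound are
#' silently dropped.  Gap runs shared by all rows would be alignment artifacts
#' and are rejected by the alignment validity itself.  Adjacent distinct gap
#' runs closer than `minFlank` reject each other, since the gap-free flank
#' requirement applies between them.  Substitutions in the flanks are allowed:
#' the flank rule concerns gaps only.
#'
#' Coordinates are reported in the reference frame of the alignment's first
#' row (panel order): a deletion in the carriers spans the deleted reference
#' bases; an insertion (gap in the reference row) is anchored at the reference
#' base preceding it with width 1.
#'
#' @param aln a [GappedAlignment].
#' @param minLen,maxLen emitted gap-run length bounds in nt (defaults 3 and
#'   50).
#' @param minFlank minimum gap-free columns required on each side (default 25).
#' @return A [GenomicRanges::GRanges] in reference coordinates with metadata
#'   columns `columnStart`, `columnEnd` (alignment columns, closed),
#'   `indelLength`, `carriers` (CharacterList), `leftFlank`, `rightFlank`,
#'   `refGap` (TRUE for insertions relative to the reference row), and
#'   placeholder `ssrOverlap`/`overlapMotif`/`inFrame` columns filled by
#'   [annotateSsrOverlap()].
#' @export
detectIndels <- function(aln, minLen = 3L, maxLen = 50L, minFlank = 25L) {
    validObject(aln)
    m <- .alnMatrix(aln)
    gaps <- m == "-"
    nc <- ncol(m)
    key <- apply(gaps, 2L, function(col) paste(which(col), collapse = ","))
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nRuns <- length(r$values)
    rows <- list()
    refPos <- .refPositions(gaps[1L, ])
    for (h in seq_len(nRuns)) {
        if (r$values[h] == "") next
        carrierIdx <- as.integer(strsplit(r$values[h], ",", fixed = TRUE)[[1L]])
        if (length(carrierIdx) >= nrow(m)) next   # not a proper subset
        len <- r$lengths[h]
        if (len < minLen || len > maxLen) next
        leftFlank <- if (h > 1L && r$values[h - 1L] == "")
            r$lengths[h - 1L] else 0L
        rightFlank <- if (h < nRuns && r$values[h + 1L] == "")
            r$lengths[h + 1L] else 0L
        if (leftFlank < minFlank || rightFlank < minFlank) next
        cs <- starts[h]; ce <- ends[h]
        refGap <- gaps[1L, cs]
        if (refGap) {
            rs <- max(refPos[cs], 1L)
            re <- rs
        } else {
            rs <- refPos[cs]
            re <- refPos[ce]
        }
        rows[[length(rows) + 1L]] <- data.frame(
            refStart = rs, refEnd = re, columnStart = cs, columnEnd = ce,
            indelLength = len,
            carriers = paste(rownames(m)[carrierIdx], collapse = ","),
            leftFlank = leftFlank, rightFlank = rightFlank, refGap = refGap,
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(columnStart = integer(), columnEnd = integer(),
                               indelLength = integer(),
                               carriers = CharacterList(),
                               leftFlank = integer(), rightFlank = integer(),
                               refGap = logical(), ssrOverlap = character(),
                               overlapMotif = character(), inFrame = logical())
        return(gr)
    }
    d <- do.call(rbind, rows)
    gr <- GRanges(alignmentContig(aln), IRanges(d$refStart, d$refEnd))
    mcols(gr) <- DataFrame(
        columnStart = d$columnStart, columnEnd = d$columnEnd,
        indelLength = d$indelLength,
        carriers = CharacterList(strsplit(d$carriers, ",", fixed = TRUE)),
        leftFlank = d$leftFlank, rightFlank = d$rightFlank, refGap = d$refGap,
        ssrOverlap = NA_character_, overlapMotif = NA_character_,
        inFrame = NA)
    gr
}

#' Annotate indels with overlapping SSR loci
#'
#' An indel overlapping an SSR span by at least 1 nt (reference coordinates)
#' gets `ssrOverlap` set to the locus key (`start-end/motif`), `overlapMotif`
#' to the motif of the overlapped locus (for compound loci, the component with
#' the largest overlap), and `inFrame = TRUE` when the indel length is a
#' multiple of that motif's length.
#'
#' @param indels a [GenomicRanges::GRanges] from [detectIndels()].
#' @param ssrs a [GenomicRanges::GRanges] of SSR loci on the same contig.
#' @return `indels` with the annotation columns filled.
#' @export
annotateSsrOverlap <- function(indels, ssrs) {
    if (length(indels) == 0L) return(indels)
    if (length(ssrs)) {
        ctgI <- unique(as.character(seqnames(indels)))
        ctgS <- unique(as.character(seqnames(ssrs)))
        if (!all(ctgS %in% ctgI) || !all(ctgI %in% ctgS))
            stop("indels and SSR loci refer to different contigs: ",
                 paste(ctgI, collapse = ","), " vs ",
                 paste(ctgS, collapse = ","))
    }
    if (length(ssrs) == 0L) return(indels)
    hits <- findOverlaps(indels, ssrs, minoverlap = 1L)
    if (length(hits) == 0L) return(indels)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ovw <- width(IRanges::pintersect(IRanges::ranges(indels)[qh],
                                     IRanges::ranges(ssrs)[sh]))
    for (q in unique(qh)) {
        sel <- which(qh == q)
        best <- sh[sel[which.max(ovw[sel])]]
        locus <- ssrs[best]
        motif <- mcols(locus)$motif
        if (mcols(locus)$ssrClass == "compound") {
            cs <- mcols(locus)$componentStart[[1L]]
            ce <- mcols(locus)$componentEnd[[1L]]
            cw <- pmin(ce, end(indels[q])) - pmax(cs, start(indels[q])) + 1L
            if (any(cw > 0L))
                motif <- mcols(locus)$componentMotif[[1L]][which.max(cw)]
        }
        mcols(indels)$ssrOverlap[q] <- paste0(start(locus), "-", end(locus),
                                              "/", mcols(locus)$motif)
        mcols(indels)$overlapMotif[q] <- motif
        mcols(indels)$inFrame[q] <-
            mcols(indels)$indelLength[q] %% nchar(motif) == 0L
    }
    indels
}

#' Candidate polymorphic-SSR report
#'
#' One row per SSR-overlapping indel, with the SSR span, motif, indel length
#' (equal to the allele-length difference between carrier and non-carrier
#' genotypes) and per-sample allele lengths counted from the alignment: the
#' number of non-gap characters each row contributes over the union of the
#' SSR's and the indel's alignment columns.  Rows are sorted by contig then
#' position.
#'
#' @param indels annotated indels from [annotateSsrOverlap()].
#' @param aln the [GappedAlignment] the indels came from.
#' @param path optional output path; when given the table is written as TSV.
#' @return A `data.frame` (invisibly when `path` is given).
#' @export
polymorphicSsrReport <- function(indels, aln, path = NULL) {
    validObject(aln)
    m <- .alnMatrix(aln)
    refPos <- .refPositions(m[1L, ] == "-")
    samples <- rownames(m)
    keep <- which(!is.na(mcols(indels)$ssrOverlap))
    cols <- c("contig", "ssr_span", "motif", "indel_start", "indel_length",
              "in_frame", "allele_diff", paste0("allele_len_", samples))
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    for (q in keep) {
        span <- strsplit(sub("/.*$", "", mcols(indels)$ssrOverlap[q]),
                         "-", fixed = TRUE)[[1L]]
        ss <- as.integer(span[1L]); se <- as.integer(span[2L])
        ssrCols <- which(refPos >= ss & refPos <= se)
        unionCols <- sort(unique(c(ssrCols,
            mcols(indels)$columnStart[q]:mcols(indels)$columnEnd[q])))
        lens <- vapply(seq_along(samples), function(i)
            sum(m[i, unionCols] != "-"), integer(1L))
        row <- data.frame(contig = as.character(seqnames(indels))[q],
                          ssr_span = paste0(ss, "-", se),
                          motif = mcols(indels)$overlapMotif[q],
                          indel_start = start(indels)[q],
                          indel_length = mcols(indels)$indelLength[q],
                          in_frame = mcols(indels)$inFrame[q],
                          allele_diff = mcols(indels)$indelLength[q],
                          stringsAsFactors = FALSE)
        row[paste0("allele_len_", samples)] <- as.list(lens)
        out <- rbind(out, row)
    }
    if (nrow(out))
        out <- out[order(out$contig, out$indel_start), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(path)) {
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(out))
    }
    out
}
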