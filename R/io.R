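#' Read contig consensus sequences from FASTA
#'
#' Reads a FASTA file of contig sequences, uppercases them, and validates that
#' ids are unique, sequences are non-empty, and the alphabet is restricted to
#' A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT", ">c2", "NNNN"), fa)
#' readContigs(fa)
#' @export
readContigs <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    firstLines <- readLines(path, n = 50L)
    nonEmpty <- which(nzchar(trimws(firstLines)))
    if (length(nonEmpty) && !startsWith(firstLines[nonEmpty[1L]], ">"))
        stop("malformed FASTA record at line ", nonEmpty[1L],
             ": expected '>' header")
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(raw))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate contig id: ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(as.character(raw))
    if (any(!nzchar(seqs)))
        stop("empty sequence for contig: ",
             paste(ids[!nzchar(seqs)], collapse = ", "))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("sequence characters outside {A,C,G,T,N} in contig: ",
             paste(ids[bad], collapse = ", "))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write contigs to FASTA
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeContigs <- function(contigs, path) {
    Biostrings::writeXStringSet(contigs, path)
    invisible(path)
}

#' Read a genotype panel configuration
#'
#' The panel config is a YAML key-value file with a `samples` list (ordered)
#' and an optional `read_groups` mapping of read-group id to sample id.
#'
#' @param path path to a YAML panel file.
#' @return A [GenotypePanel].
#' @export
readPanelConfig <- function(path) {
    if (!file.exists(path))
        stop("panel config not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$samples))
        stop("panel config must list 'samples'")
    samples <- as.character(unlist(cfg$samples))
    if (!is.null(cfg$read_groups)) {
        rg <- vapply(cfg$read_groups, as.character, character(1L))
        GenotypePanel(samples, readGroupMap = rg)
    } else {
        GenotypePanel(samples)
    }
}

#' Write a genotype panel configuration
#'
#' @param panel a [GenotypePanel].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePanelConfig <- function(panel, path) {
    yaml::write_yaml(list(samples = as.list(panelSamples(panel)),
                          read_groups = as.list(readGroupMap(panel))), path)
    invisible(path)
}

## --- TSV pileup dialect ----------------------------------------------------
## tab-separated: contig, pos (1-based), sample, countA, countC, countG, countT
## One row per (contig, pos, sample) with at least one counted base.

#' Read a TSV pileup
#'
#' Reads the package's TSV pileup dialect (tab-separated columns `contig`,
#' `pos` 1-based, `sample`, `countA`, `countC`, `countG`, `countT`) into
#' per-contig [ContigPileup] objects.  Contig lengths come from `contigs`.
#'
#' @param path path to the TSV file (a header line is required).
#' @param panel a [GenotypePanel]; rows for unknown samples are an error.
#' @param contigs a named [Biostrings::DNAStringSet] providing contig lengths.
#' @return A named list of [ContigPileup], one per contig present in the file.
#' @export
readPileupTsv <- function(path, panel, contigs) {
    if (!file.exists(path))
        stop("pileup TSV not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "integer",
                                            "character", "integer", "integer",
                                            "integer", "integer"))
    expected <- c("contig", "pos", "sample",
                  "countA", "countC", "countG", "countT")
    if (!identical(names(tab), expected))
        stop("pileup TSV must have columns: ", paste(expected, collapse = ", "))
    samples <- panelSamples(panel)
    badS <- setdiff(unique(tab$sample), samples)
    if (length(badS))
        stop("unknown sample in pileup: ", paste(badS, collapse = ", "))
    badC <- setdiff(unique(tab$contig), names(contigs))
    if (length(badC))
        stop("unknown contig in pileup: ", paste(badC, collapse = ", "))
    out <- list()
    for (ctg in unique(tab$contig)) {
        sub <- tab[tab$contig == ctg, , drop = FALSE]
        L <- Biostrings::width(contigs[ctg])
        if (any(sub$pos < 1L | sub$pos > L))
            stop("pileup position outside contig ", ctg)
        pu <- ContigPileup(ctg, L, samples)
        cnt <- pu@counts
        si <- match(sub$sample, samples)
        for (b in seq_along(DNA_BASES4)) {
            v <- sub[[paste0("count", DNA_BASES4[b])]]
            cnt[cbind(b, sub$pos, si)] <- cnt[cbind(b, sub$pos, si)] + v
        }
        pu@counts <- cnt
        out[[ctg]] <- pu
    }
    out
}

#' Write a TSV pileup
#'
#' @param pileups a named list of [ContigPileup].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePileupTsv <- function(pileups, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("contig", "pos", "sample", "countA", "countC",
                       "countG", "countT"), collapse = "\t"), con)
    for (pu in pileups) {
        cnt <- pu@counts
        for (si in seq_along(pu@samples)) {
            m <- cnt[, , si, drop = FALSE]
            dim(m) <- dim(cnt)[1:2]
            pos <- which(colSums(m) > 0L)
            if (!length(pos)) next
            rows <- paste(pu@contig, pos, pu@samples[si],
                          m[1L, pos], m[2L, pos], m[3L, pos], m[4L, pos],
                          sep = "\t")
            writeLines(rows, con)
        }
    }
    invisible(path)
}

## --- SAM ingestion ---------------------------------------------------------

## Expand one simple CIGAR into (refPos, queryPos) pairs for aligned bases.
## Supports M/=/X (aligned), I/S (query only), D/N (reference only), H/P.
.cigarAlignedBlocks <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
    if (!length(ops) || sum(nchar(ops)) != nchar(cigar))
        stop("unsupported CIGAR: ", cigar)
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    list(op = op, len = len)
}

#' Build per-genotype pileups from a SAM file
#'
#' Reads a SAM file of mapped reads carrying `RG` tags, assigns each read to a
#' genotype sample through the panel's read-group map, and tallies aligned
#' bases per position per sample.  Bases below `minBaseQuality` are excluded
#' from counts and depth; deletions and N bases are never counted.
#'
#' @param samPath path to a SAM file with `@SQ` headers.
#' @param panel a [GenotypePanel]; reads with unknown read groups are an error.
#' @param contigs a named [Biostrings::DNAStringSet]; a read extending beyond
#'   its contig end is an error.
#' @param minBaseQuality Phred cutoff below which a base is not counted
#'   (default 20).
#' @return A named list of [ContigPileup] covering every contig with >= 1
#'   counted base.
#' @export
buildPileupFromSam <- function(samPath, panel, contigs, minBaseQuality = 20L) {
    if (!file.exists(samPath))
        stop("SAM file not found: ", samPath)
    bam <- Rsamtools::asBam(samPath,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    param <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "cigar", "seq", "qual"), tag = "RG")
    rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
    keep <- !is.na(rec$pos)
    samples <- panelSamples(panel)
    rgmap <- readGroupMap(panel)
    out <- list()
    n <- sum(keep)
    if (n == 0L) return(out)
    rname <- as.character(rec$rname)[keep]
    pos <- rec$pos[keep]
    cigar <- rec$cigar[keep]
    seqs <- as.character(rec$seq)[keep]
    quals <- as.character(rec$qual)[keep]
    rgs <- rec$tag$RG[keep]
    if (any(is.na(rgs)))
        stop("mapped read without RG tag")
    badRg <- setdiff(unique(rgs), names(rgmap))
    if (length(badRg))
        stop("unknown read group: ", paste(badRg, collapse = ", "))
    smp <- rgmap[rgs]
    for (i in seq_len(n)) {
        ctg <- rname[i]
        if (!ctg %in% names(contigs))
            stop("read maps to unknown contig: ", ctg)
        L <- Biostrings::width(contigs[ctg])
        if (is.null(out[[ctg]]))
            out[[ctg]] <- ContigPileup(ctg, L, samples)
        blocks <- .cigarAlignedBlocks(cigar[i])
        q <- 1L
        r <- pos[i]
        bases <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        qv <- utf8ToInt(quals[i]) - 33L
        si <- match(smp[i], samples)
        cnt <- out[[ctg]]@counts
        for (j in seq_along(blocks$op)) {
            op <- blocks$op[j]
            l <- blocks$len[j]
            if (op %in% c("M", "=", "X")) {
                if (r + l - 1L > L)
                    stop("read extends beyond end of contig ", ctg)
                b <- bases[q:(q + l - 1L)]
                bq <- qv[q:(q + l - 1L)]
                rp <- r:(r + l - 1L)
                ok <- bq >= minBaseQuality & b %in% DNA_BASES4
                if (any(ok)) {
                    bi <- match(b[ok], DNA_BASES4)
                    idx <- cbind(bi, rp[ok], si)
                    cnt[idx] <- cnt[idx] + 1L
                }
                q <- q + l; r <- r + l
            } else if (op %in% c("I", "S")) {
                q <- q + l
            } else if (op %in% c("D", "N")) {
                r <- r + l
            } # H, P: no-op
        }
        out[[ctg]]@counts <- cnt
    }
    out
}

#' Write pileups as a minimal SAM file of single-base reads
#'
#' Emits one 1M-CIGAR read per counted base, tagged with the sample's read
#' group, so the SAM ingestion path can be exercised against any in-memory
#' pileup.  Intended for small interface tests, not bulk export.
#'
#' @param pileups a named list of [ContigPileup].
#' @param panel a [GenotypePanel] (read group == sample id is assumed for
#'   samples without an explicit mapping).
#' @param contigs a named [Biostrings::DNAStringSet] for `@SQ` headers.
#' @param path output path.
#' @param baseQuality constant Phred quality written for every base.
#' @return Invisibly, `path`.
#' @export
writePileupSam <- function(pileups, panel, contigs, path, baseQuality = 30L) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    for (ctg in names(contigs))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg,
                           Biostrings::width(contigs[ctg])), con)
    rgmap <- readGroupMap(panel)
    for (rg in names(rgmap))
        writeLines(sprintf("@RG\tID:%s\tSM:%s", rg, rgmap[rg]), con)
    qchar <- intToUtf8(baseQuality + 33L)
    k <- 0L
    for (pu in pileups) {
        cnt <- pu@counts
        idx <- which(cnt > 0L, arr.ind = TRUE)
        if (!nrow(idx)) next
        for (i in seq_len(nrow(idx))) {
            b <- DNA_BASES4[idx[i, 1L]]
            p <- idx[i, 2L]
            s <- pu@samples[idx[i, 3L]]
            rg <- names(rgmap)[match(s, rgmap)][1L]
            for (r in seq_len(cnt[idx[i, 1L], p, idx[i, 3L]])) {
                k <- k + 1L
                writeLines(sprintf("r%07d\t0\t%s\t%d\t60\t1M\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                                   k, pu@contig, p, b, qchar, rg), con)
            }
        }
    }
    invisible(path)
}
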