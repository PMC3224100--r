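## VCF v4.2 and GFF3 export of called markers.

#' Write called SNPs as VCF v4.2
#'
#' One record per SNP with `POS` 1-based, `REF` the pooled major allele
#' (EST contigs have no external reference genome) and `ALT` the minor.
#' `QUAL` is the Phred-scaled polymorphism posterior.  `INFO` carries
#' `TSTV` (ts|tv), `CLASS` (the per-sample M/P/N code in panel order),
#' `FLANK` (minimum distance to a contig end), `ISO` (distance to the nearest
#' other candidate) and `DP`; the per-sample `FORMAT` field emits `DP`.
#'
#' @param snps the `snps` [GenomicRanges::GRanges] from [callSnps()].
#' @param contigs a named [Biostrings::DNAStringSet]; an SNP position outside
#'   its contig is an error.
#' @param panel a [GenotypePanel].
#' @param path output path.
#' @param pileups optional named list of [ContigPileup] supplying per-sample
#'   depths; without it sample depths are emitted as missing.
#' @return Invisibly, `path`.
#' @export
writeSnpVcf <- function(snps, contigs, panel, path, pileups = NULL) {
    samples <- panelSamples(panel)
    lines <- c("##fileformat=VCFv4.2",
               "##source=estpoly",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       Biostrings::width(contigs)),
               "##INFO=<ID=TSTV,Number=1,Type=String,Description=\"Transition (ts) or transversion (tv)\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Per-sample M/P/N status code in panel order\">",
               "##INFO=<ID=FLANK,Number=1,Type=Integer,Description=\"Distance in nt to the nearest contig end\">",
               "##INFO=<ID=ISO,Number=1,Type=Integer,Description=\"Distance in nt to the nearest other candidate\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth across samples\">",
               "##INFO=<ID=DEEP,Number=0,Type=Flag,Description=\"Total depth >= 20\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Per-sample read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"))
    if (length(snps)) {
        ctg <- as.character(seqnames(snps))
        bad <- !ctg %in% names(contigs)
        if (any(bad))
            stop("SNP on unknown contig: ", paste(unique(ctg[bad]), collapse = ","))
        if (any(start(snps) < 1L |
                start(snps) > Biostrings::width(contigs)[match(ctg, names(contigs))]))
            stop("SNP position outside contig bounds")
        m <- mcols(snps)
        qual <- round(-10 * log10(pmax(1 - m$quality, 1e-12)), 1L)
        info <- sprintf("TSTV=%s;CLASS=%s;FLANK=%d;ISO=%d;DP=%d%s",
                        m$tstv, m$classCode, m$flank, m$isolation,
                        m$depthTotal, ifelse(m$deepCovered, ";DEEP", ""))
        fmt <- vapply(seq_along(snps), function(i) {
            if (is.null(pileups) || is.null(pileups[[ctg[i]]]))
                return(paste(rep(".", length(samples)), collapse = "\t"))
            cnt <- pileupCounts(pileups[[ctg[i]]])
            paste(colSums(cnt[, start(snps)[i], , drop = FALSE]),
                  collapse = "\t")
        }, character(1L))
        lines <- c(lines,
                   paste(ctg, start(snps), ".", m$refAllele, m$altAllele,
                         qual, "PASS", info, "DP", fmt, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write SSR loci as GFF3
#'
#' 1-based inclusive coordinates, feature type `microsatellite`, attributes
#' `motif`, `repeats` (omitted for compound loci), `ssr_class`
#' (perfect|compound) and, for compound loci, the ordered `components`
#' (`motif x repeats` joined by commas).  An empty collection yields a valid
#' header-only file.
#'
#' @param ssrs a [GenomicRanges::GRanges] from [findPerfectSsrs()] or
#'   [mergeCompound()].
#' @param contigs a named [Biostrings::DNAStringSet]; a locus outside its
#'   contig is an error.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSsrGff3 <- function(ssrs, contigs, path) {
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", names(contigs),
                       Biostrings::width(contigs)))
    if (length(ssrs)) {
        ctg <- as.character(seqnames(ssrs))
        bad <- !ctg %in% names(contigs)
        if (any(bad))
            stop("SSR locus on unknown contig: ",
                 paste(unique(ctg[bad]), collapse = ","))
        if (any(start(ssrs) < 1L |
                end(ssrs) > Biostrings::width(contigs)[match(ctg, names(contigs))]))
            stop("SSR locus outside contig bounds")
        m <- mcols(ssrs)
        hasComp <- !is.null(m$componentMotif)
        attrs <- vapply(seq_along(ssrs), function(i) {
            a <- sprintf("ID=ssr%d;motif=%s;ssr_class=%s", i, m$motif[i],
                         m$ssrClass[i])
            if (m$ssrClass[i] == "perfect")
                a <- paste0(a, sprintf(";repeats=%d", m$repeats[i]))
            if (hasComp && m$ssrClass[i] == "compound") {
                comp <- paste(m$componentMotif[[i]], m$componentRepeats[[i]],
                              sep = "x", collapse = ",")
                a <- paste0(a, ";components=", comp)
            }
            a
        }, character(1L))
        lines <- c(lines,
                   paste(ctg, "estpoly", "microsatellite", start(ssrs),
                         end(ssrs), ".", "+", ".", attrs, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write an SSR TSV report
#'
#' @param ssrs a [GenomicRanges::GRanges] of SSR loci.
#' @param path output path.
#' @return Invisibly, the written `data.frame`.
#' @export
writeSsrTsv <- function(ssrs, path) {
    m <- mcols(ssrs)
    d <- data.frame(contig = as.character(seqnames(ssrs)),
                    start = start(ssrs), end = end(ssrs),
                    length = width(ssrs),
                    motif = if (length(ssrs)) m$motif else character(),
                    repeats = if (length(ssrs)) m$repeats else integer(),
                    ssr_class = if (length(ssrs)) m$ssrClass else character(),
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(d)
}
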