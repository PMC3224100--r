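## Pipeline wiring: run the stages in dependency order from a run
## configuration, write reports with provenance headers, and assemble the
## combined marker-panel export.

.provenanceHeader <- function(params = list(), inputs = character()) {
    ver <- as.character(utils::packageVersion("estpoly"))
    h <- c(sprintf("# estpoly %s", ver))
    if (length(params))
        h <- c(h, paste0("# params: ",
                         paste(names(params), unlist(params), sep = "=",
                               collapse = " ")))
    for (f in inputs[file.exists(inputs)])
        h <- c(h, sprintf("# input: %s md5=%s", basename(f),
                          unname(tools::md5sum(f))))
    h
}

.writeReport <- function(lines, path) {
    tmp <- paste0(path, ".tmp")
    writeLines(lines, tmp)
    file.rename(tmp, path)
    invisible(path)
}

#' Combined candidate-marker panel report
#'
#' One row per candidate marker (SNP, SSR or polymorphic SSR) with flanking
#' sequences of up to `flankLen` nt on each side for downstream primer
#' design.  Rows are sorted by contig and position; per-type counts go into a
#' comment footer.
#'
#' @param snps the `snps` [GenomicRanges::GRanges] from [callSnps()] (may be
#'   empty).
#' @param ssrs a [GenomicRanges::GRanges] of SSR loci (may be empty).
#' @param polyssrs a `data.frame` from [polymorphicSsrReport()] (may be
#'   empty / `NULL`).
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param flankLen maximum flank length in nt (default 100, matching the SNP
#'   minimum-flank filter so exported SNPs always carry full flanks).
#' @param path optional output path (TSV with a count footer).
#' @return A `data.frame` with columns `type`, `contig`, `start`, `end`,
#'   `detail`, `left_flank`, `right_flank`.
#' @export
reportMarkerPanel <- function(snps, ssrs, polyssrs, contigs, flankLen = 100L,
                              path = NULL) {
    rows <- list()
    flankOf <- function(ctg, s, e) {
        L <- Biostrings::width(contigs[ctg])
        seq <- as.character(contigs[[ctg]])
        left <- substr(seq, max(1L, s - flankLen), s - 1L)
        right <- substr(seq, e + 1L, min(L, e + flankLen))
        c(left, right)
    }
    if (length(snps)) {
        for (i in seq_along(snps)) {
            ctg <- as.character(seqnames(snps))[i]
            p <- start(snps)[i]
            fl <- flankOf(ctg, p, p)
            rows[[length(rows) + 1L]] <- data.frame(
                type = "snp", contig = ctg, start = p, end = p,
                detail = sprintf("%s>%s;%s", mcols(snps)$refAllele[i],
                                 mcols(snps)$altAllele[i],
                                 mcols(snps)$classCode[i]),
                left_flank = fl[1L], right_flank = fl[2L],
                stringsAsFactors = FALSE)
        }
    }
    if (length(ssrs)) {
        for (i in seq_along(ssrs)) {
            ctg <- as.character(seqnames(ssrs))[i]
            fl <- flankOf(ctg, start(ssrs)[i], end(ssrs)[i])
            rows[[length(rows) + 1L]] <- data.frame(
                type = "ssr", contig = ctg, start = start(ssrs)[i],
                end = end(ssrs)[i],
                detail = sprintf("%s;%s", mcols(ssrs)$motif[i],
                                 mcols(ssrs)$ssrClass[i]),
                left_flank = fl[1L], right_flank = fl[2L],
                stringsAsFactors = FALSE)
        }
    }
    nPoly <- 0L
    if (!is.null(polyssrs) && nrow(polyssrs)) {
        nPoly <- nrow(polyssrs)
        for (i in seq_len(nrow(polyssrs))) {
            ctg <- polyssrs$contig[i]
            s <- polyssrs$indel_start[i]
            e <- s + polyssrs$indel_length[i] - 1L
            fl <- flankOf(ctg, s, e)
            rows[[length(rows) + 1L]] <- data.frame(
                type = "polyssr", contig = ctg, start = s, end = e,
                detail = sprintf("%s;diff=%d", polyssrs$motif[i],
                                 polyssrs$allele_diff[i]),
                left_flank = fl[1L], right_flank = fl[2L],
                stringsAsFactors = FALSE)
        }
    }
    d <- if (length(rows)) do.call(rbind, rows) else
        data.frame(type = character(), contig = character(),
                   start = integer(), end = integer(), detail = character(),
                   left_flank = character(), right_flank = character(),
                   stringsAsFactors = FALSE)
    if (nrow(d)) d <- d[order(d$contig, d$start), , drop = FALSE]
    rownames(d) <- NULL
    if (!is.null(path)) {
        body <- c(paste(colnames(d), collapse = "\t"),
                  if (nrow(d)) do.call(paste,
                      c(as.list(d), sep = "\t")),
                  sprintf("# n_snp=%d n_ssr=%d n_polyssr=%d",
                          sum(d$type == "snp"), sum(d$type == "ssr"), nPoly))
        .writeReport(body, path)
    }
    d
}

#' Run the marker-discovery pipeline
#'
#' Wires the stages in dependency order from a run configuration: read
#' contigs and panel, mine and merge SSRs (GFF3 + TSV), build pileups (TSV
#' dialect or SAM) and call SNPs (VCF + summary TSV), detect indels in the
#' per-contig gapped alignments and report candidate polymorphic SSRs, and
#' write the combined marker panel.  Every TSV report carries a provenance
#' header (tool version, parameters, input checksums).  On any stage error no
#' partial outputs are left behind (reports are written atomically) and the
#' error propagates.
#'
#' @param config a list (or path to a YAML file) with entries: `fasta`
#'   (required), `panel` (path or [GenotypePanel]), `pileup_tsv` or `sam`
#'   (optional), `alignments` (optional directory of `*.aln.fa`), `outdir`
#'   (required), `rules` (optional [SsrRules]), `params` (optional
#'   [SnpFilterParams]), `min_base_quality` (for SAM ingestion).
#' @return Invisibly, a named list of output paths and the in-memory results
#'   (`ssrs`, `snps`, `polyssrs`, `summary`).
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    if (is.null(config$fasta) || is.null(config$outdir))
        stop("config needs 'fasta' and 'outdir'")
    if (!file.exists(config$fasta))
        stop("missing input: ", config$fasta)
    outdir <- config$outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    rules <- config$rules %||% SsrRules()
    params <- config$params %||% SnpFilterParams()
    contigs <- readContigs(config$fasta)
    panel <- if (is(config$panel, "GenotypePanel")) config$panel
             else if (!is.null(config$panel)) readPanelConfig(config$panel)
             else NULL
    outputs <- list()
    ## SSR stage
    perfect <- findPerfectSsrs(contigs, rules)
    ssrs <- mergeCompound(perfect, rules)
    outputs$ssr_gff3 <- file.path(outdir, "ssrs.gff3")
    writeSsrGff3(ssrs, contigs, outputs$ssr_gff3)
    outputs$ssr_tsv <- file.path(outdir, "ssrs.tsv")
    hdr <- .provenanceHeader(list(compound_max_gap = rules@compoundMaxGap),
                             config$fasta)
    tmp <- tempfile()
    writeSsrTsv(ssrs, tmp)
    .writeReport(c(hdr, readLines(tmp)), outputs$ssr_tsv)
    ## SNP stage
    snps <- NULL
    pileups <- NULL
    if (!is.null(panel) &&
        (!is.null(config$pileup_tsv) || !is.null(config$sam))) {
        pileups <- if (!is.null(config$pileup_tsv))
            readPileupTsv(config$pileup_tsv, panel, contigs)
        else buildPileupFromSam(config$sam, panel, contigs,
                                config$min_base_quality %||% 20L)
        res <- callSnps(pileups, contigs, panel, params)
        snps <- res$snps
        outputs$vcf <- file.path(outdir, "snps.vcf")
        writeSnpVcf(snps, contigs, panel, outputs$vcf, pileups)
        summ <- snpSummaries(snps, contigs, panel)
        outputs$snp_summary <- file.path(outdir, "snp_summary.tsv")
        .writeReport(c(.provenanceHeader(list(min_quality = params@minQuality,
                                              min_isolation = params@minIsolation),
                                         config$fasta),
                       sprintf("n_snps\t%d", summ$nSnps),
                       sprintf("n_contigs_with_snps\t%d", summ$nContigsWithSnps),
                       sprintf("mean_snps_per_contig\t%.3f",
                               summ$meanSnpsPerContig),
                       sprintf("density_per_kb\t%.3f", summ$densityPerKb),
                       sprintf("ts_count\t%d", summ$tsCount),
                       sprintf("tv_count\t%d", summ$tvCount)),
                     outputs$snp_summary)
    }
    ## indel / polymorphic SSR stage
    polyssrs <- NULL
    if (!is.null(config$alignments)) {
        files <- list.files(config$alignments, pattern = "\\.aln\\.fa$",
                            full.names = TRUE)
        tabs <- list()
        for (f in files) {
            aln <- readGappedFasta(f, contig = sub("\\.aln\\.fa$", "",
                                                   basename(f)))
            ind <- detectIndels(aln)
            ctgSsrs <- ssrs[as.character(seqnames(ssrs)) ==
                            alignmentContig(aln)]
            ind <- annotateSsrOverlap(ind, ctgSsrs)
            t <- polymorphicSsrReport(ind, aln)
            if (nrow(t)) tabs[[length(tabs) + 1L]] <- t
        }
        polyssrs <- if (length(tabs)) do.call(rbind, tabs) else
            data.frame(contig = character(), indel_start = integer(),
                       indel_length = integer(), motif = character(),
                       allele_diff = integer())
        outputs$polyssr_tsv <- file.path(outdir, "polymorphic_ssrs.tsv")
        tmp <- tempfile()
        utils::write.table(polyssrs, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .writeReport(c(.provenanceHeader(inputs = config$fasta),
                       readLines(tmp)), outputs$polyssr_tsv)
    }
    ## combined marker panel
    outputs$markers_tsv <- file.path(outdir, "marker_panel.tsv")
    reportMarkerPanel(snps %||% GRanges(), ssrs, polyssrs, contigs,
                      path = outputs$markers_tsv)
    invisible(c(outputs, list(ssrs = ssrs, snps = snps, polyssrs = polyssrs)))
}
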