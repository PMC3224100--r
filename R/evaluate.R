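## Truth-closure evaluation: compare detector output against a simulation's
## planted truth sets.

#' Evaluate called SNPs against planted truth
#'
#' For every planted SNP the filter cascade is re-evaluated on the
#' truth-known alleles and the realized pileup counts: pooled coverage of the
#' two planted alleles, average coverage, flank, the polymorphism posterior
#' and the inter-sample contrast.  A planted site is *eligible* when all of
#' them pass -- i.e. when the realized data carry the evidence the filters
#' demand.  Recall over the eligible set isolates caller correctness from
#' sampling noise: a pool-only heterozygous site at high pooled depth can
#' legitimately fall below the balanced-biallelic posterior cutoff when its
#' realized minor count fluctuates low, and such sites are counted in
#' `recallAll` but not held against the caller.
#'
#' @param sim the result of [simulatePanel()].
#' @param pileups the pileups from [simulatePileup()].
#' @param snps the emitted `snps` [GenomicRanges::GRanges] from [callSnps()].
#' @param params the [SnpFilterParams] used for calling.
#' @return A list: `nTruth`, `nEligible`, `nCalled`, `truePositives`,
#'   `recallEligible`, `recallAll`, `precision`,
#'   `falsePositivesHighQuality` (emitted SNPs at unplanted sites with
#'   posterior >= 0.999), and the per-site `table` with the recomputed
#'   filter quantities and flags.
#' @export
evaluateSnpCalls <- function(sim, pileups, snps, params = SnpFilterParams()) {
    truth <- sim$truth$snps
    samples <- panelSamples(sim$panel)
    nS <- length(samples)
    calledKey <- paste(as.character(seqnames(snps)), start(snps))
    rows <- lapply(seq_len(nrow(truth)), function(i) {
        ctg <- truth$contig[i]
        p <- truth$pos[i]
        cnt <- pileupCounts(pileups[[ctg]])
        col <- cnt[, p, , drop = TRUE]
        if (is.null(dim(col))) col <- matrix(col, nrow = 4L)
        rownames(col) <- DNA_BASES4
        colnames(col) <- samples
        pooled <- rowSums(col)
        cRef <- pooled[truth$ref[i]]
        cAlt <- pooled[truth$alt[i]]
        major <- if (cRef >= cAlt) truth$ref[i] else truth$alt[i]
        minor <- if (cRef >= cAlt) truth$alt[i] else truth$ref[i]
        nMaj <- max(cRef, cAlt)
        nMin <- min(cRef, cAlt)
        L <- Biostrings::width(sim$contigs[ctg])
        flank <- min(p - 1L, L - p)
        qual <- if (nMaj + nMin > 0)
            polymorphismQuality(nMaj, nMin, params@errorRate) else 0
        st <- sampleStatus(col, major, minor, params)
        isM <- st$status == "M"
        contrast <- any(st$status == "P") ||
            (sum(isM) >= 2L && length(unique(st$majorAllele[isM])) >= 2L)
        eligible <- nMaj >= params@minMajorCov &&
            nMin >= params@minMinorCov &&
            sum(pooled) / nS >= params@minAvgCov &&
            flank >= params@minFlank &&
            qual >= params@minQuality && contrast
        data.frame(contig = ctg, pos = p, majorCount = nMaj,
                   minorCount = nMin, depthTotal = sum(pooled),
                   flank = flank, quality = qual, contrast = contrast,
                   eligible = eligible,
                   called = paste(ctg, p) %in% calledKey,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    truthKey <- paste(tab$contig, tab$pos)
    tp <- sum(calledKey %in% truthKey)
    fpIdx <- !calledKey %in% truthKey
    fpHigh <- if (length(snps)) sum(fpIdx & mcols(snps)$quality >= 0.999)
              else 0L
    list(nTruth = nrow(tab),
         nEligible = sum(tab$eligible),
         nCalled = length(snps),
         truePositives = tp,
         recallEligible = if (sum(tab$eligible))
             sum(tab$called & tab$eligible) / sum(tab$eligible) else NA_real_,
         recallAll = if (nrow(tab)) mean(tab$called) else NA_real_,
         precision = if (length(snps)) tp / length(snps) else NA_real_,
         falsePositivesHighQuality = fpHigh,
         table = tab)
}

#' Evaluate SSR and indel recovery against planted truth
#'
#' SSR recovery requires an exact match of span, motif and repeat count in
#' the perfect-locus scan.  Indel recovery requires an emitted candidate with
#' the planted reference start and length; planted indels violating the size
#' bounds must be absent.
#'
#' @param sim the result of [simulatePanel()].
#' @param ssrsFound a [GenomicRanges::GRanges] from [findPerfectSsrs()] over
#'   `sim$contigs`.
#' @param indelsFound a named list (by contig) of [detectIndels()] results
#'   over `sim$alignments`.
#' @param minLen,maxLen the indel detector bounds used.
#' @return A list: `ssrRecall`, `nSsrTruth`, `indelRecallInBounds`,
#'   `nIndelInBounds`, `outOfBoundsEmitted`, `nIndelOutOfBounds`.
#' @export
evaluateRecovery <- function(sim, ssrsFound, indelsFound,
                             minLen = 3L, maxLen = 50L) {
    truthSsr <- sim$truth$ssrs
    key <- function(g) paste(as.character(seqnames(g)), start(g), end(g),
                             mcols(g)$motif, mcols(g)$repeats)
    ssrRecall <- if (length(truthSsr))
        mean(key(truthSsr) %in% key(ssrsFound)) else NA_real_
    it <- sim$truth$indels
    inB <- it[it$length >= minLen & it$length <= maxLen, , drop = FALSE]
    oob <- it[it$length < minLen | it$length > maxLen, , drop = FALSE]
    hit <- function(r, d) {
        g <- indelsFound[[d$contig[r]]]
        !is.null(g) && length(g) > 0L &&
            any(start(g) == d$start[r] &
                mcols(g)$indelLength == d$length[r])
    }
    nHit <- sum(vapply(seq_len(nrow(inB)), hit, logical(1L), d = inB))
    nBad <- sum(vapply(seq_len(nrow(oob)), function(r) {
        g <- indelsFound[[oob$contig[r]]]
        !is.null(g) && length(g) > 0L && any(start(g) == oob$start[r])
    }, logical(1L)))
    list(ssrRecall = ssrRecall, nSsrTruth = length(truthSsr),
         indelRecallInBounds = if (nrow(inB)) nHit / nrow(inB) else NA_real_,
         nIndelInBounds = nrow(inB),
         outOfBoundsEmitted = nBad, nIndelOutOfBounds = nrow(oob))
}
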