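## Multi-sample SNP calling from genotype-partitioned pileups:
## site allele determination, Bayesian polymorphism quality, per-sample
## M/P/N status, the filter cascade, symmetric isolation, and summaries.

#' Pooled allele counts and top-two alleles at a site
#'
#' Pools base counts across samples and ranks alleles by pooled count, ties
#' broken alphabetically.  Third and fourth alleles stay in the depth but are
#' never promoted to site alleles.
#'
#' @param col a [ContigPileup] column: either a 4 x nSamples matrix of counts
#'   (rows A,C,G,T) or a named length-4 pooled count vector.
#' @return A list with `pooled` (named counts), `major`, `minor` (base or
#'   `NA` when the site is monomorphic) and `depthTotal`.
#' @examples
#' siteAlleleCounts(c(A = 15, C = 1, G = 12, T = 0))
#' @export
siteAlleleCounts <- function(col) {
    pooled <- if (is.matrix(col)) rowSums(col) else col
    if (length(pooled) != 4L)
        stop("expected counts for the four bases A,C,G,T")
    names(pooled) <- DNA_BASES4
    if (sum(pooled) == 0)
        stop("all-zero pileup column")
    ord <- order(-pooled, DNA_BASES4)    # alphabetical tie-break
    major <- DNA_BASES4[ord[1L]]
    minor <- if (pooled[ord[2L]] > 0) DNA_BASES4[ord[2L]] else NA_character_
    list(pooled = pooled, major = major, minor = minor,
         depthTotal = sum(pooled))
}

#' Posterior probability that a site is polymorphic
#'
#' Two-hypothesis Bayesian model on the pooled counts of the top-two alleles.
#' Under H0 (monomorphic) every read is the major allele with probability
#' `1 - e` and a specific other base with probability `e/3`.  Under H1
#' (balanced biallelic) each read is major or minor with equal probability
#' `(1 - e)/2 + e/6` (an error-perturbed 50/50).  With equal priors the
#' posterior of H1 is returned; it is monotone non-decreasing in the minor
#' count at fixed depth.
#'
#' @param nMajor,nMinor pooled read counts of the two site alleles
#'   (vectorised; `nMajor + nMinor` must be positive).
#' @param errorRate per-base sequencing error rate `e`.
#' @return Posterior probability of polymorphism in `[0, 1]`.
#' @examples
#' polymorphismQuality(15, 12)   # convincingly biallelic
#' polymorphismQuality(20, 0)    # no evidence of polymorphism
#' @export
polymorphismQuality <- function(nMajor, nMinor, errorRate = 0.01) {
    if (any(nMajor + nMinor <= 0))
        stop("total allele count must be positive")
    if (errorRate <= 0 || errorRate >= 1)
        stop("errorRate must lie in (0,1)")
    logL0 <- nMajor * log(1 - errorRate) + nMinor * log(errorRate / 3)
    p1 <- (1 - errorRate) / 2 + errorRate / 6
    logL1 <- (nMajor + nMinor) * log(p1)
    1 / (1 + exp(logL0 - logL1))
}

#' Per-sample intra-sample polymorphism status
#'
#' For each panel sample at a site with determined alleles: `N` when the
#' sample's depth (all four bases) is below `minSampleDepth`; `P` when the
#' sample's second-ranked site allele reaches both `withinMinorCount` reads
#' and `withinMinorFrac` of the sample depth; otherwise `M` with the sample's
#' majority site allele (ties broken alphabetically).
#'
#' @param counts a 4 x nSamples count matrix (rows A,C,G,T, columns in panel
#'   order).
#' @param major,minor the site alleles from [siteAlleleCounts()] (`minor` may
#'   be `NA`).
#' @param params a [SnpFilterParams].
#' @return A `data.frame` with columns `sample` (if column names present),
#'   `status` (`M`/`P`/`N`), `majorAllele` and `depth`.
#' @export
sampleStatus <- function(counts, major, minor, params = SnpFilterParams()) {
    stopifnot(is.matrix(counts), nrow(counts) == 4L)
    nS <- ncol(counts)
    depth <- colSums(counts)
    iMaj <- match(major, DNA_BASES4)
    cMaj <- counts[iMaj, ]
    if (is.na(minor)) {
        cMin <- rep(0L, nS)
        iMin <- NA_integer_
    } else {
        iMin <- match(minor, DNA_BASES4)
        cMin <- counts[iMin, ]
    }
    second <- pmin(cMaj, cMin)
    status <- ifelse(depth < params@minSampleDepth, "N",
              ifelse(second >= params@withinMinorCount &
                     second >= params@withinMinorFrac * depth, "P", "M"))
    majAllele <- ifelse(cMaj > cMin, major,
                 ifelse(cMin > cMaj, minor,
                        DNA_BASES4[pmin(iMaj, if (is.na(iMin)) iMaj else iMin)]))
    data.frame(sample = colnames(counts) %||% paste0("s", seq_len(nS)),
               status = status, majorAllele = majAllele,
               depth = as.integer(depth), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transition or transversion
#'
#' @param a,b two distinct bases (vectorised); symmetric in its arguments.
#' @return `"ts"` for A/G or C/T, `"tv"` for the other four unordered pairs.
#' @examples
#' tsTv("A", "G")  # "ts"
#' tsTv("A", "T")  # "tv"
#' @export
tsTv <- function(a, b) {
    if (any(a == b))
        stop("tsTv needs two distinct bases")
    if (any(!a %in% DNA_BASES4) || any(!b %in% DNA_BASES4))
        stop("bases must be one of A,C,G,T")
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    unname(ifelse(purine[a] == purine[b], "ts", "tv"))
}

#' Concatenate per-sample statuses into a class code
#'
#' @param statuses character vector of `M`/`P`/`N`, one per panel sample, in
#'   panel order.
#' @param panel a [GenotypePanel]; a length mismatch is an error.
#' @return The class code string, e.g. `"PMM"`.
#' @export
classifyCode <- function(statuses, panel) {
    if (length(statuses) != length(panelSamples(panel)))
        stop("one status per panel sample required (got ", length(statuses),
             " for a panel of ", length(panelSamples(panel)), ")")
    if (any(!statuses %in% c("M", "P", "N")))
        stop("statuses must be M, P or N")
    paste(statuses, collapse = "")
}

## Build the full candidate table for one contig: every position where at
## least two bases are observed in the pooled counts.
.contigCandidates <- function(pileup, params) {
    cnt <- pileup@counts
    L <- pileup@contigLength
    nS <- length(pileup@samples)
    pooled <- rowSums(cnt, dims = 2L)
    if (nS == 1L) pooled <- cnt[, , 1L]
    cand <- which(colSums(pooled > 0L) >= 2L)
    if (!length(cand))
        return(NULL)
    P <- pooled[, cand, drop = FALSE]
    M <- length(cand)
    majIdx <- max.col(t(P), ties.method = "first")
    cMaj <- P[cbind(majIdx, seq_len(M))]
    P2 <- P
    P2[cbind(majIdx, seq_len(M))] <- -1L
    minIdx <- max.col(t(P2), ties.method = "first")
    cMin <- P[cbind(minIdx, seq_len(M))]
    depthTotal <- colSums(P)
    pos <- cand
    quality <- polymorphismQuality(cMaj, cMin, params@errorRate)
    flank <- pmin(pos - 1L, L - pos)
    status <- matrix("", nrow = M, ncol = nS)
    smpMajor <- matrix("", nrow = M, ncol = nS)
    for (s in seq_len(nS)) {
        csMaj <- cnt[cbind(majIdx, pos, s)]
        csMin <- cnt[cbind(minIdx, pos, s)]
        sDepth <- colSums(cnt[, pos, s, drop = FALSE])
        dim(sDepth) <- NULL
        second <- pmin(csMaj, csMin)
        status[, s] <- ifelse(sDepth < params@minSampleDepth, "N",
                       ifelse(second >= params@withinMinorCount &
                              second >= params@withinMinorFrac * sDepth,
                              "P", "M"))
        smpMajor[, s] <- ifelse(csMaj > csMin, DNA_BASES4[majIdx],
                         ifelse(csMin > csMaj, DNA_BASES4[minIdx],
                                DNA_BASES4[pmin(majIdx, minIdx)]))
    }
    anyP <- rowSums(status == "P") >= 1L
    mContrast <- vapply(seq_len(M), function(i) {
        isM <- status[i, ] == "M"
        sum(isM) >= 2L && length(unique(smpMajor[i, isM])) >= 2L
    }, logical(1L))
    data.frame(contig = pileup@contig, pos = pos, contigLength = L,
               majorAllele = DNA_BASES4[majIdx],
               minorAllele = DNA_BASES4[minIdx],
               majorCount = cMaj, minorCount = cMin,
               depthTotal = depthTotal, quality = quality, flank = flank,
               classCode = apply(status, 1L, paste, collapse = ""),
               interContrast = anyP | mContrast,
               stringsAsFactors = FALSE)
}

#' Apply the SNP filter cascade
#'
#' A candidate passes when pooled major and minor coverage, average coverage
#' (total depth / panel size), flanking length, posterior quality and the
#' inter-sample polymorphism requirement (at least one P sample, or at least
#' two M samples with differing major alleles) all hold.  Isolation is applied
#' separately by [isolationFilter()].  `filtersFailed` records every violated
#' rule.
#'
#' @param cand candidate `data.frame` as built by [callSnps()] (columns
#'   `majorCount`, `minorCount`, `depthTotal`, `flank`, `quality`,
#'   `interContrast`).
#' @param nSamples panel size, the denominator of average coverage.
#' @param params a [SnpFilterParams].
#' @return `cand` with added `filtersFailed` (list column) and `pass`
#'   (logical).
#' @export
applyFilters <- function(cand, nSamples, params = SnpFilterParams()) {
    fails <- Map(function(maj, min_, dt, fl, q, ic) {
        f <- character()
        if (maj < params@minMajorCov) f <- c(f, "major_cov")
        if (min_ < params@minMinorCov) f <- c(f, "minor_cov")
        if (dt / nSamples < params@minAvgCov) f <- c(f, "avg_cov")
        if (fl < params@minFlank) f <- c(f, "flank")
        if (q < params@minQuality) f <- c(f, "quality")
        if (!ic) f <- c(f, "no_inter_sample_polymorphism")
        f
    }, cand$majorCount, cand$minorCount, cand$depthTotal, cand$flank,
       cand$quality, cand$interContrast)
    cand$filtersFailed <- unname(fails)
    cand$pass <- lengths(fails) == 0L
    cand
}

#' Symmetric isolation filter
#'
#' Any two candidates on the same contig closer than `minIsolation` nt remove
#' each other; the surviving set has all pairwise distances at least
#' `minIsolation` (boundary inclusive: a pair exactly `minIsolation` apart is
#' kept).  The reported isolation is the distance to the nearest other
#' pre-filter candidate; a lone candidate gets its contig length as a bounded
#' sentinel.
#'
#' @param cand candidate `data.frame` with columns `contig`, `pos`,
#'   `contigLength`.
#' @param minIsolation minimum pairwise distance in nt.
#' @return `cand` with added `isolation` (integer) and `isolated` (logical).
#' @export
isolationFilter <- function(cand, minIsolation = 30L) {
    cand$isolation <- rep(NA_integer_, nrow(cand))
    cand$isolated <- rep(TRUE, nrow(cand))
    for (ctg in unique(cand$contig)) {
        idx <- which(cand$contig == ctg)
        p <- cand$pos[idx]
        o <- order(p)
        p <- p[o]
        n <- length(p)
        if (n == 1L) {
            cand$isolation[idx] <- cand$contigLength[idx]
            next
        }
        gapL <- c(NA_integer_, diff(p))
        gapR <- c(diff(p), NA_integer_)
        nearest <- pmin(gapL, gapR, na.rm = TRUE)
        cand$isolation[idx[o]] <- nearest
        cand$isolated[idx[o]] <- nearest >= minIsolation
    }
    cand
}

#' Call SNPs from genotype-partitioned pileups
#'
#' The full cascade: candidate sites are every pileup position with at least
#' two observed pooled bases; site alleles are the pooled top two (ties
#' alphabetical); each candidate gets a Bayesian polymorphism posterior, a
#' flank, per-sample M/P/N statuses and a class code; [applyFilters()] and the
#' symmetric [isolationFilter()] (computed over candidates passing the
#' allele-coverage filters, before the quality cut) yield the final set.
#'
#' @param pileups a named list of [ContigPileup] (one per contig), with sample
#'   order equal to the panel order.
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param panel a [GenotypePanel].
#' @param params a [SnpFilterParams].
#' @return A list with `snps` -- a [GenomicRanges::GRanges] of emitted SNPs
#'   (metadata: `refAllele` = pooled major, `altAllele`, `majorCount`,
#'   `minorCount`, `depthTotal`, `quality`, `flank`, `isolation`, `tstv`,
#'   `classCode`, `deepCovered` flagging sites with total depth >= 20) -- and
#'   `candidates`, the full annotated candidate `data.frame`.
#' @export
callSnps <- function(pileups, contigs, panel, params = SnpFilterParams()) {
    samples <- panelSamples(panel)
    tabs <- list()
    for (pu in pileups) {
        if (!identical(pu@samples, samples))
            stop("pileup sample order must match the panel")
        t <- .contigCandidates(pu, params)
        if (!is.null(t)) tabs[[length(tabs) + 1L]] <- t
    }
    empty <- {
        gr <- GRanges()
        mcols(gr) <- DataFrame(refAllele = character(),
                               altAllele = character(),
                               majorCount = integer(), minorCount = integer(),
                               depthTotal = integer(), quality = numeric(),
                               flank = integer(), isolation = integer(),
                               tstv = character(), classCode = character(),
                               deepCovered = logical())
        gr
    }
    if (!length(tabs))
        return(list(snps = empty,
                    candidates = data.frame()))
    cand <- do.call(rbind, tabs)
    cand <- applyFilters(cand, length(samples), params)
    ## isolation over the allele-coverage-passing set (pre-quality)
    isoSet <- cand$majorCount >= params@minMajorCov &
              cand$minorCount >= params@minMinorCov
    iso <- isolationFilter(cand[isoSet, , drop = FALSE], params@minIsolation)
    cand$isolation <- rep(NA_integer_, nrow(cand))
    cand$isolated <- rep(NA, nrow(cand))
    cand$isolation[isoSet] <- iso$isolation
    cand$isolated[isoSet] <- iso$isolated
    final <- cand[cand$pass & isoSet & cand$isolated %in% TRUE, , drop = FALSE]
    if (!nrow(final))
        return(list(snps = empty, candidates = cand))
    gr <- GRanges(final$contig, IRanges(final$pos, final$pos))
    mcols(gr) <- DataFrame(
        refAllele = final$majorAllele, altAllele = final$minorAllele,
        majorCount = final$majorCount, minorCount = final$minorCount,
        depthTotal = as.integer(final$depthTotal), quality = final$quality,
        flank = final$flank, isolation = final$isolation,
        tstv = tsTv(final$majorAllele, final$minorAllele),
        classCode = final$classCode,
        deepCovered = final$depthTotal >= 20L)
    o <- order(as.character(seqnames(gr)), start(gr))
    list(snps = gr[o], candidates = cand)
}

#' Summaries of a called SNP set
#'
#' @param snps the `snps` [GenomicRanges::GRanges] from [callSnps()].
#' @param contigs a named [Biostrings::DNAStringSet] (for contig lengths).
#' @param panel a [GenotypePanel] (for the per-sample rollup).
#' @return A list: `nSnps`; `nContigsWithSnps`; `meanSnpsPerContig`;
#'   `densityPerKb` (SNPs per kb of SNP-bearing contig length); `tsCount`,
#'   `tvCount`, `tsPercent`; `classHist` (class-code table); `perContig`
#'   counts; and `perSampleRollup`, bucketing each SNP-bearing contig per
#'   sample into `M`-only, `P`-only, `M+P` or `none` (no called status).
#' @export
snpSummaries <- function(snps, contigs, panel) {
    samples <- panelSamples(panel)
    if (length(snps) == 0L) {
        roll <- matrix(0L, nrow = length(samples), ncol = 4L,
                       dimnames = list(samples, c("M", "P", "M+P", "none")))
        return(list(nSnps = 0L, nContigsWithSnps = 0L,
                    meanSnpsPerContig = 0, densityPerKb = 0,
                    tsCount = 0L, tvCount = 0L, tsPercent = NA_real_,
                    classHist = table(character()),
                    perContig = table(character()),
                    perSampleRollup = roll))
    }
    ctg <- as.character(seqnames(snps))
    perContig <- table(ctg)
    bearing <- names(perContig)
    totalKb <- sum(Biostrings::width(contigs[bearing])) / 1000
    tst <- mcols(snps)$tstv
    codes <- mcols(snps)$classCode
    roll <- matrix(0L, nrow = length(samples), ncol = 4L,
                   dimnames = list(samples, c("M", "P", "M+P", "none")))
    codeMat <- do.call(rbind, strsplit(codes, "", fixed = TRUE))
    for (s in seq_along(samples)) {
        st <- split(codeMat[, s], ctg)
        bucket <- vapply(st, function(v) {
            hasM <- any(v == "M"); hasP <- any(v == "P")
            if (hasM && hasP) "M+P" else if (hasP) "P"
            else if (hasM) "M" else "none"
        }, character(1L))
        t <- table(factor(bucket, levels = colnames(roll)))
        roll[s, ] <- as.integer(t)
    }
    list(nSnps = length(snps),
         nContigsWithSnps = length(bearing),
         meanSnpsPerContig = length(snps) / length(bearing),
         densityPerKb = length(snps) / totalKb,
         tsCount = sum(tst == "ts"), tvCount = sum(tst == "tv"),
         tsPercent = 100 * sum(tst == "ts") / length(snps),
         classHist = sort(table(codes), decreasing = TRUE),
         perContig = perContig,
         perSampleRollup = roll)
}

#' Genotype membership of contigs
#'
#' A sample is present in a contig when at least `minReads` of its read bases
#' align anywhere on it.  Returns the per-contig presence matrix and the
#' counts per presence set (the cells of a Venn diagram over samples); the
#' cell counts sum to the number of contigs.
#'
#' @param pileups a named list of [ContigPileup].
#' @param panel a [GenotypePanel].
#' @param minReads presence threshold (default 1).
#' @return A list with `presence` (logical contig x sample matrix) and
#'   `sharing` (named integer vector keyed by `+`-joined sample sets;
#'   contigs with no sample get key `"(none)"`).
#' @export
genotypeMembership <- function(pileups, panel, minReads = 1L) {
    samples <- panelSamples(panel)
    pres <- t(vapply(pileups, function(pu) {
        colSums(pu@counts, dims = 2L) >= minReads
    }, logical(length(samples))))
    colnames(pres) <- samples
    rownames(pres) <- vapply(pileups, pileupContig, character(1L))
    keys <- apply(pres, 1L, function(v) {
        if (!any(v)) "(none)" else paste(samples[v], collapse = "+")
    })
    list(presence = pres, sharing = table(keys))
}
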