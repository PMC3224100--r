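## Seeded generator of synthetic contigs, genotype haplotypes, planted
## SSR/SNP/indel truth sets, simulated pileups and gapped truth alignments.
##
## The generator emulates the study design the toolkit targets: a small panel
## of genotype samples of differing heterozygosity (one RIL-pool-like sample
## with elevated within-sample polymorphism, inbred-like samples with near
## zero), biallelic SNPs at a realistic per-kb rate, SSR tracts across motif
## lengths 2-6, and consensus indels spanning the detector's size bounds.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 100 contigs of 2 kb, a
#' three-sample panel (one pooled heterozygous sample at 0.5 minor-haplotype
#' fraction, two inbred samples), 1.36 planted SNPs per kb with >= 60 nt
#' spacing, two consensus indels per contig with lengths uniform on 2-55 nt
#' (deliberately straddling the 3-50 nt detector bounds), SSR tracts planted
#' per motif length, 40x mean per-sample depth and 0.5% per-base error.
#'
#' @param nContigs number of contigs.
#' @param contigLength contig length in nt.
#' @param samples sample ids, panel order; the first sample is the alignment
#'   reference row.
#' @param heterozygosity per-sample minor-haplotype fraction (0 = inbred-like,
#'   0.5 = balanced pool).
#' @param snpRate planted SNPs per kb.
#' @param snpMinSpacing minimum spacing between planted SNPs in nt.
#' @param snpEdgeMargin planted SNPs keep at least this flank to contig ends.
#' @param indelsPerContig consensus indels planted per contig.
#' @param indelLengths pool of indel lengths sampled uniformly.
#' @param ssrPlantRate named numeric, per-contig planting probability by motif
#'   length.
#' @param ssrExtraRepeats planted repeat counts are uniform between the class
#'   minimum and minimum + `ssrExtraRepeats`.
#' @param polySsrFrac fraction of planted SSR tracts that also receive an
#'   in-tract unit deletion in one carrier sample (a planted polymorphic SSR).
#' @param depth mean per-sample read depth per position (Poisson).
#' @param errorRate per-base sequencing error probability.
#' @param baseQuality constant Phred base quality for emitted reads.
#' @param seed mandatory integer seed; identical configurations give
#'   byte-identical outputs.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(nContigs = 100L, contigLength = 2000L,
                      samples = c("POOL1", "INB1", "INB2"),
                      heterozygosity = c(0.5, 0, 0),
                      snpRate = 1.36, snpMinSpacing = 60L,
                      snpEdgeMargin = 110L,
                      indelsPerContig = 2L, indelLengths = 2:55,
                      ssrPlantRate = c(`2` = 0.15, `3` = 0.30, `4` = 0.10,
                                       `5` = 0.05, `6` = 0.05),
                      ssrExtraRepeats = 6L, polySsrFrac = 0.3,
                      depth = 40, errorRate = 0.005, baseQuality = 30L,
                      seed) {
    if (missing(seed))
        stop("a seed is mandatory")
    stopifnot(length(samples) >= 2L, length(heterozygosity) == length(samples),
              all(heterozygosity >= 0 & heterozygosity <= 0.5),
              snpRate >= 0, depth > 0, errorRate >= 0, errorRate < 1,
              all(indelLengths >= 1L), indelsPerContig >= 0L)
    structure(list(nContigs = as.integer(nContigs),
                   contigLength = as.integer(contigLength),
                   samples = as.character(samples),
                   heterozygosity = as.numeric(heterozygosity),
                   snpRate = snpRate, snpMinSpacing = as.integer(snpMinSpacing),
                   snpEdgeMargin = as.integer(snpEdgeMargin),
                   indelsPerContig = as.integer(indelsPerContig),
                   indelLengths = as.integer(indelLengths),
                   ssrPlantRate = ssrPlantRate,
                   ssrExtraRepeats = as.integer(ssrExtraRepeats),
                   polySsrFrac = polySsrFrac,
                   depth = depth, errorRate = errorRate,
                   baseQuality = as.integer(baseQuality),
                   seed = as.integer(seed)),
              class = "SimConfig")
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.randomPrimitiveMotif <- function(k) {
    repeat {
        m <- paste(sample(DNA_BASES4, k, replace = TRUE), collapse = "")
        ch <- strsplit(m, "", fixed = TRUE)[[1L]]
        if (length(unique(ch)) > 1L && .isPrimitive(ch))
            return(canonicalMotif(m))
    }
}

## Greedily pick positions from candidates with pairwise spacing >= minGap.
.pickSpaced <- function(candidates, n, minGap) {
    picked <- integer()
    for (p in sample(candidates)) {
        if (length(picked) >= n) break
        if (!length(picked) || all(abs(picked - p) >= minGap))
            picked <- c(picked, p)
    }
    sort(picked)
}

#' Simulate a genotype panel with planted truth
#'
#' Builds random reference contigs, plants SSR tracts (with boundary bases
#' adjusted so each tract is exactly the maximal run), biallelic SNPs with a
#' valid inter-sample contrast, and consensus deletions in carrier samples
#' (including in-tract SSR unit deletions for planted polymorphic SSRs), then
#' derives per-sample haplotypes and exact gapped truth alignments.
#'
#' @param cfg a [simConfig()] configuration.
#' @return A list: `contigs` ([Biostrings::DNAStringSet]); `haplotypes`
#'   (per sample, a list of one or two [Biostrings::DNAStringSet]s of
#'   SNP-substituted haplotypes, indel-free -- reads are columnar);
#'   `alignments` (per contig [GappedAlignment] of indel-carrying consensi);
#'   `panel` (a [GenotypePanel]); and `truth` with `ssrs` (GRanges), `snps`
#'   and `indels` (data frames in reference coordinates).
#' @export
simulatePanel <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed, {
        nS <- length(cfg$samples)
        L <- cfg$contigLength
        rules <- SsrRules()
        contigSeqs <- character(cfg$nContigs)
        hap1 <- hap2 <- vector("list", nS)
        for (s in seq_len(nS)) hap1[[s]] <- hap2[[s]] <- character(cfg$nContigs)
        alnList <- vector("list", cfg$nContigs)
        truthSsr <- list(); truthSnp <- list(); truthIndel <- list()
        ids <- sprintf("contig%03d", seq_len(cfg$nContigs))
        for (ci in seq_len(cfg$nContigs)) {
            chars <- sample(DNA_BASES4, L, replace = TRUE)
            occupied <- rep(FALSE, L)   # planted feature footprint + guards
            ## --- SSR tracts -------------------------------------------------
            ssrRows <- list()
            for (k in as.integer(names(cfg$ssrPlantRate))) {
                if (stats::runif(1L) > cfg$ssrPlantRate[[as.character(k)]])
                    next
                minRep <- rules@minRepeats[[as.character(k)]]
                reps <- minRep + sample.int(cfg$ssrExtraRepeats + 1L, 1L) - 1L
                tlen <- reps * k
                placed <- FALSE
                for (try in seq_len(30L)) {
                    st <- sample(40:(L - tlen - 40L), 1L)
                    win <- max(1L, st - 20L):min(L, st + tlen + 19L)
                    if (any(occupied[win])) next
                    motif <- .randomPrimitiveMotif(k)
                    mch <- strsplit(motif, "", fixed = TRUE)[[1L]]
                    chars[st:(st + tlen - 1L)] <- rep_len(mch, tlen)
                    ## boundary guards: stop the run from extending
                    chars[st - 1L] <- sample(setdiff(DNA_BASES4, mch[k]), 1L)
                    chars[st + tlen] <- sample(setdiff(DNA_BASES4, mch[1L]), 1L)
                    occupied[win] <- TRUE
                    ssrRows[[length(ssrRows) + 1L]] <- data.frame(
                        contig = ids[ci], start = st, end = st + tlen - 1L,
                        motif = motif, motifLength = k, repeats = reps,
                        stringsAsFactors = FALSE)
                    placed <- TRUE
                    break
                }
            }
            ## --- indel spans (deletions in carrier samples) -----------------
            nIndel <- cfg$indelsPerContig
            indelRows <- list()
            indelFoot <- rep(FALSE, L)
            for (j in seq_len(nIndel)) {
                ilen <- sample(cfg$indelLengths, 1L)
                for (try in seq_len(30L)) {
                    st <- sample(31:(L - ilen - 30L), 1L)
                    win <- max(1L, st - 30L):min(L, st + ilen + 29L)
                    if (any(occupied[win]) || any(indelFoot[win])) next
                    carriers <- cfg$samples[-1L][
                        sample.int(nS - 1L, sample.int(nS - 1L, 1L)) ]
                    indelRows[[length(indelRows) + 1L]] <- data.frame(
                        contig = ids[ci], start = st, end = st + ilen - 1L,
                        length = ilen,
                        carriers = paste(sort(carriers), collapse = ","),
                        inSsr = FALSE, ssrMotifLength = NA_integer_,
                        stringsAsFactors = FALSE)
                    indelFoot[win] <- TRUE
                    break
                }
            }
            ## --- planted polymorphic SSRs: in-tract unit deletions ----------
            for (sr in ssrRows) {
                if (stats::runif(1L) > cfg$polySsrFrac) next
                k <- sr$motifLength
                maxUnits <- min(sr$repeats - rules@minRepeats[[as.character(k)]],
                                50L %/% k)
                minUnits <- as.integer(ceiling(3 / k))
                if (maxUnits < minUnits) next
                units <- sample(minUnits:maxUnits, 1L)
                ilen <- units * k
                st <- sr$start          # delete leading whole units
                carriers <- cfg$samples[-1L][sample.int(nS - 1L, 1L)]
                indelRows[[length(indelRows) + 1L]] <- data.frame(
                    contig = ids[ci], start = st, end = st + ilen - 1L,
                    length = ilen, carriers = carriers,
                    inSsr = TRUE, ssrMotifLength = k,
                    stringsAsFactors = FALSE)
            }
            indelDf <- if (length(indelRows)) do.call(rbind, indelRows) else
                data.frame(contig = character(), start = integer(),
                           end = integer(), length = integer(),
                           carriers = character(), inSsr = logical(),
                           ssrMotifLength = integer())
            ## --- SNP positions ---------------------------------------------
            nSnp <- stats::rpois(1L, cfg$snpRate * L / 1000)
            lo <- cfg$snpEdgeMargin + 1L
            hi <- L - cfg$snpEdgeMargin
            free <- setdiff(lo:hi, which(occupied | indelFoot))
            snpPos <- .pickSpaced(free, nSnp, cfg$snpMinSpacing)
            snpRows <- list()
            for (p in snpPos) {
                ref <- chars[p]
                alt <- sample(setdiff(DNA_BASES4, ref), 1L)
                repeat {
                    geno <- vapply(seq_len(nS), function(s) {
                        if (cfg$heterozygosity[s] > 0) {
                            sample(c("RA", "AA", "RR"), 1L,
                                   prob = c(0.6, 0.2, 0.2))
                        } else {
                            sample(c("AA", "RR"), 1L, prob = c(0.35, 0.65))
                        }
                    }, character(1L))
                    ## both alleles must be observable across the panel
                    hasRef <- any(geno %in% c("RR", "RA"))
                    hasAlt <- any(geno %in% c("AA", "RA"))
                    if (hasRef && hasAlt) break
                }
                snpRows[[length(snpRows) + 1L]] <- data.frame(
                    contig = ids[ci], pos = p, ref = ref, alt = alt,
                    genotype = paste(geno, collapse = ";"),
                    stringsAsFactors = FALSE)
            }
            contigSeqs[ci] <- paste(chars, collapse = "")
            ## --- haplotypes (SNP-substituted, indel-free) -------------------
            genoMat <- if (length(snpRows))
                do.call(rbind, strsplit(vapply(snpRows, `[[`, character(1L),
                                               "genotype"), ";",
                                        fixed = TRUE)) else
                matrix(character(), ncol = nS)
            for (s in seq_len(nS)) {
                h1 <- h2 <- chars
                for (r in seq_along(snpRows)) {
                    g <- genoMat[r, s]
                    p <- snpRows[[r]]$pos
                    a <- snpRows[[r]]$alt
                    if (g == "AA") { h1[p] <- a; h2[p] <- a }
                    else if (g == "RA") h2[p] <- a
                }
                hap1[[s]][ci] <- paste(h1, collapse = "")
                hap2[[s]][ci] <- paste(h2, collapse = "")
            }
            ## --- gapped truth alignment (consensi with indels) --------------
            rows <- character(nS)
            for (s in seq_len(nS)) {
                cons <- strsplit(hap1[[s]][ci], "", fixed = TRUE)[[1L]]
                if (nrow(indelDf)) {
                    carrierSets <- strsplit(indelDf$carriers, ",", fixed = TRUE)
                    for (r in seq_len(nrow(indelDf))) {
                        if (cfg$samples[s] %in% carrierSets[[r]])
                            cons[indelDf$start[r]:indelDf$end[r]] <- "-"
                    }
                }
                rows[s] <- paste(cons, collapse = "")
            }
            names(rows) <- cfg$samples
            alnList[[ci]] <- GappedAlignment(ids[ci], rows)
            truthSsr[[ci]] <- if (length(ssrRows)) do.call(rbind, ssrRows) else NULL
            truthSnp[[ci]] <- if (length(snpRows)) do.call(rbind, snpRows) else NULL
            truthIndel[[ci]] <- if (nrow(indelDf)) indelDf else NULL
        }
        contigs <- Biostrings::DNAStringSet(contigSeqs)
        names(contigs) <- ids
        names(alnList) <- ids
        haplotypes <- lapply(seq_len(nS), function(s) {
            h1 <- Biostrings::DNAStringSet(hap1[[s]]); names(h1) <- ids
            if (cfg$heterozygosity[s] > 0) {
                h2 <- Biostrings::DNAStringSet(hap2[[s]]); names(h2) <- ids
                list(h1, h2)
            } else list(h1)
        })
        names(haplotypes) <- cfg$samples
        ssrDf <- do.call(rbind, truthSsr)
        ssrGr <- if (!is.null(ssrDf) && nrow(ssrDf)) {
            g <- GRanges(ssrDf$contig, IRanges(ssrDf$start, ssrDf$end))
            mcols(g) <- DataFrame(motif = ssrDf$motif,
                                  motifLength = ssrDf$motifLength,
                                  repeats = ssrDf$repeats)
            g
        } else GRanges()
        list(contigs = contigs, haplotypes = haplotypes,
             alignments = alnList,
             panel = GenotypePanel(cfg$samples),
             truth = list(ssrs = ssrGr,
                          snps = do.call(rbind, truthSnp),
                          indels = do.call(rbind, truthIndel)))
    })
}

#' Simulate read pileups from a panel
#'
#' Reads are modelled as independent per-position base draws (pileup-level
#' simulation): per sample and position the depth is Poisson(`cfg$depth`),
#' reads are split evenly between the sample's haplotypes, and each read base
#' is flipped to a uniformly chosen other base with probability
#' `cfg$errorRate`.
#'
#' @param sim the result of [simulatePanel()].
#' @param cfg the same [simConfig()] used to build `sim`.
#' @return A named list of [ContigPileup], one per contig.
#' @export
simulatePileup <- function(sim, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed + 1L, {
        samples <- names(sim$haplotypes)
        ids <- names(sim$contigs)
        out <- vector("list", length(ids))
        names(out) <- ids
        ## error lookup: altBase[b, j] = j-th base other than b
        altBase <- t(vapply(seq_len(4L), function(b) setdiff(seq_len(4L), b),
                            integer(3L)))
        for (ci in seq_along(ids)) {
            L <- Biostrings::width(sim$contigs[ci])
            cnt <- array(0L, dim = c(4L, L, length(samples)))
            for (s in seq_along(samples)) {
                haps <- sim$haplotypes[[s]]
                n <- stats::rpois(L, cfg$depth)
                nh <- if (length(haps) == 2L)
                    list(stats::rbinom(L, n, 0.5)) else list(n)
                if (length(haps) == 2L)
                    nh <- list(nh[[1L]], n - nh[[1L]])
                for (h in seq_along(haps)) {
                    b <- match(strsplit(as.character(haps[[h]][ci]), "",
                                        fixed = TRUE)[[1L]], DNA_BASES4)
                    nthis <- nh[[h]]
                    nCorrect <- stats::rbinom(L, nthis, 1 - cfg$errorRate)
                    add <- integer(4L * L)
                    ix <- b + 4L * (seq_len(L) - 1L)
                    add[ix] <- add[ix] + nCorrect
                    nErr <- nthis - nCorrect
                    tot <- sum(nErr)
                    if (tot > 0L) {
                        posIdx <- rep.int(seq_len(L), nErr)
                        off <- sample.int(3L, tot, replace = TRUE)
                        eb <- altBase[cbind(b[posIdx], off)]
                        tab <- tabulate(eb + 4L * (posIdx - 1L), 4L * L)
                        add <- add + tab
                    }
                    cnt[, , s] <- cnt[, , s] + matrix(add, nrow = 4L)
                }
            }
            out[[ci]] <- ContigPileup(ids[ci], L, samples, cnt)
        }
        out
    })
}

#' Write the per-contig gapped truth alignments to aligned FASTA
#'
#' Gap columns sit exactly at the planted indels, so the alignment is exact
#' by construction.
#'
#' @param sim the result of [simulatePanel()].
#' @param dir output directory; one `<contig>.aln.fa` per contig.
#' @return Invisibly, the vector of written paths.
#' @export
writeGappedTruthAlignments <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(sim$alignments), function(id) {
        p <- file.path(dir, paste0(id, ".aln.fa"))
        writeGappedFasta(sim$alignments[[id]], p)
        p
    }, character(1L))
    invisible(paths)
}

#' Write truth tables as TSV
#'
#' @param sim the result of [simulatePanel()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeTruthTsv <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ssrs <- sim$truth$ssrs
    ssrDf <- if (length(ssrs))
        data.frame(contig = as.character(seqnames(ssrs)),
                   start = start(ssrs), end = end(ssrs),
                   motif = mcols(ssrs)$motif,
                   repeats = mcols(ssrs)$repeats) else
        data.frame(contig = character(), start = integer(), end = integer(),
                   motif = character(), repeats = integer())
    paths <- c(ssr = file.path(dir, "truth_ssrs.tsv"),
               snp = file.path(dir, "truth_snps.tsv"),
               indel = file.path(dir, "truth_indels.tsv"))
    utils::write.table(ssrDf, paths["ssr"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sim$truth$snps %||% data.frame(), paths["snp"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$indels %||% data.frame(), paths["indel"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
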