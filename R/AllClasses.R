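#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList IntegerList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Genotype sample panel
#'
#' An ordered panel of genotype samples together with the mapping from
#' alignment read groups to sample ids.  The panel order is load-bearing:
#' per-sample SNP status codes (e.g. \code{"PMM"}) are concatenated in panel
#' order, so the order given here defines how class codes read.
#'
#' @slot samples character vector of unique sample ids (>= 2), in panel order.
#' @slot readGroupMap named character vector; names are read-group ids, values
#'   are sample ids drawn from \code{samples}.
#' @export
setClass("GenotypePanel",
    representation(samples = "character", readGroupMap = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@samples) < 2L)
            msg <- c(msg, "a panel needs at least 2 samples")
        if (anyDuplicated(object@samples))
            msg <- c(msg, "sample ids must be unique")
        if (length(object@readGroupMap)) {
            if (is.null(names(object@readGroupMap)) ||
                any(!nzchar(names(object@readGroupMap))))
                msg <- c(msg, "readGroupMap must have read-group names")
            if (anyDuplicated(names(object@readGroupMap)))
                msg <- c(msg, "each read group must map to exactly one sample")
            bad <- setdiff(object@readGroupMap, object@samples)
            if (length(bad))
                msg <- c(msg, paste0("read groups map to unknown samples: ",
                                     paste(bad, collapse = ", ")))
        }
        if (length(msg)) msg else TRUE
    })

#' @param samples character vector of sample ids in panel order.
#' @param readGroupMap named character vector mapping read groups to samples;
#'   defaults to the identity mapping (read group == sample id).
#' @return A \code{GenotypePanel} object.
#' @examples
#' GenotypePanel(c("POOL1", "INB1", "INB2"))
#' @rdname GenotypePanel-class
#' @export
GenotypePanel <- function(samples,
                          readGroupMap = structure(samples, names = samples)) {
    new("GenotypePanel", samples = as.character(samples),
        readGroupMap = readGroupMap)
}

#' @rdname GenotypePanel-class
#' @param object,x a \code{GenotypePanel}.
#' @export
setMethod("show", "GenotypePanel", function(object) {
    cat("GenotypePanel with", length(object@samples), "samples:",
        paste(object@samples, collapse = ", "), "\n")
    cat("  read groups:", length(object@readGroupMap), "\n")
})

#' @rdname GenotypePanel-class
#' @export
panelSamples <- function(x) {
    stopifnot(is(x, "GenotypePanel"))
    x@samples
}

#' @rdname GenotypePanel-class
#' @export
readGroupMap <- function(x) {
    stopifnot(is(x, "GenotypePanel"))
    x@readGroupMap
}

#' Microsatellite search rules
#'
#' Motif-class thresholds for the perfect-SSR scan and the maximum gap for
#' compound merging.  The defaults are the conventional EST-SSR thresholds:
#' at least six repeat units for dinucleotide motifs, four for trinucleotides
#' and three for tetra-, penta- and hexanucleotides; adjacent loci no more
#' than 10 nt apart are merged into one compound repeat.
#'
#' @slot motifLengths integer vector of motif lengths searched (subset of 2:6).
#' @slot minRepeats named integer vector, minimum full repeat units per motif
#'   length (names are motif lengths as characters).
#' @slot compoundMaxGap integer, maximum nt between adjacent loci merged into a
#'   compound repeat.
#' @export
setClass("SsrRules",
    representation(motifLengths = "integer", minRepeats = "integer",
                   compoundMaxGap = "integer"),
    validity = function(object) {
        msg <- character()
        if (any(object@motifLengths < 2L) || any(object@motifLengths > 6L))
            msg <- c(msg, "motifLengths must lie in 2..6 (mononucleotide runs excluded)")
        need <- as.character(object@motifLengths)
        if (!all(need %in% names(object@minRepeats)))
            msg <- c(msg, "minRepeats must name every motif length searched")
        if (any(object@minRepeats < 2L))
            msg <- c(msg, "all minRepeats must be >= 2")
        if (length(object@compoundMaxGap) != 1L || object@compoundMaxGap < 0L)
            msg <- c(msg, "compoundMaxGap must be a single non-negative integer")
        if (length(msg)) msg else TRUE
    })

#' @param motifLengths integer vector of motif lengths to search.
#' @param minRepeats named integer vector of per-class minimum repeat units.
#' @param compoundMaxGap maximum gap (nt) for compound merging.
#' @return An \code{SsrRules} object.
#' @examples
#' SsrRules()                      # the default thresholds
#' minAttainableSsrLength(SsrRules())  # 12 nt under the defaults
#' @rdname SsrRules-class
#' @export
SsrRules <- function(motifLengths = 2:6,
                     minRepeats = c(`2` = 6L, `3` = 4L, `4` = 3L,
                                    `5` = 3L, `6` = 3L),
                     compoundMaxGap = 10L) {
    mr <- as.integer(minRepeats)
    names(mr) <- names(minRepeats)
    new("SsrRules", motifLengths = as.integer(motifLengths), minRepeats = mr,
        compoundMaxGap = as.integer(compoundMaxGap))
}

#' @rdname SsrRules-class
#' @param object a \code{SsrRules}.
#' @export
setMethod("show", "SsrRules", function(object) {
    cat("SsrRules: motif lengths", paste(object@motifLengths, collapse = ","),
        "\n  min repeats:",
        paste(names(object@minRepeats), object@minRepeats, sep = "->",
              collapse = ", "),
        "\n  compound max gap:", object@compoundMaxGap, "nt\n")
})

#' SNP filter cascade parameters
#'
#' Thresholds applied to biallelic candidate sites: minimum pooled coverage of
#' the two most abundant alleles, minimum average (per-sample) coverage,
#' minimum flanking length to the contig ends, minimum posterior quality of
#' polymorphism, and minimum absolute isolation from the nearest other
#' candidate on the contig.  The within-sample fields control the per-genotype
#' monomorphic/polymorphic (M/P/N) call.
#'
#' @slot minMajorCov minimum pooled read coverage of the most abundant allele.
#' @slot minMinorCov minimum pooled read coverage of the second allele.
#' @slot minAvgCov minimum average coverage, total site depth / panel size.
#' @slot minFlank minimum distance (nt) to the nearest contig end.
#' @slot minQuality minimum posterior probability of polymorphism.
#' @slot minIsolation minimum distance (nt) to the nearest other candidate.
#' @slot errorRate per-base sequencing error rate used by the quality model.
#' @slot withinMinorCount minimum within-sample count of the second site allele
#'   for a sample to be called intra-sample polymorphic (P).
#' @slot withinMinorFrac minimum within-sample fraction of the second site
#'   allele for a P call.
#' @slot minSampleDepth below this within-sample depth the sample status is N.
#' @export
setClass("SnpFilterParams",
    representation(minMajorCov = "integer", minMinorCov = "integer",
                   minAvgCov = "numeric", minFlank = "integer",
                   minQuality = "numeric", minIsolation = "integer",
                   errorRate = "numeric", withinMinorCount = "integer",
                   withinMinorFrac = "numeric", minSampleDepth = "integer"),
    validity = function(object) {
        msg <- character()
        nonneg <- c(minMajorCov = object@minMajorCov,
                    minMinorCov = object@minMinorCov,
                    minAvgCov = object@minAvgCov, minFlank = object@minFlank,
                    minIsolation = object@minIsolation,
                    withinMinorCount = object@withinMinorCount,
                    minSampleDepth = object@minSampleDepth)
        if (any(nonneg < 0))
            msg <- c(msg, "all thresholds must be >= 0")
        for (p in c("minQuality", "errorRate", "withinMinorFrac")) {
            v <- slot(object, p)
            if (v <= 0 || v >= 1)
                msg <- c(msg, paste(p, "must lie in (0,1)"))
        }
        if (length(msg)) msg else TRUE
    })

#' @param minMajorCov,minMinorCov,minAvgCov,minFlank,minQuality,minIsolation
#'   filter thresholds; see slots.
#' @param errorRate,withinMinorCount,withinMinorFrac,minSampleDepth model and
#'   within-sample status parameters; see slots.
#' @return A \code{SnpFilterParams} object.
#' @examples
#' SnpFilterParams()
#' SnpFilterParams(minMinorCov = 5L)
#' @rdname SnpFilterParams-class
#' @export
SnpFilterParams <- function(minMajorCov = 10L, minMinorCov = 10L,
                            minAvgCov = 10, minFlank = 100L,
                            minQuality = 0.99, minIsolation = 30L,
                            errorRate = 0.01, withinMinorCount = 4L,
                            withinMinorFrac = 0.2, minSampleDepth = 5L) {
    new("SnpFilterParams",
        minMajorCov = as.integer(minMajorCov),
        minMinorCov = as.integer(minMinorCov),
        minAvgCov = as.numeric(minAvgCov), minFlank = as.integer(minFlank),
        minQuality = as.numeric(minQuality),
        minIsolation = as.integer(minIsolation),
        errorRate = as.numeric(errorRate),
        withinMinorCount = as.integer(withinMinorCount),
        withinMinorFrac = as.numeric(withinMinorFrac),
        minSampleDepth = as.integer(minSampleDepth))
}

#' @rdname SnpFilterParams-class
#' @param object a \code{SnpFilterParams}.
#' @export
setMethod("show", "SnpFilterParams", function(object) {
    cat("SnpFilterParams:\n",
        " pooled coverage major/minor >=", object@minMajorCov, "/",
        object@minMinorCov, "\n",
        " avg coverage >=", object@minAvgCov,
        "; flank >=", object@minFlank, "nt",
        "; quality >=", object@minQuality,
        "; isolation >=", object@minIsolation, "nt\n",
        " within-sample P: count >=", object@withinMinorCount,
        "and frac >=", object@withinMinorFrac,
        "; N below depth", object@minSampleDepth, "\n")
})

#' Per-contig, per-genotype base-count pileup
#'
#' Dense per-position base counts for one contig, partitioned by genotype
#' sample.  Counts are stored as a 4 x length x samples integer array with
#' base rows A, C, G, T.  Deleted bases, Ns and bases below the base-quality
#' cutoff are never counted.
#'
#' @slot contig contig id.
#' @slot contigLength contig length in nt.
#' @slot samples sample ids (third array dimension), in panel order.
#' @slot counts integer array \code{[4, contigLength, nSamples]}.
#' @export
setClass("ContigPileup",
    representation(contig = "character", contigLength = "integer",
                   samples = "character", counts = "array"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@counts)
        if (length(d) != 3L || d[1L] != 4L)
            msg <- c(msg, "counts must be a 4 x length x samples array")
        else {
            if (d[2L] != object@contigLength)
                msg <- c(msg, "counts length dimension != contigLength")
            if (d[3L] != length(object@samples))
                msg <- c(msg, "counts sample dimension != samples")
            if (any(object@counts < 0))
                msg <- c(msg, "all counts must be >= 0")
        }
        if (length(msg)) msg else TRUE
    })

#' @param contig contig id.
#' @param contigLength contig length in nt.
#' @param samples sample ids.
#' @param counts 4 x contigLength x samples integer array (zeros if omitted).
#' @return A \code{ContigPileup}.
#' @rdname ContigPileup-class
#' @export
ContigPileup <- function(contig, contigLength, samples, counts = NULL) {
    contigLength <- as.integer(contigLength)
    if (is.null(counts))
        counts <- array(0L, dim = c(4L, contigLength, length(samples)),
                        dimnames = list(DNA_BASES4, NULL, samples))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(DNA_BASES4, NULL, samples)
    new("ContigPileup", contig = as.character(contig),
        contigLength = contigLength, samples = as.character(samples),
        counts = counts)
}

#' @rdname ContigPileup-class
#' @param object,x a \code{ContigPileup}.
#' @export
setMethod("show", "ContigPileup", function(object) {
    dt <- sum(object@counts)
    cat("ContigPileup for", object@contig, "(", object@contigLength, "nt,",
        length(object@samples), "samples );",
        "mean depth", round(dt / object@contigLength, 2), "\n")
})

#' @rdname ContigPileup-class
#' @export
pileupCounts <- function(x) {
    stopifnot(is(x, "ContigPileup"))
    x@counts
}

#' @rdname ContigPileup-class
#' @export
pileupContig <- function(x) {
    stopifnot(is(x, "ContigPileup"))
    x@contig
}

#' Gapped multi-genotype consensus alignment
#'
#' One contig's per-genotype consensus sequences, aligned with gaps.  The
#' first row (by panel order) is the reference frame: its ungapped coordinates
#' define contig positions for indel reporting.
#'
#' @slot contig contig id.
#' @slot rows named character vector of equal-length gapped sequences over
#'   \{A,C,G,T,N,-\}; names are sample ids.
#' @export
setClass("GappedAlignment",
    representation(contig = "character", rows = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@rows) < 2L)
            msg <- c(msg, "a gapped alignment needs >= 2 rows")
        if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
            msg <- c(msg, "rows must be uniquely named by sample")
        w <- unique(nchar(object@rows))
        if (length(w) > 1L)
            msg <- c(msg, "all gapped sequences must have equal length")
        if (length(object@rows) && any(grepl("[^ACGTN-]", object@rows)))
            msg <- c(msg, "alignment alphabet is {A,C,G,T,N,-}")
        if (length(w) == 1L && w > 0L && length(object@rows) >= 2L) {
            m <- do.call(rbind, strsplit(object@rows, "", fixed = TRUE))
            if (any(colSums(m == "-") == nrow(m)))
                msg <- c(msg, "all-gap columns are not allowed")
        }
        if (length(msg)) msg else TRUE
    })

#' @param contig contig id.
#' @param rows named character vector of gapped sequences.
#' @return A \code{GappedAlignment}.
#' @examples
#' GappedAlignment("c1", c(s1 = "ACGTACGT", s2 = "ACG--CGT"))
#' @rdname GappedAlignment-class
#' @export
GappedAlignment <- function(contig, rows) {
    up <- toupper(as.character(rows))
    names(up) <- names(rows)
    new("GappedAlignment", contig = as.character(contig), rows = up)
}

#' @rdname GappedAlignment-class
#' @param object,x a \code{GappedAlignment}.
#' @export
setMethod("show", "GappedAlignment", function(object) {
    cat("GappedAlignment for", object@contig, ":", length(object@rows),
        "rows x", nchar(object@rows[1L]), "columns\n")
})

#' @rdname GappedAlignment-class
#' @export
alignmentRows <- function(x) {
    stopifnot(is(x, "GappedAlignment"))
    x@rows
}

#' @rdname GappedAlignment-class
#' @export
alignmentContig <- function(x) {
    stopifnot(is(x, "GappedAlignment"))
    x@contig
}
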