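## Build a 2-row alignment: reference of length L, one gap of `gapLen`
## columns in row 2 starting after `leftFlank` columns, with `rightFlank`
## gap-free columns following.
mkAln <- function(gapLen, leftFlank = 30L, rightFlank = 30L, nRows = 2L,
                  carrierRows = 2L, seed = 1L) {
    set.seed(seed)
    L <- leftFlank + gapLen + rightFlank
    ref <- strsplit(randomSeq(L), "", fixed = TRUE)[[1L]]
    rows <- list()
    for (r in seq_len(nRows)) {
        v <- ref
        if (r %in% carrierRows && gapLen > 0L)
            v[(leftFlank + 1L):(leftFlank + gapLen)] <- "-"
        rows[[r]] <- paste(v, collapse = "")
    }
    rows <- unlist(rows)
    names(rows) <- paste0("s", seq_len(nRows))
    GappedAlignment("c1", rows)
}

test_that("indel size bounds are exact: lengths {2,3,50,51} -> {no,yes,yes,no}", {
    emitted <- vapply(c(2L, 3L, 50L, 51L), function(g)
        length(detectIndels(mkAln(g))), integer(1L))
    expect_identical(emitted, c(0L, 1L, 1L, 0L))
    got <- detectIndels(mkAln(5L))
    expect_identical(S4Vectors::mcols(got)$indelLength, 5L)
    expect_identical(S4Vectors::mcols(got)$carriers[[1L]], "s2")
    expect_identical(GenomicRanges::start(got), 31L)
    expect_identical(GenomicRanges::end(got), 35L)
})

test_that("flank bound is exact: {24,25} gap-free columns -> {no,yes}", {
    expect_length(detectIndels(mkAln(5L, leftFlank = 24L)), 0L)
    expect_length(detectIndels(mkAln(5L, leftFlank = 25L)), 1L)
    expect_length(detectIndels(mkAln(5L, rightFlank = 24L)), 0L)
    expect_length(detectIndels(mkAln(5L, rightFlank = 25L)), 1L)
})

test_that("substitutions in the flanks do not block emission", {
    aln <- mkAln(5L)
    rows <- alignmentRows(aln)
    ## mutate a few flank bases in row 2 (no gaps added)
    v <- strsplit(rows[[2L]], "", fixed = TRUE)[[1L]]
    for (p in c(5L, 10L, 50L))
        v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1L]
    aln2 <- GappedAlignment("c1", c(s1 = rows[[1L]],
                                    s2 = paste(v, collapse = "")))
    expect_length(detectIndels(aln2), 1L)
})

test_that("multi-carrier gaps are reported once with the carrier list", {
    aln <- mkAln(6L, nRows = 3L, carrierRows = c(2L, 3L))
    got <- detectIndels(aln)
    expect_length(got, 1L)
    expect_identical(S4Vectors::mcols(got)$carriers[[1L]], c("s2", "s3"))
})

test_that("adjacent distinct gap runs closer than the flank reject each other", {
    ## two 5-nt gaps in different rows separated by 10 gap-free columns
    set.seed(4)
    L <- 30L + 5L + 10L + 5L + 30L
    ref <- strsplit(randomSeq(L), "", fixed = TRUE)[[1L]]
    r2 <- ref; r2[31:35] <- "-"
    r3 <- ref; r3[46:50] <- "-"
    aln <- GappedAlignment("c1", c(s1 = paste(ref, collapse = ""),
                                   s2 = paste(r2, collapse = ""),
                                   s3 = paste(r3, collapse = "")))
    expect_length(detectIndels(aln), 0L)
})

test_that("reference-frame coordinates map back to the alignment columns", {
    ## put an insertion (gap in the reference row) before a deletion
    set.seed(5)
    L <- 120L
    ref <- strsplit(randomSeq(L), "", fixed = TRUE)[[1L]]
    r1 <- ref; r1[31:34] <- "-"          # 4-col insertion carried by row 1
    r2 <- ref; r2[71:80] <- "-"          # 10-col deletion carried by row 2
    aln <- GappedAlignment("c1", c(s1 = paste(r1, collapse = ""),
                                   s2 = paste(r2, collapse = "")))
    got <- detectIndels(aln)
    expect_length(got, 2L)
    m <- S4Vectors::mcols(got)
    ins <- got[m$refGap]
    del <- got[!m$refGap]
    ## the deletion's reference span: row-1 ungapped positions of its columns
    refPos <- cumsum(strsplit(alignmentRows(aln)[[1L]], "",
                              fixed = TRUE)[[1L]] != "-")
    expect_identical(GenomicRanges::start(del),
                     refPos[S4Vectors::mcols(del)$columnStart])
    expect_identical(GenomicRanges::end(del),
                     refPos[S4Vectors::mcols(del)$columnEnd])
    ## the insertion is anchored at the reference base preceding it
    expect_identical(GenomicRanges::start(ins), 30L)
    expect_identical(IRanges::width(ins), 1L)
})

test_that("SSR overlap annotation sets the locus and the in-frame flag", {
    ## reference carries (AGC)10 at 31..60; row 2 lacks two units (6 nt)
    set.seed(6)
    left <- randomSeq(30L)
    right <- randomSeq(30L)
    ref <- paste0(left, strrep("AGC", 10), right)
    v <- strsplit(ref, "", fixed = TRUE)[[1L]]
    v[31:36] <- "-"
    aln <- GappedAlignment("c1", c(s1 = ref, s2 = paste(v, collapse = "")))
    ssrs <- findPerfectSsrs(Biostrings::DNAStringSet(c(c1 = ref)))
    ssrs <- ssrs[S4Vectors::mcols(ssrs)$motif == canonicalMotif("AGC")]
    got <- annotateSsrOverlap(detectIndels(aln), ssrs)
    expect_length(got, 1L)
    expect_false(is.na(S4Vectors::mcols(got)$ssrOverlap))
    expect_true(S4Vectors::mcols(got)$inFrame)       # 6 mod 3 == 0
    ## a 4-nt gap in the same tract is out of frame
    v2 <- strsplit(ref, "", fixed = TRUE)[[1L]]
    v2[31:34] <- "-"
    aln2 <- GappedAlignment("c1", c(s1 = ref, s2 = paste(v2, collapse = "")))
    got2 <- annotateSsrOverlap(detectIndels(aln2), ssrs)
    expect_false(S4Vectors::mcols(got2)$inFrame)     # 4 mod 3 != 0
    ## an indel far from any SSR stays unannotated
    far <- annotateSsrOverlap(detectIndels(mkAln(5L, leftFlank = 200L)),
                              GenomicRanges::GRanges())
    expect_true(is.na(S4Vectors::mcols(far)$ssrOverlap))
    ## contig mismatch is an error
    wrong <- GenomicRanges::GRanges("other", IRanges::IRanges(31L, 60L))
    S4Vectors::mcols(wrong) <- S4Vectors::mcols(ssrs)
    expect_error(annotateSsrOverlap(detectIndels(aln), wrong),
                 "different contigs")
})

test_that("polymorphic-SSR report carries allele lengths and differences", {
    set.seed(7)
    left <- randomSeq(30L)
    right <- randomSeq(30L)
    ref <- paste0(left, strrep("AGC", 10), right)
    v <- strsplit(ref, "", fixed = TRUE)[[1L]]
    v[31:39] <- "-"                       # 9-nt in-tract deletion
    aln <- GappedAlignment("c1", c(s1 = ref, s2 = paste(v, collapse = "")))
    ssrs <- findPerfectSsrs(Biostrings::DNAStringSet(c(c1 = ref)))
    ind <- annotateSsrOverlap(detectIndels(aln), ssrs)
    rep <- polymorphicSsrReport(ind, aln)
    expect_identical(nrow(rep), 1L)
    expect_identical(rep$allele_diff, 9L)
    expect_identical(rep$allele_len_s1, 30L)      # full (AGC)10 tract
    expect_identical(rep$allele_len_s2, 21L)      # two fewer... three units
    expect_identical(rep$allele_len_s1 - rep$allele_len_s2, rep$allele_diff)
    expect_true(rep$in_frame)
    ## no SSR-overlapping indels -> empty table with the same columns
    none <- polymorphicSsrReport(detectIndels(mkAln(5L)), mkAln(5L))
    expect_identical(nrow(none), 0L)
    expect_true(all(c("contig", "allele_diff") %in% colnames(none)))
})

test_that("alignment validity is enforced", {
    expect_error(GappedAlignment("c1", c(s1 = "ACGT", s2 = "ACG")),
                 "equal length")
    expect_error(GappedAlignment("c1", c(s1 = "AC-T", s2 = "AC-T")),
                 "all-gap")
    expect_error(GappedAlignment("c1", c(s1 = "ACQT", s2 = "ACGT")),
                 "alphabet")
})
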