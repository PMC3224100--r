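test_that("canonicalMotif extracts primitive roots and smallest rotations", {
    expect_identical(canonicalMotif("GAC"), "ACG")
    expect_identical(canonicalMotif("CAC"), "ACC")
    expect_identical(canonicalMotif("ATAT"), "AT")
    expect_identical(canonicalMotif("ACGACG"), "ACG")
    expect_error(canonicalMotif("AAA"), "mononucleotide")
    expect_error(canonicalMotif("AXT"), "A,C,G,T")
    expect_identical(primitiveRoot("ATATAT"), "AT")
    expect_identical(primitiveRoot("ACGT"), "ACGT")
})

test_that("perfect-SSR scan honours the motif-class repeat minima", {
    flank <- function(s) paste0("TTGGTTGGTT", s, "GGTTGGTTGG")
    ctg <- Biostrings::DNAStringSet(c(
        six = flank(strrep("AC", 6)),     # at the dinucleotide minimum
        five = flank(strrep("AC", 5)),    # one unit below: no locus
        tri = flank(strrep("AGC", 4)),    # trinucleotide minimum
        tri3 = flank(strrep("AGC", 3))))  # below
    got <- findPerfectSsrs(ctg, SsrRules())
    expect_identical(as.character(seqnames(got)), c("six", "tri"))
    expect_identical(S4Vectors::mcols(got)$motif, c("AC", "AGC"))
    expect_identical(S4Vectors::mcols(got)$repeats, c(6L, 4L))
    expect_identical(IRanges::width(got), c(12L, 12L))
})

test_that("partial trailing units are trimmed and runs break at N", {
    ## 6.5 units of AC: span trimmed to 12 full-unit bases
    ctg <- Biostrings::DNAStringSet(c(c1 = paste0("GGTTGGTTGG",
                                                  strrep("AC", 6), "A",
                                                  "GGTTGGTTGG")))
    got <- findPerfectSsrs(ctg)
    expect_identical(IRanges::width(got), 12L)
    expect_identical(S4Vectors::mcols(got)$repeats, 6L)
    ## N splits a 12-unit run into two 6-unit fragments
    ctg2 <- Biostrings::DNAStringSet(c(c1 = paste0("GGTTGGTTGG",
                                                   strrep("AC", 6), "N",
                                                   strrep("AC", 6),
                                                   "GGTTGGTTGG")))
    got2 <- findPerfectSsrs(ctg2)
    expect_length(got2, 2L)
    expect_identical(S4Vectors::mcols(got2)$repeats, c(6L, 6L))
})

test_that("reported loci never violate class minima and motifs are primitive", {
    set.seed(101)
    rules <- SsrRules()
    for (i in 1:25) {
        gr <- findPerfectSsrs(
            Biostrings::DNAStringSet(c(x = randomSeq(800))), rules)
        if (!length(gr)) next
        m <- S4Vectors::mcols(gr)
        expect_true(all(m$repeats >=
                        rules@minRepeats[as.character(m$motifLength)]))
        expect_true(all(vapply(m$motif, function(w)
            identical(primitiveRoot(w), w), logical(1L))))
        expect_identical(IRanges::width(gr), m$repeats * m$motifLength)
    }
})

test_that("scanner matches the brute-force oracle on random sequences", {
    set.seed(202)
    for (i in 1:40) {
        s <- randomSeq(600)
        got <- ssrGrangesToTable(
            findPerfectSsrs(Biostrings::DNAStringSet(c(x = s))))
        want <- bruteForceSsrScan(s)
        expect_identical(got, want[, colnames(got)], label = paste("seq", i))
    }
})

test_that("compound merging applies the <=10 nt gap rule at both boundaries", {
    rules <- SsrRules()
    mk <- function(gap, motif2 = "AGC") {
        ## (AC)6 then a gap of `gap` nt then (motif2)4
        gapSeq <- paste(rep_len(c("T", "G", "T", "C"), gap), collapse = "")
        seqs <- paste0("TTGGATCCAGTCAGGTTGCA", strrep("AC", 6),
                       gapSeq, strrep(motif2, 4), "TTGGATCCAGTCAGGTTGCA")
        ctg <- Biostrings::DNAStringSet(c(c1 = seqs))
        mergeCompound(findPerfectSsrs(ctg, rules), rules)
    }
    atTen <- mk(10L)
    expect_length(atTen, 1L)
    expect_identical(S4Vectors::mcols(atTen)$ssrClass, "compound")
    expect_identical(S4Vectors::mcols(atTen)$componentMotif[[1L]],
                     c("AC", "AGC"))
    above <- mk(11L)
    expect_length(above, 2L)
    expect_identical(S4Vectors::mcols(above)$ssrClass,
                     c("perfect", "perfect"))
    ## at gap 0 use a second motif that cannot extend across the junction
    adjacent <- mk(0L, motif2 = "AGT")
    expect_length(adjacent, 1L)
    expect_identical(S4Vectors::mcols(adjacent)$ssrClass, "compound")
    expect_identical(S4Vectors::mcols(adjacent)$componentMotif[[1L]],
                     c("AC", "AGT"))
})

test_that("compound loci cover their components and merging is deterministic", {
    set.seed(303)
    rules <- SsrRules()
    for (i in 1:10) {
        ctg <- Biostrings::DNAStringSet(c(x = randomSeq(2000)))
        perfect <- findPerfectSsrs(ctg, rules)
        m1 <- mergeCompound(perfect, rules)
        m2 <- mergeCompound(perfect, rules)
        expect_identical(as.data.frame(m1), as.data.frame(m2))
        comp <- m1[S4Vectors::mcols(m1)$ssrClass == "compound"]
        for (j in seq_along(comp)) {
            cs <- S4Vectors::mcols(comp)$componentStart[[j]]
            ce <- S4Vectors::mcols(comp)$componentEnd[[j]]
            expect_identical(min(cs), GenomicRanges::start(comp)[j])
            expect_identical(max(ce), GenomicRanges::end(comp)[j])
            gaps <- cs[-1L] - ce[-length(ce)] - 1L
            expect_true(all(gaps <= rules@compoundMaxGap))
            expect_true(all(gaps >= 0L))
        }
        ## chains partition the input loci
        expect_identical(sum(lengths(S4Vectors::mcols(m1)$componentMotif)),
                         length(perfect))
    }
})

test_that("mergeCompound rejects unsorted or overlapping input", {
    gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(50, 10),
                                                        c(61, 21)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        motif = c("AC", "AG"), motifLength = c(2L, 2L),
        repeats = c(6L, 6L), ssrClass = "perfect")
    expect_error(mergeCompound(gr), "sorted")
})

test_that("ssrSummary tallies correctly and knows the rule-table minimum", {
    expect_identical(minAttainableSsrLength(SsrRules()), 12L)
    empty <- findPerfectSsrs(Biostrings::DNAStringSet(c(x = "ACGTACG")))
    s0 <- ssrSummary(empty)
    expect_identical(s0$total, 0L)
    expect_true(all(s0$byMotifLength == 0L))
    ctg <- Biostrings::DNAStringSet(c(
        a = paste0("GGTTGGTTGG", strrep("AC", 6), "GGTTGGTTGG",
                   strrep("AG", 7), "GGTTGGTTGG"),
        b = paste0("GGTTGGTTGG", strrep("AGC", 4), "GGTTGGTTGG")))
    s <- ssrSummary(findPerfectSsrs(ctg))
    expect_identical(unname(s$byMotifLength[c("2", "3")]), c(2L, 1L))
    expect_identical(s$total, 3L)
    expect_true(min(as.integer(names(s$lengthDist))) >=
                minAttainableSsrLength(SsrRules()))
})
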