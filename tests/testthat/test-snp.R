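test_that("site allele ranking pools samples with alphabetical tie-breaks", {
    got <- siteAlleleCounts(c(A = 15, C = 1, G = 12, T = 0))
    expect_identical(got$major, "A")
    expect_identical(got$minor, "G")
    expect_identical(got$depthTotal, 28)
    tie <- siteAlleleCounts(c(A = 10, C = 0, G = 10, T = 0))
    expect_identical(tie$major, "A")       # alphabetical tie-break
    expect_identical(tie$minor, "G")
    mono <- siteAlleleCounts(c(A = 30, C = 0, G = 0, T = 0))
    expect_identical(mono$major, "A")
    expect_true(is.na(mono$minor))
    expect_error(siteAlleleCounts(c(A = 0, C = 0, G = 0, T = 0)), "all-zero")
    ## a matrix column pools across samples
    m <- matrix(c(5L, 0L, 2L, 0L, 10L, 0L, 10L, 0L), nrow = 4L)
    got2 <- siteAlleleCounts(m)
    expect_identical(got2$major, "A")
    expect_identical(got2$minor, "G")
})

test_that("polymorphism posterior matches the exact-likelihood oracle", {
    ## frozen values computed with oracleQuality before implementation
    expect_lt(polymorphismQuality(20, 0), 0.5)
    expect_gt(polymorphismQuality(15, 12), 0.99)
    expect_lt(polymorphismQuality(15, 1), 0.99)
    for (case in list(c(20, 0), c(15, 12), c(15, 1), c(50, 10), c(9, 9))) {
        expect_equal(polymorphismQuality(case[1L], case[2L]),
                     oracleQuality(case[1L], case[2L]), tolerance = 1e-12)
    }
    ## monotone non-decreasing in the minor count at fixed depth
    for (depth in c(10L, 40L, 80L)) {
        q <- polymorphismQuality(depth - 0:depth, 0:depth)
        expect_true(all(diff(q) >= -1e-12))
    }
    expect_error(polymorphismQuality(0, 0), "positive")
})

test_that("per-sample M/P/N status follows depth and within-sample thresholds", {
    p <- SnpFilterParams()
    cnt <- matrix(0L, nrow = 4L, ncol = 4L,
                  dimnames = list(c("A", "C", "G", "T"),
                                  c("bal", "fixed", "thin", "skew")))
    cnt["A", "bal"] <- 10L; cnt["G", "bal"] <- 10L
    cnt["A", "fixed"] <- 20L
    cnt["A", "thin"] <- 2L; cnt["G", "thin"] <- 1L
    cnt["A", "skew"] <- 19L; cnt["G", "skew"] <- 1L
    st <- sampleStatus(cnt, "A", "G", p)
    expect_identical(st$status, c("P", "M", "N", "M"))
    expect_identical(st$majorAllele[c(2L, 4L)], c("A", "A"))
    expect_identical(st$depth, c(20L, 20L, 3L, 20L))
})

test_that("filter cascade flags each violated rule", {
    p <- SnpFilterParams()
    cand <- data.frame(
        majorCount = c(15L, 15L, 15L, 40L),
        minorCount = c(12L, 9L, 12L, 30L),
        depthTotal = c(27L, 40L, 150L, 70L),
        flank      = c(150L, 150L, 50L, 150L),
        quality    = c(1, 1, 1, 1),
        interContrast = c(TRUE, TRUE, TRUE, FALSE))
    got <- applyFilters(cand, nSamples = 3L, p)
    expect_identical(got$filtersFailed[[1L]], "avg_cov")     # 27/3 = 9 < 10
    expect_identical(got$filtersFailed[[2L]], "minor_cov")
    expect_identical(got$filtersFailed[[3L]], "flank")
    expect_identical(got$filtersFailed[[4L]],
                     "no_inter_sample_polymorphism")
    expect_identical(got$pass, rep(FALSE, 4L))
    ok <- applyFilters(data.frame(majorCount = 20L, minorCount = 15L,
                                  depthTotal = 90L, flank = 101L,
                                  quality = 0.999, interContrast = TRUE),
                       3L, p)
    expect_true(ok$pass)
})

test_that("isolation removes both members of a close pair, boundary at 30", {
    mk <- function(pos) data.frame(contig = "c1", pos = pos,
                                   contigLength = 2000L)
    close <- isolationFilter(mk(c(200L, 220L)), 30L)
    expect_identical(close$isolated, c(FALSE, FALSE))
    apart <- isolationFilter(mk(c(200L, 230L)), 30L)
    expect_identical(apart$isolated, c(TRUE, TRUE))
    expect_identical(apart$isolation, c(30L, 30L))
    lone <- isolationFilter(mk(200L), 30L)
    expect_true(lone$isolated)
    expect_identical(lone$isolation, 2000L)       # bounded sentinel
    ## middle of three: nearest neighbour decides, both near ones go
    trio <- isolationFilter(mk(c(100L, 120L, 300L)), 30L)
    expect_identical(trio$isolated, c(FALSE, FALSE, TRUE))
})

test_that("ts/tv partitions the six unordered base pairs 2:4 and is symmetric", {
    expect_identical(tsTv("A", "G"), "ts")
    expect_identical(tsTv("C", "T"), "ts")
    pairs <- combn(c("A", "C", "G", "T"), 2L)
    cls <- vapply(seq_len(ncol(pairs)),
                  function(i) tsTv(pairs[1L, i], pairs[2L, i]), character(1L))
    expect_identical(sum(cls == "ts"), 2L)
    expect_identical(sum(cls == "tv"), 4L)
    rev <- vapply(seq_len(ncol(pairs)),
                  function(i) tsTv(pairs[2L, i], pairs[1L, i]), character(1L))
    expect_identical(cls, rev)
    expect_error(tsTv("A", "A"), "distinct")
})

test_that("class codes concatenate per-sample statuses in panel order", {
    panel <- GenotypePanel(c("g1", "g2", "g3"))
    expect_identical(classifyCode(c("P", "M", "M"), panel), "PMM")
    expect_identical(classifyCode(c("N", "P", "M"), panel), "NPM")
    expect_identical(classifyCode(c("M", "M", "M"), panel), "MMM")
    expect_error(classifyCode(c("P", "M"), panel), "one status per")
    expect_error(classifyCode(c("P", "M", "X"), panel), "M, P or N")
})

test_that("callSnps emits a planted contrast and enforces its invariants", {
    samples <- c("g1", "g2", "g3")
    panel <- GenotypePanel(samples)
    set.seed(21)
    ctg <- randomContigs(1L, 1000L)
    L <- 1000L
    entries <- list()
    ## background: depth 12 of the reference base everywhere for all samples
    base <- strsplit(as.character(ctg[[1L]]), "", fixed = TRUE)[[1L]]
    pu <- ContigPileup("c1", L, samples)
    cnt <- pileupCounts(pu)
    bi <- match(base, c("A", "C", "G", "T"))
    for (s in 1:3) cnt[cbind(bi, seq_len(L), s)] <- 12L
    ## a clean inter-sample contrast at 500: g1 het, g2 ref, g3 alt
    ref <- base[500L]; alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    ri <- match(ref, c("A", "C", "G", "T")); ai <- match(alt, c("A", "C", "G", "T"))
    cnt[ri, 500L, 1L] <- 6L; cnt[ai, 500L, 1L] <- 6L
    cnt[ai, 500L, 3L] <- 12L; cnt[ri, 500L, 3L] <- 0L
    ## a close pair at 700/715 that isolation must remove
    for (p in c(700L, 715L)) {
        rp <- match(base[p], c("A", "C", "G", "T"))
        ap <- setdiff(1:4, rp)[1L]
        cnt[ap, p, 2L] <- 12L; cnt[rp, p, 2L] <- 0L
    }
    pu@counts <- cnt
    res <- callSnps(list(c1 = pu), ctg, panel)
    expect_identical(GenomicRanges::start(res$snps), 500L)
    m <- S4Vectors::mcols(res$snps)
    expect_identical(substr(m$classCode, 1L, 1L), "P")
    expect_true(all(m$minorCount >= 10L))
    expect_true(all(m$flank >= 100L))
    expect_false(any(grepl("^M*$", m$classCode) &
                     m$refAllele == m$altAllele))
    ## the removed pair is recorded as non-isolated candidates
    candPos <- res$candidates$pos[res$candidates$isolated %in% FALSE]
    expect_setequal(candPos, c(700L, 715L))
})

test_that("snpSummaries computes density, rollups and the ts/tv partition", {
    panel <- GenotypePanel(c("g1", "g2", "g3"))
    ctg <- Biostrings::DNAStringSet(
        c(k1 = strrep("ACGT", 500), k2 = strrep("ACGT", 750)))  # 2kb + 3kb
    gr <- GenomicRanges::GRanges(rep(c("k1", "k2"), c(4L, 6L)),
                                 IRanges::IRanges(seq(200L, 1100L, 100L),
                                                  width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        refAllele = "A", altAllele = "G",
        tstv = rep(c("ts", "tv"), c(7L, 3L)),
        classCode = c("PMM", "MPM", rep("MMM", 8L)))
    s <- snpSummaries(gr, ctg, panel)
    expect_identical(s$nSnps, 10L)
    expect_identical(s$densityPerKb, 2.0)         # 10 SNPs over 5 kb
    expect_identical(s$meanSnpsPerContig, 5.0)
    expect_identical(s$tsCount + s$tvCount, 10L)
    expect_identical(s$tsPercent, 70)
    ## sample g1 saw P (k1) and M (both): k1 bucket M+P, k2 bucket M
    expect_identical(unname(s$perSampleRollup["g1", c("M+P", "M")]),
                     c(1L, 1L))
    z <- snpSummaries(GenomicRanges::GRanges(), ctg, panel)
    expect_identical(z$nSnps, 0L)
    expect_identical(z$densityPerKb, 0)
})

test_that("genotype membership partitions contigs into presence cells", {
    samples <- c("g1", "g2", "g3")
    panel <- GenotypePanel(samples)
    mk <- function(ctg, present) {
        pu <- ContigPileup(ctg, 100L, samples)
        cnt <- pileupCounts(pu)
        for (s in match(present, samples)) cnt[1L, 10L, s] <- 3L
        pu@counts <- cnt
        pu
    }
    pus <- list(c1 = mk("c1", samples), c2 = mk("c2", c("g1", "g3")),
                c3 = mk("c3", "g2"), c4 = mk("c4", samples))
    got <- genotypeMembership(pus, panel)
    expect_identical(unname(got$sharing["g1+g2+g3"]), 2L)
    expect_identical(unname(got$sharing["g1+g3"]), 1L)
    expect_identical(sum(got$sharing), 4L)
})
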