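## Build small pileups by hand for SNP-caller tests.
## entry layout: list(c(sample, pos, "A=12,G=3"), ...)
makePileup <- function(contig, L, samples, entries = list()) {
    pu <- ContigPileup(contig, L, samples)
    cnt <- pileupCounts(pu)
    for (e in entries) {
        s <- match(e$sample, samples)
        for (b in names(e$counts))
            cnt[match(b, c("A", "C", "G", "T")), e$pos, s] <- e$counts[[b]]
    }
    pu@counts <- cnt
    pu
}

## Put count n of `base` for every sample at position pos.
addSite <- function(entries, samples, pos, perSample) {
    for (s in names(perSample))
        entries[[length(entries) + 1L]] <- list(sample = s, pos = pos,
                                                counts = perSample[[s]])
    entries
}

randomContigs <- function(n, L, prefix = "c") {
    seqs <- vapply(seq_len(n), function(i) randomSeq(L), character(1L))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0(prefix, seq_len(n))
    out
}
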