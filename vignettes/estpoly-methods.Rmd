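---
title: "Methods: models, thresholds and design choices in estpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in estpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estpoly)
```

`estpoly` discovers three classes of candidate markers in multi-genotype EST
assemblies: microsatellites (SSRs), consensus indels (including candidate
polymorphic SSRs), and SNPs.  This vignette explains the models and the
decisions behind them; it states nothing the package's tests and acceptance
script do not themselves compute.

## Coordinates

All internal coordinates are 1-based closed, the IRanges/GRanges convention,
and loci are GRanges objects throughout.  VCF and GFF3 exports are 1-based as
those formats require, so no shift is applied at the boundary; tests verify
that coordinates parsed back from VCF/GFF3 by independent readers
(VariantAnnotation, rtracklayer) equal the internal positions exactly.

## SSR mining

A perfect SSR is a maximal uninterrupted run of a primitive 2–6 nt motif.
The class minima (`SsrRules()`) are ≥ 6 repeat units for dinucleotides, ≥ 4
for trinucleotides, ≥ 3 for tetra-, penta- and hexanucleotides, so the
shortest admissible locus is `min(2·6, 3·4, 4·3, 5·3, 6·3) = 12` nt
(`minAttainableSsrLength()`).  Mononucleotide runs are excluded by
construction: a period-1 word is never a primitive 2–6-mer.

Decisions where the field's tools differ and we had to pick one:

* **Canonical motif.** Loci are reported under the lexicographically
  smallest rotation of the motif's primitive root.  The reverse complement
  is *not* folded in (AG ≠ CT): transcript strand is meaningful in ESTs.
* **Partial units.** A trailing partial unit never counts: a locus spans
  exactly `repeats × motifLength` bases.
* **N handling.** Runs break at `N`; each fragment is evaluated
  independently.
* **Overlap resolution.** Overlapping candidate runs of different motif
  classes are resolved greedily — longest span first, ties to the leftmost
  start, then the shortest motif.  This is deterministic and is applied
  identically in the brute-force reference scanner, so the two can be
  compared exactly.  A visible consequence at motif junctions: in
  `…ACACAC|AGCAGC…` the maximal period-3 run starts one base early (on the
  `C`), overlaps the dinucleotide locus, and loses the tie — the scan is
  still deterministic and matches the reference scanner.
* **Compound repeats.** Chains of perfect loci with inter-locus gaps ≤ 10 nt
  (boundary inclusive) merge into compound loci; singleton chains stay
  perfect, and components are kept in order.  Interrupted repeats are not
  modelled as single loci; they surface only through compound merging.

The scanner is validated two ways: a property suite (class minima,
primitivity, exact widths) and exact locus-set equality against an
independent brute-force scanner that tests every (start, motif length) by
unit-by-unit extension — 1,000 seeded random 1-kb sequences in the
acceptance suite.

## Indels and candidate polymorphic SSRs

Input is one gapped alignment of per-genotype consensus sequences per
contig.  A gap event is a maximal run of columns whose set of gapped rows is
constant, non-empty and a *proper* subset of rows (an all-row gap would be
an alignment artifact and is rejected by the container's validity).  An
event is emitted when its length is within 3–50 nt and at least 25 columns
that are gap-free **in every row** border it on each side.  Readings we
fixed where the rule text is open:

* Flanks must be gap-free but may contain substitutions — those are SNPs and
  are handled by the SNP caller, not the indel detector.
* Two distinct gap events closer than 25 columns reject each other: the
  flank requirement applies between them.  Conservative and deterministic.
* The reference frame is the first row in panel order; its ungapped
  coordinates define contig positions.  A deletion spans the deleted
  reference bases; an insertion (gap in the reference row) is anchored at
  the preceding reference base.
* Whether flanks must be *identical* across genotypes is not required —
  only gap-free.

An indel overlapping an SSR locus by ≥ 1 nt becomes a candidate polymorphic
SSR; `inFrame` records whether its length is a multiple of the motif length
(for compound loci, the component with the largest overlap).  Both in-frame
and out-of-frame events are reported with the flag, since restricting to
in-frame differences is a downstream choice.  The report's per-sample allele
lengths are counted directly from the alignment (non-gap characters over the
union of the SSR's and the indel's columns), so the allele difference always
equals the indel length.

## SNP calling

Pileups are per-position, per-genotype base counts (`ContigPileup`), built
from tagged SAM reads (bases under the Phred cutoff, default Q20, and Ns are
never counted; indel-containing reads contribute only matched bases) or from
a bit-exact TSV dialect that keeps tests free of binary files.  The decision
trail for the defaults that are *not* forced by the filter cascade:

* **Site alleles** are the top two pooled counts, ties broken
  alphabetically; third and fourth alleles stay in depth but are never
  promoted.
* **Quality model.** The cascade needs a "quality ≥ 0.99" semantic.  We use
  a two-hypothesis Bayesian posterior with equal priors on the pooled
  top-two counts: H0, monomorphic with per-base error `e` spread uniformly
  over the three alternatives; H1, balanced biallelic with per-read
  probability `(1−e)/2 + e/6` for each allele.  It is simple, exact,
  monotone in the minor count at fixed depth, and is checked against an
  independent product-arithmetic oracle to 1e-9 over the exhaustive grid of
  top-two counts with depth ≤ 100.  Default `e = 0.01`.
* **Average coverage** means total site depth divided by panel size
  (default threshold 10).  Sites with total depth ≥ 20 additionally carry a
  `deepCovered` flag, since a 20× depth reading of "coverage" is equally
  defensible; the flag lets users reproduce either convention.
* **Within-sample status.** A sample is `N` below 5 reads; `P` when its
  second-ranked site allele has ≥ 4 reads *and* ≥ 20% of the sample depth;
  otherwise `M`.  These three knobs (`minSampleDepth`, `withinMinorCount`,
  `withinMinorFrac`) are exposed because no published rule exists; the
  defaults are robust across the 10–60× transcript depths the generator
  emulates.
* **Inter-sample polymorphism.** A site is a SNP only with ≥ 1 `P` sample or
  ≥ 2 `M` samples of differing major alleles; an all-`M`-same-allele site is
  no polymorphism at all.
* **Isolation** (≥ 30 nt) removes *both* members of a close pair — symmetric,
  hence order-independent — and is computed over the candidates that passed
  the allele-coverage filters, before the quality cut.  A lone candidate's
  isolation is reported as its contig length (a bounded sentinel).
* **REF allele** in VCF is the pooled major allele: ESTs have no external
  reference genome.
* **Density denominator.** `snpSummaries()` divides by the summed length of
  SNP-*bearing* contigs.  The alternative (all contigs) is equally
  plausible; the choice is stated here precisely because the number is
  sensitive to it.

## The synthetic-data generator

`simConfig()` defaults describe the emulated study design: 100 contigs of
2 kb; a three-sample panel with one pooled heterozygous sample
(minor-haplotype fraction 0.5, emulating a RIL pool) and two inbred-like
samples (heterozygosity 0); planted biallelic SNPs at 1.36 per kb with ≥ 60
nt spacing and ≥ 110 nt edge margin; two consensus indels per contig with
lengths uniform on 2–55 nt, deliberately straddling the 3–50 detector
bounds; SSR tracts per motif length with repeat counts from the class
minimum up to minimum + 6; 40× mean per-sample depth; 0.5% per-base error;
constant Q30 base quality.  The seed is mandatory and identical
configurations are byte-identical.

What it emulates faithfully: genotype-partitioned coverage, the
heterozygosity contrast between a pool and inbreds, sequencing error as
uniform base flips, exact truth coordinates for every planted feature
(SSR tract boundaries are guarded so each tract is exactly the maximal run
the scanner should report).  What it does **not** emulate: realistic
Illumina error profiles or quality decay, full-length reads (reads are
independent per-position draws — sufficient because every downstream
computation is columnar; a SAM writer with 1-base reads exercises the
alignment interface), expression-level coverage variation, insertions
relative to the reference row (indels are planted as carrier deletions; the
detector itself handles both directions and is tested on both), and any
transition/transversion bias (alternative alleles are uniform, so the
simulated ts share is ~1/3 rather than the ~2/3 typical of real
transcriptome data).  Passing the closed-loop tests therefore demonstrates
algorithmic correctness under the stated model, not robustness to real
library artifacts.

### Truth-closure evaluation and what "recall" means

`evaluateSnpCalls()` re-evaluates the full filter cascade on each planted
site using the truth-known alleles and the realized counts, and calls a site
*eligible* when all thresholds pass.  Recall over the eligible set tests the
caller's wiring and must be perfect up to implementation error; it is the
quantity held to ≥ 0.99.  Recall over *all* planted sites is lower by
construction: a pool-only heterozygous site has a true pooled minor fraction
near 1/6 (one heterozygous sample among three), and at ~120× pooled depth
its realized minor count falls below the balanced-biallelic 0.99-posterior
decision boundary in a noticeable fraction of draws.  That shortfall is a
property of the quality model at these study conditions, not of the
implementation, so both numbers are computed and reported
(`snp_recall_eligible`, `snp_recall_all_planted` in the acceptance output).

## Problem sizes and runtime

The test and acceptance workloads are sized for a single CPU: the oracle
equivalence suite uses 1,000 random 1-kb sequences; the quality-model grid
is exhaustive to depth 100; the planted-truth run uses the full default
configuration above (100 contigs × 2 kb × 3 samples at 40×).  The whole
suite completes in a few minutes.

## Known limitations

* Imperfect (interrupted) repeats are not modelled as single loci.
* The caller is strictly biallelic per site; triallelic sites keep only the
  top two alleles.
* Indels are called from consensus alignments only, never from reads.
* The quality model treats reads as independent Bernoulli draws; it does not
  model mapping error, strand bias or base-quality heterogeneity.
* `genotypeMembership()` counts aligned bases as the presence signal, which
  equals read counts only for single-base reads; for longer reads it is an
  upper bound on per-read presence.
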