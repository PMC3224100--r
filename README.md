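# estpoly

Marker discovery in multi-genotype EST assemblies: SSR mining, consensus
indel detection and multi-sample SNP calling, with a seeded synthetic-data
generator that closes the loop against planted truth.

## The problem

De novo assembled transcriptome (EST) contigs built from reads of several
genotypes — for example a pool of recombinant inbred lines alongside inbred
accessions — are a rich substrate for co-dominant molecular markers, even in
species without a reference genome. `estpoly` implements the three marker
classes such projects mine, for people who need the computational side of an
EST marker pipeline to be reproducible and testable:

* **EST-SSRs** — perfect microsatellites of 2–6 nt motifs with the
  conventional class minima (≥ 6 repeat units for dinucleotides, ≥ 4 for
  trinucleotides, ≥ 3 for tetra-/penta-/hexanucleotides; the shortest
  admissible locus is therefore 12 nt).  Adjacent loci ≤ 10 nt apart are
  merged into **compound repeats**.  Motifs are reported in canonical form:
  the lexicographically smallest rotation of the primitive root, with strand
  preserved.
* **Candidate polymorphic SSRs and indels** — gaps between per-genotype
  consensus sequences in gapped per-contig alignments.  A gap run carried by
  a proper subset of genotypes is emitted when its length is 3–50 nt and at
  least 25 gap-free columns flank it on each side; indels overlapping an SSR
  locus are flagged, with an in-frame test (length divisible by the motif
  length).
* **SNPs** — biallelic sites from genotype-partitioned pileups, passed
  through a filter cascade: pooled coverage ≥ 10 for each of the two most
  abundant alleles, average coverage (total depth / panel size) ≥ 10,
  flanking length ≥ 100 nt, posterior quality ≥ 0.99 and absolute isolation
  ≥ 30 nt (both members of a closer pair are removed).  Each site is
  classified per genotype as intra-sample **M**onomorphic, **P**olymorphic
  or **N** (insufficient depth, < 5 reads), concatenated in panel order into
  class codes such as `PMM`, and tallied into transition/transversion and
  density summaries.

The site quality is a two-hypothesis Bayesian posterior on the pooled counts
(n₁, n₂) of the top-two alleles with per-base error rate *e*:

    H0 (monomorphic):       L0 = (1 − e)^n₁ · (e/3)^n₂
    H1 (balanced biallelic): L1 = p^(n₁+n₂),  p = (1 − e)/2 + e/6
    quality = L1 / (L0 + L1)        (equal priors)

## Worked example

Everything below is computed from the package's own seeded simulator, so it
reproduces exactly:

```r
library(estpoly)

cfg <- simConfig(nContigs = 20L, seed = 7L)   # 3 genotypes: 1 pool + 2 inbreds
sim <- simulatePanel(cfg)                     # contigs + planted truth
pus <- simulatePileup(sim, cfg)               # 40x pileups, 0.5% error

res <- callSnps(pus, sim$contigs, sim$panel)
s   <- snpSummaries(res$snps, sim$contigs, sim$panel)
s$nSnps              # 39 SNPs in 16 contigs
s$meanSnpsPerContig  # 2.44
s$densityPerKb       # 1.22 SNPs per kb of SNP-bearing contig
s$classHist          # PMM 26, MMM 13
```

The most abundant class code is `PMM`: polymorphic within the heterozygous
pool sample, monomorphic-but-contrasting in the two inbreds — exactly the
pattern a pooled-RIL + inbred panel is designed to reveal.  A called record
looks like:

```
  seqnames  ranges | refAllele altAllele majorCount minorCount quality flank tstv classCode
  contig001    923 |         A         T         74         52       1   922   tv       PMM
```

SSRs and the recovery loop:

```r
ssrs <- mergeCompound(findPerfectSsrs(sim$contigs))
ssrSummary(ssrs)$byMotifLength   # 2:6 -> 6 7 3 1 1 (trimers most abundant)

ev <- evaluateSnpCalls(sim, pus, res$snps)
ev$recallEligible                # 1 (all threshold-satisfying planted SNPs called)
ev$precision                     # 1 (no calls off the planted truth)
```

`writeSnpVcf()`, `writeSsrGff3()` and `polymorphicSsrReport()` export VCF
v4.2, GFF3 and TSV; `runPipeline()` wires all stages from a YAML run config,
and `inst/scripts/estpoly.R` wraps it for the shell.

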