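---
title: "Methods: disambiguating and characterizing transcribed pseudogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disambiguating and characterizing transcribed pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoshadow)
```

## The problem

A pseudogene is a genomic copy of a functional gene that has lost its
coding capacity. Because the copy is typically 80–99% identical to its
parent, short RNA-Seq reads that genuinely originate from the parent can
align perfectly well to the pseudogene, and the bias is systematic rather
than random: an exon–exon junction read from the parent cannot be placed
contiguously at the intron-bearing parent locus, but aligns contiguously —
and therefore often *better* — on an intronless processed pseudogene.
Naive quantification consequently overcalls pseudogene transcription, most
severely for the youngest, highest-identity copies.

`pseudoshadow` implements the read-level remedy and the analyses built on
top of it:

1. **Read filtering.** Collect every genome-mapped read overlapping a
   pseudogene exon block by ≥ 1 bp, realign it against all coding cDNAs,
   and keep it as a pseudogene read only when its mismatch count at the
   pseudogene is *strictly smaller* than its best mismatch count on any
   cDNA. All other records at pseudogene loci are deleted from the
   alignment stream; records elsewhere pass through untouched.
2. **Quantification.** Union-exon FPKM
   (count / (exon kb × mapped fragments in millions)) with a strict
   `> 1` FPKM transcribed call (`> 10` for "highly transcribed").
3. **Diagnostics.** The identity-window quality check tiles each
   pseudogene–parent alignment with 200-bp windows and correlates per-window
   percent identity with the number of reads starting in the window.
   Leakage from the parent produces a positive correlation; successful
   filtering removes it.
4. **Characterization.** Jensen–Shannon tissue specificity, Spearman
   correlation of pseudogene and parent tissue profiles, the eight-vs-eight
   tissue split, strand inference, small-RNA production classes, ChIP tag
   densities and anchored meta-profiles, nucleotide diversity, and mean
   conservation.

## Decisions at the boundaries

Several boundary cases are not dictated by the scientific definition of the
filter; the package resolves them explicitly and tests each one:

* **Ties.** A read with equal mismatch counts to the pseudogene and to some
  cDNA is ambiguous; it is **removed**. This keeps the filter conservative:
  pseudogene expression can be underestimated, never inflated by parent
  reads.
* **Competitor ceiling.** cDNA hits are searched up to 3 mismatches for
  ≤ 75-bp reads, emulating how short-read aligners bound their reporting.
  A read whose best cDNA placement exceeds the ceiling has *no competitor*
  and is kept (vacuously better).
* **Paired ends** are adjudicated per read; a fragment counts toward a
  pseudogene only if every aligned end survives.
* **Mapped total for FPKM** is taken *after* filtering, so the
  normalization reflects the alignment stream actually used for counting.
* **Fragment assignment.** A fragment overlapping several features goes to
  the feature with the greatest overlap, ties to the lexicographically
  smallest feature id — deterministic, order-independent counting rather
  than an isoform EM.
* **Distance groups** use an inclusive 20-kb cutoff (a gap of exactly
  20 kb is "near").
* **Strand calls** treat a lesser strand value at or below the expression
  floor (`min_expr`, default 0; 0.05 is exposed) as zero, so any
  expression against silence wins regardless of the 10× ratio.
* **Group I small-RNA pseudogenes** require *exactly zero* flank reads,
  not merely low flank density; the flank denominator is the realized
  (chromosome-truncated) flank length.
* **Nucleotide diversity** uses the plain frequency-weighted ordered-pair
  formula with no n/(n−1) correction by default (an `unbiased` flag adds
  it); sites with a missing call are excluded from both the numerator and
  the per-pair site total.
* **Spearman p-values** are exact permutation probabilities for n ≤ 8
  tissues and the t-transform (n − 2 df) otherwise; the identity-window
  Pearson p uses the same t-transform. Fewer than three usable windows, or
  zero variance, yield an explicitly *undefined* correlation — never a
  silent zero.

## The synthetic-data generator

Every analysis stage is exercised end-to-end on data the package generates
itself, with full ground truth:

* `build_toy_genome()` lays out intron-bearing genes and pseudogene copies
  on one chromosome. Processed pseudogenes are single-block copies of the
  spliced parent transcript; duplicated pseudogenes copy the locus with
  introns; unitary pseudogenes have no parent. Divergence is by random
  substitutions only (no indels), so mismatch counts are exact without
  realignment, and the realized identity is recorded per copy (within ±2
  percentage points of target for loci ≥ 500 bp).
* `simulate_rnaseq_reads()` plants exactly the two leakage mechanisms the
  filter must defeat: junction reads whose best genomic placement is the
  processed pseudogene, and uninformative reads (no diverged site in the
  span) whose genomic tie is broken by a seeded coin flip, mirroring random
  placement of multi-mappers. Each read's true origin and informative-site
  count are recorded. cDNA competitor hits are produced by an exact
  seed-and-extend search (max_mismatch + 1 seeds, pigeonhole-complete up to
  the mismatch ceiling).
* `simulate_expression_profiles()` has two modes. In correlation mode it
  draws tissue profiles from a Gaussian copula with latent Pearson
  correlation `2·sin(πρ/6)` — the classical value making the population
  Spearman correlation equal ρ — and log-normal FPKM marginals (rank
  preserving, hence unbiased recovery). In specificity mode profiles are
  one-hot/uniform mixtures whose weight is solved numerically for the
  requested JS score. The two plantings are alternatives: jointly fixing a
  profile's specificity *and* its rank correlation with a partner is
  over-determined, so `planted_js` takes precedence when given.
* `simulate_srna_reads()`, `simulate_chip_tags()` and
  `simulate_population_haplotypes()` plant, respectively, group I/II
  flank structure with group-specific length medians, Poisson tag counts at
  fold × background inside anchor windows, and segregating sites whose
  expected per-site diversity matches the target
  ((n−1)/(2n) per site at allele probability ½).

Default study conditions are 16 tissues, 50-bp single-end reads, and
pseudogene identities in the 0.80–0.95 range where most annotated human
pseudogenes fall — high enough that misassignment is a real hazard, low
enough that a 50-bp read usually carries several informative sites.

What the generator does **not** emulate: realistic error models or quality
strings, GC and positional bias, isoform mixtures, indel divergence,
repeat-induced multi-mapping beyond the parent–pseudogene pair, and linkage
structure in haplotypes. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed under
controlled conditions — not that real-data accuracy matches any published
figure.

## Numerical choices

* Coordinates are 0-based half-open everywhere inside the package; BED is
  written as stored, SAM positions convert at the boundary.
* Jensen–Shannon divergence uses base-2 logarithms with 0·log 0 ≡ 0; the
  score is `1 − sqrt(JSD)` maximized over one-hot extremes (reached at the
  argmax tissue), so one-hot profiles score exactly 1 and scoring is
  invariant to profile scaling. All-zero profiles are excluded with a flag.
* Poisson and binomial enrichment p-values are upper tails,
  `P(X ≥ k)`, computed with R's stable distribution functions.
* Medians of even-sized small-RNA length sets use the lower of the two
  middle values, so reported medians are always observed read lengths.
* One top-level seed; every stochastic operation derives its own stream as
  a multiplicative hash of seed and operation label (`derive_seed()`), so
  adding a stage never perturbs another stage's draws. Equal-mismatch
  placement ties in the simulator are resolved by a draw from the same
  derived stream, keeping runs byte-reproducible.
* Problem sizes in the shipped tests and acceptance script (2,000–13,000
  reads, 1,000 correlation pairs, 100 ChIP loci, haplotype panels of ≤ 20)
  were chosen so that brute-force oracles — exhaustive Hamming scans over
  all offsets, all-pairs diversity enumeration, direct tail summations —
  remain feasible companions to every fast implementation.

## Known limitations

* The filter operates on mismatch counts as given in the alignment records;
  indel-containing alignments are out of scope (the generator produces
  none, and real input would need its `NM` semantics checked).
* Union-exon FPKM deliberately ignores isoform structure; expression of
  genes with strong isoform switching is summarized, not resolved.
* Strand inference assumes the strand of pseudogene transcription is
  consistent across samples and that a 10× ratio separates genuine
  dominance from noise; calls near the expression floor are the least
  reliable.
* With a single cDNA competitor ceiling, a parent read with sequencing
  errors at its informative sites can still slip through; error rates well
  above ~1% per base would erode the filter's guarantees.
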