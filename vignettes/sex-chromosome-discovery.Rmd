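---
title: "Detecting sex chromosomes from k-mers and pooled allele counts"
author: "sexlinker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex chromosomes from k-mers and pooled allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinker)
```

## The problem

In many fish lineages sex chromosomes are young: the X and Y (or Z and W)
differ by scattered substitutions across a non-recombining region rather
than by anything visible cytologically, and the sex-determining region can
sit on a different chromosome even between congeneric species. Detecting
such systems from short-read data is a comparison between the sexes: the
heterogametic sex carries a haplotype (Y or W) the other sex lacks, so
male and female read sets differ in predictable ways.

`sexlinker` implements two complementary detection routes plus the
cross-species machinery to orient turnovers between systems:

1. **Sex-specific k-mers (reference-optional).** Canonical k-mers are
   counted per sex; k-mers observed in one sex and absent in the other tag
   heterogametic-haplotype variants. Only when spatial information is
   wanted are these k-mers placed on a reference.
2. **Sex-patterned SNPs (reference-based).** From pooled allele counts at
   every reference position, sites where one pool is fixed and the other
   carries a pool-private allele at intermediate frequency are classified
   XY- or ZW-patterned, and their per-window density drives a genome-wide
   rank screen.

## The k-mer route

### Counting and set algebra

Reads are decomposed into overlapping k-mers; each k-mer is stored under
its canonical form (the lexicographic minimum of the k-mer and its reverse
complement), which makes counting strand-independent. Two parameters
matter:

* `k = 22` bp (default; supported range 1–32). Small enough that
  low-coverage data still observes most k-mers twice, large enough that a
  random 22-mer is effectively unique in a vertebrate-sized genome; larger
  k also inflates error k-mers and species-private differences in
  cross-species comparisons.
* `minCount = 2`. A k-mer seen once is more likely a sequencing error than
  a real variant at 6–20× coverage; requiring two occurrences removes the
  bulk of error k-mers while keeping true k-mers, whose expected count at
  these coverages is well above 2. No higher stringency is applied, since
  at ~6× per haplotype a stricter cutoff starts discarding genuine
  sex-limited k-mers.

Sex-specific sets are the two set differences between the per-sex tables
(`diffKmerSets`), computed as a merge over lexicographically sorted keys.
Downstream steps consume presence only; counts are retained in the
`KmerCountTable` but not used after the cutoff. For mapping, a fixed-size
uniform subsample (`sampleKmers`, default 10^6, seeded and
order-independent) keeps runtime flat across datasets. The multi-species
"core" region of a shared system is the intersection of the per-species
sex-specific sets (`intersectCore`).

### Placement and enrichment

`indexReference` records every canonical reference k-mer with its first
occurrence and a multiplicity flag — an exact-match surrogate for a
short-task BLAST database. `mapKmers` looks queries up exactly and then,
by default, tries all single-base substitution neighbours
(`maxMismatch = 1`). The neighbour step is essential, not cosmetic: a
k-mer that is sex-specific *because* it carries a variant differs from the
reference at that variant by construction, so pure exact matching would
discard precisely the signal k-mers (a short-read BLAST at e ≤ 1e-3
tolerates such single mismatches, which is why the real-data workflow
works). Queries with no placement are reported as an unmapped count —
they correspond to sequence diverged beyond one substitution or absent
from the reference. A BLAST tabular import (`importBlastHits`, best
bit-score per query, identity ≥ 90 %, alignment ≥ 16 bp by default) is the
fidelity path for users who ran real BLAST.

Per-linkage-group hit counts are normalized to hits per Mb
(`lgEnrichment`). The sex call (`callSexLinkageGroup`) formalizes "one sex
features many more k-mers on one linkage group": each LG's normalized
count is divided by the median across LGs for that sex, and the maximal
fold wins if it reaches `foldThreshold = 3`; male excess calls XY, female
excess ZW. Linkage groups shorter than `minLgLength` (default 1 Mb;
unplaced scaffolds) are kept as callable but excluded from the median, and
when fewer than two LGs pass the floor all are used.

### Differentiated blocks

`callBlocks` delimits the differentiated region algorithmically. Windows
(default 100 kb) are scored by the *minimum number of point variants that
explain their hits*, `ceiling(hits / k)`, and marked when the score
reaches `minFold = 5` times the genome-wide median window score. The
threshold is floored at one variant and at `1/minFold` of the peak
window score: with sparse noise the median occupancy sits near the 0/1
knife edge, and a zero median must not let isolated single-variant
windows chain into blocks. Marked windows separated by at most `mergeGap = 1`
unmarked window merge; a block runs from its first marked window to its
last hit start + k. The ceiling transform matters: a single sequencing
error that survives the count cutoff produces up to k clustered hits in
one window — raw hit counts would let one duplicated error mark a window,
and empirically this inflated the estimated span by ~0.2 of a chromosome.
Under the variant score such an artifact scores 1 and cannot clear the
threshold. The reported `coverageFraction` (total block span over LG
length) is the statistic behind "the sex-determining region covers ~77 %
of the chromosome".

## Turnover polarity

For two species carrying different systems on the same linkage group, the
four intersections between their sex-specific sets (`crossShareTable`)
carry the turnover's direction. If the derived species' X and Y both
descend from the ancestral W, then the ancestral W-specific k-mers are
shared most with the derived female-specific (X) set and second-most with
the derived male-specific (Y) set. `inferPolarity` implements the general
form: the gametolog common to the two largest cells is the ancestral
chromosome, provided the largest cell beats the runner-up, and the
runner-up beats the rest, by `minDominance = 2` (below that the call is
indeterminate rather than forced).

`estimateSnpsFromKmers` converts a k-mer total to a SNP estimate by
dividing by k — an isolated substitution creates exactly k overlapping
sex-specific k-mers — rounding the quotient and reporting it at two
significant figures (the convention used for genome-scale totals: 10^6
22-mers ≈ 45,000 SNPs; 10^5 ≈ 4,500).

## The SNP route

`readSync` parses two-pool sync text (per-pool `A:T:C:G:N:del` counts;
female pool first by convention, reversible by flag); `pileupToSync`
builds the same table from pileup text, dropping base calls below PHRED
20 and consuming indel/read-boundary markers. N and deletion tallies
never enter frequency denominators.

Per-site pooled FST uses pool frequency vectors \(\hat p_i\):
\(H_S = \tfrac12\sum_i (1 - \sum_a \hat p_{i,a}^2)\),
\(H_T = 1 - \sum_a \bar p_a^2\) with \(\bar p\) the *unweighted* mean of
the two pools (pools, not read depths, are the sampling units),
\(F_{ST} = (H_T - H_S)/H_T\), defined 0 when \(H_T = 0\). Convexity gives
\(F_{ST} \in [0, 1]\).

`classifySexSnp` calls a site XY-patterned when the female pool is fixed
(major-allele frequency ≥ `fixedThreshold`, default 1.0) and the male pool
carries a female-absent allele at frequency in `hetRange` (default
[0.3, 0.7]); ZW is the mirror; either pool below `minDepth = 5` (A/C/G/T
depth) is unclassified, as are sites with more than two segregating
alleles. "Segregating" means a pooled count of at least 2: a singleton
count is treated as the sequencing-error floor (it still enters depths,
frequencies and the fixed-pool test). At depth 20 and error rate 0.002 a
strict any-singleton rule would veto ~4 % of genuine sites for a lone
mis-called base, pushing recovery of planted sites below what the same
data support. A site satisfying both directions at once (possible only in
threshold corner cases) is ambiguous and unclassified, which keeps the
classification exactly symmetric under pool swap. The thresholds follow
the conventions of existing sex-SNP detectors; none are stated by the
underlying analyses we emulate, so all are configuration keys.

## The window screen

`makeWindows` tiles each LG into half-open windows (default 100 kb,
partial tail kept). Each classified SNP increments exactly one window;
the per-window statistic is `log2((xy + 1)/(zw + 1))`. The pseudocount of
1 keeps the many zero-count windows finite and at log-ratio 0; such
windows are retained by default (a flag drops them) so that chromosomes
are compared over their full length.

Chromosome-level inference is rank-based: a tie-corrected Kruskal–Wallis
test across LGs, Dunn's pairwise post-hoc with Benjamini–Hochberg
correction across all pairs, and a median-rank diagnostic in which all
windows are ranked genome-wide with ties broken in input order (the
"first" rule — deliberately different from the mid-ranks used inside the
tests, and specified that way for this diagnostic only) and each LG
reports the median of its windows' ranks. A high-outlier median rank
suggests XY differentiation, a low outlier ZW. When several species are
screened, each species' Dunn family is corrected independently. Text
output floors printed p-values at "< 2.2e-16"; the numeric values are
kept in the returned objects and TSVs.

## The simulator

`simulateGenome` draws i.i.d. bases (GC 0.4, typical for teleosts);
`plantSexSystem` plants a sex-determining region by substituting the
sex-limited haplotype at rate `d` within a region (positions uniform
without replacement, so the planted SNP count is Binomial(span, d));
`simulatePoolReads` draws 150-bp single-end reads uniformly from each
sex's two haplotypes at a chosen pool coverage with uniform substitution
errors (0.002), emitting constant-Q30 qualities, or Q10 at error sites in
the error-marking mode used to exercise the PHRED filter;
`simulateSync` emits per-site pooled counts directly (heterogametic pool
Binomial(depth, 0.5) at planted sites, homogametic fixed, shared
background polymorphism at a configurable rate); `simulateTurnover`
layers divergence for the polarity analysis.

What the simulator emulates — and what it does not: substitution-only
divergence, uniform coverage, identical pool members, no recombination
map, no indels, inversions, repeats or paralogy, no insert-size
structure. Passing the recovery tests therefore demonstrates that the
statistics behave as designed under their own model assumptions; on real
data, repeats and structural variation add multi-mapping k-mers and
alignment artifacts that the multiplicity flag, the variant-score window
marking and the BLAST import filters mitigate but cannot remove.

### Why the turnover simulation needs finite coverage

Under perfect observation an XY species has *no* female-specific k-mers:
males carry an X, so every X k-mer is present in both sexes. What creates
observable X-specific k-mers in practice — and in the single-individual
data this design emulates — is coverage dropout: k-mers on a single-copy
haplotype in one sex sit at half the pool coverage, and at ~6× per pool a
meaningful fraction fall below the two-occurrence cutoff in the other
sex. The turnover simulator therefore runs at 6× (the low end of the
emulated data) and gives the derived Y faster private divergence
(`dY = 0.02`) than the derived X (`dX = 5e-4`), reflecting the
degeneration of a non-recombining chromosome; the ancestral gametologs
differ at `dZW = 0.03`. With these defaults the simulated sharing table
reproduces the published ordering and magnitude ratio of the cells
(largest ≈ 3–4× the runner-up). The per-bp rates are deliberately larger
than genome-scale estimates because the simulated spans are kilobases,
not tens of megabases; it is the ordering dZW > dY ≫ dX and the
dropout regime that the conditions preserve.

## Problem sizes used by the test suite

The automated tests exercise every stage at desk scale, chosen so the
full suite runs in minutes on one core: planted-region recovery uses 10
linkage groups of 100 kb (region spanning 60 % of one LG, d = 0.01,
12× pools, 50 seeded replicates, 5-kb block windows), polarity recovery
50 turnover replicates on a 60-kb LG at 6×, the screen calibration 20 LGs
× 30 windows with background sex-patterned SNP counts Poisson(0.5) per
window, and the oracle comparisons run on ~10^5-key tables, a 10^5-bp
reference, all two-pool count tables to depth 12, and 10^5 label
permutations. Real vertebrate datasets are orders of magnitude larger;
the streaming k-mer engine (2-bit packed, sort-and-count) processes tens
of millions of read bases per second, but Jellyfish-class disk-backed
performance is out of scope.

## Numerical and degenerate-input choices

* Canonicalization compares bytes, never locale collation; sorted k-mer
  files are written in radix (C) order.
* `KmerCountTable`/`KmerSet` validity checks canonicality on a bounded
  probe of large objects to keep construction O(n) cheap.
* Zero-depth pools make FST undefined (`NA`, site skipped); `H_T = 0`
  defines FST = 0; tiny negative rounding noise is clamped.
* All-tied rank input defines H = 0, p = 1; Dunn pairs with zero standard
  error report z = 0.
* Equal BLAST bit-scores keep the first row (file order), matching how
  best-hit-only BLAST output is consumed.
* Ties among equally enriched LGs resolve by larger normalized count;
  infinite folds (zero median) outrank finite ones the same way.
* Every stochastic function takes a mandatory seed and restores the
  caller's RNG state, so library use never perturbs a session's RNG.

## Known limitations

* k ≤ 32 (one 64-bit word per k-mer); the emulated analyses use 21–31.
* Single-mismatch neighbour lookup recovers k-mers one substitution from
  the reference; doubly-diverged k-mers count as unmapped (the real-data
  path via BLAST import has the same behaviour at its identity floor).
* The sync parser expects exactly two pools; multi-pool designs must be
  reduced upstream.
* The pipeline's windows, blocks and screens all assume a reference with
  assembled linkage groups; on scaffold-level assemblies the fold
  statistics remain usable but spatial statements degrade with assembly
  contiguity.
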