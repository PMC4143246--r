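---
title: "Identifying allopolyploid genome donors from SSR genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying allopolyploid genome donors from SSR genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydonor)
```

## The problem

An amphidiploid (allotetraploid) species carries two complete diploid
genomes, one from each of two parental species. When a co-dominant SSR
marker amplifies **one** product in diploids but **two discrete products**
in the tetraploid, each product marks one homoeologous locus, so the two
products can be attributed to the two parental sub-genomes. Once every
tetraploid call is split into a sub-genome A and a sub-genome B allele, the
two sub-genomes can be treated as additional "diploid" genomes and compared
with the candidate donor species by ordinary population-genetic distance.
The donor of each sub-genome is then simply the diploid species at minimal
genetic distance — provided the partitioning itself is sound.

`polydonor` implements this chain end to end: EST-SSR mining, marker
screening, reference-anchored partitioning, multi-allelic diversity
statistics, Nei's DA distance with neighbor-joining trees and locus
bootstrap, PCoA, and a donor-call report, plus a simulator that generates
study-shaped data with full ground truth.

## Marker screening

Usable markers are identified on a small multi-taxon panel (default 2
accessions per taxon, `screening_panel()`), reflecting how such screens are
run in practice. `classify_marker()` is total and deterministic: each
marker receives exactly one category under the fixed precedence

`NOT_AMPLIFIED` > `AMPLIFIED_SOME` > `OVER_SIZE` (> 500 bp) >
`MULTIPLE_PRODUCTS` (> 2 products anywhere, or > 1 in a diploid) >
`MONOMORPHIC` > `SINGLE_IN_TETRAPLOID` > `TWO_IN_TETRAPLOID`.

Only `TWO_IN_TETRAPLOID` markers — one product in every diploid, two
discrete products in every tetraploid, polymorphic — enter the pipeline.
Screening on the *full* accession set would be both unfaithful to practice
and self-defeating: with hundreds of mostly-selfing accessions, almost
every marker eventually shows some residual heterozygote and would be
discarded as `MULTIPLE_PRODUCTS`.

## Partitioning into sub-genomes

The anchor is a diploid taxon already believed (from prior evidence) to be
one donor. Its observed allele set per marker forms the reference profile.
For a tetraploid call with products $s_1 < s_2$, let
$d(s) = \min_r |s - r|$ over reference alleles $r$; the product with the
smaller $d$ is scored A, the other B. "Same or very similar" is thus
operationalized as nearest-neighbor distance in base pairs — the only
information fragment analysis leaves. Ties are flagged (`status = "tied"`),
never silent: A is then the product whose minimizing reference allele is
numerically smaller, falling back to the smaller product size. Calls with a
single product are stored in both slots with `status = "single_product"`
and excluded from sub-genome frequencies by default — a single product may
be homoeolog homozygosity or allele dropout, and markers are pre-screened
to avoid it. Markers without reference data are excluded
(`status = "no_reference"`) rather than clustered unsupervised; the
procedure is anchor-based by design.

Because the anchor is itself a donor candidate, the donor report also ranks
candidates for each sub-genome with the anchor removed
(`call_no_anchor`), making any anchor-induced circularity visible.

## Statistics

For allele frequencies $p_i$ at one locus in one group:

* gene diversity $H = 1 - \sum_i p_i^2$ (optional $n/(n-1)$ correction,
  off by default — the plain form is what diversity software most often
  prints);
* PIC $= 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (Botstein
  convention); always $\mathrm{PIC} \le H$;
* observed heterozygosity = fraction of two-product calls; identically 0
  for sub-genome groups, which are scored single-allele;
* allelic richness by hypergeometric rarefaction,
  $A_g = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]$.

The rarefaction depth is not standardized across software. Here group
columns are rarefied per locus to the smallest per-group copy count at that
locus (the only choice that makes cross-group columns comparable), and the
pooled "overall" column to the smallest pooled copy count across loci.
Copy coding is explicit everywhere (`copies_per_call`): the default 1
matches strongest-peak single-allele scoring; 2 treats a single-size call
as a homozygote. Both are supported because datasets scored single-allele
can still report nonzero observed heterozygosity at loci where two peaks
were recorded.

Nei's DA between frequency profiles $x$ and $y$ over $r$ shared loci is
$D_A = 1 - \frac{1}{r}\sum_{j}\sum_{i}\sqrt{x_{ij} y_{ij}}$, averaged over
shared loci only (no imputation; $r$ is reported per pair). An accession is
a population of one (heterozygote = two alleles at 0.5), which reproduces
the all-pairs individual distances of the classic population-genetics
tools. Within-group values are mean pairwise individual DA among members —
the usual reading of a "within-group distance" diagonal.

## Trees, bootstrap, ordination

`neighbor_joining()` is a textbook NJ (Q-criterion, Studier–Keppler
updates) with two deliberate choices: ties in Q are broken by the
lexicographically smallest pair of cluster labels so the tree never depends
on input order, and negative branch lengths are clamped to zero for display
(topology unaffected; flag to disable). The distance matrix is symmetrized
bitwise on entry, since BLAS products are not exactly symmetric and NJ's
argmin bookkeeping assumes exact pairing. NJ is exact on additive
matrices; the tests verify recovery up to 12 leaves and agreement with an
exhaustive least-squares topology search up to 7.

Bootstrap support resamples **loci** with replacement (the unit of
independent information here), recomputes DA and NJ, and counts
bipartitions of the original tree; runs are seed-reproducible and invariant
to locus order. A replicate in which some pair loses all shared loci is
skipped and the divisor adjusted.

`pcoa()` double-centers $-\tfrac12 D^2$ (Gower) and eigendecomposes.
DA is not guaranteed Euclidean-embeddable, so negative eigenvalues can
appear; they are reported but excluded from the percent-variance
denominator, and no Cailliez/Lingoes correction is applied by default
(corrections change the percentages; a Cailliez flag exists). Axis signs
are fixed by making the largest-magnitude coordinate positive.

## The simulator: what it emulates, and what it does not

`generate_dataset()` reproduces the *statistical shape* of a donor-study
dataset: 38 multi-allelic loci; 8 taxa totalling 268 accessions (46 of the
donor-A-like species, 13 + 47 + 13 + 49 + 42 further diploids, and 51 wild
plus 7 cultivated tetraploids); highly selfing diploids (selfing rate
0.98, so observed heterozygosity sits at its $(1-s)/(2-s)$-scale residual
of a few percent); and a monophyletic amphidiploid whose per-locus allele
pair descends from one gamete of each donor.

Design choices, made once:

* **Allele ladders.** Each locus has a motif unit length (2/3/4 with
  weights 0.45/0.45/0.10) and a base size (100–280 bp); every taxon draws
  an 8-allele ancestral pool from a window on the shared unit-spaced
  ladder, with symmetric Dirichlet(0.2) frequencies (skewed, some
  near-monomorphic loci — the realistic SSR regime). Windows overlap
  within each of the two species groups, but the two donor windows are
  disjoint, giving sub-genome assignment a clean regime by default;
  overlap is a tunable stressor (`pool_offset`).
* **Populations, not panels.** Each taxon is a Wright–Fisher population of
  census size 100 run for 20 generations with stepwise mutation
  ($10^{-3}$/allele/generation, ±1 repeat unit, reflecting at the pool
  bounds); accessions are *sampled* from it, so a 13-accession panel does
  not imply a 13-plant species. Under these conditions realized per-taxon
  gene diversity falls in ≈ 0.3–0.5, the range typical of selfing *Vigna*
  relatives.
* **Amphidiploid.** One founder (monophyletic origin; polyphyly available
  via `n_founders`), 30 post-origin generations of per-sub-genome drift at
  the tetraploid census size, with sub-genome B mutating twice as fast as
  A by default — reproducing the roughly twofold B-vs-A diversity contrast
  reported for such crops. Since the species is highly selfing, one allele
  per sub-genome per accession is tracked (effectively homozygous within a
  sub-genome). No selection, no migration: nothing in the analysis chain
  requires them.

What passing tests on simulated data do **not** show: robustness to
genotyping artifacts (stutter mis-calls, size binning drift, null
alleles), to donor pools that overlap in allele size, or to polyphyletic
origins. The partitioning accuracy of 100% is a property of the disjoint
regime; the stressors exist precisely so users can map where it degrades.

## Problem sizes and numerical choices

The test-suite simulations are scaled down (taxa of 3–10 accessions, 5–15
loci, census 12–40) so that the whole suite runs in a couple of minutes;
the acceptance script runs the full 268 × 38 shape with 400 group-tree
bootstrap replicates and 100 individual-tree replicates (1000 is the API
default, matching common practice for accession-level trees). Frequencies
sum to 1 within 1e-9; rarefaction uses `lchoose` for stability; allele
sizes are rounded to integer bp on ingest and never imputed; missing loci
propagate as `NA` and are excluded from means.

## Known limitations

* Partitioning uses allele size only; peak-height phasing, dosage, and
  likelihood-based homoeolog assignment are out of scope.
* The imperfect-SSR definition (maximal same-phase window within Hamming
  distance 2 of a perfect array, longest/fewest-mismatch/leftmost
  tie-break) is one deterministic reading of "allowing one or two base
  mismatches"; pattern-matching tools count differently, so absolute hit
  counts are tool-specific even when per-class proportions agree.
* Sub-group labels that split a polymorphic diploid taxon (e.g. a species
  complex) are supplied by the user, typically from a prior ordination —
  they are not inferred automatically.
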