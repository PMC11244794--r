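---
title: "Methods: crossover detection and coldspot cataloguing"
author: "coldspotAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover detection and coldspot cataloguing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical decisions
behind `coldspotAtlas`. It is the reference for *why* the pipeline is
built the way it is; the README shows *how* to run it.

## The measurement model

A pooled-pollen linked-read library samples thousands of haploid gametes
from one F1 hybrid. After alignment and phasing (upstream of this
package), every long DNA molecule carries an ordered series of segregating
SNP marker calls: `A` (reference parent), `B` (wild parent) or `N`
(wildcard — an unresolvable call). A molecule from a non-recombinant
chromosome region is a single haplotype run. A molecule spanning a meiotic
crossover switches haplotype exactly once; the exchange point lies
somewhere between the last marker of the first block and the first marker
of the second. The CO is therefore an *interval*, and its precision is
summarized as `resolution = 1/distance` between those flanking markers.

`call_crossover()` accepts a molecule iff:

* exactly two haplotype blocks (three or more switches mean gene
  conversion, chimeric molecules or noise: the molecule is discarded
  whole, never split — at this resolution a double switch cannot be
  distinguished from a non-crossover event);
* each block has at least `min_markers_per_block` (default 3) markers and
  `min_reads_per_block` (default 2) summed supporting reads;
* molecule span ≤ `max_molecule_span` (default 500 kb) — in droplet
  linked-read chemistry several molecules can share a barcode partition,
  and an implausibly long "molecule" is the signature of that artifact;
* wildcard fraction ≤ `max_wildcard_fraction` (default 0.1).

The block-support defaults are package choices (the upstream protocol
publishes the filter *dimensions*, not universal numeric values); they are
configuration-exposed, logged in every run manifest, and the test suite
proves filtering is monotone in each of them. The high-resolution
selection (`filter_high_resolution()`, default threshold 0.001/bp) uses
strict inequalities: a 1,000 bp interval (resolution exactly 0.001) is
*excluded*, which is the only reading under which "distance below 1 kb"
and "resolution above 0.001" coincide. A stricter 0.002 threshold is the
conventional choice when base-level sequence context matters (motif
analyses).

Events from distinct molecules with identical CO intervals are kept as
separate events: the pollen pool samples independent meioses, so identical
intervals are replication, not duplication.

## From events to the coldspot catalogue

**CO regions.** CO events are counted in 10 kb sliding windows with 5 kb
step; windows holding ≥ 1 event are merged when separated by ≤ 1 kb.
Windows are generated for every start below the chromosome end and clipped
there, so coverage is complete (`bedtools makewindows` convention).

**Coldspots.** The per-chromosome complement of the CO regions, clipped at
chromosome ends (a terminal CO-free arm counts), is filtered to stretches
≥ 1 Mb. A gap with zero segregating markers is excluded from the catalogue
— absence of markers and absence of recombination are indistinguishable —
but reported in a side channel (`attr(x, "no_marker_gaps")`).

**Clustering across hybrids.** Coldspots from all hybrids are grouped by
transitive ≥ 1 bp overlap; within each group a graph connects pairs with
≥ 50 % reciprocal overlap and splits into connected components. A
component whose genomic span `p` (max end − min start; the only
membership-stable reading of "distance between the leftmost and rightmost
member") reaches 1.5× its smallest member is re-clustered by
complete-linkage hierarchical clustering on
`d(i,j) = (f − 2I)/(f − I)` — algebraically `1 − Jaccard`, property-tested
as such — and the dendrogram is cut at 0.3, keeping merges strictly below
the cut. Determinism: members are canonically ordered
(chrom, start, end, hybrid) before linkage, distances are exact, and the
test suite asserts input-order invariance. Clusters with members from one
hybrid are `unique`, from two or more `shared`.

**Conserved coldspots** are computed independently of clustering, as the
k-way base-pair intersection of the per-hybrid coldspot unions; all
intersection fragments are retained by default (a
`drop_fragments_below` option exists because sub-Mb fragments are a
defensible exclusion, but the default reports every conserved base).

## Structural-variant filtering

Three call sets against one reference enter: wild inbred, F1 pollen, and
self (reference accession vs its own assembly — an artifact mask). An
inbred call becomes *parental* when a pollen call of the same type
overlaps it at ≥ 50 % reciprocal overlap — the community-standard SV
concordance rule; the match criterion is a package decision, since
matching by caller ID or breakpoint tolerance would serve equally and
neither is canonical. Parental DEL/INV calls with **zero** overlap against
any self call survive ("does not overlap" read literally: one shared base
discards). Size classes use strict boundaries: ≥ 50 bp (detect), > 1 kb
(analysis; the set used for enrichment — recombination suppression is a
property of kilobase-scale heterozygous SVs), > 30 kb (large-inversion
report). Other SV types pass through readers (`type = "other"`) for
reporting but are excluded from the retained set.

## Association statistics

**Permutation enrichment.** The observed statistic is the number of CO
*events* overlapping a feature set by ≥ 1 bp (events, not base pairs: the
question is how many crossovers happen in the feature context). The null
relocates the CO set with lengths preserved, placements uniform over all
valid genome positions (chromosome drawn ∝ valid starts — the
`bedtools shuffle` default; a per-chromosome and a within-compartment mode
exist). z = (obs − null mean)/null sd; empirical two-sided p uses the
(r+1)/(n+1) pseudo-count so it is never zero, and a normal-tail p is also
reported because extreme enrichments exceed empirical granularity at any
feasible permutation count. Degenerate nulls (sd = 0, e.g. features
covering the genome) are flagged, z = NA, p = 1. Across TE superfamilies,
Benjamini–Hochberg adjustment is applied and both raw and adjusted p are
reported. The permutation inner loop runs on a vectorized
start/end/`findInterval` path that the test suite cross-checks against
`countOverlaps`.

**Genic enrichment per compartment** restricts both the observed COs and
the null placements to one compartment (DEU or PER), so the
compartment-scale CO gradient cannot masquerade as gene preference; genes
are extended by 1 kb flanks.

**Fisher co-occurrence.** The genome is tiled into 10 kb windows (the CO
region scale; configurable) and the indicator "window holds a CO of hybrid
X" is cross-tabulated between two hybrids; `fisher.test` gives the
two-sided p and conditional-MLE odds ratio (infinite for empty discordant
cells, reported as such), with `shared_fraction` = windows-with-both /
windows-with-either. The window construction is a package decision — the
co-occurrence test needs a discretization unit and none is canonical.

**Landscapes.** CO density is a Gaussian KDE of event midpoints with
bandwidth 100 kb ("binwidth" of R's `density()` can only mean its `bw`
argument), evaluated per chromosome and scaled to integrate to the CO
count. Landscape similarity is the Spearman matrix of CO counts in 500 kb
windows with 50 kb step, concatenated genome-wide; constant vectors are
flagged rather than propagating NaN.

**Distance profiles.** Signed edge-to-edge distance to the nearest SV:
0 when overlapping, positive when the nearest feature lies at higher
coordinates, negative below; chromosomes without features yield `NA`
(never a sentinel magic number). A seeded shuffled-CO null band
accompanies the observed histogram.

## The synthetic corpus: what it emulates, what it does not

The generator exists so that every stage can be validated against planted
truth. Its defaults are one fixed set of study conditions (all are
`sim_config()` arguments):

* **Geometry**: 3 chromosomes × 30 Mb, centered PER covering 70 % — a
  miniature of a ~780 Mb genome that is mostly pericentromeric
  heterochromatin.
* **Markers**: Poisson-placed at 1/kb (DEU) and 0.5/kb (PER). Real marker
  sets are an order of magnitude denser; the scaled density keeps molecule
  tables small while leaving ~25–100 markers per molecule.
* **Molecules**: log-normal lengths (mean 50 kb, sd 35 kb, truncated at
  250 kb), the long-tailed size profile typical of linked-read input DNA;
  10,000 molecules per hybrid.
* **CO intensity**: a piecewise-constant track — compartment weight
  (DEU 1.0, PER 0.08, giving ~9 % pericentromeric COs), multiplied by 0.1
  inside SVs > 1 kb, by TE-superfamily factors (Gypsy 0.2 and Copia 0.3 in
  PER; Stowaway 2.0 in DEU), and by 3.0 inside genes ± 1 kb. A molecule is
  recombinant with probability proportional to the intensity integrated
  over its span (normalized so the expected recombinant count is
  `co_rate × n_molecules`), and the switch is planted in an inter-marker
  gap with probability proportional to the gap's integrated intensity.
  The proportional-recombination step matters: with a flat per-molecule
  rate the genome-scale landscape would be uniform no matter the weights,
  because placement weights act only within a ~50 kb span.
* **CO density**: the default `co_rate` (0.025) preserves the per-Mb CO
  density of a real pollen screen (~1,300 events on 780 Mb ≈ 200 on this
  90 Mb miniature). This is the scaling that preserves *coldspot
  geometry*: with CO counts preserved instead, the miniature genome would
  be 9× too CO-dense and the ≥ 1 Mb pericentromeric coldspot structure
  would dissolve. Corpora for detector power studies (the bundled fixture,
  noise and directional-recovery tests) explicitly raise `co_rate` to
  0.12.
* **Features**: TE tracks placed wholly inside their biased compartment
  (hard bias, so bias tests are exact); non-overlapping gene models with
  1–5 exons, strand and terminal UTRs, 85 % in DEU; ACRs (~700 bp)
  anchored at a random TSS with probability 0.6; SVs log-normal
  (median 4 kb), 60 % placed in DEU (reproducing the ~1.55:1 DEU:PER count
  contrast) with PER SVs doubled in length; a `parental_fraction` (0.7)
  of SVs reappears in the pollen call set with ≤ 5 % breakpoint jitter
  (safely inside the 50 % reciprocal-overlap match), and a fraction of
  self SVs is planted over parental ones to exercise the artifact mask.
* **Noise controls** (all default 0): per-marker wildcards, haplotype
  flips, and double-switch contaminant molecules.

All randomness flows from one master seed through deterministic per-stage
sub-seeds, so a corpus is bit-reproducible and writing/reading it through
the package's own TSV/BED/GFF3 formats is byte-stable.

What the generator does **not** emulate: read-level error processes
(alignment, barcode collisions beyond the span guard), marker
misphasing structure, empirically calibrated molecule-length and
noise distributions (the defaults are order-of-magnitude stand-ins),
isoform-level gene structure, and sequence content of any kind. Passing
tests on this corpus therefore demonstrate the correctness of the
*computational* pipeline under its stated model — not the upstream
phasing accuracy on real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (GRanges native); BED I/O
  converts at the boundary; package TSVs are 1-based like VCF/GFF3.
* Strict-vs-inclusive boundaries follow the literal wording everywhere:
  resolution > 0.001; SV analysis length > 1,000 bp; self-SV overlap > 0
  discards; window separation ≤ gap merges.
* The dendrogram cut keeps merges strictly below 0.3 (implemented as
  `cutree(h = 0.3 − 1e−9)`).
* Ties in genic feature assignment resolve by priority
  exon > UTR > intron > upstream > downstream, then larger overlap; every
  CO gets exactly one primary label, and multi-gene overlaps are flagged
  rather than double-counted.
* Empty inputs return typed empty results (never NULL surprises); an
  all-wildcard molecule yields zero blocks and is counted separately;
  non-monotone genetic-map rows are excluded from Marey-rate
  differentiation and counted in an attribute.
* Problem sizes in the test suite are chosen for a single CPU: the oracle
  equivalence loop runs 1,000 random two-chromosome genomes ≤ 100 kb; the
  null-calibration runs 1,000 seeded trials at 600 permutations each; the
  planted-coldspot corpus uses 8,000 molecules over 90 Mb. The calibration
  criterion (≤ 3 of 1,000 null trials with |z| > 3) sits close to its own
  expectation (≈ 2.8 under perfect calibration), so seed ranges for
  geometry, trial shuffles and permutation nulls are kept disjoint — a
  shared seed would let a shuffle re-trace the RNG stream that placed the
  features and manufacture a spurious association.

## Known limitations

* CO detection assumes exactly one switch per recombinant molecule;
  molecules spanning two genuine crossovers (rare at these molecule
  lengths, but possible) are discarded as multi-switch.
* The inbred-to-pollen SV match (50 % reciprocal overlap, same type) is a
  stand-in for an unspecified upstream convention; a breakpoint-tolerance
  matcher would be a drop-in alternative.
* Conserved-coldspot coverage depends on the number of hybrids supplied;
  with fewer than the full panel the result is labelled with the hybrids
  used rather than refused.
* The Fisher co-occurrence test discretizes at one window size; very
  different CO-region scales between hybrids would warrant a sensitivity
  scan over `window`.
* `marey_rate()` differentiates a prepared (bp, cM) table; mapping linkage
  markers onto the assembly is upstream of this package.
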