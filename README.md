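# coldspotAtlas

Genome-wide cataloguing of meiotic recombination coldspots from
pooled-pollen linked-read sequencing of interspecific hybrids.

Introgression breeding moves alleles from wild relatives into crops through
meiotic crossovers (COs). Where recombination is suppressed — around
pericentromeres, inside structural variants (SVs), in retrotransposon-dense
chromatin — whole blocks of genes are inherited as one unit ("linkage
drag"). Mapping the CO-free regions of each specific cross tells a breeder
in advance which trait combinations a given wild parent can or cannot
deliver. `coldspotAtlas` implements the full analysis for that map, from
phased single-molecule marker calls to a clustered, annotated coldspot
catalogue.

## What the package computes

Starting from per-molecule haplotype calls (`A`/`B`/`N` per SNP marker on
each linked-read molecule), the pipeline:

1. **Calls crossovers** — a molecule with exactly one haplotype switch
   yields a CO localized between its two flanking markers, with
   *resolution* defined as `1/distance` between those markers
   (`resolution > 0.001` ⇔ flanking markers < 1 kb apart). Filters on block
   marker/read support, molecule span (multi-molecule GEM guard) and
   wildcard fraction reject unreliable molecules; double-switch molecules
   are discarded as gene-conversion-like.
2. **Builds CO regions** — CO counts in 10 kb sliding windows (5 kb step);
   windows holding ≥ 1 CO are merged when within 1 kb.
3. **Detects coldspots** — CO-free complement stretches ≥ 1 Mb, kept only
   when they contain segregating markers (so a coldspot is not a marker
   desert), split by DEU/PER chromatin compartment.
4. **Clusters coldspots across hybrids** — ≥ 1 bp overlap grouping, a graph
   with edges at ≥ 50 % reciprocal overlap, connected components, and —
   for components spanning ≥ 1.5× their smallest member — complete-linkage
   hierarchical clustering on the size-weighted distance
   `d(i,j) = (f − 2I)/(f − I)` (`f` = length sum, `I` = intersection;
   identically `1 − Jaccard`), cut at height 0.3. Clusters are `unique`
   (one hybrid) or `shared` (≥ 2); the base-pair intersection over all
   hybrids gives the *conserved* coldspots.
5. **Filters structural variants** — an inbred wild-parent SV is *parental*
   when the F1 pollen pool confirms it (same type, ≥ 50 % reciprocal
   overlap); parental DEL/INV calls not overlapping any *self* SV
   (reference-vs-reference artifact mask) survive, labelled by size class
   (≥ 50 bp detect, > 1 kb analysis, > 30 kb inversion report).
6. **Quantifies associations** — seeded permutation tests (CO overlap
   counts vs length-preserving interval shuffles; z-score and empirical
   p), Fisher exact co-occurrence of COs between hybrids on genome
   windows, Gaussian-kernel CO density landscapes (100 kb bandwidth),
   Spearman landscape correlations (500 kb windows, 50 kb step), signed
   distance-to-nearest-SV profiles, and genic feature assignment
   (exon > UTR > intron > 1 kb flanks > intergenic).

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_corpus()`) produces genomes, markers, molecules with planted
COs, TE/gene/ACR annotation and three-way SV call sets, so the entire
pipeline is testable with known ground truth and no external data.

## Worked example

```r
library(coldspotAtlas)

corpus <- make_fixture(seed = 1)          # 3 x 30 Mb, 2 hybrids, planted truth
g <- corpus$genome

ev <- call_crossovers(corpus$hybrids$H1$molecules,
                      co_filter_params(), hybrid_id = "H1")
summarize_events(ev)
#>   hybrid_id n_cos mean_distance_kb sd_distance_kb
#> 1        H1   372         2.206398        1.66824

reg <- build_co_regions(ev, g)
cs  <- detect_coldspots(reg, g, corpus$hybrids$H1$markers)
length(cs); sum(width(cs)) / genome_size(g)
#> [1] 25
#> [1] 0.6528889
```

372 crossovers localize to ~2 kb between flanking markers on average; their
CO regions leave 25 marker-supported CO-free blocks ≥ 1 Mb covering ~65 %
of this corpus' genome — the dense pericentromeric heterochromatin plus
hybrid-specific gaps. Pooling both hybrids and clustering classifies those
blocks into shared and hybrid-unique coldspot clusters
(`cluster_coldspots()`), and `permutation_enrichment()` quantifies CO
suppression inside the planted SV set (negative z) and enrichment in genes
(positive z). `run_pipeline(default_config(seed = 1))` performs all stages
and writes the catalogue bundle (TSV/BED plus a config-hash manifest).

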