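Package: coldspotAtlas
Title: Crossover Detection and Recombination Coldspot Cataloguing from
    Pooled-Pollen Linked Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-wide catalogues of meiotic crossover (CO) regions
    and recombination coldspots from phased linked-read pollen molecules of
    interspecific hybrids. Calls crossovers from haplotype switches in single
    DNA molecules, derives CO regions from sliding-window counts, detects
    megabase-scale CO-free coldspots, clusters coldspots across hybrids into
    unique and shared classes, filters heterozygous parental structural
    variants (deletions and inversions), and quantifies association of
    crossovers with transposable elements, genes, structural variants and
    accessible chromatin using seeded permutation and exact tests. Includes a
    fully seeded synthetic-data generator that emulates distally enriched
    recombination landscapes so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
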