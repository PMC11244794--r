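# Helpers to re-derive catalogue statistics from deposited per-event and
# per-coldspot tables (e.g. the supplementary tables of a pollen
# recombination study), so published numbers can be recomputed from the
# published intervals alone.

#' CO-region coverage statistics from a crossover event table
#'
#' Rebuilds CO regions per hybrid with the standard windowing
#' (10 kb / 5 kb / 1 kb merge) and reports per-hybrid genome coverage plus
#' the combined union coverage over all hybrids.
#'
#' @param events `data.frame` with columns hybrid_id, chrom, left_marker,
#'   right_marker (1-based bp).
#' @param genome `GenomeLayout`.
#' @param ... passed to [build_co_regions()].
#' @return list: `per_hybrid` (`data.frame` hybrid_id, bp, fraction),
#'   `union_bp`, `union_fraction`.
#' @export
co_region_coverage_stats <- function(events, genome, ...) {
  sp <- split(events, events$hybrid_id)
  regs <- lapply(sp, function(d) build_co_regions(d, genome, ...)$regions)
  per <- do.call(rbind, lapply(names(regs), function(h) {
    cov <- interval_coverage(regs[[h]], genome)
    data.frame(hybrid_id = h, bp = cov$bp, fraction = cov$fraction)
  }))
  uni <- interval_coverage(suppressWarnings(do.call(c, unname(regs))), genome)
  list(per_hybrid = per, union_bp = uni$bp, union_fraction = uni$fraction)
}

#' Cluster a deposited coldspot table
#'
#' Applies the cross-hybrid clustering (overlap grouping, 50% reciprocal
#' overlap graph, 1.5x span rule, complete linkage cut at 0.3) to a plain
#' coldspot table and tallies unique and shared clusters.
#'
#' @param coldspots `data.frame` with columns hybrid_id, chrom, start, end
#'   (1-based inclusive).
#' @param ... passed to [cluster_coldspots()].
#' @return list: `catalogue` (per-coldspot assignment), `n_unique`,
#'   `n_shared`.
#' @export
cluster_coldspot_table <- function(coldspots, ...) {
  gr <- GRanges(coldspots$chrom, IRanges(coldspots$start, coldspots$end))
  mcols(gr)$hybrid_id <- coldspots$hybrid_id
  cat <- cluster_coldspots(gr, ...)
  cl <- attr(cat, "clusters")
  list(catalogue = cat,
       n_unique = sum(cl$class == "unique"),
       n_shared = sum(cl$class == "shared"))
}

#' Conserved-coldspot coverage from a deposited coldspot table
#'
#' Intersects the per-hybrid coldspot unions and reports the genome
#' fraction lacking COs in every hybrid.
#'
#' @param coldspots `data.frame` with columns hybrid_id, chrom, start, end.
#' @param genome `GenomeLayout`.
#' @return list: `conserved` (`GRanges`), `bp`, `fraction`.
#' @export
conserved_coverage_stats <- function(coldspots, genome) {
  sp <- split(coldspots, coldspots$hybrid_id)
  sets <- lapply(sp, function(d)
    GRanges(d$chrom, IRanges(d$start, d$end)))
  cons <- conserved_coldspots(sets, genome)
  list(conserved = cons, bp = attr(cons, "bp"),
       fraction = attr(cons, "fraction"))
}
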