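# Coldspot catalogue: CO regions, >=1 Mb CO-free coldspots, conserved
# coldspots, and cross-hybrid coldspot clustering.

#' Build CO regions from crossover events
#'
#' Counts COs in sliding windows (default 10 kb, 5 kb step), keeps windows
#' overlapping at least one CO interval, and merges kept windows lying
#' within a gap tolerance (default 1 kb) of each other. The merged result is
#' the set of CO regions for one hybrid.
#'
#' @param events crossover event `data.frame` for a single hybrid, or a
#'   `GRanges` of CO intervals.
#' @param genome `GenomeLayout`.
#' @param window,step sliding-window size and step in bp.
#' @param merge_gap merge tolerance in bp.
#' @return list of class `co_regions`: `hybrid_id`, `regions` (merged
#'   `GRanges`), `windows` (selected windows with a `n_cos` count column).
#' @export
build_co_regions <- function(events, genome, window = 10e3, step = 5e3,
                             merge_gap = 1e3) {
  gr <- if (is(events, "GRanges")) validate_in_genome(events, genome, "CO events")
        else events_gr(events, genome)
  hybrid_id <- if (is(events, "GRanges")) {
    unique(mcols(events)$hybrid_id) %||% "hybrid"
  } else unique(events$hybrid_id)
  if (length(hybrid_id) > 1L) {
    stop("build_co_regions expects events from a single hybrid")
  }
  if (!length(hybrid_id)) hybrid_id <- "hybrid"
  w <- sliding_windows(genome, window, step)
  n <- countOverlaps(w, gr)
  sel <- w[n > 0]
  mcols(sel)$n_cos <- n[n > 0]
  structure(list(hybrid_id = hybrid_id %||% "hybrid",
                 regions = merge_intervals(sel, gap = merge_gap),
                 windows = sel),
            class = "co_regions")
}

#' Detect recombination coldspots
#'
#' Coldspots are CO-free stretches of at least `min_size` bp: the
#' per-chromosome complement of the CO regions, clipped at chromosome ends
#' (terminal gaps count). Each coldspot is annotated with the number of
#' segregating markers it overlaps; gaps without any marker cannot be
#' distinguished from marker deserts and are excluded from the catalogue
#' but returned separately.
#'
#' @param regions a `co_regions` object or `GRanges` of CO regions.
#' @param genome `GenomeLayout`.
#' @param markers marker `data.frame` (chrom, pos) used to confirm that the
#'   absence of COs is not an absence of markers.
#' @param min_size minimum coldspot length in bp (default 1 Mb).
#' @param hybrid_id label; defaults to the `co_regions` hybrid.
#' @return `GRanges` of coldspots with metadata hybrid_id, marker_count,
#'   deu_bp, per_bp; the attribute `no_marker_gaps` holds the excluded
#'   zero-marker gaps.
#' @export
detect_coldspots <- function(regions, genome, markers, min_size = 1e6,
                             hybrid_id = NULL) {
  if (inherits(regions, "co_regions")) {
    hybrid_id <- hybrid_id %||% regions$hybrid_id
    regions <- regions$regions
  }
  regions <- validate_in_genome(regions, genome, "CO regions")
  gaps <- setdiff(genome_gr(genome), regions)
  gaps <- gaps[width(gaps) >= min_size]
  mk <- markers_gr(markers, genome)
  cnt <- countOverlaps(gaps, mk)
  out <- gaps[cnt >= 1]
  mcols(out)$hybrid_id <- rep(hybrid_id %||% "hybrid", length(out))
  mcols(out)$marker_count <- cnt[cnt >= 1]
  mcols(out)$deu_bp <- overlap_bp(out, genome$deu)
  mcols(out)$per_bp <- overlap_bp(out, genome$per)
  no_marker <- gaps[cnt == 0]
  attr(out, "no_marker_gaps") <- no_marker
  out
}

# per-interval bp of overlap with a (reduced) reference set
overlap_bp <- function(x, ref) {
  if (!length(x)) return(integer(0))
  hits <- findOverlaps(x, ref, ignore.strand = TRUE)
  ov <- pmin(end(x)[queryHits(hits)], end(ref)[subjectHits(hits)]) -
    pmax(start(x)[queryHits(hits)], start(ref)[subjectHits(hits)]) + 1
  out <- rep(0, length(x))
  agg <- tapply(ov, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Conserved coldspots across hybrids
#'
#' The base-pair intersection of the per-hybrid coldspot unions: genomic
#' positions lacking a CO in every hybrid supplied. When fewer hybrids than
#' the full panel are given, the result is labelled with the hybrids used.
#'
#' @param coldspot_list named list of per-hybrid coldspot `GRanges`.
#' @param genome `GenomeLayout`.
#' @param drop_fragments_below optional minimum fragment size in bp; by
#'   default all intersection bp are retained.
#' @return `GRanges` with attributes `hybrids`, `bp`, `fraction`, `deu_bp`,
#'   `per_bp`.
#' @export
conserved_coldspots <- function(coldspot_list, genome,
                                drop_fragments_below = 0) {
  stopifnot(length(coldspot_list) >= 1L)
  sets <- lapply(coldspot_list, function(x)
    reduce(validate_in_genome(x, genome, "coldspots")))
  cons <- Reduce(intersect_intervals, sets)
  if (drop_fragments_below > 0) {
    cons <- cons[width(cons) >= drop_fragments_below]
  }
  attr(cons, "hybrids") <- names(coldspot_list) %||% seq_along(coldspot_list)
  attr(cons, "bp") <- sum(as.numeric(width(cons)))
  attr(cons, "fraction") <- sum(as.numeric(width(cons))) / genome_size(genome)
  attr(cons, "deu_bp") <- sum(overlap_bp(cons, genome$deu))
  attr(cons, "per_bp") <- sum(overlap_bp(cons, genome$per))
  cons
}

#' Size-weighted Jaccard distance between interval pairs
#'
#' `d(i, j) = (f - 2 I) / (f - I)` with `f` the sum of the two lengths and
#' `I` the intersection length; algebraically identical to
#' `1 - |i intersect j| / |i union j|`. Pairs on different chromosomes are at
#' distance 1.
#'
#' @param i,j `GRanges` of equal length (pairwise).
#' @return numeric vector in \[0, 1\].
#' @export
jaccard_distance <- function(i, j) {
  stopifnot(length(i) == length(j))
  if (!length(i)) return(numeric(0))
  I <- pmax(0, pmin(end(i), end(j)) - pmax(start(i), start(j)) + 1)
  I[as.character(seqnames(i)) != as.character(seqnames(j))] <- 0
  f <- width(i) + width(j)
  (f - 2 * I) / (f - I)
}

#' Cluster coldspots across hybrids into unique/shared clusters
#'
#' Implements the position-and-size grouping of a multi-hybrid coldspot
#' catalogue:
#' 1. coldspots overlapping by >= 1 bp are grouped (transitive closure);
#' 2. within each group, a graph connects coldspots with >= 50% reciprocal
#'    overlap and is split into connected components;
#' 3. a component whose genomic span is at least `span_factor` (1.5) times
#'    the size of its smallest member is re-clustered by complete-linkage
#'    hierarchical clustering on [jaccard_distance()], cutting the
#'    dendrogram at height `cut_height` (0.3, merges strictly below the
#'    cut are kept); otherwise the component is one cluster;
#' 4. clusters are labelled `unique` (members from one hybrid) or `shared`
#'    (members from >= 2 hybrids).
#'
#' Input order does not matter: members are put in canonical
#' (chrom, start, end, hybrid) order before clustering, and cluster ids are
#' assigned in genome order.
#'
#' @param coldspots `GRanges` with a `hybrid_id` metadata column, pooled
#'   over hybrids.
#' @param min_reciprocal reciprocal-overlap edge threshold (default 0.5).
#' @param span_factor span test multiplier (default 1.5).
#' @param cut_height dendrogram cut height (default 0.3).
#' @return `data.frame` with one row per coldspot: chrom, start, end,
#'   length, hybrid_id, group_id, component_id, cluster_id, class. The
#'   attribute `clusters` summarizes each cluster (members, hybrids, span,
#'   class).
#' @export
cluster_coldspots <- function(coldspots, min_reciprocal = 0.5,
                              span_factor = 1.5, cut_height = 0.3) {
  stopifnot(is(coldspots, "GRanges"),
            !is.null(mcols(coldspots)$hybrid_id))
  cs <- as_unstranded(coldspots)
  ord <- order(as.factor(seqnames(cs)), start(cs), end(cs),
               mcols(cs)$hybrid_id)
  cs <- cs[ord]
  n <- length(cs)
  if (n == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      hybrid_id = character(0), group_id = integer(0),
                      component_id = integer(0), cluster_id = integer(0),
                      class = character(0))
    attr(out, "clusters") <- out
    return(out)
  }
  # (1) >=1 bp overlap groups = membership in the reduced union
  union_gr <- reduce(cs)
  grp <- subjectHits(findOverlaps(cs, union_gr, ignore.strand = TRUE))

  component_id <- integer(n)
  cluster_id <- integer(n)
  next_comp <- 0L
  next_clust <- 0L
  for (gid in unique(grp)) {
    members <- which(grp == gid)
    # (2) reciprocal-overlap graph -> connected components
    comp_local <- overlap_components(cs[members], min_reciprocal)
    for (cid in sort(unique(comp_local))) {
      next_comp <- next_comp + 1L
      mem <- members[comp_local == cid]
      component_id[mem] <- next_comp
      # (3) span test and optional hierarchical re-clustering
      span <- max(end(cs)[mem]) - min(start(cs)[mem]) + 1
      smallest <- min(width(cs)[mem])
      if (length(mem) >= 2L && span >= span_factor * smallest) {
        d <- outer(seq_along(mem), seq_along(mem), function(a, b)
          jaccard_distance(cs[mem[a]], cs[mem[b]]))
        hc <- stats::hclust(stats::as.dist(d), method = "complete")
        # "cut at 0.3" keeps merges whose linkage distance is < 0.3
        sub <- stats::cutree(hc, h = cut_height - 1e-9)
        for (s in sort(unique(sub))) {
          next_clust <- next_clust + 1L
          cluster_id[mem[sub == s]] <- next_clust
        }
      } else {
        next_clust <- next_clust + 1L
        cluster_id[mem] <- next_clust
      }
    }
  }
  hyb <- as.character(mcols(cs)$hybrid_id)
  n_hyb <- tapply(hyb, cluster_id, function(h) length(unique(h)))
  cls <- ifelse(n_hyb[as.character(cluster_id)] >= 2L, "shared", "unique")
  out <- data.frame(chrom = as.character(seqnames(cs)),
                    start = start(cs), end = end(cs), length = width(cs),
                    hybrid_id = hyb, group_id = grp,
                    component_id = component_id, cluster_id = cluster_id,
                    class = as.character(cls), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(out, out$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1L], n_members = nrow(d),
               n_hybrids = length(unique(d$hybrid_id)),
               chrom = d$chrom[1L], span_start = min(d$start),
               span_end = max(d$end), class = d$class[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "clusters") <- summ[order(summ$cluster_id), , drop = FALSE]
  out
}

# connected components of the >= min_reciprocal reciprocal-overlap graph
overlap_components <- function(x, min_reciprocal) {
  n <- length(x)
  if (n == 1L) return(1L)
  hits <- findOverlaps(x, x, ignore.strand = TRUE)
  hits <- hits[queryHits(hits) < subjectHits(hits)]
  ro <- reciprocal_overlap(x[queryHits(hits)], x[subjectHits(hits)])
  keep <- ro >= min_reciprocal
  edges <- data.frame(from = queryHits(hits)[keep],
                      to = subjectHits(hits)[keep])
  g <- graph_from_data_frame(edges, directed = FALSE,
                             vertices = data.frame(name = seq_len(n)))
  comp <- components(g)$membership
  as.integer(comp[as.character(seq_len(n))])
}

#' Recombination rate from a Marey map
#'
#' A Marey map pairs a marker's physical position (bp) with its genetic
#' position (cM); the local recombination rate is its derivative. Rates are
#' computed as finite differences between consecutive markers, scaled to
#' cM/Mb. Markers breaking monotonicity (decreasing cM with increasing bp)
#' are flagged and excluded before differencing.
#'
#' @param map `data.frame` with columns bp and cM.
#' @return `data.frame` with one row per inter-marker segment: start, end
#'   (bp), rate (cM/Mb); attribute `n_nonmonotone` counts dropped markers.
#' @export
marey_rate <- function(map) {
  stopifnot(all(c("bp", "cM") %in% names(map)))
  map <- map[order(map$bp), , drop = FALSE]
  keep <- map$cM >= cummax(map$cM)  # retain the monotone subset
  dropped <- sum(!keep)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) < 2L) {
    out <- data.frame(start = numeric(0), end = numeric(0), rate = numeric(0))
    attr(out, "n_nonmonotone") <- dropped
    return(out)
  }
  out <- data.frame(start = head(map$bp, -1L), end = tail(map$bp, -1L),
                    rate = diff(map$cM) / diff(map$bp) * 1e6)
  attr(out, "n_nonmonotone") <- dropped
  out
}

#' Write the coldspot catalogue
#'
#' @param catalogue `data.frame` from [cluster_coldspots()], or a plain
#'   coldspot `GRanges` with hybrid_id metadata.
#' @param tsv,bed output paths (`NULL` to skip either).
#' @return invisibly, a list of written paths.
#' @export
write_coldspots <- function(catalogue, tsv = NULL, bed = NULL) {
  if (is(catalogue, "GRanges")) {
    catalogue <- data.frame(chrom = as.character(seqnames(catalogue)),
                            start = start(catalogue), end = end(catalogue),
                            length = width(catalogue),
                            hybrid_id = mcols(catalogue)$hybrid_id,
                            marker_count = mcols(catalogue)$marker_count)
  }
  if (!is.null(tsv)) {
    fwrite(as.data.table(catalogue), tsv, sep = "\t")
  }
  if (!is.null(bed)) {
    gr <- GRanges(catalogue$chrom, IRanges(catalogue$start, catalogue$end))
    mcols(gr)$name <- paste0(catalogue$hybrid_id, "_", seq_len(nrow(catalogue)))
    write_bed(gr, bed)
  }
  invisible(list(tsv = tsv, bed = bed))
}
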