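# Crossover calling from phased pollen molecules.
#
# A linked-read molecule carries an ordered series of segregating-marker
# haplotype calls (A = reference parent, B = wild parent, N = wildcard).
# A molecule spanning a crossover switches haplotype exactly once; the CO is
# localized to the interval between the two flanking markers, and its
# resolution is defined as 1/distance between those markers.

#' Crossover calling filter parameters
#'
#' Thresholds applied to putative recombinant molecules. The resolution
#' cutoff (default 0.001/bp, i.e. flanking markers less than 1 kb apart)
#' follows the high-resolution CO definition; the span limit guards against
#' multiple molecules sharing one barcode partition (GEM) being mistaken for
#' a single long molecule. Block-support defaults (3 markers and 2 reads per
#' haplotype block, at most 10% wildcard calls) are package defaults,
#' configurable per run.
#'
#' @param min_resolution resolution threshold in 1/bp used by
#'   [filter_high_resolution()].
#' @param max_molecule_span maximum molecule span in bp.
#' @param min_markers_per_block minimum markers in each flanking block.
#' @param min_reads_per_block minimum supporting reads summed over each
#'   flanking block.
#' @param max_wildcard_fraction maximum fraction of wildcard (`N`) calls on
#'   the molecule.
#' @return object of class `co_filter_params`.
#' @export
co_filter_params <- function(min_resolution = 0.001,
                             max_molecule_span = 500e3,
                             min_markers_per_block = 3,
                             min_reads_per_block = 2,
                             max_wildcard_fraction = 0.1) {
  p <- list(min_resolution = min_resolution,
            max_molecule_span = max_molecule_span,
            min_markers_per_block = min_markers_per_block,
            min_reads_per_block = min_reads_per_block,
            max_wildcard_fraction = max_wildcard_fraction)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))))
  structure(p, class = "co_filter_params")
}

#' Segment a molecule's marker calls into haplotype blocks
#'
#' Maximal runs of identical non-wildcard haplotype, in marker order.
#' Wildcards belong to no block and are only counted.
#'
#' @param hap character vector of per-marker calls (`A`/`B`/`N`), in
#'   position order.
#' @param reads integer vector of supporting reads per marker (default 1).
#' @return `data.frame` with one row per block: `hap`, `n_markers`,
#'   `n_reads`, `first` and `last` (marker indices into the input); plus
#'   attribute `wildcards` (count of N calls).
#' @export
segment_haplotypes <- function(hap, reads = rep(1L, length(hap))) {
  stopifnot(length(hap) == length(reads))
  keep <- hap != "N"
  idx <- which(keep)
  if (!length(idx)) {
    out <- data.frame(hap = character(0), n_markers = integer(0),
                      n_reads = integer(0), first = integer(0),
                      last = integer(0))
    attr(out, "wildcards") <- length(hap)
    return(out)
  }
  r <- rle(hap[idx])
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- data.frame(
    hap = r$values,
    n_markers = r$lengths,
    n_reads = vapply(seq_along(starts), function(b)
      sum(reads[idx[starts[b]:ends[b]]]), numeric(1)),
    first = idx[starts],
    last = idx[ends])
  attr(out, "wildcards") <- sum(!keep)
  out
}

#' Call a crossover from one segmented molecule
#'
#' A CO is reported iff the molecule has exactly two haplotype blocks, each
#' meeting the marker and read support minima, the molecule span does not
#' exceed the configured maximum, and the wildcard fraction is within
#' bounds. The CO interval runs from the last marker of the first block to
#' the first marker of the second block; distance is their separation and
#' resolution its inverse.
#'
#' @param pos marker positions (bp, increasing).
#' @param hap per-marker haplotype calls (`A`/`B`/`N`).
#' @param reads per-marker supporting read counts.
#' @param params [co_filter_params()].
#' @return one-row `data.frame` (left_marker, right_marker, distance,
#'   resolution, block stats); a rejected molecule yields a zero-row frame
#'   whose attribute `reason` names the rejection (`non-recombinant`,
#'   `multi-switch`, `span`, `block-support`, `wildcards`, `no-blocks`).
#' @export
call_crossover <- function(pos, hap, reads = rep(1L, length(pos)), params = co_filter_params()) {
  stopifnot(length(pos) == length(hap))
  blocks <- segment_haplotypes(hap, reads)
  wc <- attr(blocks, "wildcards")
  reject <- function(reason) {
    out <- data.frame(left_marker = numeric(0), right_marker = numeric(0),
                      distance = numeric(0), resolution = numeric(0))
    attr(out, "reason") <- reason
    out
  }
  if (nrow(blocks) == 0L) return(reject("no-blocks"))
  if (nrow(blocks) == 1L) return(reject("non-recombinant"))
  if (nrow(blocks) > 2L) return(reject("multi-switch"))
  span <- pos[length(pos)] - pos[1L]
  if (span > params$max_molecule_span) return(reject("span"))
  if (wc / length(hap) > params$max_wildcard_fraction) return(reject("wildcards"))
  ok <- all(blocks$n_markers >= params$min_markers_per_block) &&
    all(blocks$n_reads >= params$min_reads_per_block)
  if (!ok) return(reject("block-support"))
  left <- pos[blocks$last[1L]]
  right <- pos[blocks$first[2L]]
  data.frame(left_marker = left, right_marker = right,
             distance = right - left, resolution = 1 / (right - left),
             markers_left = blocks$n_markers[1L],
             markers_right = blocks$n_markers[2L],
             reads_left = blocks$n_reads[1L],
             reads_right = blocks$n_reads[2L],
             wildcard_fraction = wc / length(hap))
}

#' Call crossovers from a molecule table
#'
#' Vectorized application of the single-molecule caller over all molecules
#' of one hybrid. Molecules from distinct gametes yielding identical CO
#' intervals are retained as independent events (a pollen pool samples
#' independent meioses).
#'
#' @param molecules molecule table ([read_molecules()] layout: molecule_id,
#'   chrom, pos, hap, reads).
#' @param params [co_filter_params()].
#' @param hybrid_id label recorded on each event.
#' @return `data.frame` of crossover events (one per recombinant molecule)
#'   with columns hybrid_id, molecule_id, chrom, left_marker, right_marker,
#'   distance, resolution and block statistics. The attribute `rejections`
#'   tabulates why molecules were discarded.
#' @export
call_crossovers <- function(molecules, params = co_filter_params(),
                            hybrid_id = "hybrid") {
  m <- as.data.table(molecules)
  setorder(m, molecule_id, pos)
  # segment every molecule at once: block id increments at each haplotype
  # change among non-wildcard calls
  m[, mol := rleid(molecule_id)]
  info <- m[hap != "N",
            {
              r <- rle(hap)
              ends <- cumsum(r$lengths)
              starts <- c(1L, head(ends, -1L) + 1L)
              list(n_blocks = length(r$values),
                   b1_markers = r$lengths[1L],
                   b2_markers = if (length(r$lengths) >= 2L) r$lengths[2L] else NA_integer_,
                   b1_reads = as.numeric(sum(reads[starts[1L]:ends[1L]])),
                   b2_reads = if (length(r$values) >= 2L)
                     as.numeric(sum(reads[starts[2L]:ends[2L]])) else NA_real_,
                   left_marker = if (length(r$values) >= 2L)
                     as.numeric(pos[ends[1L]]) else NA_real_,
                   right_marker = if (length(r$values) >= 2L)
                     as.numeric(pos[starts[2L]]) else NA_real_)
            },
            by = .(mol, molecule_id, chrom)]
  allm <- m[, .(n_calls = .N, n_wild = sum(hap == "N"),
                span = max(pos) - min(pos)),
            by = .(mol, molecule_id)]
  info <- merge(info, allm[, .(mol, n_calls, n_wild, span)], by = "mol")
  info[, wildcard_fraction := n_wild / n_calls]

  reason <- rep("pass", nrow(info))
  reason[info$n_blocks == 1L] <- "non-recombinant"
  reason[info$n_blocks > 2L] <- "multi-switch"
  two <- info$n_blocks == 2L
  reason[two & info$span > params$max_molecule_span] <- "span"
  reason[two & reason == "pass" &
           info$wildcard_fraction > params$max_wildcard_fraction] <- "wildcards"
  reason[two & reason == "pass" &
           (info$b1_markers < params$min_markers_per_block |
              info$b2_markers < params$min_markers_per_block |
              info$b1_reads < params$min_reads_per_block |
              info$b2_reads < params$min_reads_per_block)] <- "block-support"
  # molecules whose calls are all wildcards never reach `info`
  n_silent <- length(unique(m$mol)) - nrow(info)

  ev <- info[reason == "pass"]
  out <- data.frame(hybrid_id = rep(hybrid_id, nrow(ev)),
                    molecule_id = ev$molecule_id,
                    chrom = ev$chrom,
                    left_marker = ev$left_marker,
                    right_marker = ev$right_marker,
                    distance = ev$right_marker - ev$left_marker,
                    resolution = 1 / (ev$right_marker - ev$left_marker),
                    markers_left = ev$b1_markers,
                    markers_right = ev$b2_markers,
                    reads_left = ev$b1_reads,
                    reads_right = ev$b2_reads,
                    wildcard_fraction = ev$wildcard_fraction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$left_marker, out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  rej <- table(factor(reason[reason != "pass"],
                      levels = c("non-recombinant", "multi-switch", "span",
                                 "wildcards", "block-support")))
  if (n_silent > 0) rej <- c(rej, `no-blocks` = n_silent)
  attr(out, "rejections") <- rej
  out
}

#' Keep only high-resolution crossovers
#'
#' Retains events whose resolution strictly exceeds the threshold,
#' equivalently whose flanking-marker distance is strictly below
#' `1/threshold` (at the default, below 1 kb). A stricter threshold of
#' 0.002 is conventional for motif-grade localization.
#'
#' @param events crossover event `data.frame` from [call_crossovers()].
#' @param threshold resolution cutoff in 1/bp.
#' @return filtered events.
#' @export
filter_high_resolution <- function(events, threshold = 0.001) {
  events[events$resolution > threshold, , drop = FALSE]
}

#' Crossover events as genomic intervals
#'
#' The CO interval is the half-open span between the flanking markers,
#' `[left_marker, right_marker)`, expressed in 1-based inclusive GRanges
#' coordinates; its width equals the flanking-marker distance.
#'
#' @param events crossover event `data.frame`.
#' @param genome optional `GenomeLayout` for bound validation.
#' @return `GRanges` with hybrid_id, molecule_id and resolution metadata.
#' @export
events_gr <- function(events, genome = NULL) {
  gr <- GRanges(events$chrom,
                IRanges(events$left_marker, events$right_marker - 1))
  mcols(gr)$hybrid_id <- events$hybrid_id
  mcols(gr)$molecule_id <- events$molecule_id
  mcols(gr)$resolution <- events$resolution
  if (!is.null(genome)) gr <- validate_in_genome(gr, genome, "CO events")
  gr
}

#' Write crossover events as BED6 and TSV
#'
#' BED name is the molecule id and score `round(1e6 * resolution)`;
#' the TSV carries all event columns.
#'
#' @param events crossover event `data.frame`.
#' @param bed,tsv output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_events <- function(events, bed = NULL, tsv = NULL) {
  if (!is.null(tsv)) {
    fwrite(as.data.table(events), tsv, sep = "\t")
  }
  if (!is.null(bed)) {
    gr <- events_gr(events)
    mcols(gr) <- NULL
    mcols(gr)$name <- events$molecule_id
    mcols(gr)$score <- pmin(1000, round(1e6 * events$resolution))
    write_bed(gr, bed)
  }
  invisible(list(bed = bed, tsv = tsv))
}

#' Per-hybrid crossover summary
#'
#' Mirrors the per-cross reporting of a recombination screen: number of
#' events and mean +/- sd flanking-marker distance in kb.
#'
#' @param events crossover event `data.frame` (may span several hybrids).
#' @return `data.frame` with one row per hybrid.
#' @export
summarize_events <- function(events) {
  sp <- split(events, events$hybrid_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(hybrid_id = d$hybrid_id[1L],
               n_cos = nrow(d),
               mean_distance_kb = mean(d$distance) / 1e3,
               sd_distance_kb = sd(d$distance) / 1e3)
  }))
  rownames(out) <- NULL
  out
}
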