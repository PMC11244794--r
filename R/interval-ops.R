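# Interval engine: merge/intersect/coverage/windows/shuffle/distance.
# All coordinates are 1-based inclusive inside the package (GRanges native);
# BED I/O converts to 0-based half-open at the boundary (see io.R).

#' Merge intervals that overlap or lie within a gap of each other
#'
#' Equivalent to `bedtools merge -d gap`: intervals separated by at most
#' `gap` bp are fused, so output intervals are pairwise separated by more
#' than `gap` bp.
#'
#' @param x `GRanges`.
#' @param gap non-negative gap tolerance in bp (`gap = 0` merges only
#'   overlapping or book-ended intervals).
#' @param genome optional `GenomeLayout`; when given, `x` is validated
#'   against chromosome bounds.
#' @return sorted, merged `GRanges`.
#' @export
merge_intervals <- function(x, gap = 0, genome = NULL) {
  stopifnot(is(x, "GRanges"), gap >= 0)
  if (!is.null(genome)) x <- validate_in_genome(x, genome)
  reduce(sort(as_unstranded(x)), min.gapwidth = gap + 1)
}

#' Base-pair intersection of two interval sets
#'
#' @param a,b `GRanges` on the same genome.
#' @return `GRanges` covering exactly the bases present in both inputs.
#' @export
intersect_intervals <- function(a, b) {
  a <- as_unstranded(a)
  b <- as_unstranded(b)
  suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Genome coverage of an interval set
#'
#' Counts each base once however many intervals cover it.
#'
#' @param x `GRanges`.
#' @param genome `GenomeLayout`.
#' @return list with `bp` (merged union size) and `fraction` of the genome.
#' @export
interval_coverage <- function(x, genome) {
  x <- validate_in_genome(x, genome)
  bp <- sum(as.numeric(width(reduce(x))))
  list(bp = bp, fraction = bp / genome_size(genome))
}

#' Reciprocal overlap of interval pairs
#'
#' For paired intervals a and b, returns
#' `min(|a intersect b| / |a|, |a intersect b| / |b|)`, the fraction used to
#' decide whether two intervals describe the same event. Pairs on different
#' chromosomes score 0.
#'
#' @param a,b `GRanges` of equal length; overlap is computed pairwise
#'   (element i of `a` against element i of `b`).
#' @return numeric vector in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), length(a) == length(b))
  if (!length(a)) return(numeric(0))
  inter <- pmax(0, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1)
  inter[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0
  pmin(inter / width(a), inter / width(b))
}

#' Sliding windows over a genome
#'
#' Generates a window starting at every multiple of `step` below the
#' chromosome length; final windows are clipped at the chromosome end
#' (`bedtools makewindows` behaviour) so every base is covered.
#'
#' @param genome `GenomeLayout`.
#' @param size window size in bp.
#' @param step step size in bp; `step = size` gives a non-overlapping tiling.
#' @return `GRanges` with a logical `clipped` metadata column.
#' @export
sliding_windows <- function(genome, size, step = size) {
  stopifnot(size >= step, step > 0)
  lens <- seqlengths(genome$seqinfo)
  out <- lapply(seq_along(lens), function(i) {
    L <- lens[[i]]
    starts <- seq.int(1L, L, by = step)
    ends <- pmin(starts + size - 1, L)
    GRanges(names(lens)[i], IRanges(starts, ends), seqinfo = genome$seqinfo)
  })
  w <- do.call(c, out)
  mcols(w)$clipped <- width(w) < size
  w
}

# --- placement machinery shared by shuffle_intervals and the permutation
# tests.  'allowed' is a data.frame of permissible placement segments
# (chrom index, start, end); an interval of width L can start at
# (end - start + 1) - L + 1 positions inside a segment. Segments are chosen
# with probability proportional to the number of valid start positions,
# which makes placement uniform over all valid genome positions
# (bedtools shuffle default).
allowed_table <- function(genome, within = NULL) {
  gr <- if (is.null(within)) genome_gr(genome) else
    reduce(validate_in_genome(within, genome, "allowed regions"))
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             width = width(gr), stringsAsFactors = FALSE)
}

# Sample n_sets placements for each interval width. Returns list of two
# length(widths) x n_sets matrices: chrom (character index into allowed$chrom
# rows) and start. Consumes the current RNG stream.
sample_placements <- function(widths, allowed, n_sets = 1L) {
  n <- length(widths)
  seg <- matrix(0L, n, n_sets)
  pos <- matrix(0L, n, n_sets)
  for (i in seq_len(n)) {
    slots <- allowed$width - widths[i] + 1
    ok <- which(slots > 0)
    if (!length(ok)) {
      stop("interval of width ", widths[i],
           " does not fit in any allowed segment")
    }
    s <- if (length(ok) == 1L) rep.int(ok, n_sets) else
      ok[sample.int(length(ok), n_sets, replace = TRUE, prob = slots[ok])]
    seg[i, ] <- s
    pos[i, ] <- allowed$start[s] + floor(runif(n_sets) * slots[s])
  }
  list(segment = seg, start = pos)
}

#' Randomly relocate intervals over a genome
#'
#' Places each interval uniformly over all positions where it fits, keeping
#' its length (the `bedtools shuffle` model). The chromosome is drawn with
#' probability proportional to the number of valid start positions. Fully
#' reproducible for a fixed seed.
#'
#' @param x `GRanges` to relocate.
#' @param genome `GenomeLayout`.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @param within optional `GRanges` restricting placements (e.g. one
#'   chromatin compartment); default is the whole genome.
#' @param per_chromosome if `TRUE`, each interval stays on its own
#'   chromosome.
#' @return `GRanges` with the same length multiset as `x`, in input order.
#' @export
shuffle_intervals <- function(x, genome, seed = NULL, within = NULL,
                              per_chromosome = FALSE) {
  x <- validate_in_genome(x, genome)
  if (!length(x)) return(x)
  with_seed(seed, {
    if (per_chromosome) {
      out <- x
      for (chr in unique(as.character(seqnames(x)))) {
        idx <- which(as.character(seqnames(x)) == chr)
        allow <- allowed_table(genome,
          if (is.null(within)) GRanges(chr, IRanges(1, seqlengths(genome$seqinfo)[chr]))
          else within[seqnames(within) == chr])
        pl <- sample_placements(width(x)[idx], allow, 1L)
        ranges(out)[idx] <- IRanges(pl$start[, 1], width = width(x)[idx])
      }
      out
    } else {
      allow <- allowed_table(genome, within)
      pl <- sample_placements(width(x), allow, 1L)
      GRanges(allow$chrom[pl$segment[, 1]],
              IRanges(pl$start[, 1], width = width(x)),
              seqinfo = genome$seqinfo)
    }
  })
}

#' Signed distance to the nearest feature
#'
#' For each query interval, the gap in bp to the closest feature edge:
#' 0 when they overlap or are book-ended, positive when the nearest feature
#' lies downstream (higher coordinates), negative when upstream. Queries on
#' chromosomes without any feature get `NA`.
#'
#' @param a query `GRanges` (e.g. crossover intervals).
#' @param b feature `GRanges` (e.g. structural variants).
#' @return numeric vector of length `length(a)`; `NA` marks "no feature on
#'   this chromosome".
#' @export
distance_to_nearest_signed <- function(a, b) {
  a <- as_unstranded(a)
  b <- as_unstranded(b)
  out <- rep(NA_real_, length(a))
  if (!length(a) || !length(b)) return(out)
  suppressWarnings({
    hits <- distanceToNearest(a, b, ignore.strand = TRUE)
  })
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  d <- mcols(hits)$distance
  sgn <- ifelse(start(b)[si] > end(a)[qi], 1,
                ifelse(end(b)[si] < start(a)[qi], -1, 0))
  out[qi] <- d * ifelse(d == 0, 1, sgn)
  out
}

# --- fast overlap counting against a fixed merged feature set -------------
# Used in the permutation-test inner loop where building GRanges per
# permutation would dominate runtime. Cross-checked against countOverlaps
# in the test suite.
feature_index <- function(features) {
  features <- reduce(sort(as_unstranded(features)))
  sp <- split(data.frame(s = start(features), e = end(features)),
              as.character(seqnames(features)), drop = TRUE)
  lapply(sp, function(d) list(starts = d$s, ends = d$e))
}

# chrom: character vector; qs/qe: numeric starts/ends (1-based inclusive).
# Returns the number of queries overlapping >=1 feature base.
count_overlapping <- function(chrom, qs, qe, fidx) {
  total <- 0L
  for (chr in unique(chrom)) {
    f <- fidx[[chr]]
    if (is.null(f)) next
    sel <- chrom == chr
    # features with start <= qe minus features with end < qs
    n_le <- findInterval(qe[sel], f$starts)
    n_lt <- findInterval(qs[sel] - 1, f$ends)
    total <- total + sum(n_le > n_lt)
  }
  total
}
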