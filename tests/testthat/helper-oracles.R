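# Per-base brute-force oracles for the interval engine, plus small
# constructors shared across tests. Oracles work on a toy genome encoded as
# a named list of logical occupancy vectors (one element per chromosome),
# fully independent of the GRanges-based implementation.

library(GenomicRanges)

toy_genome <- function(lengths) genome_layout(lengths)

# GRanges -> occupancy bitmap
as_bitmap <- function(gr, lengths) {
  maps <- lapply(lengths, function(L) logical(L))
  for (i in seq_along(gr)) {
    chr <- as.character(seqnames(gr))[i]
    maps[[chr]][start(gr)[i]:end(gr)[i]] <- TRUE
  }
  maps
}

# occupancy bitmap -> sorted GRanges of maximal runs
bitmap_to_gr <- function(maps) {
  out <- list()
  for (chr in names(maps)) {
    r <- rle(maps[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      out[[chr]] <- GRanges(factor(chr, levels = names(maps)),
                            IRanges(starts[keep], ends[keep]))
    }
  }
  if (!length(out)) return(GRanges())
  sort(do.call(c, unname(out)))
}

# oracle merge: scan occupancy runs, fuse runs separated by <= gap
oracle_merge <- function(gr, gap, lengths) {
  maps <- as_bitmap(gr, lengths)
  out <- list()
  for (chr in names(maps)) {
    r <- rle(maps[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    s <- starts[r$values]; e <- ends[r$values]
    if (!length(s)) next
    ms <- s[1]; me <- e[1]; acc_s <- c(); acc_e <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] - me - 1 <= gap) me <- e[i]
      else { acc_s <- c(acc_s, ms); acc_e <- c(acc_e, me); ms <- s[i]; me <- e[i] }
    }
    acc_s <- c(acc_s, ms); acc_e <- c(acc_e, me)
    out[[chr]] <- GRanges(factor(chr, levels = names(maps)),
                          IRanges(acc_s, acc_e))
  }
  if (!length(out)) return(GRanges())
  sort(do.call(c, unname(out)))
}

oracle_intersect <- function(a, b, lengths) {
  ma <- as_bitmap(a, lengths)
  mb <- as_bitmap(b, lengths)
  bitmap_to_gr(mapply(function(x, y) x & y, ma, mb, SIMPLIFY = FALSE))
}

oracle_coverage <- function(gr, lengths) {
  sum(vapply(as_bitmap(gr, lengths), sum, numeric(1)))
}

# random interval set on a toy genome
random_intervals <- function(n, lengths, max_len = NULL) {
  chr <- sample(names(lengths), n, replace = TRUE)
  L <- unlist(lengths)[chr]
  max_len <- max_len %||% pmax(1, floor(L / 4))
  len <- pmax(1, floor(runif(n) * pmin(max_len, L)))
  s <- floor(runif(n) * (L - len + 1)) + 1
  gr <- GRanges(chr, IRanges(s, s + len - 1))
  seqlevels(gr) <- names(lengths)
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinate frame for seqinfo-agnostic GRanges comparison
gr_frame <- function(gr) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr), end = end(gr),
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# exact two-sided Fisher p for a 2x2 table, by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
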