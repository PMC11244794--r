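#' Genome layout: chromosome lengths and chromatin compartments
#'
#' A `GenomeLayout` holds the chromosome sizes of the reference assembly and
#' its partition into pericentromeric heterochromatin (PER) and distal
#' euchromatin (DEU). PER intervals are supplied (e.g. from cytogenetic or
#' methylation evidence); DEU is derived as their complement, so the two
#' compartments partition every chromosome exactly.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome identifiers; all lengths > 0).
#' @param per_intervals `GRanges` of pericentromere intervals (1-based,
#'   inclusive, as native to `GRanges`), or `NULL` for a genome treated as
#'   all-DEU.
#' @return An object of class `GenomeLayout` with elements `seqinfo`,
#'   `per` and `deu` (both reduced, unstranded `GRanges`).
#' @examples
#' g <- genome_layout(c(chr1 = 30e6),
#'   per_intervals = GenomicRanges::GRanges("chr1", IRanges::IRanges(7.5e6 + 1, 22.5e6)))
#' genome_size(g)
#' @export
genome_layout <- function(chrom_lengths, per_intervals = NULL) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1L)
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths))) {
    stop("chrom_lengths must have unique names")
  }
  if (any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be > 0")
  }
  si <- Seqinfo(seqnames = names(chrom_lengths),
                seqlengths = as.integer(chrom_lengths))
  whole <- GRanges(names(chrom_lengths),
                   IRanges(1L, as.integer(chrom_lengths)),
                   seqinfo = si)
  if (is.null(per_intervals)) {
    per <- GRanges(seqinfo = si)
  } else {
    per <- as_unstranded(per_intervals)
    if (!all(as.character(seqnames(per)) %in% names(chrom_lengths))) {
      stop("PER intervals on unknown chromosomes")
    }
    seqlevels(per) <- names(chrom_lengths)
    seqinfo(per) <- si
    hi <- seqlengths(si)[as.character(seqnames(per))]
    if (any(start(per) < 1L) || any(end(per) > hi)) {
      stop("PER intervals outside chromosome bounds")
    }
    per <- reduce(per)
  }
  deu <- setdiff(whole, per)
  structure(list(seqinfo = si, per = per, deu = deu),
            class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(seqlengths(x$seqinfo)), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp\n")
  cat("  PER:", format(sum(width(x$per)), big.mark = ","), "bp in",
      length(x$per), "intervals\n")
  cat("  DEU:", format(sum(width(x$deu)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Total genome size in bp
#' @param g a `GenomeLayout`.
#' @return numeric, sum of chromosome lengths.
#' @export
genome_size <- function(g) {
  stopifnot(inherits(g, "GenomeLayout"))
  sum(as.numeric(seqlengths(g$seqinfo)))
}

#' Whole-chromosome intervals of a genome
#' @param g a `GenomeLayout`.
#' @return `GRanges` with one range per chromosome.
#' @export
genome_gr <- function(g) {
  stopifnot(inherits(g, "GenomeLayout"))
  GRanges(seqlevels(g$seqinfo),
          IRanges(1L, seqlengths(g$seqinfo)),
          seqinfo = g$seqinfo)
}

#' Compartment intervals of a genome
#' @param g a `GenomeLayout`.
#' @param compartment `"DEU"` or `"PER"`.
#' @return `GRanges` of the requested compartment.
#' @export
compartment_gr <- function(g, compartment = c("DEU", "PER")) {
  compartment <- match.arg(compartment)
  if (compartment == "DEU") g$deu else g$per
}

# Check that a GRanges lies within genome bounds; stop otherwise.
validate_in_genome <- function(x, g, what = "intervals") {
  x <- as_unstranded(x)
  if (!all(as.character(seqnames(x)) %in% seqlevels(g$seqinfo))) {
    stop(what, " on chromosomes absent from the genome layout")
  }
  hi <- seqlengths(g$seqinfo)[as.character(seqnames(x))]
  if (length(x) && (any(start(x) < 1L) || any(end(x) > hi))) {
    stop(what, " outside chromosome bounds")
  }
  seqlevels(x) <- seqlevels(g$seqinfo)
  seqinfo(x) <- g$seqinfo
  x
}
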