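# Readers and writers for the plain-text exchange formats of the pipeline.
# BED files are 0-based half-open (handled by rtracklayer); package TSVs use
# 1-based inclusive coordinates like VCF/GFF3 and GRanges.

#' Read a bedtools-style genome file
#'
#' Two tab-separated columns: chromosome name, length in bp. A third
#' optional input, a BED file of pericentromere intervals, completes the
#' layout.
#'
#' @param genome_file path to the chrom/length TSV (no header).
#' @param per_bed optional path to a BED file of PER intervals.
#' @return a [genome_layout()] object.
#' @export
read_genome <- function(genome_file, per_bed = NULL) {
  d <- read.delim(genome_file, header = FALSE, col.names = c("chrom", "length"),
                  colClasses = c("character", "numeric"))
  per <- if (!is.null(per_bed)) read_bed(per_bed) else NULL
  genome_layout(setNames(d$length, d$chrom), per_intervals = per)
}

#' Write a genome layout to a genome file (and optional PER BED)
#' @param g `GenomeLayout`.
#' @param genome_file output path for the chrom/length TSV.
#' @param per_bed optional output path for the PER intervals BED.
#' @return `genome_file`, invisibly.
#' @export
write_genome <- function(g, genome_file, per_bed = NULL) {
  d <- data.frame(chrom = seqlevels(g$seqinfo),
                  length = seqlengths(g$seqinfo))
  write.table(d, genome_file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(per_bed)) write_bed(g$per, per_bed)
  invisible(genome_file)
}

#' Read a BED3/BED6 file as GRanges
#' @param path BED file path (tab-separated, 0-based half-open).
#' @return unstranded `GRanges`; name/score columns kept when present.
#' @export
read_bed <- function(path) {
  as_unstranded(rtracklayer::import(path, format = "BED"))
}

#' Write GRanges as BED
#'
#' Writes BED6 when `name`/`score` metadata columns are present, BED3
#' otherwise. Coordinates are converted to 0-based half-open.
#'
#' @param x `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(as_unstranded(x), path, format = "BED")
  invisible(path)
}

#' Read segregating SNP markers from TSV
#'
#' Expected columns: `chrom`, `pos` (1-based), and optionally `ref`, `alt`.
#' Positions must be strictly increasing per chromosome and markers
#' biallelic; violations are rejected because downstream phasing logic
#' assumes ordered, homozygous-divergent markers.
#'
#' @param path marker TSV with header.
#' @return `data.frame` with columns chrom, pos, ref, alt.
#' @export
read_markers <- function(path) {
  d <- as.data.frame(fread(path, sep = "\t"))
  validate_markers(d)
}

#' Read segregating SNP markers from VCF
#'
#' Keeps biallelic SNP records with FILTER `PASS` or `.`; positions are the
#' VCF 1-based POS.
#'
#' @param path VCF path (plain or gzipped).
#' @return `data.frame` with columns chrom, pos, ref, alt.
#' @export
read_markers_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- (is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  d <- data.frame(chrom = fix$CHROM[keep],
                  pos = as.numeric(fix$POS[keep]),
                  ref = fix$REF[keep], alt = fix$ALT[keep],
                  stringsAsFactors = FALSE)
  validate_markers(d)
}

validate_markers <- function(d) {
  stopifnot(all(c("chrom", "pos") %in% names(d)))
  if (is.null(d$ref)) d$ref <- "A"
  if (is.null(d$alt)) d$alt <- "T"
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  dup <- unlist(tapply(d$pos, d$chrom, function(p) c(FALSE, diff(p) <= 0)))
  if (any(dup)) stop("marker positions not strictly increasing per chromosome")
  if (any(d$ref == d$alt)) stop("markers must be biallelic (ref != alt)")
  rownames(d) <- NULL
  d[, c("chrom", "pos", "ref", "alt")]
}

#' Write markers to TSV
#' @param markers marker `data.frame` (chrom, pos, ref, alt).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  fwrite(as.data.table(markers), path, sep = "\t")
  invisible(path)
}

# Markers as width-1 GRanges.
markers_gr <- function(markers, genome = NULL) {
  gr <- GRanges(markers$chrom, IRanges(markers$pos, markers$pos))
  if (!is.null(genome)) gr <- validate_in_genome(gr, genome, "markers")
  gr
}

#' Read phased molecule marker calls
#'
#' One row per marker observation on a molecule. Columns: `molecule_id`,
#' `chrom`, `pos` (1-based marker position), `hap` (`A`/`B` parental
#' haplotype or `N` wildcard), `reads` (supporting read count).
#'
#' @param path molecules TSV with header.
#' @return `data.table` keyed by molecule_id and pos.
#' @export
read_molecules <- function(path) {
  d <- fread(path, sep = "\t",
             colClasses = list(character = c("molecule_id", "chrom", "hap")))
  stopifnot(all(c("molecule_id", "chrom", "pos", "hap", "reads") %in% names(d)))
  if (!all(d$hap %in% c("A", "B", "N"))) {
    stop("hap column must contain only A, B or N")
  }
  setorder(d, molecule_id, pos)
  d
}

#' Write phased molecule marker calls to TSV
#' @param molecules molecules `data.table`/`data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  fwrite(as.data.table(molecules), path, sep = "\t")
  invisible(path)
}

#' Read structural variant calls from TSV
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `type`
#' (DEL/INV/other), `source` (`wild_inbred`, `f1_pollen` or `self`).
#'
#' @param path SV TSV with header.
#' @return `GRanges` with `type` and `source` metadata columns.
#' @export
read_svs <- function(path) {
  d <- as.data.frame(fread(path, sep = "\t"))
  stopifnot(all(c("chrom", "start", "end", "type") %in% names(d)))
  gr <- GRanges(d$chrom, IRanges(d$start, d$end))
  mcols(gr)$type <- as.character(d$type)
  mcols(gr)$source <- if ("source" %in% names(d)) as.character(d$source) else NA_character_
  as_unstranded(gr)
}

#' Read structural variant calls from VCF
#'
#' Uses symbolic ALT alleles or the SVTYPE INFO field for the type and the
#' END INFO field for the end coordinate. Types other than DEL/INV are kept
#' with `type = "other"` for reporting.
#'
#' @param path VCF path.
#' @param source provenance label to attach (`wild_inbred`, `f1_pollen`,
#'   `self`).
#' @return `GRanges` with `type` and `source` metadata columns.
#' @export
read_svs_vcf <- function(path, source = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_end <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  info_type <- vcfR::extract.info(v, "SVTYPE")
  alt_type <- sub("^<(.+)>$", "\\1", fix$ALT)
  type <- ifelse(!is.na(info_type), info_type, alt_type)
  type[!type %in% c("DEL", "INV")] <- "other"
  pos <- as.numeric(fix$POS)
  end <- ifelse(is.na(info_end), pos + nchar(fix$REF) - 1, info_end)
  gr <- GRanges(fix$CHROM, IRanges(pos, pmax(pos, end)))
  mcols(gr)$type <- type
  mcols(gr)$source <- source
  as_unstranded(gr)
}

#' Write structural variant calls to TSV
#' @param svs `GRanges` with `type`/`source` metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svs <- function(svs, path) {
  d <- data.frame(chrom = as.character(seqnames(svs)),
                  start = start(svs), end = end(svs),
                  type = mcols(svs)$type,
                  source = mcols(svs)$source %||% NA_character_)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map as (physical bp, cM) pairs
#' @param path two-column TSV (bp, cM), with or without header.
#' @return `data.frame` with columns bp, cM.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  d <- read.delim(path, header = has_header)
  names(d)[1:2] <- c("bp", "cM")
  d[order(d$bp), 1:2]
}
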