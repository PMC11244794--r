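# Gene-model handling and assignment of COs / coldspots to genic features.

#' Construct a gene-model set
#'
#' @param genes `data.frame` with columns gene_id, chrom, start, end,
#'   strand, and optional utr5_len / utr3_len (bp of the transcript ends
#'   that are untranslated).
#' @param exons `data.frame` with columns gene_id, start, end (1-based
#'   inclusive), all within the gene span.
#' @param genome optional `GenomeLayout` for bound validation.
#' @return object of class `gene_models`: `table` (the gene frame),
#'   `exons`, `gr` (stranded gene-span `GRanges`).
#' @export
gene_models <- function(genes, exons, genome = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)),
            all(exons$gene_id %in% genes$gene_id))
  if (is.null(genes$utr5_len)) genes$utr5_len <- 0L
  if (is.null(genes$utr3_len)) genes$utr3_len <- 0L
  span <- genes[match(exons$gene_id, genes$gene_id), c("start", "end")]
  if (any(exons$start < span$start | exons$end > span$end)) {
    stop("exons outside gene spans")
  }
  gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                strand = genes$strand)
  mcols(gr)$gene_id <- genes$gene_id
  if (!is.null(genome)) {
    gr2 <- validate_in_genome(gr, genome, "genes")
    strand(gr2) <- strand(gr)
    gr <- gr2
  }
  structure(list(table = genes, exons = exons, gr = gr),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$table), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Consumes `gene` and `exon` records (ITAG-style `Parent`/`ID` attributes
#' tolerated); UTR lengths are taken from `five_prime_UTR` /
#' `three_prime_UTR` records when present.
#'
#' @param path GFF3 path.
#' @param genome optional `GenomeLayout`.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  gene_rec <- gff[gff$type == "gene"]
  ids <- as.character(gene_rec$ID %||% gene_rec$Name)
  genes <- data.frame(gene_id = ids,
                      chrom = as.character(seqnames(gene_rec)),
                      start = start(gene_rec), end = end(gene_rec),
                      strand = as.character(strand(gene_rec)),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  parent_of <- function(rec) {
    p <- rec$Parent
    vapply(as.list(p), function(v) sub("^mRNA:", "", v[1] %||% NA_character_),
           character(1))
  }
  ex_rec <- gff[gff$type == "exon"]
  exons <- data.frame(gene_id = sub("\\.m1$", "", parent_of(ex_rec)),
                      start = start(ex_rec), end = end(ex_rec),
                      stringsAsFactors = FALSE)
  exons <- exons[exons$gene_id %in% genes$gene_id, ]
  for (utr in c("five_prime_UTR", "three_prime_UTR")) {
    col <- if (utr == "five_prime_UTR") "utr5_len" else "utr3_len"
    rec <- gff[gff$type == utr]
    genes[[col]] <- 0L
    if (length(rec)) {
      ln <- tapply(width(rec), sub("\\.m1$", "", parent_of(rec)), sum)
      idx <- match(names(ln), genes$gene_id)
      genes[[col]][idx[!is.na(idx)]] <- as.integer(ln[!is.na(idx)])
    }
  }
  gene_models(genes, exons, genome)
}

#' Write gene models as GFF3
#' @param models a [gene_models()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  g <- models$table
  gene_gr <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand)
  mcols(gene_gr)$type <- "gene"
  mcols(gene_gr)$ID <- g$gene_id
  ex <- models$exons
  exon_gr <- GRanges(g$chrom[match(ex$gene_id, g$gene_id)],
                     IRanges(ex$start, ex$end),
                     strand = g$strand[match(ex$gene_id, g$gene_id)])
  mcols(exon_gr)$type <- "exon"
  mcols(exon_gr)$Parent <- ex$gene_id
  utr_gr <- gene_utr_ranges(models)
  all <- suppressWarnings(c(gene_gr, exon_gr, utr_gr))
  mcols(all)$source <- "coldspotAtlas"
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

# strand-aware terminal UTR intervals derived from utr5_len/utr3_len
gene_utr_ranges <- function(models) {
  g <- models$table
  mk <- function(len, five) {
    has <- len > 0
    if (!any(has)) return(GRanges())
    d <- g[has, ]
    l <- len[has]
    at_start <- (d$strand == "+") == five  # 5' UTR at low coords on + strand
    s <- ifelse(at_start, d$start, d$end - l + 1)
    gr <- GRanges(d$chrom, IRanges(s, s + l - 1), strand = d$strand)
    mcols(gr)$type <- if (five) "five_prime_UTR" else "three_prime_UTR"
    mcols(gr)$Parent <- d$gene_id
    gr
  }
  suppressWarnings(c(mk(g$utr5_len, TRUE), mk(g$utr3_len, FALSE)))
}

#' Disjoint genic feature track
#'
#' Expands gene models into labelled intervals: exon (non-UTR), 5'/3' UTR,
#' intron, and strand-aware 1 kb upstream/downstream flanks (from TSS and
#' TTS respectively, clipped at chromosome ends when a genome is given).
#' Interval arithmetic runs on plain per-gene coordinate vectors; a single
#' `GRanges` is assembled at the end.
#'
#' @param models a [gene_models()] object.
#' @param flank flank length in bp.
#' @param genome optional `GenomeLayout` used to clip flanks.
#' @return `GRanges` with metadata columns `feature` and `gene_id`.
#' @export
gene_feature_track <- function(models, flank = 1000, genome = NULL) {
  g <- models$table
  ex <- models$exons
  ex_f <- data.frame(gene_id = ex$gene_id, start = ex$start, end = ex$end)
  # terminal UTR intervals, strand-aware
  utr_f <- local({
    mk <- function(len, five) {
      has <- which(len > 0)
      if (!length(has)) return(NULL)
      d <- g[has, ]
      l <- len[has]
      at_start <- (d$strand == "+") == five
      s <- ifelse(at_start, d$start, d$end - l + 1)
      data.frame(gene_id = d$gene_id, start = s, end = s + l - 1,
                 five = five)
    }
    rbind(mk(g$utr5_len, TRUE), mk(g$utr3_len, FALSE))
  })
  pieces <- list(
    five_utr = if (!is.null(utr_f))
      intersect_frame(ex_f, utr_f[utr_f$five, ]) else NULL,
    three_utr = if (!is.null(utr_f))
      intersect_frame(ex_f, utr_f[!utr_f$five, ]) else NULL,
    exon = if (!is.null(utr_f)) setdiff_frame(ex_f, utr_f) else ex_f,
    intron = setdiff_frame(
      data.frame(gene_id = g$gene_id, start = g$start, end = g$end), ex_f))
  # flanks
  tss <- ifelse(g$strand == "+", g$start, g$end)
  tts <- ifelse(g$strand == "+", g$end, g$start)
  up_s <- ifelse(g$strand == "+", tss - flank, tss + 1)
  up_e <- ifelse(g$strand == "+", tss - 1, tss + flank)
  dn_s <- ifelse(g$strand == "+", tts + 1, tts - flank)
  dn_e <- ifelse(g$strand == "+", tts + flank, tts - 1)
  clip <- function(s, e) {
    lo <- pmax(1, s)
    hi <- if (is.null(genome)) e else
      pmin(e, seqlengths(genome$seqinfo)[g$chrom])
    ok <- hi >= lo
    data.frame(gene_id = g$gene_id[ok], start = lo[ok], end = unname(hi)[ok])
  }
  pieces$upstream <- clip(up_s, up_e)
  pieces$downstream <- clip(dn_s, dn_e)
  pieces <- pieces[!vapply(pieces, function(p) is.null(p) || !nrow(p),
                           logical(1))]
  flat <- do.call(rbind, Map(function(d, f) cbind(d, feature = f),
                             pieces, names(pieces)))
  chrom <- g$chrom[match(flat$gene_id, g$gene_id)]
  out <- GRanges(chrom, IRanges(flat$start, flat$end))
  mcols(out)$gene_id <- flat$gene_id
  mcols(out)$feature <- flat$feature
  if (!is.null(genome)) out <- validate_in_genome(out, genome, "gene features")
  BiocGenerics::sort(out)
}

# merge sorted intervals of one gene given as two numeric vectors
merge_runs <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  keep_s <- s[1]; keep_e <- e[1]
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] <= keep_e[length(keep_e)] + 1) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
  }
  list(s = keep_s, e = keep_e)
}

# per-gene interval intersection on coordinate frames (gene_id, start, end)
intersect_frame <- function(x, y) {
  if (is.null(y) || !nrow(y)) return(NULL)
  ysp <- split(y[c("start", "end")], y$gene_id)
  res_g <- list()
  xsp <- split(x[c("start", "end")], x$gene_id)
  for (gid in intersect(names(xsp), names(ysp))) {
    xs <- xsp[[gid]]; ys <- ysp[[gid]]
    ss <- numeric(0); ee <- numeric(0)
    for (j in seq_len(nrow(ys))) {
      lo <- pmax(xs$start, ys$start[j])
      hi <- pmin(xs$end, ys$end[j])
      ok <- hi >= lo
      ss <- c(ss, lo[ok]); ee <- c(ee, hi[ok])
    }
    if (length(ss)) {
      res_g[[gid]] <- data.frame(gene_id = gid, start = ss, end = ee)
    }
  }
  if (!length(res_g)) return(NULL)
  do.call(rbind, res_g)
}

# per-gene interval subtraction on coordinate frames
setdiff_frame <- function(x, y) {
  if (is.null(y) || !nrow(y)) return(x)
  ysp <- split(y[c("start", "end")], y$gene_id)
  res_g <- list()
  xsp <- split(x[c("start", "end")], x$gene_id)
  for (gid in names(xsp)) {
    xs <- merge_runs(xsp[[gid]]$start, xsp[[gid]]$end)
    ss <- xs$s; ee <- xs$e
    ys <- ysp[[gid]]
    if (!is.null(ys)) {
      for (j in seq_len(nrow(ys))) {
        ns <- numeric(0); ne <- numeric(0)
        for (i in seq_along(ss)) {
          if (ys$end[j] < ss[i] || ys$start[j] > ee[i]) {
            ns <- c(ns, ss[i]); ne <- c(ne, ee[i])
          } else {
            if (ys$start[j] > ss[i]) {
              ns <- c(ns, ss[i]); ne <- c(ne, ys$start[j] - 1)
            }
            if (ys$end[j] < ee[i]) {
              ns <- c(ns, ys$end[j] + 1); ne <- c(ne, ee[i])
            }
          }
        }
        ss <- ns; ee <- ne
        if (!length(ss)) break
      }
    }
    if (length(ss)) {
      res_g[[gid]] <- data.frame(gene_id = gid, start = ss, end = ee)
    }
  }
  if (!length(res_g)) return(NULL)
  do.call(rbind, res_g)
}

#' Assign each CO to a single genic feature
#'
#' COs spanning several features get the label of the highest-priority
#' overlap (exon > UTR > intron > upstream > downstream > intergenic),
#' ties broken by larger overlap; COs touching more than one gene are
#' flagged.
#'
#' @param cos CO intervals (`GRanges`) or event `data.frame`.
#' @param models a [gene_models()] object.
#' @param genome optional `GenomeLayout`.
#' @return `data.frame`: one row per CO with `feature` and `multi_gene`.
#' @export
assign_feature <- function(cos, models, genome = NULL) {
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  track <- gene_feature_track(models, genome = genome)
  prio <- c(exon = 1, five_utr = 2, three_utr = 2, intron = 3,
            upstream = 4, downstream = 5)
  hits <- findOverlaps(cos, track, ignore.strand = TRUE)
  ov <- pmin(end(cos)[queryHits(hits)], end(track)[subjectHits(hits)]) -
    pmax(start(cos)[queryHits(hits)], start(track)[subjectHits(hits)]) + 1
  feature <- rep("intergenic", length(cos))
  multi <- rep(FALSE, length(cos))
  if (length(hits)) {
    d <- data.frame(q = queryHits(hits),
                    f = mcols(track)$feature[subjectHits(hits)],
                    g = mcols(track)$gene_id[subjectHits(hits)],
                    p = prio[mcols(track)$feature[subjectHits(hits)]],
                    ov = ov)
    d <- d[order(d$q, d$p, -d$ov), ]
    first <- !duplicated(d$q)
    feature[d$q[first]] <- d$f[first]
    ng <- tapply(d$g, d$q, function(x) length(unique(x)))
    multi[as.integer(names(ng))] <- ng > 1
  }
  data.frame(feature = feature, multi_gene = multi)
}

#' Partition COs by distance to the nearest gene
#'
#' Counts events within genes and their `flank` (1 kb) margins, events
#' between `flank` and `far` (3 kb), and events beyond; any-bp overlap
#' decides membership.
#'
#' @param cos CO intervals or event `data.frame`.
#' @param models a [gene_models()] object.
#' @param genome optional `GenomeLayout`.
#' @param flank,far distance-class boundaries in bp.
#' @return named list: `n_within`, `n_1to3kb`, `n_beyond` (sums to
#'   `length(cos)`).
#' @export
count_genic_cos <- function(cos, models, genome = NULL, flank = 1e3,
                            far = 3e3) {
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  span <- as_unstranded(models$gr)
  near <- suppressWarnings(trim(resize(span, width(span) + 2 * flank,
                                       fix = "center")))
  wide <- suppressWarnings(trim(resize(span, width(span) + 2 * far,
                                       fix = "center")))
  within <- overlapsAny(cos, near, ignore.strand = TRUE)
  mid <- !within & overlapsAny(cos, wide, ignore.strand = TRUE)
  list(n_within = sum(within), n_1to3kb = sum(mid),
       n_beyond = sum(!within & !mid))
}

#' Coldspot gene groups and trait-gene enrichment
#'
#' Genes are assigned to coldspots by any-bp overlap; a coldspot whose
#' gene set reaches `min_genes` members forms a coldspot gene group. When
#' a trait table is supplied (columns gene_id, trait), genes linked to
#' named traits are counted per group and a Fisher exact test asks whether
#' trait genes are over-represented among coldspot genes relative to the
#' rest of the annotation.
#'
#' @param coldspots coldspot `GRanges` (pooled or per hybrid).
#' @param models a [gene_models()] object.
#' @param trait_table optional `data.frame` (gene_id, trait).
#' @param min_genes group threshold (default 20).
#' @return list: `groups` (`data.frame`, one row per qualifying coldspot),
#'   `n_coldspot_genes` (distinct genes in any coldspot),
#'   `trait_fisher` (`NULL` without a trait table).
#' @export
coldspot_gene_report <- function(coldspots, models, trait_table = NULL,
                                 min_genes = 20) {
  span <- as_unstranded(models$gr)
  hits <- findOverlaps(coldspots, span, ignore.strand = TRUE)
  genes_by_cs <- split(mcols(span)$gene_id[subjectHits(hits)],
                       queryHits(hits))
  n_genes <- lengths(genes_by_cs)
  idx <- as.integer(names(genes_by_cs))
  groups <- data.frame(
    coldspot = idx,
    chrom = as.character(seqnames(coldspots))[idx],
    start = start(coldspots)[idx], end = end(coldspots)[idx],
    hybrid_id = (mcols(coldspots)$hybrid_id %||%
                   rep(NA_character_, length(coldspots)))[idx],
    n_genes = as.integer(n_genes), stringsAsFactors = FALSE)
  if (!is.null(trait_table)) {
    trait_genes <- unique(trait_table$gene_id)
    groups$n_trait_genes <- vapply(genes_by_cs, function(gs)
      length(intersect(unique(gs), trait_genes)), integer(1))
  }
  in_cs <- unique(unlist(genes_by_cs, use.names = FALSE))
  trait_fisher <- NULL
  if (!is.null(trait_table)) {
    all_genes <- models$table$gene_id
    is_cs <- all_genes %in% in_cs
    is_tr <- all_genes %in% unique(trait_table$gene_id)
    tab <- table(coldspot = is_cs, trait = is_tr)
    if (all(dim(tab) == c(2, 2))) {
      ft <- fisher.test(tab)
      trait_fisher <- list(odds_ratio = unname(ft$estimate),
                           p = ft$p.value, table = tab)
    }
  }
  list(groups = groups[groups$n_genes >= min_genes, , drop = FALSE],
       all_counts = groups,
       n_coldspot_genes = length(in_cs),
       trait_fisher = trait_fisher)
}
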