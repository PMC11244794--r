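# Synthetic corpus generator.
#
# Emulates the statistical structure of a pooled-pollen recombination
# screen in an interspecific cross: a genome partitioned into distal
# euchromatin (DEU) and pericentromeric heterochromatin (PER); dense
# segregating SNP markers; long linked-read molecules carrying phased
# marker calls with at most one planted haplotype switch; TE superfamily
# tracks with compartment bias; gene models; ACRs; and three structural-
# variant call sets (wild inbred, F1 pollen, self) with configurable
# sharing. Crossover placement follows a piecewise-constant intensity:
# compartment weight x SV suppression x TE multipliers x gene preference.
# All randomness flows from one master seed through deterministic
# sub-stage seeds, so a corpus is bit-reproducible.

#' Simulation configuration
#'
#' Defaults describe a scaled-down tomato-like study: 3 chromosomes of
#' 30 Mb, 70% pericentromeric, markers denser in DEU, ~50 kb linked-read
#' molecules, and a per-bp CO intensity about 12x higher in DEU than PER
#' (roughly nine of ten COs in distal euchromatin). The default `co_rate`
#' preserves the per-Mb crossover density of a pooled-pollen screen
#' (~1,300 COs on a 780 Mb genome scale to ~200 here), which keeps the
#' megabase-scale coldspot geometry of the pericentromeres intact;
#' detection-power studies should raise `co_rate` instead of reading more
#' molecules. SV suppression (0.1) and TE multipliers encode crossover
#' avoidance of structural heterozygosity and retrotransposon-dense
#' chromatin, and a 3x gene preference concentrates COs in genic regions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param per_fraction fraction of each chromosome that is PER, centered.
#' @param marker_density_deu,marker_density_per expected markers per kb.
#' @param n_molecules molecules per hybrid.
#' @param molecule_mean,molecule_sd,molecule_max molecule length
#'   distribution (log-normal by moments, truncated at `molecule_max`) in bp.
#' @param co_rate probability that a molecule carries one crossover.
#' @param deu_co_weight,per_co_weight relative per-bp CO intensity of the
#'   two compartments.
#' @param sv_count structural variants per wild genome.
#' @param sv_meanlog,sv_sdlog log-normal SV length parameters (bp).
#' @param sv_deu_fraction fraction of SVs placed in distal euchromatin
#'   (wild tomato accessions carry more SVs in DEU than PER, roughly
#'   1.55:1).
#' @param sv_per_length_factor length multiplier for SVs landing in PER
#'   (pericentromeric SVs run longer than distal ones).
#' @param sv_suppression CO intensity multiplier inside SVs larger than
#'   1 kb (0 = hard suppression, 1 = no effect).
#' @param te_tracks named list of TE superfamily specs, each a list with
#'   `n` (intervals), `len_range` (bp), `bias` (`"PER"`, `"DEU"` or
#'   `"none"`; hard: all intervals fall in the biased compartment) and
#'   `multiplier` (CO intensity multiplier inside the track).
#' @param gene_count gene models to place.
#' @param gene_deu_fraction fraction of genes placed in DEU.
#' @param gene_co_multiplier CO intensity multiplier inside genes and
#'   their 1 kb flanks.
#' @param acr_count accessible chromatin regions.
#' @param acr_overlap_prob probability an ACR is anchored at a gene TSS
#'   (CO-favourable) rather than placed uniformly.
#' @param parental_fraction fraction of wild-inbred SVs also called in the
#'   F1 pollen data (i.e. truly heterozygous in the F1).
#' @param self_overlap_fraction fraction of self SVs planted on top of
#'   parental SVs (artifact overlap).
#' @param n_self_svs self SV count.
#' @param wildcard_prob per-marker probability of a wildcard (`N`) call.
#' @param flip_prob per-marker probability of a haplotype flip (noise).
#' @param double_switch_rate probability that a molecule is a
#'   gene-conversion-like double-switch contaminant.
#' @param coldspot_spec optional `GRanges` of planted zero-intensity
#'   regions (forced coldspots); `NULL` plants none beyond PER physics.
#' @param seed master seed for the corpus.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length = 30e6,
                       per_fraction = 0.7,
                       marker_density_deu = 1.0,
                       marker_density_per = 0.5,
                       n_molecules = 10e3,
                       molecule_mean = 50e3,
                       molecule_sd = 35e3,
                       molecule_max = 250e3,
                       co_rate = 0.025,
                       deu_co_weight = 1.0,
                       per_co_weight = 0.08,
                       sv_count = 400,
                       sv_meanlog = log(4e3),
                       sv_sdlog = 1.3,
                       sv_deu_fraction = 0.6,
                       sv_per_length_factor = 2.0,
                       sv_suppression = 0.1,
                       te_tracks = list(
                         Gypsy = list(n = 900, len_range = c(3e3, 12e3),
                                      bias = "PER", multiplier = 0.2),
                         Copia = list(n = 500, len_range = c(2e3, 9e3),
                                      bias = "PER", multiplier = 0.3),
                         Stowaway = list(n = 600, len_range = c(300, 2e3),
                                         bias = "DEU", multiplier = 2.0)),
                       gene_count = 2000,
                       gene_deu_fraction = 0.85,
                       gene_co_multiplier = 3.0,
                       acr_count = 1500,
                       acr_overlap_prob = 0.6,
                       parental_fraction = 0.7,
                       self_overlap_fraction = 0.1,
                       n_self_svs = 30,
                       wildcard_prob = 0,
                       flip_prob = 0,
                       double_switch_rate = 0,
                       coldspot_spec = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$per_fraction, cfg$co_rate, cfg$acr_overlap_prob,
             cfg$parental_fraction, cfg$self_overlap_fraction,
             cfg$wildcard_prob, cfg$flip_prob, cfg$double_switch_rate)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$per_fraction < 1,
            cfg$deu_co_weight >= 0, cfg$per_co_weight >= 0,
            cfg$sv_suppression >= 0, cfg$gene_co_multiplier >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate the genome layout
#'
#' Equal-length chromosomes with a centered PER interval of
#' `per_fraction * chrom_length` bp; DEU is the complement.
#'
#' @param cfg [sim_config()].
#' @return `GenomeLayout`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$chrom_length
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  lens <- setNames(rep(L, cfg$n_chromosomes), chroms)
  if (cfg$per_fraction > 0) {
    per_len <- round(cfg$per_fraction * L)
    s <- floor((L - per_len) / 2) + 1
    per <- GRanges(chroms, IRanges(s, s + per_len - 1))
  } else {
    per <- NULL
  }
  genome_layout(lens, per)
}

#' Simulate segregating SNP markers
#'
#' Poisson marker counts per compartment at the configured per-kb density,
#' positions uniform within the compartment, strictly increasing per
#' chromosome.
#'
#' @param cfg [sim_config()].
#' @param genome `GenomeLayout`.
#' @param seed stage seed (defaults to one derived from `cfg$seed`).
#' @return marker `data.frame` (chrom, pos, ref, alt).
#' @export
simulate_markers <- function(cfg, genome, seed = derive_seed(cfg$seed, "markers")) {
  with_seed(seed, {
    place <- function(comp, dens) {
      if (!length(comp) || dens <= 0) return(NULL)
      n <- rpois(length(comp), width(comp) / 1e3 * dens)
      if (sum(n) == 0) return(NULL)
      data.frame(
        chrom = rep(as.character(seqnames(comp)), n),
        pos = unlist(lapply(seq_along(comp), function(i) {
          if (n[i] == 0) return(integer(0))
          start(comp)[i] + sample.int(width(comp)[i], n[i]) - 1L
        })))
    }
    d <- rbind(place(genome$deu, cfg$marker_density_deu),
               place(genome$per, cfg$marker_density_per))
    if (is.null(d)) stop("no markers generated; increase densities")
    d <- d[!duplicated(d[c("chrom", "pos")]), ]
    d <- d[order(d$chrom, d$pos), ]
    alleles <- c("A", "C", "G", "T")
    d$ref <- sample(alleles, nrow(d), replace = TRUE)
    d$alt <- vapply(d$ref, function(r) sample(setdiff(alleles, r), 1L),
                    character(1))
    rownames(d) <- NULL
    d
  })
}

# Piecewise-constant CO intensity over the genome: compartment weight,
# multiplied inside SVs (>1 kb), TE tracks, genes+flanks, and zeroed in
# planted coldspots. Returns a GRanges partition with a `weight` column.
co_weight_track <- function(cfg, genome, features = NULL) {
  base <- c(genome$deu, genome$per)
  w0 <- c(rep(cfg$deu_co_weight, length(genome$deu)),
          rep(cfg$per_co_weight, length(genome$per)))
  mods <- list()
  if (!is.null(features)) {
    svs <- features$sv_truth
    if (!is.null(svs) && length(svs)) {
      big <- svs[width(svs) > 1e3]
      if (length(big)) mods <- c(mods, list(list(gr = reduce(big),
                                                 mult = cfg$sv_suppression)))
    }
    if (!is.null(features$te) && length(features$te)) {
      for (fam in unique(mcols(features$te)$superfamily)) {
        mult <- cfg$te_tracks[[fam]]$multiplier
        if (!is.null(mult) && mult != 1) {
          mods <- c(mods, list(list(
            gr = reduce(features$te[mcols(features$te)$superfamily == fam]),
            mult = mult)))
        }
      }
    }
    if (!is.null(features$genes) && length(features$genes$gr) &&
        cfg$gene_co_multiplier != 1) {
      gg <- as_unstranded(features$genes$gr)
      g1k <- suppressWarnings(trim(resize(gg, width(gg) + 2e3,
                                          fix = "center")))
      mods <- c(mods, list(list(gr = reduce(g1k),
                                mult = cfg$gene_co_multiplier)))
    }
  }
  if (!is.null(cfg$coldspot_spec) && length(cfg$coldspot_spec)) {
    mods <- c(mods, list(list(gr = reduce(as_unstranded(cfg$coldspot_spec)),
                              mult = 0)))
  }
  extra <- do.call(c, c(list(GRanges()),
                        lapply(mods, function(m) granges(as_unstranded(m$gr)))))
  pieces <- disjoin(c(granges(base), extra), ignore.strand = TRUE)
  hb <- findOverlaps(pieces, base)
  weight <- numeric(length(pieces))
  weight[queryHits(hb)] <- w0[subjectHits(hb)]
  for (m in mods) {
    hit <- overlapsAny(pieces, m$gr, ignore.strand = TRUE)
    weight[hit] <- weight[hit] * m$mult
  }
  mcols(pieces)$weight <- weight
  pieces
}

# Cumulative weighted length per chromosome for exact integration of the
# intensity over arbitrary intervals.
weight_cumsum <- function(track) {
  sp <- split(data.frame(s = start(track), e = end(track),
                         w = mcols(track)$weight),
              as.character(seqnames(track)), drop = TRUE)
  lapply(sp, function(d) {
    d <- d[order(d$s), ]
    list(s = d$s, e = d$e, w = d$w,
         cum = c(0, cumsum(d$w * (d$e - d$s + 1))))
  })
}

# Integral of the weight over [a, b] (1-based inclusive) on one chromosome.
# The segment list covers the chromosome without gaps, so every position
# falls in exactly one segment. cum[j] is the weighted length of segments
# 1..j-1.
weight_integral <- function(wc, a, b) {
  if (is.null(wc)) return(rep(0, length(a)))
  ja <- findInterval(a, wc$s)
  jb <- findInterval(b, wc$s)
  same <- wc$w[ja] * (b - a + 1)
  split_sum <- wc$w[ja] * (wc$e[ja] - a + 1) +
    (wc$cum[jb] - wc$cum[ja + 1L]) +
    wc$w[jb] * (b - wc$s[jb] + 1)
  ifelse(ja == jb, same, split_sum)
}

#' Simulate TE tracks, gene models, ACRs and SV call sets
#'
#' TE intervals are placed uniformly inside their biased compartment
#' (hard bias). Genes are non-overlapping spans with 1-5 exons, strand and
#' terminal UTRs; most lie in DEU. ACRs (mean ~700 bp) are anchored at a
#' random gene TSS with probability `acr_overlap_prob`, else uniform. The
#' SV truth set is split by provenance: a `parental_fraction` subset
#' reappears (with small breakpoint jitter) in the F1 pollen call set, and
#' a fraction of self SVs is planted over parental SVs to exercise the
#' artifact mask.
#'
#' @param cfg [sim_config()].
#' @param genome `GenomeLayout`.
#' @param seed stage seed.
#' @return list: `te` (`GRanges` + superfamily), `genes` (list `table`,
#'   `exons`, `gr`), `acrs`, `sv_truth`, `sv_inbred`, `sv_pollen`,
#'   `sv_self` (all `GRanges` with `type`/`source` where relevant).
#' @export
simulate_features <- function(cfg, genome, seed = derive_seed(cfg$seed, "features")) {
  with_seed(seed, {
    place_uniform <- function(n, len, comp) {
      allow <- allowed_table(genome, comp)
      pl <- sample_placements(len, allow, 1L)
      GRanges(allow$chrom[pl$segment[, 1]],
              IRanges(pl$start[, 1], width = len),
              seqinfo = genome$seqinfo)
    }
    # --- TE tracks
    te <- GRanges(seqinfo = genome$seqinfo)
    for (fam in names(cfg$te_tracks)) {
      spec <- cfg$te_tracks[[fam]]
      comp <- switch(spec$bias %||% "none",
                     PER = genome$per, DEU = genome$deu, NULL)
      if (!is.null(comp) && !length(comp)) comp <- NULL
      len <- round(runif(spec$n, spec$len_range[1], spec$len_range[2]))
      gr <- place_uniform(spec$n, len, comp)
      mcols(gr)$superfamily <- fam
      te <- c(te, gr)
    }
    # --- genes: non-overlapping spans, strand, exon chains, terminal UTRs
    n_deu <- rbinom(1, cfg$gene_count, cfg$gene_deu_fraction)
    glen <- round(runif(cfg$gene_count, 2e3, 8e3))
    comp_of <- c(rep("DEU", n_deu), rep("PER", cfg$gene_count - n_deu))
    per_or_null <- if (length(genome$per)) genome$per else NULL
    ggr <- c(place_uniform(n_deu, glen[comp_of == "DEU"], genome$deu),
             if (cfg$gene_count > n_deu)
               place_uniform(cfg$gene_count - n_deu,
                             glen[comp_of == "PER"], per_or_null)
             else GRanges(seqinfo = genome$seqinfo))
    ggr <- sort(ggr)
    # keep the first gene of every overlapping cluster -> non-overlapping set
    ggr <- ggr[!duplicated(subjectHits(findOverlaps(ggr, reduce(ggr))))]
    gene_id <- sprintf("gene%05d", seq_along(ggr))
    strand_v <- sample(c("+", "-"), length(ggr), replace = TRUE)
    exons <- do.call(rbind, lapply(seq_along(ggr), function(i) {
      n_ex <- sample.int(5L, 1L)
      cuts <- sort(sample.int(width(ggr)[i] - 1L, 2L * n_ex - 2L))
      bounds <- c(0L, cuts, width(ggr)[i])
      odd <- seq(1L, length(bounds) - 1L, by = 2L)
      data.frame(gene_id = gene_id[i],
                 start = start(ggr)[i] + bounds[odd],
                 end = start(ggr)[i] + bounds[odd + 1L] - 1L)
    }))
    utr5 <- pmin(200L, round(width(ggr) * 0.1))
    utr3 <- pmin(300L, round(width(ggr) * 0.1))
    genes_tab <- data.frame(gene_id = gene_id,
                            chrom = as.character(seqnames(ggr)),
                            start = start(ggr), end = end(ggr),
                            strand = strand_v,
                            utr5_len = utr5, utr3_len = utr3,
                            stringsAsFactors = FALSE)
    genes <- gene_models(genes_tab, exons, genome)
    # --- ACRs
    acr_len <- pmax(150L, round(rlnorm(cfg$acr_count, log(700), 0.4)))
    anchored <- runif(cfg$acr_count) < cfg$acr_overlap_prob
    tss <- ifelse(genes_tab$strand == "+", genes_tab$start, genes_tab$end)
    pick <- sample.int(nrow(genes_tab), cfg$acr_count, replace = TRUE)
    a_start <- ifelse(anchored,
                      pmax(1, tss[pick] - floor(acr_len / 2)),
                      NA_real_)
    a_chrom <- ifelse(anchored, genes_tab$chrom[pick], NA_character_)
    if (any(!anchored)) {
      unif <- place_uniform(sum(!anchored), acr_len[!anchored], NULL)
      a_start[!anchored] <- start(unif)
      a_chrom[!anchored] <- as.character(seqnames(unif))
    }
    L <- seqlengths(genome$seqinfo)[a_chrom]
    acrs <- GRanges(a_chrom,
                    IRanges(pmin(a_start, L - acr_len + 1),
                            width = acr_len),
                    seqinfo = genome$seqinfo)
    # --- SV sets
    sv_len <- pmax(60L, pmin(120e3, round(rlnorm(cfg$sv_count, cfg$sv_meanlog,
                                                 cfg$sv_sdlog))))
    sv <- if (length(genome$per)) {
      n_sv_deu <- rbinom(1, cfg$sv_count, cfg$sv_deu_fraction %||% 0.6)
      suppressWarnings(c(
        place_uniform(n_sv_deu, sv_len[seq_len(n_sv_deu)], genome$deu),
        place_uniform(cfg$sv_count - n_sv_deu,
                      sv_len[seq_len(cfg$sv_count - n_sv_deu) + n_sv_deu],
                      genome$per)))
    } else {
      place_uniform(cfg$sv_count, sv_len, NULL)
    }
    if ((cfg$sv_per_length_factor %||% 1) != 1 && length(genome$per)) {
      in_per <- overlapsAny(sv, genome$per, ignore.strand = TRUE)
      if (any(in_per)) {
        new_end <- pmin(seqlengths(genome$seqinfo)[as.character(seqnames(sv))[in_per]],
                        start(sv)[in_per] +
                          round(width(sv)[in_per] * cfg$sv_per_length_factor) - 1)
        end(sv)[in_per] <- new_end
      }
    }
    mcols(sv)$type <- sample(c("DEL", "INV"), cfg$sv_count, replace = TRUE,
                             prob = c(0.8, 0.2))
    in_pollen <- runif(cfg$sv_count) < cfg$parental_fraction
    pollen <- sv[in_pollen]
    if (length(pollen)) {
      # small breakpoint jitter, well inside the 50% reciprocal-overlap rule
      jit <- round(runif(length(pollen), -0.05, 0.05) * width(pollen))
      lo <- pmax(1, start(pollen) + jit)
      hi <- pmin(seqlengths(genome$seqinfo)[as.character(seqnames(pollen))],
                 lo + width(pollen) - 1)
      ranges(pollen) <- IRanges(lo, hi)
    }
    n_self_on <- rbinom(1, cfg$n_self_svs, cfg$self_overlap_fraction)
    n_self_on <- min(n_self_on, sum(in_pollen))
    self_len <- pmax(60L, round(rlnorm(cfg$n_self_svs, log(1e3), 1)))
    self_off <- place_uniform(cfg$n_self_svs - n_self_on,
                              self_len[seq_len(cfg$n_self_svs - n_self_on)],
                              NULL)
    self_on <- if (n_self_on > 0) {
      tgt <- sv[in_pollen][sample.int(sum(in_pollen), n_self_on)]
      GRanges(seqnames(tgt), IRanges(start(tgt),
                                     width = pmax(60L, round(width(tgt) / 2))),
              seqinfo = genome$seqinfo)
    } else GRanges(seqinfo = genome$seqinfo)
    sv_self <- c(self_off, self_on)
    mcols(sv_self)$type <- sample(c("DEL", "INV"), length(sv_self),
                                  replace = TRUE, prob = c(0.8, 0.2))
    mcols(sv)$source <- rep("wild_inbred", length(sv))
    mcols(pollen)$source <- rep("f1_pollen", length(pollen))
    mcols(sv_self)$source <- rep("self", length(sv_self))
    list(te = te, genes = genes, acrs = acrs,
         sv_truth = sv, sv_inbred = sv, sv_pollen = pollen,
         sv_self = sv_self)
  })
}

#' Simulate linked-read molecules with planted crossovers
#'
#' Each molecule gets a chromosome (probability proportional to length), a
#' uniform start and a truncated log-normal length; its marker calls take
#' one parental haplotype. With probability `co_rate` — and provided the
#' molecule has enough markers to support two well-populated blocks — a
#' single switch point is planted in an inter-marker gap drawn with
#' probability proportional to the integrated CO intensity of the gap
#' (compartment weights x SV/TE/gene multipliers). The truth table records
#' the flanking markers of every planted CO. Optional noise: wildcard
#' calls, haplotype flips, and double-switch contaminants (the detector
#' must reject the latter).
#'
#' @param cfg [sim_config()].
#' @param genome `GenomeLayout`.
#' @param markers marker `data.frame`.
#' @param features optional feature list from [simulate_features()]; when
#'   supplied, SV/TE/gene multipliers shape CO placement.
#' @param n_molecules override for `cfg$n_molecules`.
#' @param min_flank_markers markers required on each side of a planted
#'   switch (kept in sync with the detector's block filter default).
#' @param seed stage seed.
#' @return list: `molecules` (`data.table`: molecule_id, chrom, pos, hap,
#'   reads) and `truth` (`data.frame`: molecule_id, chrom, left_marker,
#'   right_marker, kind = co/double_switch).
#' @export
simulate_molecules <- function(cfg, genome, markers, features = NULL,
                               n_molecules = cfg$n_molecules,
                               min_flank_markers = 3L,
                               seed = derive_seed(cfg$seed, "molecules")) {
  track <- co_weight_track(cfg, genome, features)
  wcs <- weight_cumsum(track)
  lens_g <- seqlengths(genome$seqinfo)
  mk <- split(markers$pos, markers$chrom)
  meanlog <- log(cfg$molecule_mean^2 /
                   sqrt(cfg$molecule_mean^2 + cfg$molecule_sd^2))
  sdlog <- sqrt(log(1 + cfg$molecule_sd^2 / cfg$molecule_mean^2))
  with_seed(seed, {
    # molecule geometry
    mlen <- pmin(cfg$molecule_max,
                 pmax(5e3, round(rlnorm(n_molecules, meanlog, sdlog))))
    chrom <- sample(names(lens_g), n_molecules, replace = TRUE,
                    prob = lens_g)
    mstart <- floor(runif(n_molecules) * (lens_g[chrom] - mlen + 1)) + 1
    base_hap <- sample(c("A", "B"), n_molecules, replace = TRUE)
    # a molecule's chance of spanning a crossover is proportional to the
    # CO intensity integrated over its span, normalized so the expected
    # number of recombinant molecules stays co_rate * n_molecules
    w_span <- vapply(seq_len(n_molecules), function(i)
      weight_integral(wcs[[chrom[i]]], mstart[i],
                      mstart[i] + mlen[i] - 1), numeric(1))
    p_rec <- if (mean(w_span) > 0)
      pmin(1, cfg$co_rate * w_span / mean(w_span)) else rep(0, n_molecules)
    recomb <- runif(n_molecules) < p_rec
    dbl <- runif(n_molecules) < cfg$double_switch_rate
    recomb[dbl] <- FALSE

    rows <- vector("list", n_molecules)
    truth <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      pos_all <- mk[[chrom[i]]]
      if (is.null(pos_all)) next
      lo <- findInterval(mstart[i] - 1, pos_all) + 1L
      hi <- findInterval(mstart[i] + mlen[i] - 1, pos_all)
      if (!length(hi) || hi < lo) next
      pos <- pos_all[lo:hi]
      nm <- length(pos)
      hap <- rep(base_hap[i], nm)
      mol_id <- sprintf("mol%06d", i)
      if (recomb[i] && nm >= 2L * min_flank_markers) {
        ks <- seq(min_flank_markers, nm - min_flank_markers)
        wgt <- weight_integral(wcs[[chrom[i]]], pos[ks] + 1, pos[ks + 1L])
        if (any(wgt > 0)) {
          k <- if (length(ks) == 1L) ks else
            ks[sample.int(length(ks), 1L, prob = wgt)]
          other <- if (base_hap[i] == "A") "B" else "A"
          hap[(k + 1L):nm] <- other
          truth[[i]] <- list(molecule_id = mol_id, chrom = chrom[i],
                             left_marker = pos[k],
                             right_marker = pos[k + 1L],
                             kind = "co")
        }
      } else if (dbl[i] && nm >= 3L * min_flank_markers) {
        # gene-conversion-like contaminant: two switches
        k1 <- min_flank_markers
        k2 <- min(nm - min_flank_markers, k1 + min_flank_markers)
        other <- if (base_hap[i] == "A") "B" else "A"
        hap[(k1 + 1L):k2] <- other
        truth[[i]] <- list(molecule_id = mol_id, chrom = chrom[i],
                           left_marker = pos[k1],
                           right_marker = pos[k1 + 1L],
                           kind = "double_switch")
      }
      if (cfg$flip_prob > 0) {
        fl <- runif(nm) < cfg$flip_prob
        hap[fl] <- ifelse(hap[fl] == "A", "B", "A")
      }
      if (cfg$wildcard_prob > 0) {
        hap[runif(nm) < cfg$wildcard_prob] <- "N"
      }
      rows[[i]] <- list(molecule_id = rep(mol_id, nm),
                        chrom = rep(chrom[i], nm),
                        pos = pos, hap = hap,
                        reads = 1L + rpois(nm, 0.5))
    }
    keep_r <- !vapply(rows, is.null, logical(1))
    molecules <- data.table::rbindlist(lapply(rows[keep_r], as.data.table))
    keep_t <- !vapply(truth, is.null, logical(1))
    truth <- if (any(keep_t)) {
      as.data.frame(data.table::rbindlist(truth[keep_t]))
    } else {
      data.frame(molecule_id = character(0), chrom = character(0),
                 left_marker = numeric(0), right_marker = numeric(0),
                 kind = character(0))
    }
    list(molecules = molecules, truth = truth)
  })
}

#' Generate a complete multi-hybrid synthetic corpus
#'
#' Shared genome, TE/gene/ACR annotation and self-SV mask; per hybrid, an
#' independent wild SV landscape (a configurable fraction shared across
#' hybrids), markers, and molecules whose planted COs respect that
#' hybrid's SV set. This reproduces the cross-hybrid coldspot structure:
#' conserved coldspots from the shared PER physics, shared clusters from
#' shared SVs, unique clusters from hybrid-specific SVs.
#'
#' @param cfg [sim_config()].
#' @param hybrids character vector of hybrid ids.
#' @param sv_shared_fraction fraction of each hybrid's SVs drawn from a
#'   common pool.
#' @return list of class `sim_corpus`: `cfg`, `genome`, `features`
#'   (shared annotation), and `hybrids`, a named list with per-hybrid
#'   `markers`, `molecules`, `truth`, `features` (hybrid-specific SV sets).
#' @export
simulate_corpus <- function(cfg, hybrids = c("PM", "NE", "CH", "HB", "PN"),
                            sv_shared_fraction = 0.4) {
  genome <- simulate_genome(cfg)
  shared <- simulate_features(cfg, genome)
  n_shared <- round(sv_shared_fraction * cfg$sv_count)
  # the shared SV pool is sampled across the whole set so it represents
  # both compartments (the set is stored DEU-first)
  pool_idx <- with_seed(derive_seed(cfg$seed, "svpool"),
                        sort(sample.int(length(shared$sv_truth),
                                        min(n_shared,
                                            length(shared$sv_truth)))))
  out <- list()
  for (h in hybrids) {
    own_cfg <- cfg
    own_cfg$sv_count <- cfg$sv_count - n_shared
    own <- simulate_features(own_cfg, genome,
                             seed = derive_seed(cfg$seed, paste0("sv_", h)))
    feats <- shared
    feats$sv_truth <- c(shared$sv_truth[pool_idx], own$sv_truth)
    feats$sv_inbred <- feats$sv_truth
    # pollen set: re-derive from the combined truth so parental_fraction
    # holds for the hybrid's full SV landscape
    feats$sv_pollen <- with_seed(derive_seed(cfg$seed, paste0("pollen_", h)), {
      tr <- feats$sv_truth
      keep <- runif(length(tr)) < cfg$parental_fraction
      p <- tr[keep]
      if (length(p)) {
        jit <- round(runif(length(p), -0.05, 0.05) * width(p))
        lo <- pmax(1, start(p) + jit)
        hi <- pmin(seqlengths(genome$seqinfo)[as.character(seqnames(p))],
                   lo + width(p) - 1)
        ranges(p) <- IRanges(lo, hi)
      }
      mcols(p)$source <- rep("f1_pollen", length(p))
      p
    })
    markers <- simulate_markers(cfg, genome,
                                seed = derive_seed(cfg$seed, paste0("mk_", h)))
    mols <- simulate_molecules(cfg, genome, markers, features = feats,
                               seed = derive_seed(cfg$seed, paste0("mol_", h)))
    out[[h]] <- list(markers = markers, molecules = mols$molecules,
                     truth = mols$truth, features = feats)
  }
  structure(list(cfg = cfg, genome = genome, features = shared,
                 hybrids = out),
            class = "sim_corpus")
}

#' Write a corpus to disk in the pipeline's exchange formats
#'
#' Genome TSV + PER BED, per-hybrid marker and molecule TSVs, SV TSVs,
#' feature BEDs, and a YAML manifest recording the configuration and seed.
#'
#' @param corpus `sim_corpus` from [simulate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- corpus$genome
  write_genome(g, file.path(dir, "genome.tsv"), file.path(dir, "per.bed"))
  te <- corpus$features$te
  mcols(te)$name <- mcols(te)$superfamily
  mcols(te) <- mcols(te)["name"]
  write_bed(te, file.path(dir, "te.bed"))
  write_bed(corpus$features$acrs, file.path(dir, "acrs.bed"))
  write_gene_models(corpus$features$genes, file.path(dir, "genes.gff3"))
  for (h in names(corpus$hybrids)) {
    hd <- corpus$hybrids[[h]]
    write_markers(hd$markers, file.path(dir, paste0(h, ".markers.tsv")))
    write_molecules(hd$molecules, file.path(dir, paste0(h, ".molecules.tsv")))
    svs <- c(hd$features$sv_inbred, hd$features$sv_pollen,
             hd$features$sv_self)
    write_svs(svs, file.path(dir, paste0(h, ".svs.tsv")))
    fwrite(as.data.table(hd$truth), file.path(dir, paste0(h, ".truth.tsv")),
           sep = "\t")
  }
  cfg <- corpus$cfg
  cfg$coldspot_spec <- NULL  # GRanges not YAML-serializable; re-derivable
  cfg$te_tracks <- lapply(cfg$te_tracks, function(t)
    lapply(t, function(v) if (is.numeric(v)) as.numeric(v) else v))
  yaml::write_yaml(list(config = unclass(cfg),
                        hybrids = names(corpus$hybrids)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
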