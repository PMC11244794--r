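# Association statistics: permutation enrichment/depletion of COs in
# feature sets, Fisher overlap tests, CO landscape tracks and correlations,
# and signed distance profiles.

#' Permutation test for CO enrichment in a feature set
#'
#' The observed statistic is the number of CO intervals overlapping at
#' least one feature base. The null distribution relocates the CO set
#' `n_perm` times over the genome (or a restricted region), preserving
#' interval lengths, exactly as [shuffle_intervals()] does. The z-score is
#' `(observed - null mean) / null sd`; a positive sign states enrichment, a
#' negative one suppression. The empirical p-value is two-sided with a +1
#' pseudo-count, `(1 + #{|null - mean| >= |obs - mean|}) / (n_perm + 1)`,
#' so it can never be exactly zero; a normal-tail p-value from the z-score
#' is also reported (extreme enrichments exceed empirical granularity).
#'
#' @param cos CO intervals (`GRanges`) or a crossover event `data.frame`.
#' @param features feature intervals (`GRanges`), non-empty.
#' @param genome `GenomeLayout`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param within optional `GRanges` restricting null placements (e.g. one
#'   compartment).
#' @return object of class `permutation_result`: observed, null_mean,
#'   null_sd, z, p_empirical, p_normal, n_perm, seed, degenerate flag and
#'   the full null vector.
#' @export
permutation_enrichment <- function(cos, features, genome, n_perm = 10000,
                                   seed = NULL, within = NULL) {
  stopifnot(n_perm >= 100)
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  cos <- validate_in_genome(cos, genome, "CO intervals")
  features <- validate_in_genome(features, genome, "features")
  if (!length(features)) stop("features must be non-empty")
  fidx <- feature_index(features)
  observed <- count_overlapping(as.character(seqnames(cos)),
                                start(cos), end(cos), fidx)
  allow <- allowed_table(genome, within)
  widths <- width(cos)
  null <- with_seed(seed, {
    pl <- sample_placements(widths, allow, n_sets = n_perm)
    chrom_mat <- allow$chrom[pl$segment]
    dim(chrom_mat) <- dim(pl$segment)
    vapply(seq_len(n_perm), function(k) {
      qs <- pl$start[, k]
      count_overlapping(chrom_mat[, k], qs, qs + widths - 1, fidx)
    }, numeric(1))
  })
  mu <- mean(null)
  sdev <- sd(null)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sdev
  p_emp <- if (degenerate) 1 else
    (1 + sum(abs(null - mu) >= abs(observed - mu))) / (n_perm + 1)
  p_norm <- if (degenerate) 1 else 2 * pnorm(-abs(z))
  structure(list(observed = observed, null_mean = mu, null_sd = sdev,
                 z = z, p_empirical = p_emp, p_normal = p_norm,
                 n_perm = n_perm, seed = seed, degenerate = degenerate,
                 null = null),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (n_perm = %d): observed = %d, null = %.2f +/- %.2f\n",
              x$n_perm, x$observed, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("  degenerate null (sd = 0); p = 1\n")
  } else {
    cat(sprintf("  z = %.2f, empirical p = %.3g, normal-tail p = %.3g\n",
                x$z, x$p_empirical, x$p_normal))
  }
  invisible(x)
}

#' Enrichment over several feature tracks with FDR correction
#'
#' Runs [permutation_enrichment()] per track (e.g. TE superfamilies) and
#' applies Benjamini-Hochberg correction across the empirical p-values.
#'
#' @param cos CO intervals or event `data.frame`.
#' @param feature_list named list of feature `GRanges`.
#' @param genome `GenomeLayout`.
#' @param n_perm,seed passed to [permutation_enrichment()]; per-track seeds
#'   are derived from `seed` and the track name.
#' @return `data.frame` with one row per track: observed, null_mean,
#'   null_sd, z, p_raw, p_adj.
#' @export
enrichment_table <- function(cos, feature_list, genome, n_perm = 10000,
                             seed = NULL) {
  stopifnot(length(feature_list) >= 1L, !is.null(names(feature_list)))
  res <- lapply(names(feature_list), function(nm) {
    permutation_enrichment(cos, feature_list[[nm]], genome, n_perm = n_perm,
                           seed = derive_seed(seed, nm))
  })
  out <- data.frame(feature = names(feature_list),
                    observed = vapply(res, `[[`, numeric(1), "observed"),
                    null_mean = vapply(res, `[[`, numeric(1), "null_mean"),
                    null_sd = vapply(res, `[[`, numeric(1), "null_sd"),
                    z = vapply(res, `[[`, numeric(1), "z"),
                    p_raw = vapply(res, `[[`, numeric(1), "p_empirical"),
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out
}

#' Fisher's exact test for CO co-occurrence between two hybrids
#'
#' Tiles the genome into non-overlapping windows and cross-tabulates the
#' indicator "window contains a CO of hybrid A" against the same for
#' hybrid B; the two-sided Fisher exact test asks whether the two hybrids
#' recombine in the same windows more often than chance.
#'
#' @param cos_a,cos_b CO intervals (`GRanges`) or event `data.frame`s.
#' @param genome `GenomeLayout`.
#' @param window tiling window size in bp (default 10 kb, the CO-region
#'   window scale).
#' @return list: `odds_ratio` (conditional MLE; `Inf` reported as upper
#'   bound for empty discordant cells), `p`, `shared_fraction`
#'   (windows with both / windows with either), `table` (the 2x2 matrix).
#' @export
overlap_fisher <- function(cos_a, cos_b, genome, window = 10e3) {
  if (is.data.frame(cos_a)) cos_a <- events_gr(cos_a, genome)
  if (is.data.frame(cos_b)) cos_b <- events_gr(cos_b, genome)
  if (!length(cos_a) || !length(cos_b)) {
    stop("both CO sets must be non-empty")
  }
  w <- sliding_windows(genome, window, window)
  a <- countOverlaps(w, cos_a, ignore.strand = TRUE) > 0
  b <- countOverlaps(w, cos_b, ignore.strand = TRUE) > 0
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, dimnames = list(A = c("co", "no"),
                                          B = c("co", "no")))
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       shared_fraction = sum(a & b) / sum(a | b), table = tab)
}

#' Genic enrichment of COs within a compartment
#'
#' Restricts COs to one chromatin compartment (DEU or PER), counts overlaps
#' with genes extended by 1 kb flanks, and compares against shuffles placed
#' within the same compartment only, so the compartment-scale CO gradient
#' cannot masquerade as gene preference.
#'
#' @param cos CO intervals or event `data.frame`.
#' @param genes gene spans (`GRanges`).
#' @param genome `GenomeLayout`.
#' @param compartment `"DEU"` or `"PER"`.
#' @param flank flank size added to each gene in bp (default 1 kb).
#' @param n_perm,seed permutation settings.
#' @return a `permutation_result`; attribute `n_cos_in_compartment` gives
#'   the restricted CO count (0 is flagged via an error).
#' @export
genic_enrichment <- function(cos, genes, genome,
                             compartment = c("DEU", "PER"), flank = 1000,
                             n_perm = 10000, seed = NULL) {
  compartment <- match.arg(compartment)
  comp <- compartment_gr(genome, compartment)
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  cos <- validate_in_genome(cos, genome, "CO intervals")
  keep <- overlapsAny(cos, comp, ignore.strand = TRUE)
  if (!any(keep)) stop("no CO in compartment ", compartment)
  feats <- suppressWarnings(trim(resize(as_unstranded(genes),
                                        width(genes) + 2 * flank, fix = "center")))
  res <- permutation_enrichment(cos[keep], feats, genome, n_perm = n_perm,
                                seed = seed, within = comp)
  attr(res, "n_cos_in_compartment") <- sum(keep)
  res
}

#' Crossover density landscape (Gaussian KDE)
#'
#' Kernel density of CO interval midpoints per chromosome, bandwidth 100 kb
#' (the `bw` argument of [stats::density()]), evaluated on a regular grid
#' and scaled so the per-chromosome track integrates to the CO count.
#'
#' @param cos CO intervals or event `data.frame`.
#' @param genome `GenomeLayout`.
#' @param bandwidth Gaussian kernel bandwidth in bp.
#' @param grid evaluation grid spacing in bp.
#' @return `data.frame` with columns chrom, pos, density (COs per bp).
#' @export
landscape_density <- function(cos, genome, bandwidth = 100e3, grid = 10e3) {
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  cos <- validate_in_genome(cos, genome, "CO intervals")
  if (!length(cos)) stop("at least one CO required")
  mids <- (start(cos) + end(cos)) / 2
  chroms <- as.character(seqnames(cos))
  out <- lapply(seqlevels(genome$seqinfo), function(chr) {
    x <- mids[chroms == chr]
    if (!length(x)) return(NULL)
    L <- seqlengths(genome$seqinfo)[[chr]]
    npt <- max(2L, floor(L / grid) + 1L)
    d <- density(x, bw = bandwidth, from = 0, to = L, n = npt)
    data.frame(chrom = chr, pos = d$x, density = d$y * length(x))
  })
  do.call(rbind, out)
}

#' CO counts per sliding window, per hybrid
#'
#' @param cos_by_hybrid named list of CO interval sets (or event
#'   `data.frame`s), one per hybrid.
#' @param genome `GenomeLayout`.
#' @param window,step window size and step in bp (defaults 500 kb / 50 kb).
#' @return matrix of CO counts, windows x hybrids; window coordinates as
#'   attribute `windows`.
#' @export
landscape_counts <- function(cos_by_hybrid, genome, window = 500e3,
                             step = 50e3) {
  w <- sliding_windows(genome, window, step)
  counts <- vapply(cos_by_hybrid, function(cs) {
    if (is.data.frame(cs)) cs <- events_gr(cs, genome)
    countOverlaps(w, validate_in_genome(cs, genome), ignore.strand = TRUE)
  }, numeric(length(w)))
  attr(counts, "windows") <- w
  counts
}

#' Spearman correlation matrix of CO landscapes between hybrids
#'
#' Correlates per-window CO count vectors (genome-wide concatenation of
#' 500 kb windows, 50 kb step) between every pair of hybrids.
#'
#' @inheritParams landscape_counts
#' @return list with `rho` (symmetric matrix, unit diagonal), `p`
#'   (two-sided p-values, `NA` on the diagonal and for constant vectors),
#'   and `counts` (the window matrix).
#' @export
landscape_correlation <- function(cos_by_hybrid, genome, window = 500e3,
                                  step = 50e3) {
  stopifnot(length(cos_by_hybrid) >= 2L)
  counts <- landscape_counts(cos_by_hybrid, genome, window, step)
  nh <- ncol(counts)
  rho <- diag(1, nh)
  p <- matrix(NA_real_, nh, nh)
  dimnames(rho) <- dimnames(p) <- list(colnames(counts), colnames(counts))
  for (i in seq_len(nh - 1L)) {
    for (j in seq((i + 1L), nh)) {
      if (sd(counts[, i]) == 0 || sd(counts[, j]) == 0) next
      ct <- suppressWarnings(cor.test(counts[, i], counts[, j],
                                      method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p, counts = counts)
}

#' Signed distance profile of COs to the nearest SV
#'
#' Computes the signed edge-to-edge distance from every CO to its nearest
#' SV, together with a null band from relocated CO sets.
#'
#' @param cos CO intervals or event `data.frame`.
#' @param svs SV intervals (`GRanges`).
#' @param genome `GenomeLayout`.
#' @param n_perm number of shuffled CO sets forming the null band.
#' @param seed integer seed.
#' @param breaks histogram break vector in bp (default +/- 100 kb in 5 kb
#'   bins).
#' @return list: `observed` (signed distances), `hist_observed`,
#'   `hist_null` (matrix, bins x permutations), `breaks`.
#' @export
sv_distance_profile <- function(cos, svs, genome, n_perm = 100, seed = NULL,
                                breaks = seq(-100e3, 100e3, by = 5e3)) {
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  cos <- validate_in_genome(cos, genome, "CO intervals")
  svs <- validate_in_genome(svs, genome, "SVs")
  if (!length(cos) || !length(svs)) stop("both sets must be non-empty")
  obs <- distance_to_nearest_signed(cos, svs)
  binit <- function(d) {
    d <- d[!is.na(d)]
    d <- pmin(pmax(d, min(breaks)), max(breaks))
    tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      binit(distance_to_nearest_signed(
        shuffle_intervals(cos, genome), svs))
    }, numeric(length(breaks) - 1L))
  })
  list(observed = obs, hist_observed = binit(obs), hist_null = null,
       breaks = breaks)
}

#' Spearman correlation of CO counts with feature coverage per window
#'
#' @param cos CO intervals or event `data.frame`.
#' @param features feature intervals (`GRanges`), e.g. one TE superfamily.
#' @param genome `GenomeLayout`.
#' @param window,step window size and step in bp.
#' @return list with `rho`, `p`, and the per-window `data.frame`
#'   (co_count, feature_bp).
#' @export
spearman_feature_correlation <- function(cos, features, genome,
                                         window = 500e3, step = 50e3) {
  if (is.data.frame(cos)) cos <- events_gr(cos, genome)
  cos <- validate_in_genome(cos, genome, "CO intervals")
  features <- reduce(validate_in_genome(features, genome, "features"))
  w <- sliding_windows(genome, window, step)
  co_count <- countOverlaps(w, cos, ignore.strand = TRUE)
  feat_bp <- overlap_bp(w, features)
  if (sd(co_count) == 0 || sd(feat_bp) == 0) {
    return(list(rho = NA_real_, p = NA_real_,
                windows = data.frame(co_count = co_count,
                                     feature_bp = feat_bp),
                flag = "constant vector"))
  }
  ct <- suppressWarnings(cor.test(co_count, feat_bp, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       windows = data.frame(co_count = co_count, feature_bp = feat_bp))
}
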