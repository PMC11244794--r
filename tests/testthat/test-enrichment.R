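# Association statistics: permutation enrichment, Fisher co-occurrence,
# landscape tracks and distance profiles.

test_that("permutation test detects constructed enrichment and suppression", {
  g <- toy_genome(c(chr1 = 30e6))
  feats <- GRanges("chr1", IRanges(1, 3e6))  # 10% of the genome
  set.seed(14)
  n <- 300
  s_in <- floor(runif(n) * (3e6 - 2000)) + 1
  cos_in <- GRanges("chr1", IRanges(s_in, s_in + 1999))
  res <- permutation_enrichment(cos_in, feats, g, n_perm = 500, seed = 3)
  expect_equal(res$observed, n)
  expect_gt(res$null_mean, 0.05 * n)
  expect_lt(res$null_mean, 0.15 * n)  # binomial null ~ 0.1 n
  expect_gt(res$z, 5)
  expect_lt(res$p_empirical, 0.01)
  # all COs outside the features: suppression, z < 0
  s_out <- floor(runif(n) * (27e6 - 3e6 - 2000)) + 3e6 + 1
  cos_out <- GRanges("chr1", IRanges(s_out, s_out + 1999))
  res2 <- permutation_enrichment(cos_out, feats, g, n_perm = 500, seed = 3)
  expect_lt(res2$z, 0)
  # features covering the whole genome: degenerate null
  res3 <- permutation_enrichment(cos_in, genome_gr(g), g, n_perm = 100,
                                 seed = 1)
  expect_true(res3$degenerate)
  expect_equal(res3$observed, n)
  expect_equal(res3$p_empirical, 1)
  # reproducible for a fixed seed
  res4 <- permutation_enrichment(cos_in, feats, g, n_perm = 500, seed = 3)
  expect_identical(res$null, res4$null)
})

test_that("enrichment_table runs per track and adjusts p-values", {
  g <- toy_genome(c(chr1 = 10e6))
  set.seed(2)
  s <- floor(runif(150) * (1e6 - 1000)) + 1
  cos <- GRanges("chr1", IRanges(s, s + 999))
  fl <- list(hot = GRanges("chr1", IRanges(1, 1e6)),
             cold = GRanges("chr1", IRanges(9e6, 10e6)))
  tab <- enrichment_table(cos, fl, g, n_perm = 300, seed = 5)
  expect_equal(tab$feature, c("hot", "cold"))
  expect_gt(tab$z[1], 3)
  expect_lt(tab$z[2], 0)
  expect_true(all(tab$p_adj >= tab$p_raw))
})

test_that("Fisher co-occurrence matches the exact hypergeometric form", {
  # identical CO sets: full sharing, infinite odds ratio
  g <- toy_genome(c(chr1 = 1e6))
  set.seed(3)
  s <- floor(runif(30) * (1e6 - 500)) + 1
  cos <- GRanges("chr1", IRanges(s, s + 499))
  f <- overlap_fisher(cos, cos, g, window = 10e3)
  expect_equal(f$shared_fraction, 1)
  expect_true(is.infinite(f$odds_ratio))
  expect_error(overlap_fisher(GRanges(), cos, g), "non-empty")
  # hand 2x2 table equals the hypergeometric oracle
  tab <- matrix(c(10, 5, 5, 80), 2)
  expect_equal(fisher.test(tab)$p.value,
               oracle_fisher_p(10, 5, 5, 80), tolerance = 1e-12)
  # exhaustive small tables
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (d in 0:5) {
    expect_equal(fisher.test(matrix(c(a, b, cc, d), 2))$p.value,
                 oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("genic enrichment is confined to its compartment", {
  cfg <- sim_config(seed = 31)
  g <- simulate_genome(cfg)
  fe <- simulate_features(cfg, g)
  # place COs inside DEU genes only
  gg <- fe$genes$gr[overlapsAny(fe$genes$gr, g$deu, type = "within")]
  set.seed(8)
  pick <- sample(length(gg), 200, replace = TRUE)
  mid <- floor((start(gg)[pick] + end(gg)[pick]) / 2)
  cos <- GRanges(seqnames(gg)[pick], IRanges(mid, mid + 500))
  res <- genic_enrichment(cos, fe$genes$gr, g, "DEU", n_perm = 300, seed = 9)
  expect_gt(res$z, 3)
  expect_equal(attr(res, "n_cos_in_compartment"), 200L)
  expect_error(genic_enrichment(GRanges("chr1", IRanges(1, 10)), fe$genes$gr,
                                g, "PER", n_perm = 100),
               "no CO in compartment")
})

test_that("density landscape integrates to the CO count", {
  g <- toy_genome(c(chr1 = 30e6))
  one <- GRanges("chr1", IRanges(15e6, 15e6 + 1000))
  d <- landscape_density(one, g, bandwidth = 100e3, grid = 10e3)
  # unimodal bell centered at the midpoint
  expect_equal(d$pos[which.max(d$density)], 15e6, tolerance = 2e4)
  expect_equal(sum(diff(d$pos[1:2]) * d$density), 1, tolerance = 0.01)
  # two distant COs: two equal modes, integral = 2
  two <- GRanges("chr1", IRanges(c(5e6, 25e6), c(5e6, 25e6)))
  d2 <- landscape_density(two, g)
  expect_equal(sum(diff(d2$pos[1:2]) * d2$density), 2, tolerance = 0.02)
  at5 <- d2$density[which.min(abs(d2$pos - 5e6))]
  at25 <- d2$density[which.min(abs(d2$pos - 25e6))]
  at15 <- d2$density[which.min(abs(d2$pos - 15e6))]
  expect_equal(at5, at25, tolerance = 1e-6)
  expect_lt(at15, at5 / 10)
})

test_that("landscape correlation is 1 on itself, lower for a shifted landscape", {
  g <- toy_genome(c(chr1 = 30e6))
  set.seed(12)
  s <- sort(floor(rbeta(400, 1.2, 4) * 29e6)) + 1  # asymmetric landscape
  cos <- GRanges("chr1", IRanges(s, s + 1000))
  flipped <- GRanges("chr1", IRanges(30e6 - s - 1000, 30e6 - s))
  lc <- landscape_correlation(list(a = cos, b = cos, c = flipped), g,
                              window = 500e3, step = 50e3)
  expect_equal(unname(diag(lc$rho)), c(1, 1, 1))
  expect_equal(lc$rho["a", "b"], 1)
  expect_lt(lc$rho["a", "c"], 1)
  expect_equal(lc$rho, t(lc$rho))
})

test_that("distance profiles localize COs relative to SVs", {
  g <- toy_genome(c(chr1 = 30e6))
  svs <- GRanges("chr1", IRanges(seq(1e6, 28e6, by = 1e6),
                                 seq(1e6, 28e6, by = 1e6) + 10e3))
  # COs placed 5 kb beyond each SV end
  cos <- shift(svs, 15e3)
  cos <- resize(cos, 500, fix = "start")
  prof <- sv_distance_profile(cos, svs, g, n_perm = 20, seed = 4)
  # each CO sits 5 kb (edge gap 4999 bp) beyond its SV, which lies upstream
  expect_true(all(prof$observed == -4999))
  # COs inside SVs: all distances zero
  prof0 <- sv_distance_profile(resize(svs, 100, fix = "center"), svs, g,
                               n_perm = 20, seed = 4)
  expect_true(all(prof0$observed == 0))
  # null band reproduces under the same seed
  prof2 <- sv_distance_profile(cos, svs, g, n_perm = 20, seed = 4)
  expect_identical(prof$hist_null, prof2$hist_null)
})

test_that("window-level feature correlation recovers the planted sign", {
  cfg <- sim_config(n_molecules = 4000, co_rate = 0.12, seed = 33)
  g <- simulate_genome(cfg)
  mk <- simulate_markers(cfg, g)
  fe <- simulate_features(cfg, g)
  mo <- simulate_molecules(cfg, g, mk, fe)
  ev_gr <- GRanges(mo$truth$chrom,
                   IRanges(mo$truth$left_marker, mo$truth$right_marker))
  gypsy <- fe$te[mcols(fe$te)$superfamily == "Gypsy"]
  res <- spearman_feature_correlation(ev_gr, gypsy, g)
  expect_lt(res$rho, 0)  # retrotransposon track suppresses COs
  stow <- fe$te[mcols(fe$te)$superfamily == "Stowaway"]
  res2 <- spearman_feature_correlation(ev_gr, stow, g)
  expect_gt(res2$rho, 0)
  # constant vectors are flagged, not an error
  res3 <- spearman_feature_correlation(
    GRanges("chr1", IRanges(1, 100)),
    GRanges("chr1", IRanges(1, genome_size(g) / 3)), g,
    window = genome_size(g) / 3, step = genome_size(g) / 3)
  expect_true(is.na(res3$rho) || is.finite(res3$rho))
})
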