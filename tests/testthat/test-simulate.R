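# Synthetic-data generator: geometry, marker statistics, planted-CO
# placement and reproducibility.

test_that("simulate_genome centers PER and derives DEU as its complement", {
  cfg0 <- sim_config(per_fraction = 0, n_chromosomes = 2)
  g0 <- simulate_genome(cfg0)
  expect_length(g0$per, 0L)
  expect_equal(sum(width(g0$deu)), genome_size(g0))

  cfg <- sim_config(per_fraction = 0.5, chrom_length = 30e6,
                    n_chromosomes = 1)
  g <- simulate_genome(cfg)
  expect_equal(start(g$per), 7.5e6 + 1)
  expect_equal(end(g$per), 22.5e6)
  # PER and DEU partition the chromosome
  expect_equal(sum(width(g$per)) + sum(width(g$deu)), 30e6)
  expect_length(intersect_intervals(g$per, g$deu), 0L)
  expect_error(sim_config(per_fraction = 1))
})

test_that("marker counts follow the configured densities", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, per_fraction = 0,
                    marker_density_deu = 1, seed = 5)
  g <- simulate_genome(cfg)
  mk <- simulate_markers(cfg, g)
  expect_lt(abs(nrow(mk) - 1000), 3 * sqrt(1000))  # Poisson moments
  expect_true(all(diff(mk$pos) > 0))
  # zero PER density -> no markers in PER
  cfg2 <- sim_config(n_chromosomes = 1, marker_density_per = 0, seed = 5)
  g2 <- simulate_genome(cfg2)
  mk2 <- simulate_markers(cfg2, g2)
  expect_false(any(overlapsAny(markers_gr <- GRanges(mk2$chrom,
                                                     IRanges(mk2$pos, mk2$pos)),
                               g2$per)))
  # fixed seed -> identical set
  expect_identical(simulate_markers(cfg, g), simulate_markers(cfg, g))
})

test_that("co_rate = 0 yields single-haplotype molecules and zero CO calls", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5e6, per_fraction = 0,
                    n_molecules = 300, co_rate = 0, seed = 2)
  g <- simulate_genome(cfg)
  mk <- simulate_markers(cfg, g)
  mo <- simulate_molecules(cfg, g, mk)
  expect_equal(nrow(mo$truth), 0L)
  per_mol <- tapply(mo$molecules$hap, mo$molecules$molecule_id,
                    function(h) length(unique(h)))
  expect_true(all(per_mol == 1))
  ev <- call_crossovers(mo$molecules, co_filter_params(), "x")
  expect_equal(nrow(ev), 0L)
})

test_that("hard SV suppression plants no CO inside large SVs", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20e6, per_fraction = 0,
                    n_molecules = 2000, co_rate = 0.12, sv_suppression = 0,
                    seed = 3)
  g <- simulate_genome(cfg)
  mk <- simulate_markers(cfg, g)
  fe <- simulate_features(cfg, g)
  mo <- simulate_molecules(cfg, g, mk, fe)
  truth <- mo$truth[mo$truth$kind == "co", ]
  co_gr <- GRanges(truth$chrom, IRanges(truth$left_marker + 1,
                                        truth$right_marker))
  big_sv <- fe$sv_truth[width(fe$sv_truth) > 1e3]
  # the switch interval may touch a bounding marker outside, but the CO
  # placement weight is zero inside the SV: no switch interval may lie
  # fully within an SV
  inside <- overlapsAny(co_gr, big_sv, type = "within")
  expect_false(any(inside))
})

test_that("planted CO compartment share matches the intensity weights", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 20e6,
                    per_fraction = 0.5, marker_density_per = 1,
                    deu_co_weight = 1, per_co_weight = 0.25,
                    n_molecules = 10000, co_rate = 0.12,
                    gene_co_multiplier = 1, seed = 8)
  g <- simulate_genome(cfg)
  mk <- simulate_markers(cfg, g)
  mo <- simulate_molecules(cfg, g, mk)  # no features: compartments only
  truth <- mo$truth[mo$truth$kind == "co", ]
  mid <- (truth$left_marker + truth$right_marker) / 2
  in_deu <- overlapsAny(GRanges(truth$chrom, IRanges(mid, mid)), g$deu)
  p_expect <- (0.5 * 1) / (0.5 * 1 + 0.5 * 0.25)  # 0.8
  se <- sqrt(p_expect * (1 - p_expect) / nrow(truth))
  expect_lt(abs(mean(in_deu) - p_expect), 4 * se)
})

test_that("feature simulation honours hard compartment bias and provenance", {
  cfg <- sim_config(seed = 21)
  g <- simulate_genome(cfg)
  fe <- simulate_features(cfg, g)
  gypsy <- fe$te[mcols(fe$te)$superfamily == "Gypsy"]
  expect_true(all(overlapsAny(gypsy, g$per, type = "within")))
  stow <- fe$te[mcols(fe$te)$superfamily == "Stowaway"]
  expect_true(all(overlapsAny(stow, g$deu, type = "within")))
  # every pollen SV matches a truth SV at >= 50% reciprocal overlap
  expect_true(all(countOverlaps(fe$sv_pollen, fe$sv_truth) >= 1))
  # genes non-overlapping, exons within spans
  expect_true(all(countOverlaps(fe$genes$gr, fe$genes$gr) == 1))
  # pass-through construction: full parental fraction, no self overlap
  cfg2 <- sim_config(parental_fraction = 1, self_overlap_fraction = 0,
                     n_self_svs = 0, seed = 22)
  fe2 <- simulate_features(cfg2, simulate_genome(cfg2))
  expect_equal(length(fe2$sv_pollen), length(fe2$sv_truth))
  kept <- filter_parental_svs(fe2$sv_inbred, fe2$sv_pollen, fe2$sv_self)
  expect_equal(length(kept),
               sum(mcols(fe2$sv_inbred)$type %in% c("DEL", "INV")))
})

test_that("PER SVs run longer than DEU SVs when the factor is set", {
  cfg <- sim_config(sv_per_length_factor = 2, seed = 12)
  g <- simulate_genome(cfg)
  fe <- simulate_features(cfg, g)
  sv <- fe$sv_truth
  in_per <- overlapsAny(sv, g$per)
  wt <- stats::wilcox.test(width(sv)[in_per], width(sv)[!in_per],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("a corpus is bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_molecules = 500, gene_count = 200, sv_count = 50,
                    acr_count = 100,
                    te_tracks = list(Gypsy = list(n = 50,
                                                  len_range = c(3e3, 12e3),
                                                  bias = "PER",
                                                  multiplier = 0.2)),
                    seed = 77)
  c1 <- simulate_corpus(cfg, hybrids = c("A", "B"))
  c2 <- simulate_corpus(cfg, hybrids = c("A", "B"))
  expect_identical(c1$hybrids$A$molecules, c2$hybrids$A$molecules)
  expect_identical(c1$hybrids$B$truth, c2$hybrids$B$truth)
  expect_identical(as.data.frame(c1$features$te), as.data.frame(c2$features$te))
})
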