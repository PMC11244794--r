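# Coldspot catalogue: CO regions, >=1 Mb gap detection, conserved
# intersection, Jaccard distance, cross-hybrid clustering, Marey rates.

mk_events <- function(chrom, left, right, hybrid = "H1") {
  data.frame(hybrid_id = rep(hybrid, length(left)),
             molecule_id = sprintf("m%d", seq_along(left)),
             chrom = rep(chrom, length(left)),
             left_marker = left, right_marker = right,
             distance = right - left, resolution = 1 / (right - left))
}

uniform_markers <- function(lengths, by = 10e3) {
  do.call(rbind, lapply(names(lengths), function(chr)
    data.frame(chrom = chr, pos = seq(by, lengths[[chr]], by = by),
               ref = "A", alt = "T")))
}

test_that("CO regions come from selected windows merged within 1 kb", {
  g <- toy_genome(c(chr1 = 40e3))
  ev <- mk_events("chr1", c(12000, 13000), c(12001, 13001))
  reg <- build_co_regions(ev, g, window = 10e3, step = 5e3, merge_gap = 1e3)
  # windows [5001,15000] and [10001,20000] hold the COs -> region [5001,20000]
  expect_equal(start(reg$regions), 5001)
  expect_equal(end(reg$regions), 20000)
  # no COs -> no regions
  empty <- build_co_regions(mk_events("chr1", numeric(0), numeric(0)), g)
  expect_length(empty$regions, 0L)
  # a CO interval spanning a window boundary counts for all windows it hits
  ev2 <- mk_events("chr1", 9800, 10200)
  reg2 <- build_co_regions(ev2, g)
  expect_equal(sum(mcols(reg2$windows)$n_cos), 3L)  # [1,10k],[5k,15k],[10k,20k]
})

test_that("coldspots are >= 1 Mb CO-free gaps with marker support", {
  g <- toy_genome(c(chr1 = 30e6))
  mk <- uniform_markers(c(chr1 = 30e6))
  regions <- GRanges("chr1", IRanges(5e6 + 1, 5.02e6))
  cs <- detect_coldspots(regions, g, mk, hybrid_id = "H1")
  expect_equal(start(cs), c(1, 5.02e6 + 1))
  expect_equal(end(cs), c(5e6, 30e6))
  expect_true(all(mcols(cs)$marker_count > 0))
  # a 0.9 Mb gap is not a coldspot
  g2 <- toy_genome(c(chr1 = 3e6))
  regions2 <- GRanges("chr1", IRanges(c(1, 9e5 + 1), c(0.1e6, 3e6)))
  cs2 <- detect_coldspots(regions2, g2, uniform_markers(c(chr1 = 3e6)))
  expect_length(cs2, 0L)
  # zero-marker gaps are flagged, not catalogued
  g3 <- toy_genome(c(chr1 = 10e6))
  mk3 <- data.frame(chrom = "chr1", pos = seq(6e6, 10e6, by = 1e4),
                    ref = "A", alt = "T")
  cs3 <- detect_coldspots(GRanges("chr1", IRanges(4e6 + 1, 5e6)), g3, mk3)
  expect_equal(start(cs3), 5e6 + 1)  # the marker-backed gap
  flagged <- attr(cs3, "no_marker_gaps")
  expect_equal(start(flagged), 1)
  expect_equal(end(flagged), 4e6)
})

test_that("coldspots never overlap their own CO regions and tile the genome", {
  corpus <- fixture_corpus()
  g <- corpus$genome
  for (h in names(corpus$hybrids)) {
    ev <- fixture_events(h)
    reg <- build_co_regions(ev, g)
    cs <- detect_coldspots(reg, g, corpus$hybrids[[h]]$markers)
    expect_length(intersect_intervals(cs, reg$regions), 0L)
    # complement arithmetic: coldspot bp + non-coldspot bp = genome bp
    non <- setdiff(genome_gr(g), cs)
    expect_equal(sum(width(cs)) + sum(width(non)), genome_size(g))
  }
})

test_that("jaccard_distance equals the size-weighted identity 1 - J", {
  i <- GRanges("chr1", IRanges(1, 100))
  expect_equal(jaccard_distance(i, i), 0)
  expect_equal(jaccard_distance(i, GRanges("chr1", IRanges(500, 600))), 1)
  expect_equal(jaccard_distance(i, GRanges("chr2", IRanges(1, 100))), 1)
  j <- GRanges("chr1", IRanges(51, 150))
  # f = 200, I = 50 -> (200-100)/(200-50) = 2/3; cross-check 1 - 50/150
  expect_equal(jaccard_distance(i, j), 2 / 3)
  expect_equal(jaccard_distance(i, j), 1 - 50 / 150)
  # identity on random pairs
  set.seed(40)
  a <- random_intervals(500, list(c1 = 100e3))
  b <- random_intervals(500, list(c1 = 100e3))
  I <- pmax(0, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1)
  U <- width(a) + width(b) - I
  expect_equal(jaccard_distance(a, b), 1 - I / U)
})

test_that("clustering groups by position and size into unique/shared", {
  # five identical coldspots from five hybrids -> one shared cluster
  cs <- GRanges(rep("chr1", 5), IRanges(1, 2e6))
  mcols(cs)$hybrid_id <- paste0("H", 1:5)
  out <- cluster_coldspots(cs)
  cl <- attr(out, "clusters")
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 5L)
  expect_equal(cl$class, "shared")

  # reciprocal overlap 0.1 < 0.5: two components, two unique clusters
  cs2 <- GRanges("chr1", IRanges(c(1, 0.9e6 + 1), c(1e6, 2e6)))
  mcols(cs2)$hybrid_id <- c("H1", "H1")
  out2 <- cluster_coldspots(cs2)
  cl2 <- attr(out2, "clusters")
  expect_equal(nrow(cl2), 2L)
  expect_true(all(cl2$class == "unique"))

  # span 1.4 Mb < 1.5 x smallest (1 Mb): single cluster, no re-clustering
  cs3 <- GRanges("chr1", IRanges(c(1, 2e5 + 1, 4e5 + 1),
                                 c(1e6, 1.2e6, 1.4e6)))
  mcols(cs3)$hybrid_id <- c("H1", "H2", "H3")
  out3 <- cluster_coldspots(cs3)
  expect_equal(nrow(attr(out3, "clusters")), 1L)
  expect_equal(attr(out3, "clusters")$class, "shared")

  # wide component re-clusters: two tight pairs far apart inside one
  # overlap chain split by the dendrogram cut
  cs4 <- GRanges("chr1", IRanges(c(1, 1, 2.5e6 + 1, 2.5e6 + 1, 1.2e6),
                                 c(1.5e6, 1.5e6, 4e6, 4e6, 2.8e6)))
  mcols(cs4)$hybrid_id <- paste0("H", 1:5)
  out4 <- cluster_coldspots(cs4)
  expect_gt(nrow(attr(out4, "clusters")), 1L)

  # singleton coldspot forms its own unique cluster
  cs5 <- GRanges("chr2", IRanges(1, 1.2e6))
  mcols(cs5)$hybrid_id <- "H4"
  out5 <- cluster_coldspots(cs5)
  expect_equal(attr(out5, "clusters")$class, "unique")
})

test_that("clustering is input-order invariant and partitions the input", {
  corpus <- fixture_corpus()
  g <- corpus$genome
  css <- lapply(names(corpus$hybrids), function(h)
    detect_coldspots(build_co_regions(fixture_events(h), g), g,
                     corpus$hybrids[[h]]$markers, hybrid_id = h))
  pooled <- suppressWarnings(do.call(c, css))
  out1 <- cluster_coldspots(pooled)
  set.seed(1)
  perm <- sample(length(pooled))
  out2 <- cluster_coldspots(pooled[perm])
  expect_identical(out1, out2)  # canonical ordering inside
  # every coldspot sits in exactly one cluster
  expect_equal(nrow(out1), length(pooled))
  expect_false(any(is.na(out1$cluster_id)))
  by_cl <- table(out1$cluster_id)
  expect_equal(sum(by_cl), length(pooled))
  # class labels consistent with member hybrids
  for (cid in unique(out1$cluster_id)) {
    mem <- out1[out1$cluster_id == cid, ]
    expect_equal(unique(mem$class),
                 if (length(unique(mem$hybrid_id)) >= 2) "shared" else "unique")
  }
})

test_that("conserved coldspots are the k-way intersection of unions", {
  g <- toy_genome(c(chr1 = 10e6))
  same <- GRanges("chr1", IRanges(1, 3e6))
  five <- lapply(1:5, function(i) same)
  names(five) <- paste0("H", 1:5)
  cons <- conserved_coldspots(five, g)
  expect_equal(gr_frame(cons), gr_frame(same))
  expect_equal(attr(cons, "fraction"), 0.3)
  # one hybrid recombining inside removes that sub-interval
  five$H3 <- GRanges("chr1", IRanges(c(1, 1.5e6 + 1), c(1e6, 3e6)))
  cons2 <- conserved_coldspots(five, g)
  expect_equal(start(cons2), c(1, 1.5e6 + 1))
  expect_equal(end(cons2), c(1e6, 3e6))
  # empty set in one hybrid -> empty conserved set
  five$H5 <- GRanges()
  expect_length(conserved_coldspots(five, g), 0L)
})

test_that("marey_rate differentiates the genetic map", {
  # linear 1 cM/Mb
  map <- data.frame(bp = seq(0, 10e6, by = 1e6), cM = seq(0, 10, by = 1))
  r <- marey_rate(map)
  expect_true(all(abs(r$rate - 1) < 1e-12))
  # flat segment = rate 0 (coldspot signature)
  map2 <- data.frame(bp = c(0, 1e6, 2e6, 3e6), cM = c(0, 5, 5, 8))
  r2 <- marey_rate(map2)
  expect_equal(r2$rate, c(5, 0, 3))
  # two-segment map matches hand finite differences
  map3 <- data.frame(bp = c(0, 2e6, 3e6), cM = c(0, 1, 4))
  expect_equal(marey_rate(map3)$rate, c(0.5, 3))
  # decreasing cM flagged and excluded
  map4 <- data.frame(bp = c(0, 1e6, 2e6, 3e6), cM = c(0, 2, 1, 3))
  r4 <- marey_rate(map4)
  expect_equal(attr(r4, "n_nonmonotone"), 1L)
  expect_equal(nrow(r4), 2L)
})
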