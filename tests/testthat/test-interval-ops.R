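# Interval engine against per-base brute-force oracles and hand examples.

test_that("merge_intervals handles overlaps, gaps and empty input", {
  g <- toy_genome(c(chr1 = 10e3))
  # overlapping union (0-based [0,10)+[5,20) -> [0,20))
  m <- merge_intervals(GRanges("chr1", IRanges(c(1, 6), c(10, 20))), gap = 0, g)
  expect_equal(start(m), 1)
  expect_equal(end(m), 20)
  # separation 1490 > 1000 -> unchanged
  x <- GRanges("chr1", IRanges(c(1, 1501), c(10, 2000)))
  expect_length(merge_intervals(x, gap = 1000, g), 2L)
  # separation exactly equal to gap merges; one more bp does not
  y <- GRanges("chr1", IRanges(c(1, 111), c(10, 200)))
  expect_length(merge_intervals(y, gap = 100, g), 1L)
  expect_length(merge_intervals(y, gap = 99, g), 2L)
  expect_length(merge_intervals(GRanges(), gap = 1000), 0L)
  # out-of-bounds input rejected
  expect_error(merge_intervals(GRanges("chr1", IRanges(1, 20e3)), 0, g),
               "bounds")
})

test_that("intersect and coverage match hand examples", {
  g <- toy_genome(c(chr1 = 1000))
  i <- intersect_intervals(GRanges("chr1", IRanges(1, 100)),
                           GRanges("chr1", IRanges(51, 150)))
  expect_equal(as.data.frame(i)[, c("start", "end")],
               data.frame(start = 51, end = 100))
  expect_length(intersect_intervals(GRanges("chr1", IRanges(1, 10)),
                                    GRanges("chr1", IRanges(50, 60))), 0L)
  expect_equal(interval_coverage(GRanges(), g), list(bp = 0, fraction = 0))
  expect_equal(interval_coverage(GRanges("chr1", IRanges(1, 1000)), g)$fraction, 1)
  # overlapping intervals counted once
  cov <- interval_coverage(GRanges("chr1", IRanges(c(1, 51), c(100, 150))), g)
  expect_equal(cov$bp, 150)
})

test_that("interval engine agrees with per-base oracle on random toy genomes", {
  set.seed(202)
  # a pool of layouts reused across cases (layout construction dominates)
  pool <- lapply(1:6, function(i) {
    lens <- setNames(sample(5e3:50e3, 2), c("cA", "cB"))
    list(lengths = as.list(lens), g = toy_genome(lens))
  })
  for (rep in 1:150) {
    pick <- pool[[sample.int(6, 1)]]
    lengths <- pick$lengths
    g <- pick$g
    a <- random_intervals(sample(1:12, 1), lengths)
    b <- random_intervals(sample(1:12, 1), lengths)
    gap <- sample(c(0, 1, 10, 500, 5e3), 1)
    expect_identical(gr_frame(merge_intervals(a, gap, g)),
                     gr_frame(oracle_merge(a, gap, lengths)))
    expect_identical(gr_frame(intersect_intervals(a, b)),
                     gr_frame(oracle_intersect(a, b, lengths)))
    expect_equal(interval_coverage(a, g)$bp, oracle_coverage(a, lengths))
  }
})

test_that("reciprocal_overlap is symmetric, bounded, 1 iff identical", {
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 250))
  expect_equal(reciprocal_overlap(a, a), 1)
  expect_equal(reciprocal_overlap(a, GRanges("chr1", IRanges(500, 600))), 0)
  expect_equal(reciprocal_overlap(a, GRanges("chr2", IRanges(1, 100))), 0)
  expect_equal(reciprocal_overlap(a, b), 0.25)  # min(50/100, 50/200)
  set.seed(7)
  x <- random_intervals(200, list(c1 = 50e3))
  y <- random_intervals(200, list(c1 = 50e3))
  expect_equal(reciprocal_overlap(x, y), reciprocal_overlap(y, x))
  ro <- reciprocal_overlap(x, y)
  expect_true(all(ro >= 0 & ro <= 1))
  expect_identical(ro == 1,
                   start(x) == start(y) & end(x) == end(y))
})

test_that("sliding_windows tile and clip as bedtools makewindows", {
  g <- toy_genome(c(chr1 = 20e3))
  w <- sliding_windows(g, 10e3, 5e3)
  expect_equal(start(w), c(1, 5001, 10001, 15001))
  expect_equal(end(w), c(10000, 15000, 20000, 20000))
  expect_equal(mcols(w)$clipped, c(FALSE, FALSE, FALSE, TRUE))
  # every base covered
  expect_equal(interval_coverage(w, g)$fraction, 1)
  # step == size: non-overlapping tiling
  t2 <- sliding_windows(g, 5e3, 5e3)
  expect_true(all(width(reduce(t2)) == 20e3))
  expect_length(t2, 4L)
  # chromosome shorter than the window: one clipped window
  g2 <- toy_genome(c(chr1 = 3e3))
  w2 <- sliding_windows(g2, 10e3, 5e3)
  expect_length(w2, 1L)
  expect_equal(width(w2), 3e3)
})

test_that("shuffle preserves lengths, is seeded, and places uniformly", {
  g <- toy_genome(c(chr1 = 10e3))
  x <- GRanges("chr1", IRanges(101, 1100))  # 1 kb interval
  s1 <- shuffle_intervals(x, g, seed = 5)
  s2 <- shuffle_intervals(x, g, seed = 5)
  expect_identical(s1, s2)
  expect_equal(width(s1), width(x))
  # placements are independent per interval, so one shuffle of 10,000
  # copies samples the placement distribution of a single interval
  n <- 10000
  reps <- rep(x, n)
  starts <- start(shuffle_intervals(reps, g, seed = 77))
  mu <- (1 + 9001) / 2
  sd_mean <- sqrt((9001 - 1)^2 / 12 / n)
  expect_lt(abs(mean(starts) - mu), 3.5 * sd_mean)

  # multi-chromosome: placement frequency proportional to valid positions
  g3 <- toy_genome(c(c1 = 30e3, c2 = 10e3))
  y <- rep(GRanges("c1", IRanges(1, 1000)), n)
  seqlevels(y) <- seqlevels(g3$seqinfo)
  chrs <- as.character(seqnames(shuffle_intervals(y, g3, seed = 78)))
  p1 <- (30e3 - 1000 + 1) / ((30e3 - 1000 + 1) + (10e3 - 1000 + 1))
  se <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(mean(chrs == "c1") - p1), 3 * se)
  # lengths preserved as a multiset for mixed interval sizes
  mix <- random_intervals(50, list(c1 = 30e3, c2 = 10e3), max_len = 2000)
  seqlevels(mix) <- seqlevels(g3$seqinfo)
  sh <- shuffle_intervals(mix, g3, seed = 1)
  expect_identical(sort(width(sh)), sort(width(mix)))
  # an interval longer than every chromosome is rejected
  expect_error(shuffle_intervals(GRanges("c1", IRanges(1, 30e3)),
                                 toy_genome(c(c1 = 30e3, c2 = 10e3)),
                                 seed = 1, within = GRanges("c2", IRanges(1, 10e3))),
               "does not fit")
})

test_that("distance_to_nearest_signed follows the signed-gap convention", {
  b <- GRanges("chr1", IRanges(501, 600))
  expect_equal(distance_to_nearest_signed(GRanges("chr1", IRanges(520, 550)), b), 0)
  expect_equal(distance_to_nearest_signed(GRanges("chr1", IRanges(101, 200)), b), 300)
  expect_equal(distance_to_nearest_signed(GRanges("chr1", IRanges(801, 900)), b), -200)
  expect_true(is.na(distance_to_nearest_signed(GRanges("chr2", IRanges(1, 10)), b)))
  expect_true(all(is.na(distance_to_nearest_signed(
    GRanges("chr1", IRanges(1, 10)), GRanges()))))
  # brute-force check on random sets
  set.seed(31)
  a <- random_intervals(40, list(c1 = 20e3), max_len = 200)
  f <- random_intervals(15, list(c1 = 20e3), max_len = 200)
  d <- distance_to_nearest_signed(a, f)
  for (i in seq_along(a)) {
    gaps <- vapply(seq_along(f), function(j) {
      if (start(f)[j] > end(a)[i]) start(f)[j] - end(a)[i] - 1
      else if (end(f)[j] < start(a)[i]) end(f)[j] - start(a)[i] + 1
      else 0
    }, numeric(1))
    expect_equal(abs(d[i]), min(abs(gaps)))
  }
})

test_that("fast overlap counter agrees with countOverlaps", {
  set.seed(99)
  for (rep in 1:25) {
    lengths <- list(c1 = 40e3, c2 = 25e3)
    q <- random_intervals(30, lengths, max_len = 500)
    f <- random_intervals(12, lengths, max_len = 3000)
    fidx <- coldspotAtlas:::feature_index(f)
    fast <- coldspotAtlas:::count_overlapping(
      as.character(seqnames(q)), start(q), end(q), fidx)
    expect_identical(fast, sum(countOverlaps(q, f) > 0))
  }
})
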