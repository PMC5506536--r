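test_that("bed_slop expands with clamping, fractions and strand awareness", {
  g <- toy_genome(chr1 = 100)
  expect_equal(bed_slop(bed3("chr1", 2, 4), g, both = 5), bed3("chr1", 0, 9))

  # 1-bp TSS slopped 1000 both ways -> width 2001
  g2 <- toy_genome(chr1 = 1e6)
  tss <- bed3("chr1", 5000, 5001)
  slopped <- bed_slop(tss, g2, both = 1000)
  expect_equal(slopped$end - slopped$start, 2001)

  x <- tibble::tibble(chrom = "chr1", start = 10, end = 20, strand = "-")
  expect_equal(
    bed_slop(x, g, left = 3, strand_aware = TRUE)[, c("start", "end")],
    tibble::tibble(start = 10, end = 23)
  )
  # fraction: both = 0.5 of a width-10 interval expands 5 each side
  expect_equal(
    bed_slop(bed3("chr1", 40, 50), g, both = 0.5, fraction = TRUE),
    bed3("chr1", 35, 55)
  )
  expect_error(bed_slop(bed3("chr1", 1, 2), g, both = -1), class = "bedtbl_bad_args")
  expect_error(
    bed_slop(bed3("chr1", 1, 2), g, both = 1, strand_aware = TRUE),
    class = "bedtbl_missing_column"
  )
})

test_that("bed_shift moves intervals and handles bounds", {
  g <- toy_genome(chr1 = 100)
  expect_equal(bed_shift(bed3("chr1", 10, 20), g, size = 5), bed3("chr1", 15, 25))
  expect_equal(
    bed_shift(bed3("chr1", 10, 20), g, size = 0.5, fraction = TRUE),
    bed3("chr1", 15, 25)
  )
  expect_error(
    bed_shift(bed3("chr1", 95, 99), g, size = 10),
    class = "bedtbl_out_of_bounds"
  )
  # clamped to zero width -> dropped with a warning
  expect_warning(
    res <- bed_shift(bed3("chr1", 95, 99), g, size = 5, trim = TRUE),
    class = "bedtbl_zero_width_dropped"
  )
  expect_equal(nrow(res), 0)
  # minus-strand rows shift backwards when strand-aware
  x <- tibble::tibble(chrom = "chr1", start = 50, end = 60, strand = "-")
  expect_equal(bed_shift(x, g, size = 5, strand_aware = TRUE)$start, 45)
})

test_that("bed_flank emits abutting intervals, clamped", {
  g <- toy_genome(chr1 = 1000)
  fl <- bed_flank(bed3("chr1", 100, 200), g, both = 50)
  expect_equal(fl[, c("start", "end")], tibble::tibble(start = c(50, 200), end = c(100, 250)))

  g2 <- toy_genome(chr1 = 100)
  fl2 <- bed_flank(bed3("chr1", 10, 20), g2, left = 50)
  expect_equal(fl2, bed3("chr1", 0, 10)) # clamped at chromosome start

  x <- tibble::tibble(chrom = "chr1", start = 10, end = 20, strand = "-")
  fl3 <- bed_flank(x, g2, left = 5, strand_aware = TRUE)
  expect_equal(fl3[, c("start", "end")], tibble::tibble(start = 20, end = 25))
})

test_that("bed_merge unions intervals within max_dist and aggregates", {
  x <- bed3("chr1", c(1, 10, 100), c(50, 75, 120))
  m <- bed_merge(x)
  expect_equal(m, bed3("chr1", c(1, 100), c(75, 120)))
  # idempotence
  expect_equal(bed_merge(m), m)

  expect_equal(
    bed_merge(bed3("chr1", c(0, 15), c(10, 20)), max_dist = 10),
    bed3("chr1", 0, 20)
  )
  # book-ended intervals union at max_dist = 0
  expect_equal(nrow(bed_merge(bed3("chr1", c(0, 10), c(10, 20)))), 1)

  withval <- tibble::tibble(
    chrom = "chr1", start = c(0, 5), end = c(10, 20), value = c(3, 5)
  )
  magg <- bed_merge(withval, aggs = list(
    .max = c("max", "value"),
    .concat = c("concat", "value")
  ))
  expect_equal(magg$.max, 5)
  expect_equal(magg$.concat, "3,5")
  expect_error(
    bed_merge(withval, aggs = list(.m = c("max", "nope"))),
    class = "bedtbl_unknown_column"
  )
  # non-grouped extra columns are dropped (ill-defined after union)
  expect_false("value" %in% names(bed_merge(withval)))

  # merge idempotence on random tables
  g <- make_genome(2, c(5e3, 1e4), seed = 51)
  r <- make_intervals(g, 200, c(50, 800), seed = 52)
  mr <- bed_merge(r, max_dist = 5)
  expect_equal(bed_merge(mr, max_dist = 5), mr)
})

test_that("bed_cluster labels merge components with global sorted ids", {
  x <- bed3("chr1", c(0, 5, 30), c(10, 20, 40))
  expect_equal(bed_cluster(x)$.id, c(1L, 1L, 2L))
  x2 <- bed3(c("chr1", "chr2"), c(0, 0), c(10, 10))
  expect_equal(bed_cluster(x2)$.id, c(1L, 2L))

  # clusters agree with bed_merge
  g <- make_genome(2, c(5e3, 8e3), seed = 61)
  r <- make_intervals(g, 150, c(50, 600), seed = 62)
  cl <- bed_cluster(r)
  via_clusters <- dplyr::summarise(
    dplyr::group_by(cl, chrom, .id),
    start = min(start), end = max(end), .groups = "drop"
  )
  via_clusters <- via_clusters[order(via_clusters$chrom, via_clusters$start), ]
  m <- bed_merge(r)
  expect_equal(via_clusters$start, m$start)
  expect_equal(via_clusters$end, m$end)
})

test_that("bed_complement returns uncovered genome regions", {
  g <- toy_genome(chr1 = 100)
  expect_equal(
    bed_complement(bed3("chr1", 20, 30), g),
    bed3("chr1", c(0, 30), c(20, 100))
  )
  expect_equal(nrow(bed_complement(bed3("chr1", 0, 100), g)), 0)
  g2 <- toy_genome(chr1 = 100, chr2 = 50)
  empty <- bed3(character(), numeric(), numeric())
  expect_equal(
    bed_complement(empty, g2),
    bed3(c("chr1", "chr2"), c(0, 0), c(100, 50))
  )

  # complement partition: merged x plus complement exactly tile [0, size)
  gg <- make_genome(2, c(3e3, 6e3), seed = 71)
  r <- make_intervals(gg, 100, c(50, 500), seed = 72)
  comp <- bed_complement(r, gg)
  expect_equal(
    interval_bp(bed_merge(r)) + interval_bp(comp),
    sum(gg$size)
  )
  expect_equal(nrow(bed_intersect(bed_merge(r), comp)), 0)
})

test_that("bed_makewindows subdivides intervals exactly", {
  g <- toy_genome(chr1 = 1e6)
  # width-2001 interval with 50 bp windows -> 41 windows, last of width 1
  w <- bed_makewindows(bed3("chr1", 0, 2001), win_size = 50)
  expect_equal(nrow(w), 41)
  expect_equal(w$end[41] - w$start[41], 1)
  expect_equal(w$.win_id, 1:41)

  expect_equal(nrow(bed_makewindows(bed3("chr1", 0, 100), win_size = 50)), 2)

  w4 <- bed_makewindows(bed3("chr1", 0, 10), num_win = 4)
  expect_equal(w4$end - w4$start, c(3, 3, 2, 2)) # larger windows first
  expect_error(
    bed_makewindows(bed3("chr1", 0, 3), num_win = 4),
    class = "bedtbl_bad_args"
  )
  wr <- bed_makewindows(bed3("chr1", 0, 100), win_size = 25, reverse = TRUE)
  expect_equal(wr$.win_id, 4:1)

  # conservation: each parent's windows concatenate exactly back to it
  r <- make_intervals(make_genome(1, c(1e4, 2e4), seed = 81), 50, c(20, 900), seed = 82)
  r$name <- paste0("parent", seq_len(nrow(r)))
  rw <- bed_makewindows(r, win_size = 33)
  expect_equal(sum(rw$end - rw$start), sum(r$end - r$start))
  per_parent <- split(rw, rw$name)
  expect_true(all(vapply(per_parent, function(p) {
    p <- p[order(p$.win_id), ]
    parent <- r[r$name == p$name[1], ]
    all(p$start[-1] == p$end[-nrow(p)]) &&
      p$start[1] == parent$start && p$end[nrow(p)] == parent$end
  }, logical(1))))
})

test_that("bed12_to_exons expands blocks with 5'-to-3' ranks", {
  b12 <- tibble::tibble(
    chrom = "chr1", start = 1000, end = 1700, name = "tx1", score = "0",
    strand = "+", thickStart = 1000, thickEnd = 1700, itemRgb = "0",
    blockCount = 2L, blockSizes = "100,200", blockStarts = "0,500"
  )
  ex <- bed12_to_exons(b12)
  expect_equal(ex$start, c(1000, 1500))
  expect_equal(ex$end, c(1100, 1700))
  expect_equal(ex$score, c(1L, 2L))

  b12m <- b12
  b12m$strand <- "-"
  exm <- bed12_to_exons(b12m)
  expect_equal(exm$score, c(2L, 1L)) # ranks reversed on minus strand

  b1 <- b12
  b1$blockCount <- 1L
  b1$blockSizes <- "700"
  b1$blockStarts <- "0"
  ex1 <- bed12_to_exons(b1)
  expect_equal(nrow(ex1), 1)
  expect_equal(c(ex1$start, ex1$end), c(1000, 1700))

  bad <- b12
  bad$blockCount <- 3L
  expect_error(bed12_to_exons(bad), class = "bedtbl_bad_blocks")
})
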