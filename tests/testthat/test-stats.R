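test_that("bed_jaccard matches closed forms on degenerate inputs", {
  x <- bed3("chr1", c(0, 200), c(100, 300))
  self <- bed_jaccard(x, x)
  expect_equal(self$len_i, 200L)
  expect_equal(self$len_u, 400)
  expect_equal(self$jaccard, 1)
  expect_equal(self$n, 2L)

  disjoint <- bed_jaccard(x, bed3("chr1", 1000, 1100))
  expect_equal(disjoint$jaccard, 0)
  expect_equal(disjoint$n, 0L)
})

test_that("bed_jaccard is symmetric and matches the bp-accounting oracle", {
  for (seed in c(131, 132, 133)) {
    g <- make_genome(2, c(5e3, 8e3), seed = seed)
    x <- make_intervals(g, 150, c(50, 500), seed = seed + 1)
    y <- make_intervals(g, 150, c(50, 500), seed = seed + 2)
    jxy <- bed_jaccard(x, y)
    jyx <- bed_jaccard(y, x)
    expect_equal(jxy, jyx)
    expect_gte(jxy$jaccard, 0)
    expect_lte(jxy$jaccard, 1)

    # independent oracle: inclusion-exclusion over swept coverage
    len_i <- brute_bp(x) + brute_bp(y) - brute_bp(dplyr::bind_rows(x, y))
    len_u <- brute_bp(x) + brute_bp(y)
    expect_equal(jxy$len_i, len_i)
    expect_equal(jxy$jaccard, len_i / (len_u - len_i))
  }
})

test_that("bed_reldist computes midpoint relative distances in [0, 0.5]", {
  y <- bed3(c("chr1", "chr1"), c(0, 99), c(1, 101)) # midpoints 0.5 and 100
  x <- bed3("chr1", 25, 26) # midpoint 25.5
  r <- bed_reldist(x, y, detail = TRUE)
  expect_equal(r$.reldist, (25.5 - 0.5) / (100 - 0.5), tolerance = 1e-12)

  # exact quarter and half positions with even midpoints
  y2 <- bed3(c("chr1", "chr1"), c(0, 100), c(2, 102)) # midpoints 1, 101
  expect_equal(bed_reldist(bed3("chr1", 25, 27), y2, detail = TRUE)$.reldist, 0.25)
  expect_equal(bed_reldist(bed3("chr1", 50, 52), y2, detail = TRUE)$.reldist, 0.5)

  # x outside the y midpoint span is omitted
  expect_equal(nrow(bed_reldist(bed3("chr1", 500, 502), y2, detail = TRUE)), 0)

  # histogram form: 0.05 bins, frequencies sum to 1
  g <- make_genome(1, c(1e5, 1e5), seed = 141)
  rx <- make_intervals(g, 500, 10, seed = 142)
  ry <- make_intervals(g, 50, 10, seed = 143)
  h <- bed_reldist(rx, ry)
  expect_equal(h$.reldist, seq(0, 0.45, 0.05))
  expect_equal(sum(h$.freq), 1)
  d <- bed_reldist(rx, ry, detail = TRUE)
  expect_true(all(d$.reldist >= 0 & d$.reldist <= 0.5))
})

test_that("bed_absdist scales nearest-midpoint distances by y density", {
  g <- toy_genome(chr = 1000)
  x <- bed3("chr", 9, 11) # midpoint 10
  y <- bed3(c("chr", "chr"), c(0, 99), c(0, 101)) # midpoints 0 and 100
  a <- suppressWarnings(bed_absdist(x, y, g)) # (zero-width y row is flagged)
  expect_equal(a$.absdist, 10)
  expect_equal(a$.absdist_scaled, 10 * 2 / 1000)

  # coincident midpoints give 0
  expect_equal(
    suppressWarnings(bed_absdist(bed3("chr", 99, 101), y, g))$.absdist, 0
  )

  # x on chromosomes without y get NA
  g2 <- toy_genome(chr = 1000, chr2 = 1000)
  a2 <- suppressWarnings(bed_absdist(bed3("chr2", 0, 10), y, g2))
  expect_true(is.na(a2$.absdist))

  # brute-force agreement on random fixtures
  gg <- make_genome(1, c(5e4, 5e4), seed = 151)
  rx <- make_intervals(gg, 100, c(10, 100), seed = 152)
  ry <- make_intervals(gg, 30, c(10, 100), seed = 153)
  got <- bed_absdist(rx, ry, gg)
  want <- vapply(
    (rx$start + rx$end) / 2,
    function(m) min(abs(m - (ry$start + ry$end) / 2)),
    numeric(1)
  )
  expect_equal(got$.absdist, want)
})

test_that("bed_fisher builds the contingency table and exact p-value", {
  g <- toy_genome(chr1 = 1000)
  x <- bed3("chr1", seq(0, 90, 10), seq(0, 90, 10) + 10)
  self <- bed_fisher(x, x, g)
  expect_equal(self$n12, 0)
  expect_equal(self$n21, 0)
  # maximal association: the one-sided table extreme
  expect_true(self$p_value < 1e-6)

  # toy: |x| = |y| = 10, 5 overlaps, 1000 bp genome, mean width 10
  y <- bed3(
    "chr1",
    c(seq(0, 40, 10), seq(500, 540, 10)),
    c(seq(0, 40, 10), seq(500, 540, 10)) + 10
  )
  ft <- bed_fisher(x, y, g)
  expect_equal(ft$n11, 5)
  expect_equal(ft$n12, 5)
  expect_equal(ft$n21, 5)
  expect_equal(ft$n22, 100 - 15)
  # independent hypergeometric-sum oracle on the same table
  m <- matrix(c(5, 5, 5, 85), nrow = 2, byrow = TRUE)
  k <- m[1, 1] + m[1, 2]
  K <- m[1, 1] + m[2, 1]
  N <- sum(m)
  dens <- stats::dhyper(0:k, K, N - K, k)
  p_oracle <- sum(dens[dens <= dens[m[1, 1] + 1] * (1 + 1e-7)])
  expect_equal(ft$p_value, p_oracle, tolerance = 1e-12)

  expect_error(
    bed_fisher(bed3(character(), numeric(), numeric()), x, g),
    class = "bedtbl_empty_input"
  )
})

test_that("bed_projection computes exact per-chromosome binomial tests", {
  g <- toy_genome(chr1 = 1000)
  # y covers exactly half; successes = trials/2 -> ratio 1
  y <- bed3("chr1", 0, 500)
  x <- bed3("chr1", c(seq(0, 480, 40), seq(500, 980, 40)), c(seq(0, 480, 40), seq(500, 980, 40)) + 2)
  pr <- bed_projection(x, y, g)
  expect_equal(pr$obs_exp_ratio, 1, tolerance = 1e-12)
  expect_false(pr$lower_tail)

  # all 100 x midpoints inside y with p0 = 0.5: closed-form two-sided tail
  x2 <- bed3("chr1", seq(0, 396, 4), seq(0, 396, 4) + 2)
  pr2 <- bed_projection(x2, y, g)
  expect_equal(pr2$p_value, 2 * 0.5^100, tolerance = 1e-12)

  # chroms without x are absent
  g2 <- toy_genome(chr1 = 1000, chr2 = 1000)
  expect_equal(bed_projection(x, y, g2)$chrom, "chr1")

  # p-values match an independent binomial-density oracle to 1e-12
  set.seed(161)
  for (i in 1:5) {
    trials <- sample(5:60, 1)
    cov_frac <- runif(1, 0.1, 0.9)
    gg <- toy_genome(chrZ = 10000)
    yy <- bed3("chrZ", 0, round(10000 * cov_frac))
    starts <- sample(0:9998, trials)
    xx <- bed3("chrZ", starts, starts + 1)
    got <- bed_projection(xx, yy, gg)
    p0 <- (yy$end - yy$start) / 10000
    succ <- sum(floor((xx$start + xx$end) / 2) < yy$end)
    dens <- stats::dbinom(0:trials, trials, p0)
    want <- sum(dens[dens <= dens[succ + 1] * (1 + 1e-7)])
    expect_equal(got$p_value, min(1, want), tolerance = 1e-12)
  }
})

test_that("empirical_pvalue uses the add-one estimator", {
  expect_equal(empirical_pvalue(10, rep(1, 100)), 1 / 101)
  expect_equal(empirical_pvalue(10, rep(1, 100)), 0.00990099, tolerance = 1e-7)
  expect_equal(empirical_pvalue(0, rep(1, 100)), 1)
  expect_equal(empirical_pvalue(-5, c(0, 1, 2)), 1) # obs below the null minimum
  expect_error(empirical_pvalue(1, numeric()), class = "bedtbl_empty_input")
})

test_that("shuffle_null is seeded and produces one score per replicate", {
  g <- make_genome(2, c(2e4, 3e4), seed = 171)
  x <- make_intervals(g, 50, c(100, 500), seed = 172)
  y <- make_intervals(g, 50, c(100, 500), seed = 173)
  null1 <- shuffle_null(x, y, g, nreps = 10, statistic = "jaccard", seed = 5)
  null2 <- shuffle_null(x, y, g, nreps = 10, statistic = "jaccard", seed = 5)
  expect_identical(null1, null2)
  expect_length(null1, 10)
  expect_true(all(null1 >= 0 & null1 <= 1))

  proj <- shuffle_null(x, y, g, nreps = 5, statistic = "projection", seed = 6)
  expect_true(all(proj >= 0 & proj <= 1))
})
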