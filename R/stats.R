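# Overlap-significance statistics between two interval sets, plus the
# shuffle-based empirical p-value procedure.

#' Jaccard similarity of two interval sets
#'
#' Both inputs are merged internally, then: `len_i` is the total bp of
#' intersection between the merged sets, `len_u` the sum of their merged
#' bp, `jaccard = len_i / (len_u - len_i)` (intersection over union), and
#' `n` the count of intersecting pairs between the merged sets. Symmetric
#' and deterministic.
#'
#' @param x,y interval tibbles.
#' @return a one-row tibble with `len_i`, `len_u`, `jaccard`, `n`.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' bed_jaccard(x, x) # jaccard of a set with itself is 1
#' @export
bed_jaccard <- function(x, y) {
  mx <- bed_merge(dplyr::ungroup(x)[c("chrom", "start", "end")])
  my <- bed_merge(dplyr::ungroup(y)[c("chrom", "start", "end")])
  pairs <- overlap_join(mx, my)
  len_i <- sum(pairs$.overlap)
  len_u <- interval_bp(mx) + interval_bp(my)
  tibble(
    len_i = len_i,
    len_u = len_u,
    jaccard = if (len_u - len_i > 0) len_i / (len_u - len_i) else as.numeric(len_i > 0),
    n = nrow(pairs)
  )
}

midpoints <- function(x) (x$start + x$end) / 2

#' Relative distances between two interval sets
#'
#' For each x midpoint m with flanking y midpoints l <= m <= r on the same
#' chromosome, the relative distance is `min(m - l, r - m) / (r - l)`, a
#' value in `[0, 0.5]` whose expectation is 0.25 when x is placed
#' independently of y. x rows without two flanking y midpoints are omitted.
#'
#' @param x,y interval tibbles.
#' @param detail return per-row values instead of the histogram.
#' @return with `detail = TRUE`, x rows with a `.reldist` column; otherwise
#'   a histogram over 0.05-wide bins with `.counts`, `.total`, `.freq`.
#' @export
bed_reldist <- function(x, y, detail = FALSE) {
  x <- bed_sort(validate_table(dplyr::ungroup(x)))
  y <- bed_sort(validate_table(dplyr::ungroup(y)))
  ym_by_chrom <- lapply(split(midpoints(y), y$chrom), sort)
  xm <- midpoints(x)
  vals <- rep(NA_real_, nrow(x))
  for (chrom in names(ym_by_chrom)) {
    ym <- ym_by_chrom[[chrom]]
    if (length(ym) < 2) next
    rows <- which(x$chrom == chrom)
    m <- xm[rows]
    i <- findInterval(m, ym)
    ok <- i >= 1 & i < length(ym)
    l <- ym[pmax(i, 1)]
    r <- ym[pmin(i + 1, length(ym))]
    span <- r - l
    v <- ifelse(span > 0, pmin(m - l, r - m) / span, 0)
    vals[rows[ok]] <- v[ok]
  }
  keep <- !is.na(vals)
  if (detail) {
    out <- x[keep, , drop = FALSE]
    out$.reldist <- vals[keep]
    return(out)
  }
  v <- vals[keep]
  breaks <- seq(0, 0.5, by = 0.05)
  bin <- pmin(findInterval(v, breaks), length(breaks) - 1)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  tibble(
    .reldist = breaks[-length(breaks)],
    .counts = counts,
    .total = length(v),
    .freq = if (length(v) > 0) counts / length(v) else rep(NA_real_, length(counts))
  )
}

#' Absolute distances between two interval sets
#'
#' For each x row, `.absdist` is the minimum distance from its midpoint to
#' any y midpoint on the same chromosome, and `.absdist_scaled` multiplies
#' it by the per-chromosome y density (y count / chromosome size), making
#' values comparable across chromosomes of different sizes and coverage.
#' x rows on chromosomes with no y get `NA`.
#'
#' @param x,y interval tibbles.
#' @param genome a genome tibble.
#' @return `x`, sorted, with `.absdist` and `.absdist_scaled` columns.
#' @export
bed_absdist <- function(x, y, genome) {
  x <- bed_sort(validate_table(dplyr::ungroup(x)))
  y <- bed_sort(validate_table(dplyr::ungroup(y)))
  ym_by_chrom <- lapply(split(midpoints(y), y$chrom), sort)
  xm <- midpoints(x)
  d <- rep(NA_real_, nrow(x))
  dens <- rep(NA_real_, nrow(x))
  for (chrom in names(ym_by_chrom)) {
    ym <- ym_by_chrom[[chrom]]
    rows <- which(x$chrom == chrom)
    if (length(rows) == 0) next
    m <- xm[rows]
    i <- findInterval(m, ym)
    d_lo <- ifelse(i >= 1, m - ym[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(ym), ym[pmin(i + 1, length(ym))] - m, Inf)
    d[rows] <- pmin(d_lo, d_hi)
    size <- genome$size[match(chrom, genome$chrom)]
    dens[rows] <- length(ym) / size
  }
  x$.absdist <- d
  x$.absdist_scaled <- d * dens
  x
}

#' Fisher's exact test for overlap between two interval sets
#'
#' Builds a 2x2 contingency table from interval counts: `n11` x rows
#' overlapping any y, `n12` the remaining x rows, `n21` y rows beyond the
#' shared overlap count (floored at 0), and `n22` the remaining capacity of
#' the genome expressed in units of the mean interval width of the combined
#' sets. The two-sided Fisher exact test on that table estimates whether x
#' and y co-occur more (or less) than expected. The table construction is a
#' convention (genome "slots" are not true independent trials); treat the
#' p-value as a screening statistic.
#'
#' @param x,y non-empty interval tibbles.
#' @param genome a genome tibble.
#' @return a one-row tibble with `n11`, `n12`, `n21`, `n22`, the odds-ratio
#'   `estimate` and the two-sided `p_value`.
#' @export
bed_fisher <- function(x, y, genome) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    abort("`x` and `y` must be non-empty", class = "bedtbl_empty_input")
  }
  x <- dplyr::ungroup(x)
  y <- dplyr::ungroup(y)
  idx <- overlap_join_idx(x[c("chrom", "start", "end")], y[c("chrom", "start", "end")])
  n11 <- length(unique(idx$xi))
  n12 <- nrow(x) - n11
  n21 <- max(0, nrow(y) - n11)
  mean_width <- mean(c(x$end - x$start, y$end - y$start))
  slots <- round(sum(genome$size) / mean_width)
  n22 <- max(0, slots - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble(
    n11 = n11, n12 = n12, n21 = n21, n22 = n22,
    estimate = unname(ft$estimate),
    p_value = ft$p.value
  )
}

#' Projection test for overlap between two interval sets
#'
#' Per chromosome, counts how many x midpoints fall inside any (merged) y
#' interval and compares that to the binomial expectation under uniform
#' placement, where the success probability is y's coverage fraction of the
#' chromosome. Reports an exact two-sided binomial p-value, the
#' observed/expected ratio, and whether the observation is below
#' expectation. Chromosomes with no x rows are absent from the result.
#'
#' @param x,y interval tibbles.
#' @param genome a genome tibble.
#' @return a per-chromosome tibble with `chrom`, `p_value`,
#'   `obs_exp_ratio`, `lower_tail`.
#' @export
bed_projection <- function(x, y, genome) {
  x <- bed_sort(validate_table(dplyr::ungroup(x)))
  my <- bed_merge(dplyr::ungroup(y)[c("chrom", "start", "end")])
  my <- suppressWarnings(bound_intervals(my, genome, trim = TRUE))
  xm <- midpoints(x)
  chroms <- intersect(unique(x$chrom), genome$chrom)
  rows <- lapply(chroms, function(chrom) {
    xi <- which(x$chrom == chrom)
    m <- xm[xi]
    yc <- my[my$chrom == chrom, , drop = FALSE]
    trials <- length(xi)
    if (nrow(yc) == 0) {
      successes <- 0L
      p0 <- 0
    } else {
      # midpoint inside a half-open y interval: start <= m < end
      i <- findInterval(m, yc$start)
      successes <- sum(i >= 1 & m < yc$end[pmax(i, 1)])
      p0 <- sum(yc$end - yc$start) / genome$size[match(chrom, genome$chrom)]
    }
    if (p0 == 0 && successes > 0) {
      abort("x midpoints inside y on a chromosome with zero y coverage",
        class = "bedtbl_data_error"
      )
    }
    expected <- trials * p0
    tibble(
      chrom = chrom,
      p_value = stats::binom.test(successes, trials, p0, "two.sided")$p.value,
      obs_exp_ratio = if (expected > 0) successes / expected else NA_real_,
      lower_tail = successes < expected
    )
  })
  dplyr::bind_rows(rows)
}

#' Empirical p-value against a permutation null
#'
#' The add-one estimator: `(count(null >= obs) + 1) / (length(null) + 1)`.
#' With zero exceedances among 100 replicates this is 1/101 ~ 0.0099; it can
#' never return 0, reflecting that the observed value is itself one draw.
#'
#' @param obs observed statistic (scalar).
#' @param null numeric vector of null-replicate statistics (non-empty).
#' @return the empirical p-value.
#' @examples
#' empirical_pvalue(10, rep(1, 100)) # 1/101
#' @export
empirical_pvalue <- function(obs, null) {
  if (length(null) == 0) {
    abort("`null` must be non-empty", class = "bedtbl_empty_input")
  }
  (sum(null >= obs) + 1) / (length(null) + 1)
}

#' Null distribution of overlap statistics by shuffling
#'
#' Shuffles `x` against the genome `nreps` times and scores each replicate
#' against `y`: `statistic = "jaccard"` records the jaccard index;
#' `"projection"` records the genome-wide fraction of x midpoints falling
#' inside merged y intervals. The whole vector is reproducible from `seed`.
#'
#' @param x,y interval tibbles.
#' @param genome a genome tibble.
#' @param nreps number of shuffle replicates (>= 1).
#' @param statistic `"jaccard"` or `"projection"`.
#' @param seed optional integer seed for the whole procedure.
#' @param ... passed to [bed_shuffle()] (e.g. `incl`, `excl`, `max_tries`).
#' @return numeric vector of length `nreps`.
#' @export
shuffle_null <- function(x, y, genome, nreps = 100,
                         statistic = c("jaccard", "projection"),
                         seed = NULL, ...) {
  statistic <- match.arg(statistic)
  if (nreps < 1) {
    abort("`nreps` must be >= 1", class = "bedtbl_bad_args")
  }
  my <- bed_merge(dplyr::ungroup(y)[c("chrom", "start", "end")])
  score <- function(shuf) {
    if (statistic == "jaccard") {
      return(bed_jaccard(shuf, my)$jaccard)
    }
    m <- midpoints(shuf)
    hits <- 0L
    for (chrom in unique(shuf$chrom)) {
      yc <- my[my$chrom == chrom, , drop = FALSE]
      if (nrow(yc) == 0) next
      mm <- m[shuf$chrom == chrom]
      i <- findInterval(mm, yc$start)
      hits <- hits + sum(i >= 1 & mm < yc$end[pmax(i, 1)])
    }
    hits / nrow(shuf)
  }
  with_seed(seed, {
    vapply(seq_len(nreps), function(rep) {
      score(bed_shuffle(x, genome, seed = NULL, ...))
    }, numeric(1))
  })
}
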