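# Deterministic synthetic data generators, so every operation is testable
# without external files: toy genomes, random interval tables, and a
# bedGraph-shaped ChIP-signal emulator with Gaussian bumps at transcription
# start sites.

#' Generate a synthetic genome
#'
#' @param n_chroms number of chromosomes (`chr1` ... `chrN`).
#' @param size_range length-2 vector of chromosome size bounds (bp).
#' @param seed optional integer seed.
#' @return a genome tibble, sorted by chromosome name.
#' @examples
#' make_genome(3, c(1e5, 2e5), seed = 1)
#' @export
make_genome <- function(n_chroms = 3, size_range = c(1e5, 2e5), seed = NULL) {
  if (n_chroms == 0) {
    return(tibble(chrom = character(), size = integer()))
  }
  if (any(size_range <= 0)) {
    abort("chromosome sizes must be positive", class = "bedtbl_bad_args")
  }
  with_seed(seed, {
    sizes <- floor(runif(n_chroms, size_range[1], size_range[2] + 1))
    g <- tibble(chrom = paste0("chr", seq_len(n_chroms)), size = sizes)
    g[order(g$chrom, method = "radix"), , drop = FALSE]
  })
}

#' Generate random interval tables
#'
#' Draws `n` intervals: chromosomes with probability proportional to size,
#' widths from `width_dist` (a single value for fixed widths, or a length-2
#' range sampled uniformly), starts uniform so the interval fits the
#' chromosome. Optionally adds a random `+`/`-` strand column.
#'
#' @param genome a genome tibble.
#' @param n number of intervals.
#' @param width_dist fixed width, or `c(min, max)` range.
#' @param seed optional integer seed.
#' @param with_strand add a random strand column.
#' @return a sorted, valid interval tibble with `n` rows.
#' @export
make_intervals <- function(genome, n = 100, width_dist = c(100, 1000),
                           seed = NULL, with_strand = FALSE) {
  max_w <- max(width_dist)
  if (all(genome$size < max_w)) {
    abort("widths do not fit any chromosome", class = "bedtbl_bad_args")
  }
  with_seed(seed, {
    usable <- genome[genome$size >= max_w, , drop = FALSE]
    ci <- sample.int(nrow(usable), n, replace = TRUE, prob = usable$size)
    w <- if (length(width_dist) == 1) {
      rep(width_dist, n)
    } else {
      floor(runif(n, width_dist[1], width_dist[2] + 1))
    }
    start <- runif_start(usable$size[ci] - w)
    out <- tibble(chrom = usable$chrom[ci], start = start, end = start + w)
    if (with_strand) {
      out$strand <- sample(c("+", "-"), n, replace = TRUE)
    }
    bed_sort(validate_table(out))
  })
}

#' Emulate ChIP signal around transcription start sites
#'
#' Emits bedGraph-shaped rows tiling a region around each 1-bp TSS in 10 bp
#' steps: the value is a baseline plus a Gaussian bump of the given height
#' and half-width centered on the TSS, plus normal noise. This emulates the
#' shape of promoter-proximal ChIP enrichment; it does not emulate read
#' sampling, mappability gaps or strand asymmetry of real coverage data.
#'
#' @param genome a genome tibble.
#' @param tss a table of width-1 intervals marking TSS positions.
#' @param peak_height bump height at the TSS (signal units).
#' @param peak_halfwidth Gaussian sigma (bp).
#' @param noise_sd standard deviation of additive noise.
#' @param baseline constant background level.
#' @param region half-width of the emitted region around each TSS (bp).
#' @param step emission step size (bp).
#' @param seed optional integer seed.
#' @return a sorted bedGraph-shaped tibble (`chrom`, `start`, `end`,
#'   `value`).
#' @export
make_tss_signal <- function(genome, tss, peak_height = 100, peak_halfwidth = 200,
                            noise_sd = 1, baseline = 0, region = 1500,
                            step = 10, seed = NULL) {
  if (any(tss$end - tss$start != 1)) {
    abort("`tss` must contain width-1 intervals", class = "bedtbl_bad_args")
  }
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(tss)), function(i) {
      center <- (tss$start[i] + tss$end[i]) / 2
      size <- genome$size[match(tss$chrom[i], genome$chrom)]
      lo <- max(0, center - region)
      hi <- min(size, center + region)
      starts <- seq(lo, hi - step, by = step)
      mid <- starts + step / 2
      bump <- peak_height * exp(-((mid - center)^2) / (2 * peak_halfwidth^2))
      tibble(
        chrom = tss$chrom[i],
        start = starts,
        end = starts + step,
        value = baseline + bump + rnorm(length(starts), sd = noise_sd)
      )
    })
    bed_sort(dplyr::bind_rows(pieces))
  })
}
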