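# Seeded interval randomization. All stochastic functions take an explicit
# `seed`; when given, the Mersenne-Twister stream is seeded locally and the
# caller's RNG state is restored afterwards, so results are reproducible
# without touching global state. With `seed = NULL` the current stream is
# used (this is how shuffle_null() draws many dependent replicates from one
# seed).

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# integer draw uniform on [0, max_start] (inclusive), vectorized over max_start
runif_start <- function(max_start) {
  pmin(floor(runif(length(max_start)) * (max_start + 1)), max_start)
}

#' Generate random intervals from a genome
#'
#' Draws `n` intervals of exactly `length` bp: the chromosome is chosen with
#' probability proportional to its size and the start is uniform on
#' `[0, size - length]`. Chromosomes shorter than `length` are excluded
#' (with a warning); if none can hold an interval, an error is raised.
#'
#' @param genome a genome tibble.
#' @param length interval width in bp.
#' @param n number of intervals.
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return a sorted BED3 tibble of `n` random intervals.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", size = 10000)
#' bed_random(g, length = 100, n = 5, seed = 42)
#' @export
bed_random <- function(genome, length = 1000, n = 1e6, seed = NULL) {
  usable <- genome[genome$size >= length, , drop = FALSE]
  if (nrow(usable) == 0) {
    abort("`length` exceeds every chromosome size", class = "bedtbl_bad_args")
  }
  if (nrow(usable) < nrow(genome)) {
    warn(paste0(
      nrow(genome) - nrow(usable),
      " chromosome(s) shorter than `length` excluded"
    ), class = "bedtbl_short_chroms")
  }
  with_seed(seed, {
    ci <- sample.int(nrow(usable), n, replace = TRUE, prob = usable$size)
    start <- runif_start(usable$size[ci] - length)
    bed_sort(tibble(
      chrom = usable$chrom[ci],
      start = start,
      end = start + length
    ))
  })
}

# sorted per-chrom exclusion lists for rejection tests
excl_index <- function(excl) {
  if (is.null(excl) || nrow(excl) == 0) {
    return(list())
  }
  excl <- bed_sort(dplyr::ungroup(excl))
  lapply(split(excl[c("start", "end")], excl$chrom), as.list)
}

hits_excl <- function(ex, chrom, start, end) {
  e <- ex[[chrom]]
  if (is.null(e)) {
    return(FALSE)
  }
  any(e$start < end & e$end > start)
}

#' Shuffle interval coordinates against a genome
#'
#' Relocates every row of `x` to a new, uniformly drawn position of the same
#' width. With `within_chrom = TRUE` (default) rows stay on their
#' chromosome; otherwise a chromosome is drawn with probability proportional
#' to its size for each attempt. When `incl` is given, placements are drawn
#' uniformly from within those intervals instead of whole chromosomes.
#' Placements intersecting `excl` are rejected and redrawn, up to
#' `max_tries` per row, after which a named error reports the offending row.
#' Extra columns are carried unchanged, and rows may land on top of each
#' other (placements are independent).
#'
#' @param x an interval tibble.
#' @param genome a genome tibble.
#' @param incl optional interval tibble of allowed placement regions; every
#'   x width must fit inside at least one region.
#' @param excl optional interval tibble of forbidden regions.
#' @param within_chrom keep each row on its original chromosome.
#' @param max_tries rejection-sampling attempts per row.
#' @param seed optional integer seed.
#' @return the shuffled, sorted table; widths and row count conserved.
#' @export
bed_shuffle <- function(x, genome, incl = NULL, excl = NULL,
                        within_chrom = TRUE, max_tries = 1000, seed = NULL) {
  validate_table(x)
  unknown <- setdiff(unique(x$chrom), genome$chrom)
  if (within_chrom && length(unknown) > 0) {
    abort(
      paste0("chromosome(s) not in genome: ", paste(unknown, collapse = ", ")),
      class = "bedtbl_unknown_chrom"
    )
  }
  ex <- excl_index(excl)
  regions <- if (!is.null(incl)) {
    ri <- bed_sort(dplyr::ungroup(incl))[c("chrom", "start", "end")]
    ri
  } else {
    tibble(chrom = genome$chrom, start = 0, end = genome$size)
  }

  with_seed(seed, {
    n <- nrow(x)
    new_start <- numeric(n)
    new_chrom <- character(n)
    widths <- x$end - x$start
    for (i in seq_len(n)) {
      w <- widths[i]
      cand <- if (within_chrom) {
        regions[regions$chrom == x$chrom[i], , drop = FALSE]
      } else {
        regions
      }
      # feasible start positions per candidate region
      slots <- pmax(0, cand$end - cand$start - w + 1)
      if (sum(slots) == 0) {
        abort(
          paste0(
            "row ", i, " (", x$chrom[i], ":", x$start[i], "-", x$end[i],
            "): no region can hold a ", w, " bp interval"
          ),
          class = "bedtbl_shuffle_failed"
        )
      }
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ri <- sample.int(nrow(cand), 1, prob = slots)
        s <- cand$start[ri] + runif_start(slots[ri] - 1)
        if (!hits_excl(ex, cand$chrom[ri], s, s + w)) {
          new_start[i] <- s
          new_chrom[i] <- cand$chrom[ri]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(
          paste0(
            "row ", i, " (", x$chrom[i], ":", x$start[i], "-", x$end[i],
            "): no placement found in ", max_tries, " tries"
          ),
          class = "bedtbl_shuffle_failed"
        )
      }
    }
    out <- dplyr::ungroup(x)
    out$chrom <- new_chrom
    out$start <- new_start
    out$end <- new_start + widths
    bed_sort(restore_groups(out, bt_groups(x)))
  })
}
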