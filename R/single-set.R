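# Single-set interval transformations. All operations respect dplyr
# groupings (per-chromosome is implicit) and return sorted tables.

resolve_sides <- function(both, left, right) {
  if (!is.null(both)) {
    if (!is.null(left) || !is.null(right)) {
      abort("give either `both` or `left`/`right`, not both",
        class = "bedtbl_bad_args"
      )
    }
    left <- both
    right <- both
  } else {
    if (is.null(left) && is.null(right)) {
      abort("one of `both` or `left`/`right` is required", class = "bedtbl_bad_args")
    }
    left <- left %||% 0
    right <- right %||% 0
  }
  if (left < 0 || right < 0) {
    abort("expansion sizes must be non-negative", class = "bedtbl_bad_args")
  }
  list(left = left, right = right)
}

# swap left/right on "-" strand rows; returns per-row left/right vectors
sided_sizes <- function(x, left, right, strand_aware) {
  if (!strand_aware) {
    return(list(left = rep(left, nrow(x)), right = rep(right, nrow(x))))
  }
  if (!"strand" %in% names(x)) {
    abort("`strand_aware` requires a strand column", class = "bedtbl_missing_column")
  }
  neg <- x$strand == "-"
  list(
    left = ifelse(neg, right, left),
    right = ifelse(neg, left, right)
  )
}

drop_zero_width <- function(x, quiet = FALSE) {
  zw <- x$end <= x$start
  if (any(zw) && !quiet) {
    warn(paste0(sum(zw), " zero-width interval(s) dropped"),
      class = "bedtbl_zero_width_dropped"
    )
  }
  x[!zw, , drop = FALSE]
}

#' Expand interval coordinates
#'
#' Widens intervals by `both` bp on each side, or by `left`/`right` bp
#' separately. With `fraction = TRUE` sizes are interpreted as fractions of
#' each interval's width. With `strand_aware = TRUE`, left and right are
#' swapped for `"-"` strand rows. Results are clamped to `[0, size(chrom)]`.
#'
#' @param x an interval tibble.
#' @param genome a genome tibble bounding the expansion.
#' @param both expansion applied to both sides (exclusive with left/right).
#' @param left,right per-side expansions in bp (or width fractions).
#' @param strand_aware swap sides on minus-strand rows.
#' @param fraction interpret sizes as fractions of interval width.
#' @return the expanded, sorted table.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", size = 100)
#' bed_slop(tibble::tibble(chrom = "chr1", start = 2, end = 4), g, both = 5)
#' @export
bed_slop <- function(x, genome, both = NULL, left = NULL, right = NULL,
                     strand_aware = FALSE, fraction = FALSE) {
  sides <- resolve_sides(both, left, right)
  sz <- sided_sizes(x, sides$left, sides$right, strand_aware)
  if (fraction) {
    w <- x$end - x$start
    sz$left <- sz$left * w
    sz$right <- sz$right * w
  }
  x$start <- x$start - sz$left
  x$end <- x$end + sz$right
  x$start <- pmax(x$start, 0)
  res <- bound_intervals(x, genome, trim = TRUE)
  bed_sort(drop_zero_width(res))
}

#' Shift interval coordinates
#'
#' Moves both coordinates by `size` bp (or `size` fractions of each
#' interval's width). With `strand_aware = TRUE`, minus-strand rows shift by
#' `-size`. With `trim = TRUE` out-of-bounds results are clamped to the
#' chromosome (rows collapsing to zero width are dropped with a warning);
#' without it any out-of-bounds row is an error.
#'
#' @inheritParams bed_slop
#' @param size shift in bp (negative allowed), or width fraction.
#' @param trim clamp out-of-bounds results instead of erroring.
#' @return the shifted, sorted table.
#' @export
bed_shift <- function(x, genome, size, fraction = FALSE, trim = FALSE,
                      strand_aware = FALSE) {
  shift <- if (fraction) size * (x$end - x$start) else rep(size, nrow(x))
  if (strand_aware) {
    if (!"strand" %in% names(x)) {
      abort("`strand_aware` requires a strand column", class = "bedtbl_missing_column")
    }
    shift <- ifelse(x$strand == "-", -shift, shift)
  }
  x$start <- x$start + shift
  x$end <- x$end + shift
  sizes <- genome$size[match(x$chrom, genome$chrom)]
  oob <- x$start < 0 | x$end > sizes
  if (!trim && any(oob, na.rm = TRUE)) {
    abort("shifted interval(s) out of genome bounds (use trim = TRUE to clamp)",
      class = "bedtbl_out_of_bounds"
    )
  }
  res <- bound_intervals(x, genome, trim = TRUE)
  bed_sort(drop_zero_width(res))
}

#' Create flanking intervals
#'
#' Emits up to two new intervals abutting each input interval's edges: a
#' left flank ending at `start` and a right flank starting at `end`. Sides
#' follow the same `both`/`left`/`right`, `strand_aware` and `fraction`
#' semantics as [bed_slop()]. Flanks are clamped to the chromosome; flanks
#' clamped to zero width are omitted.
#'
#' @inheritParams bed_slop
#' @return a sorted table of flanking intervals, extra columns carried.
#' @export
bed_flank <- function(x, genome, both = NULL, left = NULL, right = NULL,
                      strand_aware = FALSE, fraction = FALSE) {
  sides <- resolve_sides(both, left, right)
  sz <- sided_sizes(x, sides$left, sides$right, strand_aware)
  if (fraction) {
    w <- x$end - x$start
    sz$left <- sz$left * w
    sz$right <- sz$right * w
  }
  lf <- x
  lf$end <- x$start
  lf$start <- x$start - sz$left
  rf <- x
  rf$start <- x$end
  rf$end <- x$end + sz$right
  res <- dplyr::bind_rows(lf, rf)
  res$start <- pmax(res$start, 0)
  res <- suppressWarnings(bound_intervals(res, genome, trim = TRUE))
  res <- drop_zero_width(res, quiet = TRUE)
  bed_sort(restore_groups(res, bt_groups(x)))
}

#' Merge overlapping intervals
#'
#' Unions intervals whose gap is at most `max_dist` bp within each
#' chromosome/group; book-ended intervals (gap 0) merge at the default
#' `max_dist = 0`. Grouping columns are kept in the output; other extra
#' columns are dropped unless summarised through `aggs` (their values are
#' ill-defined after union). The operation is idempotent.
#'
#' @param x an interval tibble.
#' @param max_dist maximum gap (bp) between intervals to merge.
#' @param aggs aggregation spec: named list of `c(reducer, column)` entries
#'   (or `"reducer:column"` strings) summarising member rows, e.g.
#'   `list(.max = c("max", "value"))`.
#' @return the merged, sorted table.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(1, 10, 100), end = c(50, 75, 120))
#' bed_merge(x)
#' @export
bed_merge <- function(x, max_dist = 0, aggs = NULL) {
  validate_table(x)
  aggs <- normalize_aggs(aggs, names(x))
  res <- partition_map(bed_sort(x), function(df) {
    cid <- cluster_ids(df, max_dist)
    grp_cols <- intersect(bt_groups(x), names(df))
    pieces <- lapply(split(seq_len(nrow(df)), cid), function(i) {
      row <- tibble(
        chrom = df$chrom[1],
        start = min(df$start[i]),
        end = max(df$end[i])
      )
      for (g in grp_cols) row[[g]] <- df[[g]][i[1]]
      if (length(aggs) > 0) {
        row <- dplyr::bind_cols(row, apply_aggs(df[i, , drop = FALSE], aggs))
      }
      row
    })
    dplyr::bind_rows(pieces)
  })
  bed_sort(res)
}

# cluster ids (1..k) for a sorted single-partition table
cluster_ids <- function(df, max_dist) {
  if (nrow(df) <= 1) {
    return(rep(1L, nrow(df)))
  }
  reach <- cummax(df$end)
  cumsum(c(TRUE, df$start[-1] - reach[-nrow(df)] > max_dist))
}

#' Identify (but do not merge) overlapping intervals
#'
#' Adds a `.id` column: rows that [bed_merge()] would union (gap at most
#' `max_dist`) share an id. Ids are consecutive positive integers in sorted
#' order and unique across the whole table.
#'
#' @inheritParams bed_merge
#' @return `x`, sorted, with a `.id` column.
#' @export
bed_cluster <- function(x, max_dist = 0) {
  validate_table(x)
  res <- partition_map(bed_sort(x), function(df) {
    df$.cluster_key <- paste(df$chrom[1], paste(unlist(df[1, bt_groups(x)]), collapse = "\r"),
      cluster_ids(df, max_dist),
      sep = "\r"
    )
    df
  })
  res <- bed_sort(res)
  res$.id <- match(res$.cluster_key, unique(res$.cluster_key))
  res$.cluster_key <- NULL
  res
}

#' Create intervals not covered by a query
#'
#' Returns, per genome chromosome, the gaps in `[0, size)` left uncovered by
#' the merged input. Chromosomes absent from `x` are returned whole;
#' groupings are ignored (coverage is a property of the union).
#'
#' @param x an interval tibble.
#' @param genome a genome tibble.
#' @return a sorted BED3 table of uncovered intervals.
#' @export
bed_complement <- function(x, genome) {
  merged <- bed_merge(dplyr::ungroup(x)[c("chrom", "start", "end")])
  merged <- suppressWarnings(bound_intervals(merged, genome, trim = TRUE))
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    size <- genome$size[i]
    m <- merged[merged$chrom == chrom, , drop = FALSE]
    edges_start <- c(0, m$end)
    edges_end <- c(m$start, size)
    keep <- edges_end > edges_start
    tibble(chrom = chrom, start = edges_start[keep], end = edges_end[keep])
  })
  bed_sort(dplyr::bind_rows(pieces))
}

#' Subdivide intervals into windows
#'
#' Splits each interval into consecutive windows. In `win_size` mode, full
#' windows of `win_size` bp are emitted with any remainder as a final
#' shorter window. In `num_win` mode, the interval is cut into that many
#' windows with sizes as equal as possible, larger-by-1 windows first. A
#' `.win_id` column numbers windows 1..k per parent (descending when
#' `reverse = TRUE`, as needed for minus-strand features); all parent
#' columns are carried through.
#'
#' @param x an interval tibble.
#' @param genome accepted for interface compatibility; windowing needs no
#'   genome bounds (inputs are assumed already bounded).
#' @param win_size window width in bp (>= 1); exclusive with `num_win`.
#' @param num_win number of windows per interval; exclusive with `win_size`.
#' @param reverse number windows in descending order.
#' @return a sorted window table.
#' @export
bed_makewindows <- function(x, genome = NULL, win_size = NULL, num_win = NULL,
                            reverse = FALSE) {
  if (is.null(win_size) == is.null(num_win)) {
    abort("exactly one of `win_size` or `num_win` is required",
      class = "bedtbl_bad_args"
    )
  }
  if (!is.null(win_size) && win_size < 1) {
    abort("`win_size` must be >= 1", class = "bedtbl_bad_args")
  }
  x <- bed_sort(validate_table(x))
  widths <- x$end - x$start
  if (!is.null(num_win) && any(num_win > widths)) {
    abort("`num_win` exceeds interval width", class = "bedtbl_bad_args")
  }
  sizes_per_row <- lapply(seq_len(nrow(x)), function(i) {
    w <- widths[i]
    if (!is.null(win_size)) {
      k <- w %/% win_size
      sizes <- rep(win_size, k)
      if (w %% win_size > 0) sizes <- c(sizes, w %% win_size)
    } else {
      base <- w %/% num_win
      rem <- w %% num_win
      sizes <- c(rep(base + 1, rem), rep(base, num_win - rem))
    }
    sizes
  })
  k <- lengths(sizes_per_row)
  parent <- rep(seq_len(nrow(x)), k)
  offsets <- unlist(lapply(sizes_per_row, function(s) cumsum(c(0, s[-length(s)]))))
  out <- dplyr::ungroup(x)[parent, , drop = FALSE]
  out$start <- x$start[parent] + offsets
  out$end <- out$start + unlist(sizes_per_row)
  out$.win_id <- unlist(lapply(k, function(n) if (reverse) rev(seq_len(n)) else seq_len(n)))
  bed_sort(restore_groups(out, bt_groups(x)))
}

#' Expand BED12 blocks to BED6 exons
#'
#' Emits one BED6 row per block at the block's genomic coordinates. The
#' `score` column carries the exon rank numbered 5' to 3' (so ranks run
#' descending along the genome for `"-"` strand transcripts); `name` and
#' `strand` are carried through.
#'
#' @param x a BED12 interval tibble (from [read_bed()] with 12 fields).
#' @return a sorted BED6 table of exons.
#' @export
bed12_to_exons <- function(x) {
  needed <- c("blockCount", "blockSizes", "blockStarts", "name", "strand")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("not a BED12 table; missing: ", paste(missing_cols, collapse = ", ")),
      class = "bedtbl_missing_column"
    )
  }
  x <- bed_sort(validate_table(x))
  sizes <- lapply(strsplit(as.character(x$blockSizes), ","), as.integer)
  starts <- lapply(strsplit(as.character(x$blockStarts), ","), as.integer)
  if (any(lengths(sizes) != x$blockCount) || any(lengths(starts) != x$blockCount)) {
    abort("blockSizes/blockStarts lengths disagree with blockCount",
      class = "bedtbl_bad_blocks"
    )
  }
  k <- x$blockCount
  parent <- rep(seq_len(nrow(x)), k)
  bstart <- unlist(starts)
  bsize <- unlist(sizes)
  rank <- unlist(lapply(seq_len(nrow(x)), function(i) {
    if (x$strand[i] == "-") rev(seq_len(k[i])) else seq_len(k[i])
  }))
  out <- tibble(
    chrom = x$chrom[parent],
    start = x$start[parent] + bstart,
    end = x$start[parent] + bstart + bsize,
    name = x$name[parent],
    score = rank,
    strand = x$strand[parent]
  )
  bed_sort(out)
}
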