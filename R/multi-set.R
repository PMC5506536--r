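# Two-set interval operations, built on the overlap engine. x and y must
# carry identical grouping columns (if any); pairs are only formed within
# matching chromosome + group partitions.

#' Report intersecting intervals from two tables
#'
#' By default returns one row per overlapping (x, y) pair with columns
#' present in both inputs suffixed and the intersection width in `.overlap`
#' (see [overlap_join()]). With `invert = TRUE` returns instead the x rows
#' with no overlapping y, keeping x's schema.
#'
#' @param x,y interval tibbles with identical grouping columns (if any).
#' @param invert return non-overlapping x rows instead of pairs.
#' @param suffixes length-2 character vector disambiguating shared columns.
#' @return pair rows, or x rows when `invert = TRUE`; sorted.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(25, 100), end = c(50, 125))
#' y <- tibble::tibble(chrom = "chr1", start = 30, end = 75)
#' bed_intersect(x, y)
#' @export
bed_intersect <- function(x, y, invert = FALSE, suffixes = c(".x", ".y")) {
  if (suffixes[1] == suffixes[2]) {
    abort("suffixes must differ", class = "bedtbl_bad_args")
  }
  idx <- overlap_join_idx(x, y)
  if (invert) {
    keep <- setdiff(seq_len(nrow(idx$x)), unique(idx$xi))
    return(idx$x[sort(keep), , drop = FALSE])
  }
  restore_groups(build_pairs(idx$x, idx$y, idx$xi, idx$yi, suffixes), bt_groups(x))
}

#' Apply summary functions over overlapping intervals
#'
#' Appends one column per aggregation entry to `x`, computed over the y rows
#' overlapping each x row. x rows with no overlapping y get `NA` (not 0);
#' the x row count and order are preserved.
#'
#' @inheritParams bed_intersect
#' @param aggs named list of `c(reducer, column)` entries (or
#'   `"reducer:column"` strings) whose source columns live in `y`, e.g.
#'   `list(win_sum = c("sum", "value"))`.
#' @return `x`, sorted, with aggregate columns appended.
#' @export
bed_map <- function(x, y, aggs) {
  aggs <- normalize_aggs(aggs, names(y))
  clash <- intersect(names(aggs), names(x))
  if (length(clash) > 0) {
    abort(
      paste0("agg output name collides with x column: ", paste(clash, collapse = ", ")),
      class = "bedtbl_agg_name_collision"
    )
  }
  idx <- overlap_join_idx(x, y)
  out <- idx$x
  hit_rows <- split(idx$yi, idx$xi)
  agg_rows <- lapply(hit_rows, function(yi) {
    apply_aggs(dplyr::ungroup(idx$y)[yi, , drop = FALSE], aggs)
  })
  agg_tbl <- dplyr::bind_rows(agg_rows)
  xi <- as.integer(names(hit_rows))
  for (nm in names(aggs)) {
    col <- rep(NA, nrow(out))
    if (nrow(agg_tbl) > 0) {
      col[xi] <- agg_tbl[[nm]]
    }
    out[[nm]] <- col
  }
  out
}

#' Remove interval regions based on overlaps
#'
#' With `any = FALSE` (default), each x row is replaced by the parts of it
#' not covered by the merged y intervals of its partition: an x row fully
#' covered vanishes, a row pierced in the middle yields two rows, and extra
#' columns are duplicated onto every fragment. With `any = TRUE`, x rows
#' touching any y are dropped entirely.
#'
#' @inheritParams bed_intersect
#' @param any drop whole x rows on any overlap instead of trimming.
#' @return the subtracted, sorted table with x's schema.
#' @export
bed_subtract <- function(x, y, any = FALSE) {
  ym <- bed_merge(dplyr::ungroup(y)[, c("chrom", "start", "end", bt_groups(y))])
  ym <- restore_groups(ym, bt_groups(y))
  idx <- overlap_join_idx(x, ym)
  if (any) {
    keep <- setdiff(seq_len(nrow(idx$x)), unique(idx$xi))
    return(idx$x[sort(keep), , drop = FALSE])
  }
  xs <- idx$x
  untouched <- setdiff(seq_len(nrow(xs)), unique(idx$xi))
  pieces <- list(dplyr::ungroup(xs)[untouched, , drop = FALSE])
  if (length(idx$xi) > 0) {
    per_x <- split(idx$yi, idx$xi)
    frag <- lapply(names(per_x), function(key) {
      i <- as.integer(key)
      cover <- dplyr::ungroup(idx$y)[sort(per_x[[key]]), c("start", "end")]
      cur <- xs$start[i]
      fs <- numeric()
      fe <- numeric()
      for (j in seq_len(nrow(cover))) {
        if (cover$start[j] > cur) {
          fs <- c(fs, cur)
          fe <- c(fe, min(cover$start[j], xs$end[i]))
        }
        cur <- max(cur, cover$end[j])
        if (cur >= xs$end[i]) break
      }
      if (cur < xs$end[i]) {
        fs <- c(fs, cur)
        fe <- c(fe, xs$end[i])
      }
      if (length(fs) == 0) {
        return(NULL)
      }
      row <- dplyr::ungroup(xs)[rep(i, length(fs)), , drop = FALSE]
      row$start <- fs
      row$end <- fe
      row
    })
    pieces <- c(pieces, frag)
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- dplyr::ungroup(xs)[integer(), , drop = FALSE]
  }
  bed_sort(restore_groups(out, bt_groups(x)))
}

#' Find overlaps within a search window
#'
#' Reports (x, y) pairs whose members come within `win` bp of each other:
#' equivalent to intersecting `x` expanded by `win` on both sides against
#' `y`, but the pairs report x's original coordinates (the window is a
#' search radius, not a transformation). `.overlap` reflects the windowed
#' intersection. `win = 0` is identical to [bed_intersect()].
#'
#' @inheritParams bed_intersect
#' @param genome a genome tibble bounding the expansion.
#' @param win search radius in bp (>= 0).
#' @return suffixed pair rows with original x coordinates; sorted.
#' @export
bed_window <- function(x, y, genome, win, suffixes = c(".x", ".y")) {
  if (win < 0) {
    abort("`win` must be >= 0", class = "bedtbl_bad_args")
  }
  xx <- dplyr::mutate(x, .orig_start = .data$start, .orig_end = .data$end)
  xx <- bed_slop(xx, genome, both = win)
  res <- bed_intersect(xx, y, suffixes = suffixes)
  sx <- paste0("start", suffixes[1])
  ex <- paste0("end", suffixes[1])
  res[[sx]] <- res$.orig_start
  res[[ex]] <- res$.orig_end
  res$.orig_start <- NULL
  res$.orig_end <- NULL
  res
}

#' Find the closest intervals independent of overlaps
#'
#' For each x row, reports the y rows of its partition at minimal absolute
#' distance as suffixed pairs with `.overlap` and a signed `.dist`
#' (negative = upstream; book-ended neighbours are +/-1; overlap is 0 and
#' dominates). Ties produce multiple rows; x rows with no y in their
#' partition are omitted. See [nearest_join()] for the exact convention.
#'
#' @inheritParams bed_intersect
#' @return suffixed pair rows with `.overlap` and `.dist`; sorted by x.
#' @export
bed_closest <- function(x, y, suffixes = c(".x", ".y")) {
  restore_groups(nearest_join(x, y, suffixes), bt_groups(x))
}
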