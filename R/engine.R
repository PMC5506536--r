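# Overlap engine: indexed pair queries between two interval tables.
#
# Per (chrom x group-values) partition, y is held sorted by start; candidate
# overlaps for a query [xs, xe) are located by binary search on the sorted
# starts (all y with start < xe), then filtered by end > xs. Coordinates are
# half-open, so book-ended pairs (end.x == start.y) never overlap.

# pair keys: chrom plus grouping columns shared by both tables
join_keys <- function(x, y) {
  gx <- bt_groups(x)
  gy <- bt_groups(y)
  if (!setequal(gx, gy)) {
    abort(
      paste0(
        "incompatible grouping columns: x grouped by {",
        paste(gx, collapse = ", "), "}, y by {", paste(gy, collapse = ", "), "}"
      ),
      class = "bedtbl_incompatible_groups"
    )
  }
  c("chrom", gx)
}

# index rows of a table by partition key string
partition_index <- function(x, keys) {
  key_str <- do.call(paste, c(unname(as.list(dplyr::ungroup(x)[keys])), sep = "\r"))
  split(seq_len(nrow(x)), key_str)
}

# suffix columns present in both tables; chrom is never suffixed
suffix_pair_columns <- function(x, y, suffixes = c(".x", ".y")) {
  xn <- setdiff(names(x), "chrom")
  yn <- setdiff(names(y), "chrom")
  shared <- intersect(xn, yn)
  list(
    x = ifelse(xn %in% shared, paste0(xn, suffixes[1]), xn),
    y = ifelse(yn %in% shared, paste0(yn, suffixes[2]), yn)
  )
}

# assemble suffixed pair rows from row indices into x and y
build_pairs <- function(x, y, xi, yi, suffixes = c(".x", ".y")) {
  x <- dplyr::ungroup(x)
  y <- dplyr::ungroup(y)
  sfx <- suffix_pair_columns(x, y, suffixes)
  out <- x[xi, "chrom", drop = FALSE]
  xpart <- x[xi, setdiff(names(x), "chrom"), drop = FALSE]
  names(xpart) <- sfx$x
  ypart <- y[yi, setdiff(names(y), "chrom"), drop = FALSE]
  names(ypart) <- sfx$y
  out <- dplyr::bind_cols(out, xpart, ypart)
  sx <- x$start[xi]
  ex <- x$end[xi]
  sy <- y$start[yi]
  ey <- y$end[yi]
  out$.overlap <- as.integer(pmax(0, pmin(ex, ey) - pmax(sx, sy)))
  out
}

# overlapping (x-row, y-row) index pairs within one partition; x/y index
# vectors refer to the full tables and must already be in sorted order
partition_overlap_pairs <- function(x, y, ix, iy) {
  if (length(ix) == 0 || length(iy) == 0) {
    return(list(xi = integer(), yi = integer()))
  }
  xs <- x$start[ix]
  xe <- x$end[ix]
  ys <- y$start[iy]
  ye <- y$end[iy]
  hi <- findInterval(xe - 1, ys) # count of y with start < end.x
  xi <- rep(seq_along(ix), hi)
  yj <- sequence(hi)
  keep <- ye[yj] > xs[xi]
  list(xi = ix[xi[keep]], yi = iy[yj[keep]])
}

#' Join two interval tables on strict overlap
#'
#' Returns one row per strictly-overlapping (x, y) pair within matching
#' chromosome (and grouping) partitions. Columns present in both inputs are
#' disambiguated with `.x`/`.y` suffixes (never `chrom`); `.overlap` gives
#' the intersection width in bp. Book-ended pairs, where one interval ends
#' exactly where the other starts, are not overlaps under half-open
#' coordinates and are not returned.
#'
#' @param x,y interval tibbles with identical grouping columns (if any).
#' @param suffixes length-2 character vector of column suffixes.
#' @return a tibble of suffixed pair rows ordered by x sort order then y
#'   sort order.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' y <- tibble::tibble(chrom = "chr1", start = 5, end = 15)
#' overlap_join(x, y)
#' @export
overlap_join <- function(x, y, suffixes = c(".x", ".y")) {
  idx <- overlap_join_idx(x, y)
  build_pairs(idx$x, idx$y, idx$xi, idx$yi, suffixes)
}

# sorted tables plus overlapping row-index pairs, ordered by x then y
overlap_join_idx <- function(x, y) {
  keys <- join_keys(x, y)
  x <- bed_sort(validate_table(x))
  y <- bed_sort(validate_table(y))
  px <- partition_index(x, keys)
  py <- partition_index(y, keys)
  parts <- lapply(names(px), function(k) {
    partition_overlap_pairs(x, y, px[[k]], py[[k]] %||% integer())
  })
  xi <- unlist(lapply(parts, `[[`, "xi"))
  yi <- unlist(lapply(parts, `[[`, "yi"))
  if (is.null(xi)) {
    xi <- integer()
    yi <- integer()
  }
  ord <- order(xi, yi)
  list(x = x, y = y, xi = xi[ord], yi = yi[ord])
}

#' Find nearest neighbours between two interval tables
#'
#' For every x row, reports all y rows of its partition at minimal absolute
#' distance; overlapping y rows count as distance 0 and take precedence over
#' any non-overlapping neighbour. Ties are all reported. x rows whose
#' partition contains no y are omitted.
#'
#' Distance sign convention: overlap is 0; a y downstream of x gets
#' `start.y - end.x + 1` (so a book-ended downstream neighbour is +1); a y
#' upstream gets `end.y - start.x - 1` (book-ended upstream is -1). Negative
#' distances therefore denote upstream neighbours.
#'
#' @inheritParams overlap_join
#' @return a tibble of suffixed pair rows with `.overlap` and `.dist`.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' y <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
#' nearest_join(x, y) # book-ended: .dist is +1
#' @export
nearest_join <- function(x, y, suffixes = c(".x", ".y")) {
  keys <- join_keys(x, y)
  x <- bed_sort(validate_table(x))
  y <- bed_sort(validate_table(y))
  px <- partition_index(x, keys)
  py <- partition_index(y, keys)

  all_xi <- integer()
  all_yi <- integer()
  all_d <- integer()
  for (k in names(px)) {
    ix <- px[[k]]
    iy <- py[[k]] %||% integer()
    if (length(iy) == 0) next
    ys <- y$start[iy]
    ye <- y$end[iy]
    ye_ord <- order(ye, method = "radix")
    ye_sorted <- ye[ye_ord]

    ovl <- partition_overlap_pairs(x, y, ix, iy)
    has_ovl <- ix %in% ovl$xi
    if (length(ovl$xi) > 0) {
      all_xi <- c(all_xi, ovl$xi)
      all_yi <- c(all_yi, ovl$yi)
      all_d <- c(all_d, rep(0L, length(ovl$xi)))
    }
    for (i in ix[!has_ovl]) {
      xs_i <- x$start[i]
      xe_i <- x$end[i]
      pos <- findInterval(xe_i - 1, ys) + 1L # first y with start >= end.x
      d_down <- if (pos <= length(ys)) ys[pos] - xe_i + 1L else NA_integer_
      idx <- findInterval(xs_i, ye_sorted) # last y with end <= start.x
      d_up <- if (idx >= 1) ye_sorted[idx] - xs_i - 1L else NA_integer_
      best <- min(abs(c(d_down, d_up)), na.rm = TRUE)
      if (!is.na(d_down) && d_down == best) {
        hit <- which(ys == ys[pos])
        all_xi <- c(all_xi, rep(i, length(hit)))
        all_yi <- c(all_yi, iy[hit])
        all_d <- c(all_d, rep(as.integer(d_down), length(hit)))
      }
      if (!is.na(d_up) && -d_up == best) {
        hit <- which(ye == ye_sorted[idx])
        all_xi <- c(all_xi, rep(i, length(hit)))
        all_yi <- c(all_yi, iy[hit])
        all_d <- c(all_d, rep(as.integer(d_up), length(hit)))
      }
    }
  }
  ord <- order(all_xi, all_yi)
  out <- build_pairs(x, y, all_xi[ord], all_yi[ord], suffixes)
  out$.dist <- all_d[ord]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
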