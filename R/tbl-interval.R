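#' Validate an interval table
#'
#' Checks the interval-table contract: `chrom`, `start` and `end` columns are
#' present, coordinates are non-negative numbers with `end >= start`
#' (half-open, so a zero-width row is flagged with a warning but kept), any
#' `strand` column only contains `"+"`, `"-"` or `"."`, and every grouping
#' column exists in the table. Each violation raises a distinct condition
#' class so callers can handle them individually.
#'
#' @param x an interval tibble.
#' @return `x`, unchanged, invisibly classified as valid.
#'
#' @examples
#' validate_table(tibble::tibble(chrom = "chr1", start = 1, end = 10))
#' @export
validate_table <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame of intervals", class = "bedtbl_not_table")
  }
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "bedtbl_missing_column"
    )
  }
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort("`start` and `end` must be numeric", class = "bedtbl_bad_coord_type")
  }
  if (any(x$start < 0, na.rm = TRUE)) {
    abort("negative `start` coordinate", class = "bedtbl_negative_start")
  }
  if (any(x$end < x$start, na.rm = TRUE)) {
    abort("`start` greater than `end`", class = "bedtbl_start_gt_end")
  }
  if (any(x$end == x$start, na.rm = TRUE)) {
    warn("zero-width interval(s) present", class = "bedtbl_zero_width")
  }
  if ("strand" %in% names(x)) {
    bad <- setdiff(unique(x$strand), c("+", "-", "."))
    if (length(bad) > 0) {
      abort(
        paste0("invalid strand value(s): ", paste(bad, collapse = ", ")),
        class = "bedtbl_bad_strand"
      )
    }
  }
  grp <- dplyr::group_vars(x)
  lost <- setdiff(grp, names(x))
  if (length(lost) > 0) {
    abort(
      paste0("grouping column(s) absent: ", paste(lost, collapse = ", ")),
      class = "bedtbl_missing_group_column"
    )
  }
  x
}

#' Group an interval table
#'
#' Attaches a grouping specification to the table. Single-set operations then
#' run per chromosome and per group value; two-set operations only pair rows
#' whose shared grouping-column values agree. `chrom` is an implicit grouping
#' in every operation and may not be named explicitly; neither may `start` or
#' `end`.
#'
#' @param x an interval tibble.
#' @param columns character vector of column names (e.g. `"strand"`); empty
#'   vector removes all groupings.
#' @return `x` grouped by `columns`.
#'
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 1, end = 10, strand = "+")
#' group_table(x, "strand")
#' @export
group_table <- function(x, columns = character()) {
  if (anyDuplicated(columns)) {
    abort("duplicate grouping columns", class = "bedtbl_bad_group_spec")
  }
  if (any(columns %in% c("chrom", "start", "end"))) {
    abort("chrom/start/end cannot be grouping columns",
      class = "bedtbl_bad_group_spec"
    )
  }
  unknown <- setdiff(columns, names(x))
  if (length(unknown) > 0) {
    abort(
      paste0("unknown grouping column(s): ", paste(unknown, collapse = ", ")),
      class = "bedtbl_unknown_column"
    )
  }
  if (length(columns) == 0) {
    return(dplyr::ungroup(x))
  }
  dplyr::group_by(dplyr::ungroup(x), dplyr::across(dplyr::all_of(columns)))
}

#' Flip strands
#'
#' Swaps `"+"` and `"-"` strand values; `"."` (unstranded) rows are left
#' unchanged, as are all other columns. Applying the function twice returns
#' the original table.
#'
#' @param x an interval tibble with a `strand` column.
#' @return `x` with strands flipped.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 1, end = 10, strand = "+")
#' flip_strands(x)
#' @export
flip_strands <- function(x) {
  if (!"strand" %in% names(x)) {
    abort("`x` has no strand column", class = "bedtbl_missing_column")
  }
  dplyr::mutate(x, strand = dplyr::case_match(
    .data$strand,
    "+" ~ "-",
    "-" ~ "+",
    .default = .data$strand
  ))
}

#' Constrain intervals to a genome
#'
#' With `trim = TRUE`, coordinates are clamped into `[0, size(chrom)]`; with
#' `trim = FALSE`, rows not fully inside their chromosome are dropped. Rows on
#' chromosomes absent from `genome` are always dropped, with a warning
#' reporting the count.
#'
#' @param x an interval tibble.
#' @param genome a genome tibble from [read_genome()].
#' @param trim clamp out-of-bounds coordinates rather than dropping rows.
#' @return the bounded table, sorted.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", size = 100)
#' bound_intervals(tibble::tibble(chrom = "chr1", start = 90, end = 110), g, trim = TRUE)
#' @export
bound_intervals <- function(x, genome, trim = FALSE) {
  sizes <- genome$size[match(x$chrom, genome$chrom)]
  unknown <- is.na(sizes)
  if (any(unknown)) {
    warn(paste0(sum(unknown), " interval(s) dropped: chromosome not in genome"),
      class = "bedtbl_unknown_chrom"
    )
    x <- x[!unknown, , drop = FALSE]
    sizes <- sizes[!unknown]
  }
  if (trim) {
    x$start <- pmax(x$start, 0)
    x$end <- pmin(x$end, sizes)
    x$start <- pmin(x$start, x$end)
  } else {
    keep <- x$start >= 0 & x$end <= sizes
    x <- x[keep, , drop = FALSE]
  }
  bed_sort(x)
}

#' Spacing between adjacent intervals
#'
#' Adds a `.spacing` column: the gap between each interval's `start` and the
#' `end` of the previous interval on the same chromosome (and group), in
#' sorted order. The first interval per chromosome/group gets `NA`;
#' overlapping neighbours yield negative spacings.
#'
#' @param x an interval tibble.
#' @return `x`, sorted, with a `.spacing` column.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(1, 20), end = c(10, 30))
#' interval_spacing(x)
#' @export
interval_spacing <- function(x) {
  res <- partition_map(bed_sort(x), function(df) {
    df$.spacing <- c(NA_real_, df$start[-1] - df$end[-nrow(df)])
    df
  })
  bed_sort(res)
}

# --- internal helpers -------------------------------------------------------

# stable sort by (chrom bytewise, start, end); grouping preserved
bed_sort <- function(x) {
  ord <- order(x$chrom, x$start, x$end, method = "radix")
  x[ord, , drop = FALSE]
}

# grouping columns beyond the implicit chrom
bt_groups <- function(x) {
  setdiff(dplyr::group_vars(x), "chrom")
}

# apply f to each (chrom x group-values) partition, then bind preserving the
# original grouping; f receives a plain tibble
partition_map <- function(x, f) {
  grp <- bt_groups(x)
  if (nrow(x) == 0) {
    return(x)
  }
  keys <- c("chrom", grp)
  ux <- dplyr::ungroup(x)
  idx <- split(seq_len(nrow(ux)), ux[keys], drop = TRUE, lex.order = TRUE)
  parts <- lapply(idx, function(i) f(ux[i, , drop = FALSE]))
  out <- dplyr::bind_rows(parts)
  restore_groups(out, grp)
}

restore_groups <- function(x, grp) {
  grp <- intersect(grp, names(x))
  if (length(grp) == 0) {
    return(dplyr::ungroup(x))
  }
  dplyr::group_by(dplyr::ungroup(x), dplyr::across(dplyr::all_of(grp)))
}

# total covered bp, assuming rows within a partition may overlap -> merge first
interval_bp <- function(x) {
  if (nrow(x) == 0) {
    return(0)
  }
  sum(x$end - x$start)
}
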