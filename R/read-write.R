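# Format dialects: ordered column names and readr types. BED scores stay
# character (UCSC allows non-numeric scores); coordinates are integers.
bt_dialects <- list(
  bed3 = list(
    names = c("chrom", "start", "end"),
    types = "cii"
  ),
  bed6 = list(
    names = c("chrom", "start", "end", "name", "score", "strand"),
    types = "ciiccc"
  ),
  bed12 = list(
    names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "thickStart", "thickEnd", "itemRgb",
      "blockCount", "blockSizes", "blockStarts"
    ),
    types = "ciiccciicicc"
  ),
  bedgraph = list(
    names = c("chrom", "start", "end", "value"),
    types = "ciid"
  ),
  narrowpeak = list(
    names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "signalValue", "pValue", "qValue", "peak"
    ),
    types = "ciicccdddi"
  ),
  broadpeak = list(
    names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "signalValue", "pValue", "qValue"
    ),
    types = "ciicccddd"
  ),
  genome = list(
    names = c("chrom", "size"),
    types = "ci"
  )
)

# Read lines from a path, URL or connection; gzip detected by magic bytes,
# never by extension.
read_source_lines <- function(source) {
  if (inherits(source, "connection")) {
    return(readLines(source, warn = FALSE))
  }
  if (!is.character(source) || length(source) != 1) {
    abort("`source` must be a single path, URL or connection",
      class = "bedtbl_bad_source"
    )
  }
  if (grepl("^(https?|ftp)://", source)) {
    con <- gzcon(url(source, open = "rb"))
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (!file.exists(source)) {
    abort(paste0("file not found: ", source), class = "bedtbl_file_not_found")
  }
  magic <- readBin(source, "raw", n = 2)
  con <- if (length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(source, open = "rt")
  } else {
    file(source, open = "rt")
  }
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

drop_header_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  lines[!grepl("^(#|track\\b|browser\\b)", lines)]
}

parse_dialect_lines <- function(lines, dialect) {
  d <- bt_dialects[[dialect]]
  if (length(lines) == 0) {
    out <- readr::read_tsv(I(""),
      col_names = d$names,
      col_types = d$types, progress = FALSE
    )
    return(as_tibble(out))
  }
  counts <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(counts != length(d$names))) {
    bad <- which(counts != length(d$names))[1]
    abort(
      paste0(
        dialect, " needs ", length(d$names), " fields, line ", bad,
        " has ", counts[bad]
      ),
      class = "bedtbl_parse_error"
    )
  }
  # parsing issues surface through problems() as typed errors, not warnings
  out <- suppressWarnings(readr::read_tsv(
    I(paste0(paste(lines, collapse = "\n"), "\n")),
    col_names = d$names, col_types = d$types, na = character(),
    progress = FALSE
  ))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(
      paste0(
        "malformed input for ", dialect, " (first problem, line ",
        probs$row[1], "): ", probs$expected[1], " / got ", probs$actual[1]
      ),
      class = "bedtbl_parse_error"
    )
  }
  as_tibble(out)
}

#' Read a BED file
#'
#' Reads BED3, BED6 or BED12 into an interval tibble with standard column
#' names. Lines starting with `#`, `track` or `browser` are skipped. Input
#' may be a local path, a URL, or a connection; gzip compression is detected
#' from the file content. With `n_fields = NULL` the field count is inferred
#' from the first data line.
#'
#' @param source path, URL or connection.
#' @param n_fields 3, 6, 12, or `NULL` to infer.
#' @return a sorted interval tibble.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t11873\t14409", f)
#' read_bed(f)
#' @export
read_bed <- function(source, n_fields = NULL) {
  lines <- drop_header_lines(read_source_lines(source))
  nf <- if (length(lines) == 0) {
    if (is.null(n_fields)) 3L else n_fields
  } else if (is.null(n_fields)) {
    length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  } else {
    n_fields
  }
  dialect <- switch(as.character(nf),
    "3" = "bed3",
    "6" = "bed6",
    "12" = "bed12",
    abort(paste0("unsupported BED field count: ", nf), class = "bedtbl_bad_dialect")
  )
  out <- parse_dialect_lines(lines, dialect)
  bed_sort(validate_table(out))
}

#' Read a chrom.sizes (genome) file
#'
#' @param source path, URL or connection to a two-column tab-delimited file
#'   of chromosome names and sizes.
#' @return a tibble with `chrom` and `size` columns, sorted by chromosome.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1000", f)
#' read_genome(f)
#' @export
read_genome <- function(source) {
  lines <- drop_header_lines(read_source_lines(source))
  out <- parse_dialect_lines(lines, "genome")
  if (anyDuplicated(out$chrom)) {
    abort("duplicate chromosome in genome file", class = "bedtbl_duplicate_chrom")
  }
  if (any(out$size <= 0)) {
    abort("non-positive chromosome size", class = "bedtbl_bad_genome_size")
  }
  out[order(out$chrom, method = "radix"), , drop = FALSE]
}

#' Read a bedGraph file
#'
#' @param source path, URL or connection; four tab-delimited columns with a
#'   numeric signal value (scientific notation accepted).
#' @return a sorted interval tibble with a double `value` column.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t0\t10\t2.5", f)
#' read_bedgraph(f)
#' @export
read_bedgraph <- function(source) {
  lines <- drop_header_lines(read_source_lines(source))
  out <- parse_dialect_lines(lines, "bedgraph")
  bed_sort(validate_table(out))
}

#' Read ENCODE peak files
#'
#' narrowPeak files carry 10 columns (BED6 plus `signalValue`, `pValue`,
#' `qValue` and the `peak` summit offset); broadPeak files carry 9 (no
#' summit). `"."` placeholders in the statistics columns become `NA`.
#'
#' @param source path, URL or connection.
#' @param flavor `"narrow"` or `"broad"`.
#' @return a sorted interval tibble with dialect column names.
#' @export
read_peak <- function(source, flavor = c("narrow", "broad")) {
  flavor <- match.arg(flavor)
  dialect <- if (flavor == "narrow") "narrowpeak" else "broadpeak"
  d <- bt_dialects[[dialect]]
  lines <- drop_header_lines(read_source_lines(source))
  if (length(lines) > 0) {
    nf <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    if (nf != length(d$names)) {
      abort(
        paste0(
          flavor, "Peak requires ", length(d$names), " columns, found ", nf
        ),
        class = "bedtbl_bad_dialect"
      )
    }
  }
  # read everything as character first: "." is a numeric placeholder in the
  # statistics columns but a legitimate strand value
  raw <- suppressWarnings(readr::read_tsv(
    I(if (length(lines) == 0) "" else paste0(paste(lines, collapse = "\n"), "\n")),
    col_names = d$names,
    col_types = paste(rep("c", length(d$names)), collapse = ""),
    na = character(), progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed ", flavor, "Peak input at line ", probs$row[1]),
      class = "bedtbl_parse_error"
    )
  }
  types <- strsplit(d$types, "")[[1]]
  for (j in seq_along(types)) {
    if (types[j] == "c") next
    val <- raw[[j]]
    val[val == "."] <- NA_character_
    conv <- suppressWarnings(
      if (types[j] == "i") as.integer(val) else as.numeric(val)
    )
    if (any(is.na(conv) & !is.na(val))) {
      abort(paste0("non-numeric value in column ", d$names[j]),
        class = "bedtbl_parse_error"
      )
    }
    raw[[j]] <- conv
  }
  bed_sort(validate_table(as_tibble(raw)))
}

#' @rdname read_peak
#' @export
read_narrowpeak <- function(source) read_peak(source, "narrow")

#' @rdname read_peak
#' @export
read_broadpeak <- function(source) read_peak(source, "broad")

#' Read VCF records as intervals
#'
#' Consumes only the coordinate-bearing fields of a VCF: each record becomes
#' one interval with `start = POS - 1` and `end = start + nchar(REF)`
#' (converting 1-based inclusive VCF positions to 0-based half-open
#' coordinates). `ID`, `REF` and `ALT` are carried as extra columns.
#'
#' @param source path, URL or connection to VCF text.
#' @return a sorted interval tibble.
#' @export
read_vcf_intervals <- function(source) {
  lines <- read_source_lines(source)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      ID = character(), REF = character(), ALT = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5)) {
    abort("malformed VCF record: fewer than 5 fields", class = "bedtbl_parse_error")
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  if (anyNA(pos)) {
    abort("malformed VCF record: non-integer POS", class = "bedtbl_parse_error")
  }
  ref <- vapply(fields, `[[`, "", 4)
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = pos - 1L,
    end = pos - 1L + nchar(ref),
    ID = vapply(fields, `[[`, "", 3),
    REF = ref,
    ALT = vapply(fields, `[[`, "", 5)
  )
  bed_sort(validate_table(out))
}

#' Write an interval table as tab-delimited text
#'
#' Writes the dialect's columns in order, coordinates as integers, missing
#' optional values as `"."`, one newline-terminated record per row. Output
#' round-trips bit-exactly through the matching reader.
#'
#' @param x an interval tibble whose schema covers the dialect's columns.
#' @param sink output path or connection.
#' @param dialect one of `"bed3"`, `"bed6"`, `"bed12"`, `"bedgraph"`,
#'   `"narrowpeak"`, `"broadpeak"`, `"genome"`.
#' @return `sink`, invisibly.
#' @export
write_table <- function(x, sink, dialect = "bed3") {
  if (!dialect %in% names(bt_dialects)) {
    abort(paste0("unknown dialect: ", dialect), class = "bedtbl_bad_dialect")
  }
  d <- bt_dialects[[dialect]]
  missing_cols <- setdiff(d$names, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "table lacks ", dialect, " column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "bedtbl_dialect_mismatch"
    )
  }
  out <- dplyr::ungroup(x)[, d$names, drop = FALSE]
  int_cols <- d$names[strsplit(d$types, "")[[1]] == "i"]
  for (col in int_cols) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_tsv(out, sink, na = ".", col_names = FALSE, progress = FALSE)
  invisible(sink)
}
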