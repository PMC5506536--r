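# Aggregation specifications for bed_map() and bed_merge().
#
# An agg spec is a named list: output column name -> (reducer, source column).
# Entries may be written as c("sum", "value") or compactly as "sum:value".
# `count` needs no source column; `concat` takes an optional third element,
# the delimiter (default ",").

bt_reducers <- c(
  "sum", "mean", "median", "sd", "var", "min", "max",
  "count", "count_distinct", "concat", "first", "last"
)

normalize_aggs <- function(aggs, schema) {
  if (is.null(aggs) || length(aggs) == 0) {
    return(list())
  }
  if (is.null(names(aggs)) || any(!nzchar(names(aggs)))) {
    abort("every agg entry must be named", class = "bedtbl_bad_agg")
  }
  if (anyDuplicated(names(aggs))) {
    abort("duplicate agg output names", class = "bedtbl_bad_agg")
  }
  clash <- intersect(names(aggs), schema)
  if (length(clash) > 0) {
    abort(
      paste0("agg output name collides with input column: ", paste(clash, collapse = ", ")),
      class = "bedtbl_agg_name_collision"
    )
  }
  out <- lapply(aggs, function(spec) {
    if (is.character(spec) && length(spec) == 1 && grepl(":", spec)) {
      spec <- strsplit(spec, ":", fixed = TRUE)[[1]]
    }
    reducer <- spec[[1]]
    if (!reducer %in% bt_reducers) {
      abort(paste0("unknown reducer: ", reducer), class = "bedtbl_unknown_reducer")
    }
    column <- if (length(spec) >= 2) spec[[2]] else NA_character_
    if (reducer != "count") {
      if (is.na(column)) {
        abort(paste0("reducer `", reducer, "` needs a source column"),
          class = "bedtbl_bad_agg"
        )
      }
      if (!column %in% schema) {
        abort(paste0("unknown agg source column: ", column),
          class = "bedtbl_unknown_column"
        )
      }
    }
    delim <- if (length(spec) >= 3) spec[[3]] else ","
    list(reducer = reducer, column = column, delim = delim)
  })
  out
}

# apply a normalized agg spec to member rows -> one-row tibble
apply_aggs <- function(df, aggs) {
  vals <- lapply(aggs, function(a) {
    v <- if (!is.na(a$column)) df[[a$column]] else NULL
    switch(a$reducer,
      sum = sum(v, na.rm = TRUE),
      mean = mean(v, na.rm = TRUE),
      median = stats::median(v, na.rm = TRUE),
      sd = stats::sd(v, na.rm = TRUE),
      var = stats::var(v, na.rm = TRUE),
      min = min(v, na.rm = TRUE),
      max = max(v, na.rm = TRUE),
      count = nrow(df),
      count_distinct = length(unique(v)),
      concat = paste(v, collapse = a$delim),
      first = v[1],
      last = v[length(v)]
    )
  })
  tibble::as_tibble(vals)
}
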