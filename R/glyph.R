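# Operation glyphs: small labeled-track figures showing the inputs and the
# output of an interval operation, in the style of genome-arithmetic
# documentation. The model is renderer-independent so the result can be
# tested without graphics; text/SVG/PNG backends are thin.

#' Build a glyph model for an interval operation
#'
#' Executes the named operation on the given inputs and assembles a model
#' with one track per named input plus one result track labeled with the
#' rendered call (e.g. `"bed_intersect(x, y)"`). The result track always
#' equals running the operation directly. Operations returning scalar
#' statistics cannot be drawn.
#'
#' @param op_name name of a single- or two-input interval operation of this
#'   package (e.g. `"bed_merge"`, `"bed_intersect"`).
#' @param inputs named list of interval tibbles; names become track labels.
#' @param op_args list of further arguments passed to the operation.
#' @param label_col optional column whose values label individual intervals.
#' @return a `glyph_model` object with `tracks`, `result_label` and `range`.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(25, 100), end = c(50, 125))
#' y <- tibble::tibble(chrom = "chr1", start = 30, end = 75)
#' bed_glyph("bed_intersect", list(x = x, y = y))
#' @export
bed_glyph <- function(op_name, inputs, op_args = list(), label_col = NULL) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    abort("`inputs` must be a fully named list of interval tables",
      class = "bedtbl_bad_args"
    )
  }
  fn <- tryCatch(
    get(op_name, envir = asNamespace("bedtbl"), mode = "function"),
    error = function(e) {
      abort(paste0("unknown operation: ", op_name), class = "bedtbl_bad_args")
    }
  )
  result <- suppressWarnings(do.call(fn, c(unname(inputs), op_args)))
  drawable <- is.data.frame(result) && "chrom" %in% names(result) &&
    (all(c("start", "end") %in% names(result)) ||
      all(c("start.x", "end.x", "start.y", "end.y") %in% names(result)))
  if (!drawable) {
    abort(paste0("operation `", op_name, "` does not return drawable intervals"),
      class = "bedtbl_not_glyphable"
    )
  }
  # two-set pair output: draw the intersected spans from the suffixed coords
  if (!"start" %in% names(result)) {
    result <- tibble(
      chrom = result$chrom,
      start = pmax(result$start.x, result$start.y),
      end = pmin(result$end.x, result$end.y)
    )
  }
  result_label <- paste0(op_name, "(", paste(names(inputs), collapse = ", "), ")")
  tracks <- c(inputs, stats::setNames(list(dplyr::ungroup(result)), result_label))
  coords <- dplyr::bind_rows(lapply(tracks, function(t) {
    dplyr::ungroup(t)[c("start", "end")]
  }))
  if (nrow(coords) == 0) {
    rng <- c(0, 1)
  } else {
    lo <- min(coords$start)
    hi <- max(coords$end)
    pad <- 0.02 * max(hi - lo, 1) # cosmetic 2% pad, fixed for snapshots
    rng <- c(lo - pad, hi + pad)
  }
  structure(
    list(
      tracks = tracks,
      result_label = result_label,
      range = rng,
      label_col = label_col
    ),
    class = "glyph_model"
  )
}

#' @export
print.glyph_model <- function(x, ...) {
  cat(render_glyph_text(x), sep = "\n")
  invisible(x)
}

#' Render a glyph model
#'
#' Writes a deterministic rendering of a [bed_glyph()] model. The `text`
#' format draws ASCII tracks (byte-stable across runs, suitable for
#' snapshot tests); `svg` writes a standalone well-formed SVG document;
#' `png` draws through the grDevices bitmap device.
#'
#' @param m a `glyph_model`.
#' @param sink output file path (or connection for text/svg).
#' @param format `"text"`, `"svg"` or `"png"`.
#' @return `sink`, invisibly.
#' @export
render_glyph <- function(m, sink, format = c("text", "svg", "png")) {
  format <- match.arg(format)
  switch(format,
    text = writeLines(render_glyph_text(m), sink),
    svg = writeLines(render_glyph_svg(m), sink),
    png = render_glyph_png(m, sink)
  )
  invisible(sink)
}

glyph_rows <- function(track, label_col) {
  t <- dplyr::ungroup(track)
  labels <- if (!is.null(label_col) && label_col %in% names(t)) {
    as.character(t[[label_col]])
  } else {
    rep(NA_character_, nrow(t))
  }
  tibble(start = t$start, end = t$end, label = labels)
}

render_glyph_text <- function(m, width = 60) {
  rng <- m$range
  span <- max(rng[2] - rng[1], 1)
  col_of <- function(p) pmin(width, pmax(1, 1 + floor((p - rng[1]) / span * (width - 1))))
  lab_w <- max(nchar(names(m$tracks))) + 2
  lines <- character()
  for (nm in names(m$tracks)) {
    rows <- glyph_rows(m$tracks[[nm]], m$label_col)
    if (nrow(rows) == 0) {
      lines <- c(lines, paste0(formatC(nm, width = lab_w, flag = "-"), "(empty)"))
      next
    }
    for (i in seq_len(nrow(rows))) {
      c1 <- col_of(rows$start[i])
      c2 <- max(col_of(rows$end[i]) - 1, c1)
      bar <- rep(" ", width)
      bar[c1:c2] <- "="
      txt <- paste0(
        formatC(if (i == 1) nm else "", width = lab_w, flag = "-"),
        paste(bar, collapse = "")
      )
      if (!is.na(rows$label[i])) txt <- paste0(txt, " ", rows$label[i])
      lines <- c(lines, sub(" +$", "", txt))
    }
    lines <- c(lines, "")
  }
  ruler <- paste0(
    formatC("", width = lab_w), format(rng[1], digits = 6), " .. ",
    format(rng[2], digits = 6)
  )
  c(lines, ruler)
}

render_glyph_svg <- function(m, width = 600, track_h = 40) {
  rng <- m$range
  span <- max(rng[2] - rng[1], 1)
  xpos <- function(p) 100 + (p - rng[1]) / span * (width - 120)
  n_rows <- sum(vapply(m$tracks, function(t) max(1L, nrow(t)), integer(1)))
  height <- 20 + n_rows * track_h
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
      width, height
    )
  )
  yy <- 10
  fills <- c("#4878d0", "#ee854a", "#6acc64", "#d65f5f", "#956cb4")
  ti <- 0
  for (nm in names(m$tracks)) {
    ti <- ti + 1
    fill <- fills[(ti - 1) %% length(fills) + 1]
    rows <- glyph_rows(m$tracks[[nm]], m$label_col)
    out <- c(out, sprintf(
      "<text x=\"5\" y=\"%d\" font-size=\"12\" font-family=\"monospace\">%s</text>",
      yy + 18, esc(nm)
    ))
    if (nrow(rows) == 0) yy <- yy + track_h
    for (i in seq_len(nrow(rows))) {
      x1 <- xpos(rows$start[i])
      x2 <- xpos(rows$end[i])
      out <- c(out, sprintf(
        "<rect x=\"%.2f\" y=\"%d\" width=\"%.2f\" height=\"20\" fill=\"%s\" stroke=\"black\"/>",
        x1, yy + 4, max(x2 - x1, 1), fill
      ))
      if (!is.na(rows$label[i])) {
        out <- c(out, sprintf(
          "<text x=\"%.2f\" y=\"%d\" font-size=\"10\" font-family=\"monospace\">%s</text>",
          x1, yy + 2, esc(rows$label[i])
        ))
      }
      yy <- yy + track_h
    }
  }
  c(out, "</svg>")
}

render_glyph_png <- function(m, sink, width = 600, height = NULL) {
  n_rows <- sum(vapply(m$tracks, function(t) max(1L, nrow(t)), integer(1)))
  height <- height %||% (40 + n_rows * 40)
  grDevices::png(sink, width = width, height = height)
  on.exit(grDevices::dev.off())
  rng <- m$range
  graphics::par(mar = c(2, 8, 1, 1))
  graphics::plot(NULL,
    xlim = rng, ylim = c(0, n_rows + 1), yaxt = "n",
    xlab = "", ylab = "", bty = "n"
  )
  yy <- n_rows
  for (nm in names(m$tracks)) {
    rows <- glyph_rows(m$tracks[[nm]], m$label_col)
    graphics::mtext(nm, side = 2, at = yy, las = 1, cex = 0.8)
    if (nrow(rows) == 0) {
      yy <- yy - 1
      next
    }
    for (i in seq_len(nrow(rows))) {
      graphics::rect(rows$start[i], yy - 0.3, rows$end[i], yy + 0.3, col = "steelblue")
      if (!is.na(rows$label[i])) {
        graphics::text((rows$start[i] + rows$end[i]) / 2, yy + 0.45, rows$label[i], cex = 0.7)
      }
      yy <- yy - 1
    }
  }
  invisible(sink)
}
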