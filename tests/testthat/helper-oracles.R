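# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately use naive all-pairs scans so they share no code with
# the engine they check.

bed3 <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

toy_genome <- function(...) {
  entries <- c(...)
  tibble::tibble(chrom = names(entries), size = unname(entries))
}

# all-pairs overlap oracle; honors chrom plus any extra key columns
brute_overlap_pairs <- function(x, y, keys = character()) {
  x <- dplyr::ungroup(x)
  y <- dplyr::ungroup(y)
  grid <- expand.grid(xi = seq_len(nrow(x)), yi = seq_len(nrow(y)))
  keep <- x$chrom[grid$xi] == y$chrom[grid$yi]
  for (k in keys) {
    keep <- keep & x[[k]][grid$xi] == y[[k]][grid$yi]
  }
  ov <- pmin(x$end[grid$xi], y$end[grid$yi]) - pmax(x$start[grid$xi], y$start[grid$yi])
  keep <- keep & ov > 0
  out <- tibble::tibble(
    chrom = x$chrom[grid$xi],
    start.x = x$start[grid$xi], end.x = x$end[grid$xi],
    start.y = y$start[grid$yi], end.y = y$end[grid$yi],
    .overlap = as.integer(ov)
  )[keep, , drop = FALSE]
  out[order(out$chrom, out$start.x, out$end.x, out$start.y, out$end.y), ]
}

# brute-force nearest distances under the signed convention
brute_nearest_dist <- function(xs, xe, ys, ye) {
  d <- mapply(function(s, e) {
    ov <- pmin(e, ye) - pmax(s, ys)
    ifelse(ov > 0, 0L, ifelse(ys >= e, ys - e + 1L, ye - s - 1L))
  }, xs, xe, SIMPLIFY = FALSE)
  vapply(d, function(v) v[which.min(abs(v))], numeric(1))
}

# total covered bp of a possibly-overlapping set, by merged sweep
brute_bp <- function(x) {
  x <- dplyr::ungroup(x)
  total <- 0
  for (chrom in unique(x$chrom)) {
    s <- x$start[x$chrom == chrom]
    e <- x$end[x$chrom == chrom]
    o <- order(s)
    s <- s[o]
    e <- e[o]
    cur_s <- s[1]
    cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) {
        total <- total + cur_e - cur_s
        cur_s <- s[i]
        cur_e <- e[i]
      } else {
        cur_e <- max(cur_e, e[i])
      }
    }
    total <- total + cur_e - cur_s
  }
  total
}

# intersection bp of two sets by position-wise sweep over merged edges
brute_intersect_bp <- function(x, y) {
  total <- 0
  for (chrom in union(x$chrom, y$chrom)) {
    xs <- x[x$chrom == chrom, , drop = FALSE]
    ys <- y[y$chrom == chrom, , drop = FALSE]
    if (nrow(xs) == 0 || nrow(ys) == 0) next
    for (i in seq_len(nrow(xs))) {
      total <- total + sum(pmax(
        0,
        pmin(xs$end[i], ys$end) - pmax(xs$start[i], ys$start)
      ))
    }
  }
  total
}

# the paper's strand-grouped worked tables
worked_x <- function() {
  group_table(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1, 50, 100),
    end = c(100, 150, 200),
    strand = c("+", "+", "-")
  ), "strand")
}

worked_y <- function() {
  group_table(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(50, 50, 50),
    end = c(125, 150, 150),
    strand = c("+", "-", "+")
  ), "strand")
}

pair_key <- function(p) {
  paste(p$chrom, p$start.x, p$end.x, p$start.y, p$end.y, p$.overlap)
}

run_cli <- function(args) {
  out <- tempfile()
  err <- tempfile()
  code <- paste0(
    "status <- bedtbl::run_command(c(",
    paste(sprintf("'%s'", args), collapse = ","),
    ")); quit(save='no', status=status)"
  )
  status <- system2("Rscript", c("-e", shQuote(code)), stdout = out, stderr = err)
  list(
    status = status,
    stdout = readLines(out, warn = FALSE),
    stderr = readLines(err, warn = FALSE)
  )
}
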