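---
title: "Interval arithmetic in bedtbl: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval arithmetic in bedtbl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedtbl)
```

## The data model

An interval table is a tibble with at least `chrom` (character), `start`
and `end` (numeric, base pairs). Coordinates are **0-based, half-open**
throughout, as in BED files: an interval covers positions
`start, start+1, ..., end-1`, its width is `end - start`, and two intervals
overlap exactly when `max(start1, start2) < min(end1, end2)`. A
consequence worth internalizing is that *book-ended* intervals — where one
ends precisely where the other starts — share no base and never count as
overlapping.

Every exported operation returns rows sorted by `(chrom, start, end)`,
with chromosomes compared **bytewise** (so `"chr10" < "chr2"`). Genome-file
order is deliberately not preserved: bytewise order is deterministic and
locale-independent, which matters more for reproducibility than cosmetic
`chr1..chr22` ordering.

A *genome* is a two-column tibble of chromosome names and sizes. It bounds
all coordinate arithmetic: `bed_slop()`, `bed_shift()` and `bed_flank()`
clamp into `[0, size]`, `bed_complement()` tiles `[0, size)`, and the
randomizers only propose positions that fit. Rows on chromosomes missing
from the genome are dropped with a warning rather than raising an error;
interval sets routinely contain scaffolds absent from an analysis genome,
and a hard error there would make pipelines brittle.

**Zero-width intervals.** Trimming can legitimately produce zero-width
rows (e.g. shifting an interval flush against a chromosome end). They
carry no bases, so operations that would emit them drop them with a
warning; `validate_table()` flags them on input but does not reject, since
width-0 rows are occasionally used as point markers. Point features such
as transcription start sites should be width-1 intervals.

## Grouping

Grouping uses `dplyr::group_by()` directly: `group_table(x, "strand")` is
a validated wrapper. `chrom` is an implicit grouping everywhere and may
not be named explicitly. Single-set operations run per
(chromosome × group values); two-set operations require the two tables to
carry the *same* grouping columns and pair only partitions whose values
agree. `"."` (unstranded) is an ordinary group value, not missing data —
`flip_strands()` therefore swaps `+`/`-` and leaves `.` alone, which keeps
the function an involution.

## The overlap engine

Each partition of `y` is held in sorted order; a query `[xs, xe)` first
narrows to candidates with `start < xe` by binary search
(`findInterval`) over the sorted starts, then filters by `end > xs`. This
is the classical sorted-list formulation of an interval index; the
engine's contract is purely the query invariant (return exactly the rows
with `max(starts) < min(ends)`), and the test suite enforces it against an
all-pairs brute-force oracle on randomized tables (50 seeds × 200
intervals in the acceptance suite) rather than against any particular
tree structure. Rows with identical coordinates are kept in stable input
order, and all of them are reported.

`nearest_join()` adds the distance search: overlapping rows dominate at
distance 0; otherwise the nearest upstream (largest `end <= start.x`) and
downstream (smallest `start >= end.x`) candidates are compared and all
ties at the minimal absolute distance are returned. The signed convention
is:

* overlap → `0`
* downstream `y` → `start.y - end.x + 1` (book-ended neighbour: `+1`)
* upstream `y` → `end.y - start.x - 1` (book-ended neighbour: `-1`)

so negative distances always denote upstream neighbours, and the off-by-one
keeps "book-ended" distinguishable from "overlapping". When an overlap
exists, equally-near non-overlapping neighbours (at distance ±1) are *not*
reported: distance 0 strictly dominates.

## Single-set numerics

* `bed_merge()` unions intervals whose gap is at most `max_dist` (gap 0 =
  book-ended, merged at the default `max_dist = 0`); it is idempotent.
  Grouping columns survive; other extra columns are dropped unless
  summarised via an aggregation spec, because their values are ill-defined
  after union.
* `bed_cluster()` computes the same components but labels instead of
  merging; ids are consecutive integers in global sorted order.
* `bed_makewindows()` in `win_size` mode emits full windows with any
  remainder as a final shorter window (a width-2001 region with 50-bp
  windows gives 41, the last of width 1). In `num_win` mode sizes differ
  by at most 1 with the larger windows first — the placement is arbitrary
  but fixed and documented, so downstream window numbering is stable.
  `reverse = TRUE` numbers windows descending, which is how minus-strand
  features get 5′→3′ window ids.
* `bed12_to_exons()` numbers exon ranks 5′→3′ (descending along the genome
  on `-` transcripts) and stores the rank in `score`, yielding standard
  BED6.
* Aggregation specs are named lists of `(reducer, column)` pairs —
  `list(win_sum = c("sum", "value"))` — with reducers `sum, mean, median,
  sd, var, min, max, count, count_distinct, concat, first, last`. Numeric
  reducers are missing-value-aware (`na.rm = TRUE`). The same spec
  grammar drives `bed_map()`, `bed_merge()` and the CLI's
  `--agg out=reducer:column` flags; columns are always referred to by
  name, never by position.

`bed_map()` keeps every x row: rows with no overlapping y get `NA`
aggregates, not 0. A missing-aware mean downstream (as in the TSS profile
below) then simply ignores them; conflating "no data" with "signal 0"
would bias profiles toward zero in sparse regions.

## Randomization

All stochastic functions take an explicit `seed`; when supplied, the
Mersenne-Twister stream is seeded locally and the caller's RNG state is
restored, so there is no hidden global state and identical seeds give
identical tables. `bed_random()` draws chromosomes with probability
proportional to size and starts uniformly on `[0, size - length]`.
`bed_shuffle()` relocates each row at its original width — per-chromosome
by default, size-weighted across chromosomes with
`within_chrom = FALSE` — sampling uniformly over the allowed regions
(`incl` if given, otherwise whole chromosomes) and rejecting placements
that touch `excl`, up to `max_tries` per row before a loud, row-naming
error. Rejection sampling was chosen over carving `excl` out of the
allowed space: it is simpler to verify, exactly uniform over the feasible
space, and failure is explicit rather than silent. Shuffled rows may land
on top of each other; placements are independent, which is the correct
null for the overlap statistics here.

## Overlap statistics

`bed_jaccard()` merges both inputs, then reports `len_i` (intersection
bp), `len_u` (sum of merged bp), `jaccard = len_i / (len_u - len_i)` —
i.e. intersection over union, with the union expressed through the sum —
and `n`, the number of intersecting pairs between the merged sets.

The remaining statistics follow the conventions of the genome-arithmetic
tools they are named after, documented here because no single canonical
formula exists:

* **projection**: per chromosome, `successes` = x midpoints inside merged
  y, `p0` = merged y bp / chromosome size, exact two-sided
  `binom.test(successes, trials, p0)`; `obs_exp_ratio = successes /
  (trials * p0)`.
* **fisher**: contingency table `n11` = x rows overlapping any y, `n12 =
  |x| - n11`, `n21 = max(0, |y| - n11)` (each set counted from its own
  perspective; reciprocal overlap counts can differ and are not
  subtracted), `n22` = remaining genome capacity in units of the mean
  interval width of the combined sets, floored at 0. The genome "slots"
  are not true independent trials, so the p-value is a screening statistic,
  not a calibrated error rate — the projection test is the better-founded
  of the two.
* **reldist**: midpoint of x relative to its two flanking y midpoints,
  `min(m - l, r - m) / (r - l)` in `[0, 0.5]`; x rows without two flanks
  are omitted; the histogram form uses 0.05-wide bins. Under independence
  the mean is 0.25, which the suite verifies on 10,000 uniform draws.
* **absdist**: nearest y-midpoint distance, plus a scaled form multiplied
  by per-chromosome y density (`count / size`) so chromosomes of different
  sizes and coverages are comparable.

`empirical_pvalue()` implements the add-one estimator
`(#{null ≥ obs} + 1) / (n + 1)`: with zero exceedances among 100
replicates it returns 1/101 ≈ 0.0099, and it can never return 0 — the
observed value is itself one draw from the null when the null is true.
`shuffle_null()` produces the replicate vector (jaccard, or genome-wide
projection success fraction) from seeded shuffles.

## The synthetic-signal generator

`make_tss_signal()` emits bedGraph rows in 10-bp steps around each width-1
TSS: a baseline, plus a Gaussian bump centered on the TSS midpoint
(height 100, sigma 200 bp by default — promoter-scale enrichment), plus
i.i.d. normal noise. The 10-bp step is a compromise between the
resolution of real coverage tracks and test speed. The generator emulates
the *shape* of promoter-proximal ChIP enrichment only: it does not model
read sampling noise, mappability gaps, strand asymmetry, or
copy-number-driven baseline shifts. Passing the pipeline-recovery test
(slop 1000 → 50-bp windows → map sum → per-window mean peaks at the
center window, 21 of 41) therefore demonstrates that the *arithmetic* is
correct end-to-end, not that the package handles every pathology of real
coverage data.

## Problem sizes and tolerances

The test suite runs entirely on generated data at desk scale: engine
oracles use 50 seeds × 200 intervals, property checks use tables of
100–300 intervals over 2–3 synthetic chromosomes, the reldist calibration
uses 10,000 uniform draws (±0.01 on the 0.25 expectation), and projection
p-values are required to match an independent binomial-density oracle to
1e-12. One acceptance test reproduces published chr22 pipeline numbers
and needs the corresponding public data files; it fails informatively when
they are not present rather than silently skipping.

## Known limitations

* No BigWig/BAM/tabix input and no remote genome-database connectors;
  files are plain or gzipped text.
* No fractional-overlap thresholds on intersection, and no k-way joins in
  the engine (compose two-set operations instead).
* `bed_fisher()`'s table construction is a convention (see above).
* Shuffling is uniform: no GC-, gap- or spacing-matched nulls.
* The engine's candidate filter scans all y with `start < end.x`; deeply
  nested interval sets degrade toward linear scans per query. At the
  package's intended interactive scales (10⁴–10⁶ rows) this has not been
  limiting.
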