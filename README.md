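# bedtbl

Genome interval arithmetic on tidy data frames.

Much of regulatory genomics reduces to questions about sets of genomic
intervals: which SNPs fall inside exons, how ChIP-seq signal distributes
around transcription start sites, whether two feature sets overlap more than
chance would allow. `bedtbl` answers these questions entirely inside R.
Interval tables are ordinary tibbles with `chrom`, `start`, `end` columns
(0-based, half-open BED coordinates), so they compose directly with
dplyr/ggplot2 pipelines; a command-line front end exposes the same
operations over files for shell pipelines.

The package provides:

- **Readers/writers** for BED3/6/12, bedGraph, narrowPeak/broadPeak,
  chrom.sizes ("genome") files and the coordinate fields of VCF, with
  transparent gzip handling (detected from content, not extension).
- **An interval-search engine** (`overlap_join()`, `nearest_join()`)
  locating overlapping and nearest intervals per chromosome partition by
  binary search over sorted starts. Two intervals overlap iff
  `max(start1, start2) < min(end1, end2)`; book-ended intervals
  (`end1 == start2`) do not overlap.
- **Single-set operations**: `bed_slop`, `bed_shift`, `bed_flank`,
  `bed_merge`, `bed_cluster`, `bed_complement`, `bed_makewindows`,
  `bed12_to_exons`, `bound_intervals`, `interval_spacing`, `flip_strands`.
- **Two-set operations**: `bed_intersect`, `bed_map`, `bed_subtract`,
  `bed_window`, `bed_closest`. All operations honour `dplyr::group_by()`
  groupings (e.g. by `strand`), pairing only subsets whose grouping values
  agree.
- **Randomization**: seeded `bed_random` (size-weighted chromosome choice)
  and `bed_shuffle` (rejection sampling against include/exclude regions).
- **Overlap statistics**: `bed_jaccard`, `bed_projection`, `bed_fisher`,
  `bed_reldist`, `bed_absdist`, plus `shuffle_null()` /
  `empirical_pvalue()` for permutation testing.
- **Glyphs**: `bed_glyph()` renders the inputs and output of an operation
  as labeled tracks (text/SVG/PNG) for teaching and documentation.

## The statistics in brief

For merged interval sets *x* and *y* with intersection `len_i` bp and
`len_u` = bp(*x*) + bp(*y*):

```
jaccard(x, y) = len_i / (len_u - len_i)        # intersection / union
```

The **projection test** models, per chromosome, the number of *x* midpoints
falling inside *y* as Binomial(n_x, p₀) with p₀ = covered(*y*) / chrom size,
and reports the exact two-sided binomial p-value and observed/expected
ratio. The **relative distance** of an *x* midpoint *m* between flanking *y*
midpoints *l* ≤ *m* ≤ *r* is `min(m - l, r - m) / (r - l)` ∈ [0, 0.5], with
mean 0.25 under independence. Permutation significance uses the add-one
estimator

```
p = (#{null >= observed} + 1) / (n_reps + 1)
```

over statistics recomputed on seeded shuffles of *x*.

## A worked example

Strand-grouped intersection — only same-strand intervals are paired:

```r
library(bedtbl)
library(dplyr)

x <- tibble::tribble(
  ~chrom, ~start, ~end, ~strand,
  "chr1",      1,  100,  "+",
  "chr1",     50,  150,  "+",
  "chr2",    100,  200,  "-"
) |> group_by(strand)

y <- tibble::tribble(
  ~chrom, ~start, ~end, ~strand,
  "chr1",     50,  125,  "+",
  "chr1",     50,  150,  "-",
  "chr2",     50,  150,  "+"
) |> group_by(strand)

bed_intersect(x, y)
#> # A tibble: 2 × 8
#>   chrom start.x end.x strand.x start.y end.y strand.y .overlap
#>   <chr>   <dbl> <dbl> <chr>      <dbl> <dbl> <chr>       <int>
#> 1 chr1        1   100 +             50   125 +              50
#> 2 chr1       50   150 +             50   125 +              75
```

Two pairs survive: the chr2 intervals sit on opposite strands. `.overlap`
is the intersection width in bp (50 and 75 here). Flipping `y`'s strands
with `flip_strands(y)` instead pairs opposite strands and yields three rows
with overlaps 50, 100 and 50.

Operations can be drawn as glyphs:

```r
x <- tibble::tibble(chrom = "chr1", start = c(1, 10, 100), end = c(50, 75, 120))
bed_glyph("bed_merge", list(x = x))
#> x              =======================
#>                    ===============================
#>                                                               =========
#>
#> bed_merge(x)   ===================================
#>                                                               =========
#>
#>               -1.38 .. 122.38
```

The first two intervals overlap and merge into `[1, 75)`; the third is
disjoint and survives unchanged.

From the shell, the same operations run over files:

```sh
bedtbl merge peaks.bed --max-dist 10
bedtbl jaccard peaks.bed exons.bed
bedtbl shuffle peaks.bed --genome hg19.chrom.sizes --excl gaps.bed --seed 7
```

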