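Package: bedtbl
Title: Tidy Genome Interval Arithmetic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome interval arithmetic on tidy data frames. Reads BED,
    bedGraph, narrowPeak/broadPeak, chrom.sizes and VCF coordinate data into
    tibbles, performs grouped single-set and two-set interval operations
    (merge, complement, intersect, subtract, closest, map, windows and more)
    with an interval-search engine honoring per-strand grouping, generates
    seeded random and shuffled interval sets, computes overlap-significance
    statistics (jaccard, projection, fisher, relative and absolute distances,
    shuffle-based empirical p-values) and renders operation glyphs for
    teaching and documentation. A command-line front end exposes the same
    operations over files for pipeline use.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
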