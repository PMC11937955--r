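Package: boundalign
Title: Exact Pairwise Edit-Distance Alignment by Bound-and-Align
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast exact pairwise edit-distance (Levenshtein) alignment of long,
    noisy nucleotide or arbitrary byte sequences using a bound-and-align
    strategy. A cascade of cheap heuristics (windowed score bounding with
    high-error-window detection, and banded alignment with band doubling)
    first computes an upper bound on the optimal alignment score; a
    score-bounded, tile-based bit-parallel aligner then computes the exact
    optimal score and CIGAR while restricting work to the part of the
    dynamic-programming matrix that the bound admits. A Hirschberg
    divide-and-conquer driver keeps traceback memory below a configurable
    threshold for very long sequences. Includes a synthetic pair generator,
    a quadratic dynamic-programming oracle for validation, file readers and
    writers for FASTA and a two-line pair format, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
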