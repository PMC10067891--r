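Package: dnacodes
Title: Constraint-Satisfying DNA Code Sets for Data Storage via Moth-Flame Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing robust codeword sets for DNA-based data
    storage. Provides combinatorial coding-constraint predicates (fixed
    GC content, homopolymer run-length limits, minimum pairwise Hamming
    distance, reverse-complement distance, and a secondary-structure stem
    screen), a moth-flame metaheuristic optimizer augmented with
    Levy-flight and opposition-based-learning mutation strategies, a
    greedy optimizer-driven search that constructs validated code sets
    and lower-bound tables, a benchmark-function harness with Wilcoxon
    rank-sum comparison, nearest-neighbor melting-temperature analysis
    of code sets, and a lossless binary-to-nucleotide codec.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
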