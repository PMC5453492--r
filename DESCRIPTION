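Package: satseeker
Title: De Novo Tandem Repeat Discovery and Abundance Ranking from
    Low-Coverage Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers high-copy tandem repeat (satellite) families de novo
    from low-coverage single-end shotgun reads and ranks them by genomic
    abundance. Reads are assembled into repeat-tolerant contigs with a de
    Bruijn graph assembler that recovers tandem arrays as unrolled cycles,
    tandem repeats are detected and scored by wraparound dynamic programming
    against a consensus monomer, reads are recruited back to tandem contigs
    to estimate per-family genomic fractions, and families are extracted by
    greedy seed-and-remove homology clustering with Karlin-Altschul E-value
    thresholds. A fully seeded simulator plants tandem families of known
    genomic fraction so that every stage of the pipeline is verifiable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    rlang,
    tibble,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
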