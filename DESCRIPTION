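Package: hyperedit
Title: Detection of Clustered A-to-I RNA Hyper-Editing from RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects dense clusters of A-to-I RNA editing ("hyper-editing")
    in RNA-seq reads that fail standard alignment. Unmapped reads are
    realigned after a transformed-alphabet substitution (e.g. all A bases
    rewritten to G in both reads and genome), native-alphabet mismatches
    are recovered, and reads carrying a dense cluster of identical
    mismatches are called hyper-edited. A twelve-mismatch-type screen
    gauges specificity, a per-million-mapped-bases normalization supports
    cross-dataset comparison, neighbour-nucleotide preferences around
    edited sites are profiled and clustered across datasets, and
    reverse-complement local alignment links editing clusters to
    double-stranded-RNA-forming genomic structure. A synthetic-data module
    generates genomes with repeat families and reads with planted editing,
    sequencing errors and SNPs, together with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
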