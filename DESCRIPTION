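Package: kmforge
Title: Joint Multi-Sample k-mer Counting and Partitioned Bloom Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs per-sample Bloom filters and k-mer count matrices
    from collections of short-read sequencing samples. Reads are decomposed
    into super-k-mers by minimizer, k-mers (or their hash values) are counted
    per partition with exclusive consecutive hash spaces, equivalent
    partitions are merged across samples, and low-abundance k-mers that are
    solid in enough other samples are rescued before binarization. Hash-major
    presence/absence sub-matrices are transposed into sample-major
    partitioned Bloom filters with partition-aware query. A synthetic
    community generator with known ground truth supports end-to-end
    evaluation of the filtering behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
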